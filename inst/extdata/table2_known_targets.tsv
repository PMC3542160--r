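mirna	target_gene	align_score	tpb	category	annotation	target_class
miR156	ppa006611m	3	150.2	3	Squamosa promoter-binding-like protein	conserved
miR156	ppa007056m	2	500.7	2	Squamosa promoter-binding-like protein	conserved
miR156	ppa021582m	2	1151.5	2	Squamosa promoter-binding-like protein	conserved
miR156	ppa024285m	3	3704.8	0	Squamosa promoter-binding-like protein	conserved
miR159	ppa003628m	3.5	2252.9	0	MYB transcription factor	conserved
miR160	ppa002082m	1	1301.7	2	Auxin response factor	conserved
miR160	ppa002710m	1	1251.6	2	Auxin response factor	conserved
miR164	ppa007653m	2.5	11214.7	0	NAC domain-containing protein	conserved
miR165	ppa001343m	2.5	2353.1	2	Homeobox-leucine zipper protein	conserved
miR165	ppa001378m	2.5	4856.3	0	Homeobox-leucine zipper protein	conserved
miR166	ppa001343m	3	2353.1	2	Homeobox-leucine zipper protein	conserved
miR166	ppa001378m	3	4856.3	0	Homeobox-leucine zipper protein	conserved
miR167	ppa001179m	4.5	1201.6	2	Auxin response factor	conserved
miR168	ppa000619m	4	275.4	2	Argonaute protein	conserved
miR168	ppa000900m	4	275.4	2	Argonaute protein	conserved
miR169	ppa006634m	3.5	1226.6	2	Nuclear transcription factor Y subunit A	conserved
miR390	AJ875750	NA	NA	NA	PpTAS3	conserved
miR393	ppa003344m	1	1401.8	2	Auxin signaling F-box protein	conserved
miR393	ppa003465m	2	550.7	3	Auxin signaling F-box protein	conserved
miR395	ppa002425m	2	600.8	2	Sulfate transmembrane transporter	conserved
miR396	ppa003017m	3.5	4005.2	0	Growth-regulating factor	conserved
miR396	ppa006912m	3	4956.5	2	Growth-regulating factor	conserved
miR396	ppa011917m	3.5	7960.4	0	Growth-regulating factor	conserved
miR396	ppa019623m	3	9312.2	0	Growth-regulating factor	conserved
miR396	ppa021277m	4	22179.0	0	Growth-regulating factor	conserved
miR396	ppa022199m	3	28086.7	0	Growth-regulating factor	conserved
miR396	ppa024293m	3	700.9	2	Growth-regulating factor	conserved
miR397	ppa003308m	4	550.7	2	Laccase	conserved
miR397	ppa003408m	3	300.4	3	Laccase	conserved
miR397	ppa003646m	1.5	9011.8	0	Laccase	conserved
miR397	ppa003714m	3	400.5	3	Laccase	conserved
miR397	ppa022440m	1.5	250.3	3	Laccase	conserved
miR408	ppa018507m	1	1051.4	2	Copper ion binding protein	conserved
miR408	ppa021383m	3	3104.1	2	Copper ion binding protein	conserved
Tas3-siRNA	ppa001557m	2	650.9	2	Auxin response factor	conserved
Tas3-siRNA	ppa001392m	1.5	22529.4	2	Auxin response factor	conserved
miR396	ppa003643m	4	400.5	3	Rho guanyl-nucleotide exchange factor	novel_for_conserved
miR408	ppa004802m	3.5	500.7	3	Selenium-binding protein	novel_for_conserved
miR408	ppa007350m	4	3404.4	2	Cyclin D3	novel_for_conserved
miR505	ppa012208m	4.5	275.4	2	ATP synthase	other_known
miR505	ppa012241m	4.5	275.4	2	ATP synthase	other_known
miR530	ppa004922m	4	50.1	4	ATP binding	other_known
miR828	ppa010908m	1	55247.2	0	MYB transcription factor	other_known
miR828	ppa016135m	3	2152.8	2	MYB transcription factor	other_known
miR828	ppa024533m	2	1852.4	2	MYB transcription factor	other_known
miR858	ppa005421m	4.5	851.1	2	3-ketoacyl-CoA thiolase	other_known
miR858	ppa006057m	4.5	851.1	2	3-ketoacyl-CoA thiolase	other_known
miR858	ppa006769m	4	150.2	3	MYB transcription factor	other_known
miR858	ppa009143m	4	150.2	3	MYB transcription factor	other_known
miR858	ppa010252m	4	3754.9	2	MYB transcription factor	other_known
miR858	ppa015883m	3	650.9	0	MYB transcription factor	other_known
miR858	ppa016135m	3.5	16481.5	2	MYB transcription factor	other_known
miR858	ppa016385m	4	1201.6	0	MYB transcription factor	other_known
miR858	ppa016708m	4.5	650.9	2	MYB transcription factor	other_known
miR858	ppa017136m	3.5	35.0	3	MYB transcription factor	other_known
miR858	ppa018561m	4	1201.6	2	MYB transcription factor	other_known
miR858	ppa019380m	4	35.0	1	MYB transcription factor	other_known
miR858	ppa022205m	4	4070.3	0	MYB transcription factor	other_known
miR858	ppa022431m	4.5	6959.1	2	MYB transcription factor	other_known
miR858	ppa022465m	3.5	16481.5	0	MYB transcription factor	other_known
miR858	ppa023768m	2.5	3704.8	2	MYB transcription factor	other_known
miR858	ppa023812m	3.5	4070.3	0	MYB transcription factor	other_known
miR858	ppa024074m	4.5	4070.3	0	MYB transcription factor	other_known
miR894	ppa005211m	4	300.4	3	Ankyrin repeat family protein	other_known
miR2478	ppa024560m	4.5	300.4	3	Disease resistance-responsive protein	other_known
miR2911	ppa004713m	4.5	2052.7	2	Vacuolar processing enzyme	other_known
miR2916	ppa008099m	4.5	200.3	2	Galacturonosyltransferase-like protein	other_known
miR4171-5	ppa010474m	4.5	650.9	2	C3HC4-type RING finger family protein	other_known
miR4171-5	ppa012554m	4	150.2	3	Universal stress protein (USP)	other_known
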