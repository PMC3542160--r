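---
title: "Methods: small-RNA discovery, degradome validation and phasing in mirphas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-RNA discovery, degradome validation and phasing in mirphas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mirphas)
```

# Scope

`mirphas` re-implements, at desk scale, the computational core of a plant
small-RNA study: discovery of miRNAs from deep-sequenced small-RNA
libraries (known-family assignment plus hairpin-based de novo calling),
degradome (PARE) validation of cleavage targets with category
classification, 21-nt phasing-register analysis of tasiRNA-producing loci,
and precursor-processing statistics from blot band intensities. Every
stage is exercised against a bundled synthetic-data generator with planted
ground truth, so the whole pipeline is testable without external
downloads.

# Read processing

Raw reads are 3'-adapter trimmed (leftmost full occurrence, or a terminal
suffix-prefix overlap of at least `min_overlap = 6` nt; reads without
adapter evidence are discarded), length-filtered to 15-31 nt, collapsed to
unique tags with per-library counts, and mapped to the genome by exact
full-length matching on both strands (`Biostrings::matchPDict`, grouped by
tag width). Normalisation is reads per million (rpm): a tag's count scaled
by $10^6$ over the library's genome-matched *redundant* read total — not
the unique tag count — because perfectly genome-matched reads define the
usable sequencing effort of a library. Minus-strand hits report the
forward-strand start coordinate, matching the usual match-site
presentation of miRNA tables.

Coordinates are held 1-based inclusive internally (the native convention
of R and Bioconductor ranges); emitted BED is 0-based half-open via
`rtracklayer`. This deviates from an early design sketch that called for
0-based internal coordinates; in R the 1-based representation removes a
conversion layer at every Bioconductor boundary.

# Known-family assignment and ncRNA screening

Tags of 20-22 nt are compared to reference sets by ungapped alignment with
at most two mismatches. Against mature miRNA references the tag's 5' end
may sit within ±2 nt of the reference 5' end and reference length must be
within 2 nt; against ncRNA references (rRNA/tRNA/snoRNA fragments) the tag
slides freely with up to 2 nt of terminal overhang tolerated. The
two-mismatch rule is ungapped by construction — an indel would shift the
register of everything downstream, which the rule's mismatch counting
cannot represent. A tag within two mismatches of both an ncRNA and a
miRNA reference is resolved toward the *closer* reference, ties toward
the miRNA; this avoids discarding genuine miRNAs shadowed by ncRNA
look-alikes, a case the removal-first ordering leaves undefined.
Equidistant references are resolved by (mismatches, |length difference|,
reference name), so assignment is deterministic.

# Hairpin discovery

## Folding contract

Candidate precursor windows (three per genome hit: tag-at-5'-end,
tag-at-3'-end, centered; flank 150 nt, capped at 400 nt) are folded by
maximum base pairing — a Nussinov dynamic program over A-U/G-C/G-U pairs
with a minimum hairpin loop of 3 nt and a deterministic traceback
(5'-most partner preferred on ties). Maximum-pairing rather than
thermodynamic MFE is the deliberate contract: results are exactly
reproducible and testable against an independent recursion, and a
thermodynamic backend can replace the folder without touching the duplex
evaluation downstream. The flank default covers the 90-130 nt precursor
range typically observed for plant pre-miRNAs with margin on both arms.

## Duplex evaluation

The fold determines the arm (majority side of the mature core's
partners) and *candidate duplex registers*: along a clean helix,
`partner(i) + i` is constant, so the most frequent register values (top
3) each propose a star interval, refined by a ±2 nt local search. For
each candidate star interval the mature core (mature minus its 2-nt 3'
overhang) is aligned antiparallel against the proposed star region by a
small alignment DP (pair gain 1 for canonical and G:U pairs, gap penalty
0.6, diagonal preferred on ties). Aligned non-pairing columns count as
mismatches (this covers symmetric internal loops, one count per mature
position); maximal gap runs on either strand count as bulges. The locus
qualifies when *any* candidate interval yields at most 4 mismatches and
at most 1 bulge; among candidates, qualifying intervals are preferred,
then lowest defect load (a bulge weighing two mismatches), then proximity
to the register projection.

Why not count mismatches directly off the global fold? A maximum-pairing
fold absorbs true duplex mismatches by locally re-pairing bases into
shifted registers or into the loop, so unpaired-position counts on the
fold systematically under- and over-shoot. The gap penalty of 0.6 is the
smallest value that stops the aligner from trading one honest mismatch
column for two gap runs plus a rescued pair (which needs `2·gp > 1`),
while still permitting the single forced gap of a genuinely bulged
duplex. The bulge weight of 2 in the selection key prevents a shifted
interval from undercutting the true one by converting a gap run into end
mismatches.

## Star detection, support fractions, classification

A star read is any read whose 5' end lies within 1 nt of the predicted
star 5' end with length within 2 nt — our reading of the standard
annotation criteria; the tolerance is not prescribed by them. Support
requires, strictly, pair fraction > 0.75 (mature + star reads over all
same-strand reads in the window) and uniqueness fraction > 0.75 (reads
from tags whose every genome hit lies within the locus's accepted
windows). The uniqueness definition is locus-level read share; the
alternative tag-level multi-mapping reading of the rule is noted as
ambiguous. Multi-locus tags attribute their full read counts to each
accepted locus (no fractional apportioning), matching one-row-per-miRNA
reporting with multiple match sites. A locus is `novel` when a star read
is observed at any accepted locus and `candidate` otherwise; accepted
calls whose mature maps inside the accepted window of a higher-expressed
call are reported as that call's star strand rather than as a separate
miRNA, so each duplex yields one table row.

Candidate tags must further carry at least `min_reads = 5` total reads —
an expression floor in the spirit of the standard annotation criteria
that also keeps the folding workload proportional to plausible loci.

# Degradome validation

Target sites are scored in the Targetfinder lineage: mismatch 1.0, G:U
wobble 0.5, a single interior one-nucleotide gap 2.0, all penalties
doubled at miRNA positions 2-13 (5' end = position 1). The alignment is
antiparallel against the site read 5'→3'; per window start the best of
the ungapped and single-gap configurations is kept, the ungapped width
winning ties. Thresholds are 4.5 for conserved and less-conserved miRNAs
and 5 for novel and candidate miRNAs. Edge bulges are disallowed —
otherwise a gapped window could mimic the adjacent ungapped site at no
cost and every real site would be reported twice.

Degradome tags map to transcripts by exact match; the per-position count
of tag 5' ends forms the t-plot, normalised as tpb
(`raw × 10^9 / total mapped degradome tags` — the denominator is
transcriptome-mapped tags, i.e. normalisation within the degradome
library). The guided-cleavage position is the transcript base facing
miRNA position 10 (cut between 10 and 11, the standard plant slicing
register). With `r` the raw count there, `M` the transcript maximum and
`med` the median over covered positions (median over covered positions
only is our documented choice): category 4 if `r = 1`; else 3 if
`r ≤ med`; else 2 if `med < r < M`; else 1 if the maximum is tied; else
0. `r = 0` yields "no degradome evidence", not a category. A call is
emitted only for sites with `r ≥ 1`; below-threshold predictions without
degradome support are kept in a separate prediction list.

# Phasing

Reads of exactly 21 nt within the analysis span (anchor to anchor +
21 × 10 cycles by default; a span upstream of the anchor covers
dual-cleavage TAS3-like geometries, registers anchored at the 3' cleavage
site) are binned by `(position − anchor) mod 21` into the 21 radial-graph
registers. Register 0 is the in-phase register; per-tissue accumulation
totals register-0 reads per library. The optional enrichment statistic —
an upper-tail binomial test of the dominant register against success
probability 1/21, Bonferroni-corrected ×21 for register selection — is an
extension beyond the radial display and is off in report-shaped output.
Phased siRNAs are named by signed offset from the cleavage anchor
(`locus-siRNA(−81)` style); the offset convention (anchor = 0) is ours
and invertible, not asserted as anyone else's.

# Processing statistics

From blot band intensities: `APE = SFI × 100 / (LFI + SFI)` (percent of
locus signal in the processed small fragment) and
`RTA = (LFI + SFI) / CFI` (total locus signal over the loading-control
band). The coupling summary is the Spearman rank correlation of APE and
RTA across samples — rank-based because intensities are arbitrary units;
zero variance in either statistic flags the correlation as undefined
rather than returning a number.

# The synthetic world

The default simulated study plants, in a 8 × 50 kb toy genome
(GC 0.38, peach-like):

* ten novel miRNA hairpins whose mature sequences and four-tissue rpm
  profiles are patterned on published peach-specific miRNA abundances
  (totals roughly 500-23,000 rpm), with duplex defects spanning the
  accepted range (0-4 mismatches, 0-1 bulges) on alternating arms;
* two known trigger miRNAs (miR390- and miR828-family, with their real
  mature sequences in the known reference set);
* two TAS-like transcripts cleaved by the triggers, producing 8 cycles of
  21-nt phased siRNAs with a 10% off-phase noise fraction and
  leaf/flower- vs flower-skewed tissue profiles;
* sixteen degradome-validated targets across twelve miRNAs (the two TAS
  transcripts included), with planted alignment scores spanning 0-5 and
  guided-cleavage tag counts of 20-400 over Poisson background
  (0.02 tags/nt);
* a genomic background with the field's hallmark length distribution
  (24-nt mode, 21-nt secondary mode) filling 90% of each 50,000-read
  library.

Count noise is Poisson around the rpm expectations (negative binomial
available via `noise = "nbinom"`); no dispersion was published for the
profiles, so the noise magnitude is a stated choice, not a calibration.
Star reads are emitted at 30% of the mature expectation — chosen once so
that the weakest planted miRNA still leaves a few star reads at 50,000
reads per library, consistent with the substantial miRNA* accumulation
seen in real libraries. Hairpin loops are generated as self-folding
hairpins (random arm + GAAA apex + its reverse complement) so that the
planted stem remains the maximum-pairing optimum; real loops are less
structured, which is one reason a green recovery test does not establish
performance on thermodynamically marginal real precursors. Background
reads avoid a 200 nt exclusion zone around planted loci ("no
cross-mapping"); `cross_mapping = TRUE` lifts this. Negative-control
hairpins (5 mismatches; 2 bulges) use shift-intolerant matures (no lag-1
pairing equivalence) and a fixed loop, so their rejection is
deterministic.

What the generator does *not* emulate: genome repeat structure and
hc-siRNA clustering beyond the length distribution, multi-locus miRNA
families, sequencing errors, partial adapters (available as an option but
off by default), and thermodynamically suboptimal precursors. Green tests
therefore establish correctness of the rules and arithmetic, and recovery
under the stated world — not sensitivity on real tissue libraries.

# Configuration and reproducibility

Every numeric criterion lives in `pipeline_config()`: mismatch tolerance
2, duplex caps 4/1, strict support fractions 0.75, alignment thresholds
4.5/5, flank 150 nt, length window 15-31 nt, expression floor 5 reads.
Config round-trips through JSON (`jsonlite`); YAML was dropped because
the deployment stack carries no R YAML parser, and JSON loses nothing
here. All generators take explicit seeds and restore the caller's RNG
state; the full pipeline is byte-deterministic under a fixed seed, which
the acceptance suite asserts on the emitted tables.

# Known limitations

* Maximum-base-pair folding over-pairs relative to thermodynamic
  structure; the duplex-alignment evaluation compensates for defect
  counting, but arm/register determination can in principle be misled on
  highly self-similar sequences.
* The degradome scanner reports one site per window start; two
  overlapping biological sites closer than one miRNA length are merged
  into whichever start scores best.
* The uncoupling summary is descriptive; no multiple-testing control is
  applied across loci.
* De novo calling does not exclude phased-siRNA loci: an abundant
  in-register tasiRNA whose flanking window happens to admit a qualifying
  duplex can surface as a `candidate` miRNA. TAS loci are analysed
  separately by the phasing stage, mirroring how such loci are treated in
  practice; the recovery acceptance counts false calls as accepted loci
  overlapping *no* planted feature.
* Printed alignment scores in the reference target tables shipped as
  fixtures are not recomputable without the underlying sequences, and
  printed APE percentages are not recomputable without the underlying
  intensities; neither is used as a numeric target anywhere in the test
  suite.
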