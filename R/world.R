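# The default simulated study: ten specific (novel) miRNA hairpins whose
# expression profiles are patterned on published peach-specific miRNA
# abundances, two known trigger miRNAs (miR390/miR828 families), two
# TAS-like loci cleaved by the triggers, sixteen degradome-validated target
# transcripts across twelve miRNAs, and a 24-nt-dominant genomic background.

default_novel_profiles <- function() {
  list(
    mirS1  = list(seq = "ACCUGGCUCUGAUACCAUAAC",  rpm = c(root = 1571, leaf = 908,  flower = 13139, fruit = 7818)),
    mirS2  = list(seq = "UGAAGGAAGAUUUGUGGAAAG",  rpm = c(root = 1573, leaf = 3962, flower = 117,   fruit = 53)),
    mirS3  = list(seq = "CUUCCCAAACCUCCCAUUCCUA", rpm = c(root = 40,   leaf = 33,   flower = 1288,  fruit = 2804)),
    mirS4  = list(seq = "UGAGCAAUGGCACACAGCCCU",  rpm = c(root = 0,    leaf = 0,    flower = 1273,  fruit = 1837)),
    mirS5  = list(seq = "UUUCCGAAACCUCCCAUUCCAA", rpm = c(root = 60,   leaf = 3,    flower = 515,   fruit = 2080)),
    mirS6  = list(seq = "UUAUACAAUGAAAUCACGGCCG", rpm = c(root = 1286, leaf = 309,  flower = 249,   fruit = 328)),
    mirS7  = list(seq = "UGGCACCAAUGAUACCAAGUUU", rpm = c(root = 0,    leaf = 0,    flower = 986,   fruit = 404)),
    mirS8  = list(seq = "CAGGAAAGAAUGUGAUGAGUA",  rpm = c(root = 124,  leaf = 469,  flower = 111,   fruit = 100)),
    mirS9  = list(seq = "UCGGACAUGGUUAGAUCAGGU",  rpm = c(root = 420,  leaf = 160,  flower = 90,    fruit = 130)),
    mirS10 = list(seq = "UAGGCUAAUCGGAAUCGUGGCA", rpm = c(root = 30,   leaf = 120,  flower = 260,   fruit = 190)))
}

default_known_mirnas <- function() {
  data.frame(
    name = c("miR156a", "miR159a", "miR172a", "miR390a", "miR828a", "miR858a"),
    family = c("miR156", "miR159", "miR172", "miR390", "miR828", "miR858"),
    class = c("conserved", "conserved", "conserved", "conserved",
              "less-conserved", "less-conserved"),
    sequence = c("UGACAGAAGAGAGUGAGCAC", "UUUGGAUUGAAGGGAGCUCUA",
                 "AGAAUCUUGAUGAUGCUGCAU", "AAGCUCAGGAGGGAUAGCGCC",
                 "UCUUGCUUAAAUGAGUAUUCCA", "UUUCGUUGUCUGUUCGACCUUG"),
    stringsAsFactors = FALSE)
}

#' Simulate the default small-RNA study
#'
#' Builds the package's canonical synthetic fixture: a toy genome with ten
#' planted novel miRNA hairpins, two known trigger miRNAs (miR390- and
#' miR828-family), two TAS-like phased-siRNA loci, four tissue sRNA
#' libraries, a degradome library over sixteen target transcripts (twelve
#' distinct targeted miRNAs, the two TAS transcripts included) plus decoy
#' transcripts, and ground-truth tables throughout.
#'
#' @param seed master integer seed; all generator seeds derive from it.
#' @param depth reads per sRNA library.
#' @param scaffold_count,scaffold_length toy genome dimensions.
#' @param background_fraction fraction of each library emitted as genomic
#'   background.
#' @param degradome_depth nominal degradome depth.
#' @param adapter 3' adapter appended to reads (`NULL` for pre-trimmed).
#' @param negative_controls also plant two non-canonical hairpins (5
#'   mismatches; 2 bulges) that must fail hairpin evaluation.
#' @param cross_mapping allow background reads inside planted loci.
#' @return a list (class `srna_sim`) with `genome`, `truth`, `planted`,
#'   `libraries`, `degradome`, `transcriptome`, `targets`, `tas`,
#'   `known_refs`, `ncrna_refs` and the parameters used.
#' @export
simulate_study <- function(seed = 1, depth = 50000L,
                           scaffold_count = 8L, scaffold_length = 50000L,
                           background_fraction = 0.9,
                           degradome_depth = 20000L,
                           adapter = DEFAULT_ADAPTER,
                           negative_controls = FALSE,
                           cross_mapping = FALSE) {
  seed <- as.integer(seed)
  known <- default_known_mirnas()
  world <- with_seed(seed, {
    novel <- default_novel_profiles()
    mm <- c(0L, 1L, 2L, 3L, 4L, 0L, 1L, 2L, 0L, 1L)   # planted duplex defects
    bg <- c(0L, 0L, 1L, 0L, 1L, 0L, 0L, 1L, 0L, 0L)
    arms <- rep(c("5p", "3p"), 5)
    planted <- Map(function(id, x, m, b, a)
      planted_mirna(id, x$seq, x$rpm, duplex_mismatches = m, bulges = b,
                    arm = a),
      names(novel), novel, mm, bg, arms)
    trig390 <- planted_mirna("miR390a", known$sequence[known$name == "miR390a"],
                             c(root = 50, leaf = 100, flower = 2000, fruit = 300))
    trig828 <- planted_mirna("miR828a", known$sequence[known$name == "miR828a"],
                             c(root = 50, leaf = 800, flower = 600, fruit = 400),
                             duplex_mismatches = 1L)
    planted <- c(planted, list(trig390, trig828))
    tas <- list(
      planted_tas("tas1", trig828, cleavage_pos = 80L,
                  phased_sirna_count = 8L, off_phase_noise_fraction = 0.1,
                  tissue_profile = c(root = 60, leaf = 900, flower = 700, fruit = 140)),
      planted_tas("tas2", trig390, cleavage_pos = 80L,
                  phased_sirna_count = 8L, off_phase_noise_fraction = 0.1,
                  tissue_profile = c(root = 40, leaf = 90, flower = 1200, fruit = 150)))
    planted <- c(planted, tas)
    if (negative_controls) {
      # shift-intolerant matures (no lag-1 pairing equivalence) and a fixed
      # self-folding loop, so no alternative duplex register can rescue the
      # planted defects in any seed
      nc_loop <- paste0("GCCAUCGAUGGUACGUACGGAU", "GAAA",
                        revcomp("GCCAUCGAUGGUACGUACGGAU"))
      planted <- c(planted, list(
        planted_mirna("negM5", "AGCAGCAGCAGCAGCAGCAGC",
                      c(root = 300, leaf = 300, flower = 300, fruit = 300),
                      duplex_mismatches = 5L, negative_control = TRUE,
                      loop_seq = nc_loop),
        planted_mirna("negB2", "GCAGCAGCAGCAGCAGCAGCA",
                      c(root = 300, leaf = 300, flower = 300, fruit = 300),
                      bulges = 2L, negative_control = TRUE,
                      loop_seq = nc_loop)))
    }
    gw <- generate_genome(toy_genome_spec(scaffold_count, scaffold_length,
                                          seed = seed), planted)
    # degradome targets: sixteen unique targets across twelve miRNAs --
    # mirS1..mirS4 get two gene targets, mirS5..mirS10 one each, and the
    # trigger sites on the two TAS transcripts complete the sixteen
    pm <- gw$planted
    by_id <- setNames(pm, vapply(pm, function(p) p$id, character(1)))
    assign_tbl <- data.frame(
      mirna = c(rep(paste0("mirS", 1:4), each = 2), paste0("mirS", 5:10)),
      gene = sprintf("g%02d", 1:14), stringsAsFactors = FALSE)
    scores <- c(0, 1, 2, 3, 4, 4.5, 5, 2.5, 0, 3.5, 1.5, 5, 2, 4)
    tag_counts <- c(200L, 60L, 120L, 45L, 300L, 25L, 90L, 150L,
                    400L, 35L, 70L, 20L, 250L, 55L)
    targets <- Map(function(g, m, s, n)
      planted_target(g, by_id[[m]], intended_align_score = s, tag_count = n),
      assign_tbl$gene, assign_tbl$mirna, scores, tag_counts)
    decoys <- setNames(
      vapply(1:4, function(i) random_dna(400, 0.42), character(1)),
      sprintf("decoy%02d", 1:4))
    list(gw = gw, tas = tas, targets = targets, decoys = decoys)
  })
  libs <- generate_srna_libraries(
    world$gw, library_specs(depth, background_fraction),
    seed = seed + 1L, adapter = adapter, cross_mapping = cross_mapping)
  degradome <- generate_degradome(world$targets, world$tas,
                                  depth = degradome_depth, seed = seed + 2L)
  ncrna <- with_seed(seed + 3L, setNames(
    as_rna(vapply(1:3, function(i) random_dna(80, 0.5), character(1))),
    c("rRNA_frag1", "tRNA_frag1", "snoRNA_frag1")))
  transcriptome <- c(degradome$transcripts, world$decoys)
  structure(list(
    genome = world$gw$genome, truth = world$gw$truth,
    planted = world$gw$planted,
    libraries = libs, degradome = degradome,
    transcriptome = transcriptome,
    targets = world$targets, tas = world$tas,
    known_refs = known, ncrna_refs = ncrna,
    params = list(seed = seed, depth = depth,
                  background_fraction = background_fraction,
                  degradome_depth = degradome_depth,
                  adapter = adapter)),
    class = "srna_sim")
}
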