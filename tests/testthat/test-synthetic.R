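# Generators: determinism, planted-structure guarantees, conservation.

test_that("genome generation is deterministic and embeds precursors verbatim", {
  mk <- function() {
    set.seed(11)
    planted <- c(
      lapply(1:10, function(i)
        planted_mirna(paste0("m", i), random_rna(21), c(lib = 100))),
      lapply(1:2, function(i)
        planted_tas(paste0("t", i),
                    planted_mirna("trig", "ACCUGGCUCUGAUACCAUAAC", c(lib = 10)),
                    tissue_profile = c(lib = 100))))
    generate_genome(toy_genome_spec(8, 5000, seed = 5), planted)
  }
  g1 <- mk(); g2 <- mk()
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$truth, g2$truth)
  expect_equal(nrow(g1$truth), 12L)
  # re-extraction oracle: the embedded substring equals the construction
  for (r in seq_len(nrow(g1$truth))) {
    tr <- g1$truth[r, ]
    p <- g1$planted[[r]]
    emb <- substr(g1$genome[[tr$scaffold]], tr$start, tr$end)
    want <- as_dna(if (tr$type == "mirna") p$precursor_seq else p$transcript_seq)
    if (tr$strand == "-") want <- revcomp(want)
    expect_identical(emb, want)
  }
})

test_that("overlapping planted features raise an error naming both", {
  set.seed(2)
  a <- planted_mirna("featA", random_rna(21), c(lib = 1),
                     scaffold = "scaffold_1", start = 1200)
  b <- planted_mirna("featB", random_rna(21), c(lib = 1),
                     scaffold = "scaffold_1", start = 1230)
  expect_error(generate_genome(toy_genome_spec(2, 5000, seed = 1), list(a, b)),
               "featA.*featB")
})

test_that("spec invariants on the planted duplex are validated", {
  set.seed(3)
  expect_error(planted_mirna("x", random_rna(21), c(l = 1),
                             duplex_mismatches = 5), "canonical")
  expect_error(planted_mirna("x", random_rna(21), c(l = 1), bulges = 2),
               "canonical")
  expect_error(planted_mirna("x", random_rna(19), c(l = 1)), "20-22")
  expect_error(toy_genome_spec(scaffold_length = 500), ">= 1000")
  expect_error(toy_genome_spec(gc_fraction = 1.2), "gc_fraction")
  expect_error(planted_tas("t", planted_mirna("m", random_rna(21), c(l = 1)),
                           off_phase_noise_fraction = 1), "off_phase")
})

test_that("star is the duplex partner of mature with 2-nt 3' overhangs", {
  set.seed(4)
  p <- planted_mirna("x", "ACCUGGCUCUGAUACCAUAAC", c(l = 1))
  L <- nchar(p$mature_seq)
  expect_identical(substr(p$star_seq, 1, L - 2),
                   revcomp(substr(p$mature_seq, 1, L - 2)))
  expect_equal(nchar(p$star_seq), L)
})

test_that("libraries: background off means every read is planted", {
  w <- tiny_world()
  gw <- list(genome = w$genome, truth = w$truth, planted = w$planted)
  libs <- generate_srna_libraries(
    gw, library_specs(depth = 2000, background_fraction = 0),
    seed = 9, adapter = NULL)
  planted_seqs <- unlist(lapply(w$planted, function(p)
    if (inherits(p, "planted_mirna")) as_dna(c(p$mature_seq, p$star_seq))
    else NULL))
  tas_tx <- vapply(w$planted[vapply(w$planted, inherits, TRUE,
                                    what = "planted_tas")],
                   function(p) as_dna(p$transcript_seq), character(1))
  ok <- vapply(unlist(libs$reads), function(r)
    r %in% planted_seqs || any(grepl(r, tas_tx, fixed = TRUE)), logical(1))
  expect_true(all(ok))
  # conservation: counts table totals equal emitted reads
  tot <- tapply(libs$counts$count, libs$counts$library, sum)
  expect_equal(as.integer(tot[names(libs$reads)]),
               unname(lengths(libs$reads)))
})

test_that("libraries: invalid background fraction errors; length mode is 24", {
  w <- tiny_world()
  gw <- list(genome = w$genome, truth = w$truth, planted = w$planted)
  expect_error(generate_srna_libraries(
    gw, list(list(name = "x", depth = 2000, background_fraction = 1.5)),
    seed = 1), "background fraction")
  expect_error(generate_srna_libraries(
    gw, list(list(name = "x", depth = 100, background_fraction = 0.5)),
    seed = 1), "depth")
  lens <- nchar(w$libraries$reads$root) - nchar(w$params$adapter)
  tab <- table(lens)
  expect_equal(names(which.max(tab)), "24")
})

test_that("planted mature counts follow the stated Poisson expectations", {
  w <- tiny_world()
  gw <- list(genome = w$genome, truth = w$truth, planted = w$planted)
  depth <- 50000L
  libs <- generate_srna_libraries(gw, library_specs(depth = depth),
                                  seed = 31, adapter = NULL)
  cnt <- libs$counts
  for (p in w$planted) {
    if (!inherits(p, "planted_mirna")) next
    for (lib in names(p$tissue_profile)) {
      lam <- p$tissue_profile[[lib]] * depth / 1e6
      got <- cnt$count[cnt$library == lib & cnt$feature_id == p$id &
                         cnt$part == "mature"]
      # exact Poisson band at the 3-sigma two-sided level (the normal
      # approximation misbehaves at the small expectations)
      expect_gte(got, qpois(0.00135, lam))
      expect_lte(got, qpois(1 - 0.00135, lam))
    }
  }
})

test_that("degradome: clean single-target fixture and truth regeneration", {
  set.seed(6)
  m <- planted_mirna("m1", random_rna(21), c(l = 1))
  tgt <- planted_target("g1", m, intended_align_score = 0, tag_count = 50,
                        background_tag_rate = 0)
  d <- generate_degradome(list(tgt), depth = 100, seed = 3)
  expect_equal(length(d$tags), 50L)
  expect_true(all(d$tags == substr(d$transcripts[["g1"]], tgt$cleavage_pos,
                                   tgt$cleavage_pos + 19L)))
  expect_error(generate_degradome(list(tgt), depth = 10, seed = 3), "depth")
  expect_error(generate_degradome(list(), depth = 10), "at least one")
  # regenerate with the same seed: per-position truth identical
  w <- tiny_world()
  d1 <- generate_degradome(w$targets, w$tas, depth = 20000, seed = 8)
  d2 <- generate_degradome(w$targets, w$tas, depth = 20000, seed = 8)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$tags, d2$tags)
  # every tag is accounted for in the truth table
  expect_equal(sum(d1$truth$count), length(d1$tags))
})

test_that("planted hairpins pass evaluation; negative controls fail", {
  for (seed in c(101, 202)) {
    w <- simulate_study(seed = seed, depth = 1000,
                        scaffold_length = 30000, negative_controls = TRUE)
    for (p in w$planted) {
      if (!inherits(p, "planted_mirna")) next
      fl <- fold_rna(p$precursor_seq)
      n <- nchar(p$precursor_seq)
      L <- nchar(p$mature_seq)
      ms <- if (p$arm == "5p") 1L else n - L + 1L
      ev <- evaluate_hairpin(list(sequence = p$precursor_seq), fl, ms,
                             ms + L - 1L)
      if (p$duplex_mismatches <= 4 && p$bulges <= 1)
        expect_true(ev$accepted, label = paste(p$id, "seed", seed))
      else
        expect_false(ev$accepted, label = paste(p$id, "seed", seed))
    }
  }
})
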