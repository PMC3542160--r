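# Folding, window extraction, duplex evaluation, star detection, support.

test_that("fold_rna returns forced optima on hand cases", {
  f <- fold_rna("GGGAAACCC")
  expect_equal(f$structure, "(((...)))")
  expect_equal(f$n_paired, 6L)
  expect_equal(fold_rna("AAAAAAA")$n_paired, 0L)
  expect_error(fold_rna("ACGX"), "invalid base")
  expect_error(fold_rna(strrep("A", 401)), "400")
})

test_that("fold_rna matches an independent Nussinov recursion", {
  set.seed(12)
  for (i in 1:20) {
    s <- random_rna(sample(25:60, 1))
    expect_equal(fold_rna(s)$n_paired / 2, oracle_nussinov(s),
                 label = s)
  }
})

test_that("fold_rna is optimal against exhaustive structure enumeration", {
  set.seed(13)
  for (i in 1:10) {
    s <- random_rna(sample(8:13, 1))
    expect_equal(fold_rna(s)$n_paired / 2, oracle_enumerate_max_pairs(s),
                 label = s)
  }
})

test_that("fold structures are well-formed", {
  set.seed(14)
  for (i in 1:15) {
    s <- random_rna(sample(20:80, 1))
    f <- fold_rna(s)
    p <- f$partner
    idx <- which(p > 0)
    expect_true(all(p[p[idx]] == idx))                  # involution
    expect_true(all(abs(idx - p[idx]) >= 4))            # min loop 3
    b <- strsplit(s, "")[[1]]
    for (i2 in idx[idx < p[idx]]) {
      pr <- paste0(b[i2], b[p[i2]])
      expect_true(pr %in% c("AU", "UA", "GC", "CG", "GU", "UG"))
    }
    db <- strsplit(f$structure, "")[[1]]
    expect_equal(sum(db == "("), sum(db == ")"))
  }
})

test_that("extract_windows covers the tag and clips at scaffold ends", {
  set.seed(15)
  genome <- c(sA = random_dna(2000, 0.5))
  hit <- list(scaffold = "sA", start = 1000, end = 1020, strand = "+")
  wins <- extract_windows(hit, genome, flank = 150)
  expect_length(wins, 3L)
  for (w in wins) {
    expect_true(w$start <= 1000 && w$end >= 1020)
    tagseq <- substr(w$sequence, w$tag_start, w$tag_end)
    expect_equal(tagseq, as_rna(substr(genome[["sA"]], 1000, 1020)))
  }
  edge <- list(scaffold = "sA", start = 10, end = 30, strand = "+")
  for (w in extract_windows(edge, genome, flank = 150)) {
    expect_gte(w$start, 1)
    tagseq <- substr(w$sequence, w$tag_start, w$tag_end)
    expect_equal(tagseq, as_rna(substr(genome[["sA"]], 10, 30)))
  }
  minus <- list(scaffold = "sA", start = 1000, end = 1020, strand = "-")
  for (w in extract_windows(minus, genome, flank = 150)) {
    tagseq <- substr(w$sequence, w$tag_start, w$tag_end)
    expect_equal(tagseq, as_rna(revcomp(substr(genome[["sA"]], 1000, 1020))))
  }
  expect_error(extract_windows(hit, genome, flank = 10), ">= 50")
  expect_error(extract_windows(list(scaffold = "sA", start = 1990,
                                    end = 2010, strand = "+"), genome),
               "outside")
})

test_that("a planted precursor is fully contained in at least one window", {
  w <- tiny_world()
  proc <- tiny_processed()
  tr <- w$truth[w$truth$type == "mirna", ][1, ]
  moff <- tr$start + tr$mature_offset - 1L
  hit <- list(scaffold = tr$scaffold, start = moff,
              end = moff + nchar(tr$mature_seq) - 1L, strand = tr$strand)
  wins <- extract_windows(hit, w$genome, flank = 150)
  contains <- vapply(wins, function(x)
    x$start <= tr$start && x$end >= tr$end, logical(1))
  expect_true(any(contains))
})

test_that("duplex evaluation recovers planted defect counts", {
  mats <- c("ACCUGGCUCUGAUACCAUAAC", "UGAGCAAUGGCACACAGCCCU")
  for (seed in 1:3) {
    set.seed(seed)
    for (mm in c(0L, 2L, 4L)) for (bg in 0:1) {
      p <- planted_mirna("x", mats[(seed %% 2) + 1], c(l = 1),
                         duplex_mismatches = mm, bulges = bg,
                         arm = sample(c("5p", "3p"), 1))
      fl <- fold_rna(p$precursor_seq)
      n <- nchar(p$precursor_seq)
      L <- nchar(p$mature_seq)
      ms <- if (p$arm == "5p") 1L else n - L + 1L
      ev <- evaluate_hairpin(list(sequence = p$precursor_seq), fl, ms,
                             ms + L - 1L)
      expect_true(ev$accepted, label = sprintf("mm=%d bg=%d seed=%d", mm, bg, seed))
      expect_lte(ev$mismatches + 2 * ev$bulges, mm + 2 * bg)
    }
  }
  # fixed negative controls: shift-intolerant mature + deterministic loop
  nc_loop <- paste0("GCCAUCGAUGGUACGUACGGAU", "GAAA",
                    revcomp("GCCAUCGAUGGUACGUACGGAU"))
  for (cfg in list(c(5L, 0L), c(0L, 2L))) {
    p <- planted_mirna("neg",
                       if (cfg[2] >= 2) "GCAGCAGCAGCAGCAGCAGCA"
                       else "AGCAGCAGCAGCAGCAGCAGC",
                       c(l = 1), duplex_mismatches = cfg[1], bulges = cfg[2],
                       negative_control = TRUE, loop_seq = nc_loop)
    fl <- fold_rna(p$precursor_seq)
    ev <- evaluate_hairpin(list(sequence = p$precursor_seq), fl, 1,
                           nchar(p$mature_seq))
    expect_false(ev$accepted)
  }
})

test_that("the published miRC1 duplex is accepted as a hairpin", {
  mature <- "ACCUGGCUCUGAUACCAUAAC"
  star <- "CGUGGUAUCAGAGUCAUGUUA"
  set.seed(99)
  loop <- paste0("GCAUCGUAAGGCAUCCGAUAUG", "GAAA",
                 revcomp("GCAUCGUAAGGCAUCCGAUAUG"))
  prec <- paste0(mature, loop, star)
  ev <- evaluate_hairpin(list(sequence = prec), fold_rna(prec), 1, 21)
  expect_true(ev$accepted)
  expect_lte(ev$mismatches, 4L)
  expect_lte(ev$bulges, 1L)
})

test_that("star detection applies the +-1 nt / +-2 nt rule", {
  reads <- data.frame(start = c(70, 73), length = c(21, 21), count = c(3, 5))
  s <- star_detection(reads, 70, 90)
  expect_true(s$observed)
  expect_equal(s$count, 3L)                # offset-3 read is not star evidence
  expect_false(star_detection(reads[2, , drop = FALSE], 70, 90)$observed)
  expect_false(star_detection(
    data.frame(start = 70, length = 26, count = 1), 70, 90)$observed)
  expect_true(star_detection(
    data.frame(start = 71, length = 22, count = 1), 70, 90)$observed)
})

test_that("locus support fractions follow the strict >75% rules", {
  lr <- data.frame(count = c(60, 20, 20),
                   all_hits_inside = c(TRUE, TRUE, FALSE))
  sup <- locus_support(lr, mature_count = 60, star_count = 20)
  expect_equal(sup$pair_fraction, 0.8)
  expect_equal(sup$uniqueness_fraction, 0.8)
  sup2 <- locus_support(data.frame(count = c(70, 30),
                                   all_hits_inside = TRUE), 70, 0)
  expect_equal(sup2$pair_fraction, 0.7)    # fails the > 0.75 rule downstream
  expect_false(sup2$pair_fraction > 0.75)
  expect_error(locus_support(data.frame(count = integer(0),
                                        all_hits_inside = logical(0)), 0, 0),
               "zero reads")
})

test_that("discovery classifies novel vs candidate by star evidence", {
  w <- tiny_world()
  proc <- tiny_processed()
  len <- nchar(proc$tags$sequence)
  cl <- len >= 20 & len <= 22
  ann <- annotate_tags(proc$tags$sequence[cl], w$known_refs, w$ncrna_refs)
  calls <- discover_mirnas(proc, ann, w$genome)
  expect_true(all(calls$calls$class %in% c("novel", "candidate")))
  expect_true(all(calls$calls$pair_fraction > 0.75))
  expect_true(all(calls$calls$uniqueness_fraction > 0.75))
  # no star reads emitted -> every call is a candidate
  gw <- list(genome = w$genome, truth = w$truth, planted = w$planted)
  libs0 <- generate_srna_libraries(gw, library_specs(depth = 8000),
                                   seed = 77, adapter = NULL,
                                   star_fraction = 0)
  proc0 <- preprocess_libraries(libs0$reads, w$genome, adapter = NULL)
  len0 <- nchar(proc0$tags$sequence)
  ann0 <- annotate_tags(proc0$tags$sequence[len0 >= 20 & len0 <= 22],
                        w$known_refs, w$ncrna_refs)
  calls0 <- discover_mirnas(proc0, ann0, w$genome)
  expect_gt(nrow(calls0$calls), 0)
  expect_true(all(calls0$calls$class == "candidate"))
  expect_true(all(calls0$calls$star_sequence == "None detected"))
})
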