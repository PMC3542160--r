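# Adapter trimming, collapsing, exact mapping, rpm, length profiles.

ADAPT <- "TGGAATTCTCGGGTG"

test_that("trim_adapter applies the documented rules", {
  r <- trim_adapter(c(paste0("ACGTACGT", ADAPT),                  # too short
                      paste0(strrep("ACGTT", 5), "A", ADAPT),     # 26-nt insert
                      "ACGTACGTACGTACGTACGTA",                    # no adapter
                      paste0(strrep("AC", 10), substr(ADAPT, 1, 7))), # partial
                    ADAPT)
  expect_equal(r$status, c("too_short", "ok", "no_adapter", "ok"))
  expect_equal(r$insert[2], paste0(strrep("ACGTT", 5), "A"))
  expect_equal(r$insert[4], strrep("AC", 10))
  # a 21-nt insert with the full adapter comes back exactly
  ins <- strrep("GAT", 7)
  expect_equal(trim_adapter(paste0(ins, ADAPT), ADAPT)$insert, ins)
  # overlap below min_overlap is not adapter evidence
  r2 <- trim_adapter(paste0(strrep("AC", 10), substr(ADAPT, 1, 5)), ADAPT,
                     min_overlap = 6)
  expect_equal(r2$status, "no_adapter")
  expect_error(trim_adapter("ACGT", ""), "non-empty")
})

test_that("collapse conserves per-library counts", {
  x <- collapse_reads(list(l1 = c("AAAT", "AAAT", "CCCG"), l2 = character(0)))
  expect_equal(nrow(x), 2L)
  expect_equal(sort(x$l1), c(1L, 2L))
  expect_equal(x$l2, c(0L, 0L))
  w <- tiny_world()
  proc <- tiny_processed()
  for (lib in proc$libraries) {
    expect_equal(sum(proc$tags[[lib]]), proc$stats$length_filtered[
      proc$stats$library == lib])
  }
})

test_that("map_tags equals the brute-force window-scan oracle", {
  set.seed(21)
  genome <- setNames(
    vapply(1:2, function(i) random_dna(4000, 0.45), character(1)),
    c("s1", "s2"))
  picks <- vapply(1:15, function(i) {
    s <- sample(3900, 1)
    substr(genome[[sample(2, 1)]], s, s + 24)
  }, character(1))
  tags <- unique(c(picks, revcomp(picks[1:5]),
                   vapply(1:10, function(i) random_dna(25, 0.5), character(1))))
  got <- map_tags(tags, genome)
  want <- oracle_map(tags, genome)
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("map_tags handles strands and degenerate tags", {
  genome <- c(chr = paste0(strrep("A", 50), "ACGTACGTACGTACGTACGTA",
                           strrep("C", 50)))
  tag <- "ACGTACGTACGTACGTACGTA"
  h <- map_tags(tag, genome)
  expect_true(all(h$start[h$strand == "+"] == 51))
  h2 <- map_tags(revcomp(tag), genome)
  expect_true("-" %in% h2$strand)
  expect_warning(h3 <- map_tags(c(tag, "ACGTNACGTACGTACGTACGT"), genome),
                 "degenerate")
  expect_false("ACGTNACGTACGTACGTACGT" %in% h3$sequence)
})

test_that("rpm arithmetic is exact, linear and invertible", {
  expect_equal(normalize_rpm(0, 1e6), 0)
  expect_equal(normalize_rpm(10, 1e6), 10)
  expect_error(normalize_rpm(5, 0), "positive")
  counts <- c(3L, 17L, 250L)
  total <- 52341
  expect_equal(normalize_rpm(counts, total) * total / 1e6, counts)
  expect_equal(normalize_rpm(2 * counts, 2 * total),
               normalize_rpm(counts, total))
})

test_that("length distribution splits and percentages behave", {
  proc <- tiny_processed()
  ld <- length_distribution(proc)
  for (lib in proc$libraries) {
    sel <- ld$library == lib
    expect_equal(sum(ld$redundant_pct[sel]), 100, tolerance = 1e-9)
    expect_equal(sum(ld$unique_pct[sel]), 100, tolerance = 1e-9)
    red <- tapply(ld$redundant[sel], ld$length[sel], sum)
    expect_equal(names(which.max(red)), "24")  # generator construction
  }
  # one tag of length 21, count 5
  p2 <- list(tags = data.frame(sequence = strrep("ACU", 7), l1 = 5L,
                               n_hits = 1L, stringsAsFactors = FALSE),
             libraries = "l1")
  ld2 <- length_distribution(p2)
  expect_equal(ld2$redundant[ld2$length == 21 & ld2$matched], 5L)
  expect_equal(ld2$unique[ld2$length == 21 & ld2$matched], 1L)
})

test_that("preprocess conserves counts through trim and collapse", {
  w <- tiny_world()
  proc <- tiny_processed()
  st <- proc$stats
  expect_true(all(st$genome_matched <= st$length_filtered))
  expect_true(all(st$length_filtered <= st$adapter_found))
  expect_true(all(st$adapter_found <= st$raw_reads))
  expect_equal(st$raw_reads, unname(lengths(w$libraries$reads)))
})
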