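# Target scoring, transcriptome scanning, t-plots, category rules.

test_that("score_target_site applies the stated penalties", {
  mir <- "UGACAGAAGAGAGUGAGCACA"            # 21 nt
  perfect <- as_dna(revcomp(mir))
  expect_equal(score_target_site(mir, perfect)$score, 0)
  # single mismatch at miRNA position 15 -> 1.0 (outside the 2-13 core)
  s <- strsplit(perfect, "")[[1]]
  s[21 + 1 - 15] <- as_dna(substr(mir, 15, 15))
  expect_equal(score_target_site(mir, paste(s, collapse = ""))$score, 1)
  # G:U at miRNA position 5 -> 0.5 doubled -> 1.0
  stopifnot(substr(mir, 5, 5) == "A")       # need G or U: use position 4 (C? )
  mir2 <- "UGACGGAAGAGAGUGAGCACA"           # position 5 is G
  s2 <- strsplit(as_dna(revcomp(mir2)), "")[[1]]
  s2[21 + 1 - 5] <- "T"                     # G:U wobble
  expect_equal(score_target_site(mir2, paste(s2, collapse = ""))$score, 1)
  # mismatch in the core doubles
  s3 <- strsplit(perfect, "")[[1]]
  s3[21 + 1 - 10] <- as_dna(substr(mir, 10, 10))
  expect_equal(score_target_site(mir, paste(s3, collapse = ""))$score, 2)
  expect_error(score_target_site(mir, substr(perfect, 1, 15)), "shorter")
})

test_that("planted sites score exactly their intended value", {
  set.seed(30)
  for (sc in c(0, 1, 2.5, 4, 4.5, 5)) {
    m <- planted_mirna("m", "UGAAGGAAGAUUUGUGGAAAG", c(l = 1))
    tg <- planted_target("g", m, intended_align_score = sc)
    site <- substr(tg$transcript_seq, tg$site_start, tg$site_end)
    expect_equal(score_target_site(m$mature_seq, site)$score, sc)
  }
})

test_that("scan_transcriptome equals the exhaustive scoring oracle", {
  set.seed(31)
  mir <- random_rna(21)
  txs <- setNames(c(vapply(1:3, function(i) random_dna(300, 0.45),
                           character(1)),
                    paste0(random_dna(100, 0.45), as_dna(revcomp(mir)),
                           random_dna(100, 0.45))),
                  c("t1", "t2", "t3", "t4"))
  got <- scan_transcriptome(mir, txs, threshold = 8)
  want <- do.call(rbind, lapply(names(txs), function(tx) {
    o <- oracle_scan(mir, txs[[tx]], 8)
    if (nrow(o)) cbind(transcript_id = tx, o, stringsAsFactors = FALSE)
  }))
  want$cleavage_pos <- want$start + want$width - 10L
  want <- want[order(want$score, want$transcript_id, want$start), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
  # the planted perfect site is present with score 0
  expect_true(any(got$transcript_id == "t4" & got$score == 0 &
                    got$start == 101))
})

test_that("threshold is respected around the 4.5 / 5 boundary", {
  set.seed(32)
  m <- planted_mirna("m", "UGAGCAAUGGCACACAGCCCU", c(l = 1))
  tg <- planted_target("g", m, intended_align_score = 5)
  tx <- c(g = tg$transcript_seq)
  expect_equal(nrow(scan_transcriptome(m$mature_seq, tx, 4.5)), 0L)
  hit <- scan_transcriptome(m$mature_seq, tx, 5)
  expect_true(any(hit$score == 5 & hit$start == tg$site_start))
})

test_that("t-plot profiles and tpb arithmetic", {
  set.seed(34)
  tx <- c(tr = random_dna(400, 0.5))
  tags <- rep(substr(tx[["tr"]], 100, 119), 10)
  mapped <- map_degradome(tags, tx)
  expect_equal(mapped$total, 10)
  prof <- build_tplot("tr", mapped, 400)
  expect_equal(prof$raw[100], 10L)
  expect_equal(prof$tpb[100], 1e9)
  expect_equal(sum(prof$raw), 10L)
  # conservation: tpb over all transcripts sums to 1e9
  w <- tiny_world()
  md <- map_degradome(w$degradome$tags, w$transcriptome)
  expect_equal(sum(md$positions$count) * 1e9 / md$total, 1e9)
  # empty coverage transcript
  prof0 <- build_tplot("absent", md, 100)
  expect_true(all(prof0$raw == 0))
  expect_error(build_tplot("x", list(total = 0, positions = NULL), 10),
               "tpb undefined")
  # synthetic degradome equals the generator's per-position truth
  tru <- w$degradome$truth
  for (r in sample(nrow(tru), 20)) {
    expect_equal(
      md$positions$count[md$positions$transcript_id == tru$transcript_id[r] &
                           md$positions$position == tru$position[r]],
      tru$count[r])
  }
})

test_that("category rules are exhaustive and exclusive", {
  mkprof <- function(raw) structure(
    list(transcript_id = "t", raw = raw, tpb = raw * 1e9 / max(1, sum(raw)),
         total = sum(raw)), class = "transcript_profile")
  raw <- integer(300); raw[100] <- 5L
  expect_equal(categorize_cleavage(mkprof(raw), 100)$category, 0L)
  raw2 <- integer(300); raw2[c(100, 200)] <- 5L
  expect_equal(categorize_cleavage(mkprof(raw2), 100)$category, 1L)
  expect_equal(categorize_cleavage(mkprof(raw2), 200)$category, 1L)
  raw3 <- integer(300); raw3[100] <- 1L; raw3[200] <- 7L
  expect_equal(categorize_cleavage(mkprof(raw3), 100)$category, 4L)
  raw4 <- integer(300); raw4[1:10] <- c(8L, rep(2L, 9))
  expect_equal(categorize_cleavage(mkprof(raw4), 2)$category, 3L)  # r <= med
  raw5 <- integer(300); raw5[1:11] <- c(9L, 5L, rep(1L, 9))
  expect_equal(categorize_cleavage(mkprof(raw5), 2)$category, 2L)  # med < r < M
  nc <- categorize_cleavage(mkprof(raw5), 50)
  expect_true(is.na(nc$category))
  expect_equal(nc$status, "no degradome evidence")
  # property: for random profiles every covered position gets exactly one category
  set.seed(33)
  for (i in 1:20) {
    raw <- integer(50)
    pos <- sample(50, 12)
    raw[pos] <- rpois(12, 3) + 1L
    p <- mkprof(raw)
    cats <- vapply(pos, function(x) categorize_cleavage(p, x)$category,
                   integer(1))
    expect_true(all(cats %in% 0:4))
    expect_equal(sum(raw == max(raw)) > 1,
                 !any(cats == 0))           # unique max <=> one category-0 site
  }
})

test_that("call_targets reproduces the planted 12-miRNA / 16-target design", {
  w <- tiny_world()
  novel <- w$truth[w$truth$type == "mirna" &
                     !grepl("^miR", w$truth$feature_id), ]
  mt <- rbind(
    data.frame(mirna_id = novel$feature_id, sequence = novel$mature_seq,
               class = "novel", stringsAsFactors = FALSE),
    data.frame(mirna_id = c("miR390a", "miR828a"),
               sequence = w$known_refs$sequence[
                 match(c("miR390a", "miR828a"), w$known_refs$name)],
               class = c("conserved", "less-conserved"),
               stringsAsFactors = FALSE))
  tc <- call_targets(mt, w$transcriptome, w$degradome$tags)
  expect_equal(length(unique(tc$calls$target_gene)), 16L)
  expect_equal(length(unique(tc$calls$mirna_id)), 12L)
  # every planted (miRNA, gene, cleavage) triple is called with its score
  for (t in w$targets) {
    row <- tc$calls[tc$calls$mirna_id == t$mirna_id &
                      tc$calls$target_gene == t$transcript_id &
                      tc$calls$cleavage_pos == t$cleavage_pos, ]
    expect_equal(nrow(row), 1L, label = t$transcript_id)
    expect_equal(row$align_score, t$intended_align_score)
    expect_gte(row$raw, t$tag_count)
  }
  # a site below threshold with zero degradome tags is not called
  expect_true(all(tc$calls$raw >= 1))
  expect_gt(nrow(tc$predictions), nrow(tc$calls))
})
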