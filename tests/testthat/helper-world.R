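# Shared fixtures, built lazily once per test run.

.cache <- new.env(parent = emptyenv())

# a small but complete simulated study reused across test files
tiny_world <- function() {
  if (is.null(.cache$world))
    .cache$world <- simulate_study(seed = 42, depth = 8000L,
                                   scaffold_length = 30000L)
  .cache$world
}

tiny_processed <- function() {
  if (is.null(.cache$proc)) {
    w <- tiny_world()
    .cache$proc <- preprocess_libraries(w$libraries$reads, w$genome,
                                        adapter = w$params$adapter)
  }
  .cache$proc
}

# brute-force exact mapper: slide every window of each scaffold (oracle for
# map_tags; independent of Biostrings)
oracle_map <- function(tags, genome) {
  rows <- list()
  for (tg in tags) {
    w <- nchar(tg)
    rc <- revcomp(tg)
    for (sc in names(genome)) {
      g <- genome[[sc]]
      n <- nchar(g)
      if (n < w) next
      starts <- seq_len(n - w + 1L)
      wins <- substring(g, starts, starts + w - 1L)
      for (s in starts[wins == tg])
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = tg, scaffold = sc, start = s, end = s + w - 1L,
          strand = "+", stringsAsFactors = FALSE)
      for (s in starts[wins == rc])
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = tg, scaffold = sc, start = s, end = s + w - 1L,
          strand = "-", stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence = character(0), scaffold = character(0),
               start = integer(0), end = integer(0), strand = character(0))
  out[order(out$sequence, out$scaffold, out$start, out$strand), , drop = FALSE]
}

# independent maximum-base-pair fold: plain memoized R recursion
oracle_nussinov <- function(seq, min_loop = 3L) {
  b <- strsplit(as_rna(seq), "")[[1]]
  n <- length(b)
  pairs_ok <- function(x, y)
    (x == "A" && y == "U") || (x == "U" && (y == "A" || y == "G")) ||
    (x == "G" && (y == "C" || y == "U")) || (x == "C" && y == "G")
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- rec(i, j - 1L)
    for (k in i:(j - min_loop - 1L)) {
      if (!pairs_ok(b[k], b[j])) next
      left <- if (k > i) rec(i, k - 1L) else 0L
      mid <- if (k + 1L <= j - 1L) rec(k + 1L, j - 1L) else 0L
      best <- max(best, 1L + left + mid)
    }
    memo[[key]] <- best
    best
  }
  if (n < 2) return(0L)
  rec(1L, n)
}

# exhaustive enumeration of every nested structure (tiny n only)
oracle_enumerate_max_pairs <- function(seq, min_loop = 3L) {
  b <- strsplit(as_rna(seq), "")[[1]]
  n <- length(b)
  pairs_ok <- function(x, y)
    (x == "A" && y == "U") || (x == "U" && (y == "A" || y == "G")) ||
    (x == "G" && (y == "C" || y == "U")) || (x == "C" && y == "G")
  rec <- function(pos) {
    if (!length(pos)) return(0L)
    i <- pos[1]
    best <- rec(pos[-1])                           # i unpaired
    for (j in pos[-1]) {
      if (j - i <= min_loop) next
      if (!pairs_ok(b[i], b[j])) next
      inside <- pos[pos > i & pos < j]
      outside <- pos[pos > j]
      best <- max(best, 1L + rec(inside) + rec(outside))
    }
    best
  }
  rec(seq_len(n))
}

# independent target-site scoring oracle (plain R, mirrors the documented
# penalty scheme: mismatch 1, G:U 0.5, interior gap 2, doubled at 2-13)
oracle_score_site <- function(mirna, site) {
  m <- strsplit(as_rna(mirna), "")[[1]]
  t <- rev(strsplit(as_rna(site), "")[[1]])
  L <- length(m); W <- length(t)
  w <- function(i) if (i >= 2 && i <= 13) 2 else 1
  cls <- function(a, b) {
    if ((a == "A" && b == "U") || (a == "U" && b == "A") ||
        (a == "G" && b == "C") || (a == "C" && b == "G")) 0
    else if ((a == "G" && b == "U") || (a == "U" && b == "G")) 0.5
    else 1
  }
  score_cfg <- function(bm, bt) {
    s <- 0; ti <- 1
    for (i in seq_len(L)) {
      if (i == bm) { s <- s + 2 * w(i); next }
      if (ti == bt) { s <- s + 2 * w(i); ti <- ti + 1 }
      s <- s + cls(m[i], t[ti]) * w(i)
      ti <- ti + 1
    }
    s
  }
  if (W == L) return(score_cfg(0, 0))
  if (W == L + 1) return(min(vapply(2:(W - 1), function(b) score_cfg(0, b), 0)))
  if (W == L - 1) return(min(vapply(2:(L - 1), function(b) score_cfg(b, 0), 0)))
  stop("bad width")
}

oracle_scan <- function(mirna, transcript, threshold) {
  L <- nchar(mirna); n <- nchar(transcript)
  rows <- list()
  for (s in seq_len(max(0, n - L + 2))) {
    best <- Inf; bw <- 0
    for (W in (L - 1):(L + 1)) {
      if (s + W - 1 > n || W < 1) next
      sc <- oracle_score_site(mirna, substr(transcript, s, s + W - 1))
      if (sc < best || (sc == best && W == L)) { best <- sc; bw <- W }
    }
    if (is.finite(best) && best <= threshold)
      rows[[length(rows) + 1L]] <- data.frame(start = s, width = bw,
                                              score = best)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(0), width = integer(0), score = numeric(0))
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                                collapse = "")
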