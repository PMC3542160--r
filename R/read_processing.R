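# Read preprocessing: 3' adapter removal, length filtering, collapsing to
# unique tags with per-library counts, exact genome mapping (both strands),
# rpm normalization and length-distribution profiling.

#' Trim the 3' adapter from raw reads
#'
#' Returns the insert preceding the leftmost full-adapter occurrence; when
#' the full adapter is absent, a terminal suffix of the read matching an
#' adapter prefix of at least `min_overlap` nt is trimmed instead. Reads
#' with no detectable adapter are rejected (`no_adapter`), as are inserts
#' outside `[min_len, max_len]` (`too_short` / `too_long`).
#'
#' @param reads character vector of raw reads (DNA).
#' @param adapter 3' adapter sequence.
#' @param min_overlap minimum terminal suffix-prefix overlap (default 6 nt).
#' @param min_len,max_len admissible insert length range.
#' @return data.frame with columns `insert` (NA when rejected) and `status`
#'   (`ok`, `no_adapter`, `too_short`, `too_long`).
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 6L,
                         min_len = 15L, max_len = 31L) {
  if (is.null(adapter) || nchar(adapter) == 0) stopf("adapter must be non-empty")
  reads <- toupper(reads)
  adapter <- toupper(adapter)
  pos <- regexpr(adapter, reads, fixed = TRUE)
  insert <- ifelse(pos > 0, substr(reads, 1, pos - 1), NA_character_)
  # terminal partial-adapter rescue for reads without a full occurrence
  miss <- which(pos < 0)
  if (length(miss) && nchar(adapter) - 1L >= min_overlap) {
    n <- nchar(reads[miss])
    found <- rep(NA_integer_, length(miss))
    for (k in seq(nchar(adapter) - 1L, min_overlap, by = -1L)) {   # longest first
      idx <- which(is.na(found) & n >= k)
      if (!length(idx)) next
      hit <- substr(reads[miss][idx], n[idx] - k + 1L, n[idx]) ==
        substr(adapter, 1L, k)
      found[idx[hit]] <- k
    }
    ok <- !is.na(found)
    insert[miss[ok]] <- substr(reads[miss][ok], 1L,
                               nchar(reads[miss][ok]) - found[ok])
  }
  status <- ifelse(is.na(insert), "no_adapter",
            ifelse(nchar(insert) < min_len, "too_short",
            ifelse(nchar(insert) > max_len, "too_long", "ok")))
  insert[status != "ok"] <- NA_character_
  data.frame(insert = insert, status = status, stringsAsFactors = FALSE)
}

#' Collapse per-library reads into unique tags
#'
#' @param reads_by_library named list of character vectors of (trimmed,
#'   length-filtered) reads; alternatively vectors of unique sequences with
#'   `counts_by_library` multiplicities (collapsed-FASTA input).
#' @param counts_by_library optional named list of integer multiplicities
#'   parallel to `reads_by_library`.
#' @return data.frame of class `tag_table`: `sequence` plus one integer
#'   count column per library. The column sums conserve the library read
#'   counts.
#' @export
collapse_reads <- function(reads_by_library, counts_by_library = NULL) {
  libs <- names(reads_by_library)
  if (is.null(libs)) stopf("reads_by_library must be a named list")
  all_seq <- unique(unlist(reads_by_library, use.names = FALSE))
  out <- data.frame(sequence = all_seq, stringsAsFactors = FALSE)
  for (lib in libs) {
    cnt <- integer(length(all_seq))
    idx <- match(reads_by_library[[lib]], all_seq)
    w <- if (is.null(counts_by_library)) rep(1L, length(idx))
         else counts_by_library[[lib]]
    if (length(idx)) {
      tb <- tapply(w, idx, sum)
      cnt[as.integer(names(tb))] <- as.integer(tb)
    }
    out[[lib]] <- cnt
  }
  class(out) <- c("tag_table", "data.frame")
  out
}

#' Map unique tags to a genome by exact full-length match
#'
#' All and only exact occurrences on both strands are reported. Minus-strand
#' hits report the start of the match on the forward strand. Tags containing
#' degenerate bases are skipped with a warning.
#'
#' @param tags character vector of tag sequences (DNA), or a `tag_table`.
#' @param genome named character vector of scaffold sequences.
#' @return data.frame with columns `sequence`, `scaffold`, `start`, `end`
#'   (1-based inclusive) and `strand`.
#' @export
map_tags <- function(tags, genome) {
  if (inherits(tags, "tag_table") || is.data.frame(tags)) tags <- tags$sequence
  tags <- toupper(as_dna(tags))
  bad <- grepl("[^ACGT]", tags)
  if (any(bad)) {
    warnf("skipping %d tag(s) with degenerate bases", sum(bad))
    tags <- tags[!bad]
  }
  subjects <- Biostrings::DNAStringSet(unlist(genome))
  hits <- list()
  for (w in sort(unique(nchar(tags)))) {
    tw <- tags[nchar(tags) == w]
    for (str in c("+", "-")) {
      q <- if (str == "+") tw else as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(tw)))
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(q))
      for (sc in names(genome)) {
        m <- Biostrings::startIndex(Biostrings::matchPDict(pd, subjects[[sc]]))
        n_per <- lengths(m)
        if (sum(n_per) == 0) next
        st <- unlist(m, use.names = FALSE)
        hits[[length(hits) + 1L]] <- data.frame(
          sequence = rep(tw, n_per), scaffold = sc,
          start = st, end = st + w - 1L, strand = str,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(sequence = character(0), scaffold = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out[order(out$sequence, out$scaffold, out$start, out$strand), , drop = FALSE]
}

#' Reads-per-million normalization
#'
#' `rpm = count * 1e6 / total`, where `total` is the library's
#' genome-matched redundant read count. Rounding happens only at report
#' time.
#'
#' @param count numeric vector of tag counts.
#' @param total genome-matched read total of the library (> 0).
#' @return numeric vector of rpm values.
#' @export
normalize_rpm <- function(count, total) {
  if (length(total) != 1 || is.na(total) || total <= 0)
    stopf("library genome-matched total must be a single positive number")
  count * 1e6 / total
}

#' Preprocess raw libraries end to end
#'
#' Adapter trimming (optional), collapsing, exact mapping and per-library
#' statistics. The rpm denominator of each library is its genome-matched
#' redundant read total.
#'
#' @param reads_by_library named list of raw read vectors.
#' @param genome named character vector of scaffolds.
#' @param adapter 3' adapter, or `NULL` for pre-trimmed reads (then only
#'   the length filter applies).
#' @param min_overlap,min_len,max_len see [trim_adapter()].
#' @return list of class `srna_processed`: `tags` (tag_table with an extra
#'   `n_hits` column), `hits`, `stats` (per-library data.frame), `rpm`
#'   (matrix tags x libraries).
#' @export
preprocess_libraries <- function(reads_by_library, genome,
                                 adapter = NULL, min_overlap = 6L,
                                 min_len = 15L, max_len = 31L) {
  libs <- names(reads_by_library)
  trimmed <- list()
  stats_rows <- list()
  for (lib in libs) {
    raw <- reads_by_library[[lib]]
    if (!is.null(adapter)) {
      tr <- trim_adapter(raw, adapter, min_overlap, min_len, max_len)
      keep <- tr$insert[tr$status == "ok"]
      adapter_found <- sum(tr$status != "no_adapter")
    } else {
      len <- nchar(raw)
      keep <- raw[len >= min_len & len <= max_len]
      adapter_found <- length(raw)
    }
    trimmed[[lib]] <- keep
    stats_rows[[lib]] <- data.frame(
      library = lib, raw_reads = length(raw), adapter_found = adapter_found,
      length_filtered = length(keep), stringsAsFactors = FALSE)
  }
  tags <- collapse_reads(trimmed)
  hits <- map_tags(tags, genome)
  nh <- table(hits$sequence)
  tags$n_hits <- as.integer(nh[tags$sequence])
  tags$n_hits[is.na(tags$n_hits)] <- 0L
  matched <- tags$n_hits > 0
  stats <- do.call(rbind, stats_rows)
  stats$genome_matched <- vapply(libs, function(l)
    sum(tags[[l]][matched]), numeric(1))
  rownames(stats) <- NULL
  rpm <- vapply(libs, function(l)
    normalize_rpm(tags[[l]], stats$genome_matched[stats$library == l]),
    numeric(nrow(tags)))
  if (is.null(dim(rpm))) rpm <- matrix(rpm, nrow = nrow(tags),
                                       dimnames = list(NULL, libs))
  structure(list(tags = tags, hits = hits, stats = stats, rpm = rpm,
                 libraries = libs),
            class = "srna_processed")
}

#' Per-length redundant and unique tag counts
#'
#' For each length in `[min_len, max_len]` and each library: redundant
#' (count-weighted) and unique (distinct tag) totals, split by
#' genome-matched status, with percentages per panel.
#'
#' @param processed an `srna_processed` object, see
#'   [preprocess_libraries()].
#' @param min_len,max_len length range to tabulate.
#' @return data.frame with columns `library`, `length`, `matched`,
#'   `redundant`, `unique`, `redundant_pct`, `unique_pct`.
#' @export
length_distribution <- function(processed, min_len = 15L, max_len = 31L) {
  tags <- processed$tags
  lens <- nchar(tags$sequence)
  matched <- tags$n_hits > 0
  rows <- list()
  for (lib in processed$libraries) {
    for (m in c(TRUE, FALSE)) {
      sel <- matched == m
      red <- tapply(tags[[lib]][sel], factor(lens[sel], levels = min_len:max_len),
                    sum, default = 0L)
      uni <- tapply(tags[[lib]][sel] > 0, factor(lens[sel], levels = min_len:max_len),
                    sum, default = 0L)
      rows[[length(rows) + 1L]] <- data.frame(
        library = lib, length = min_len:max_len, matched = m,
        redundant = as.integer(red), unique = as.integer(uni),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  for (lib in unique(out$library)) {
    sel <- out$library == lib
    out$redundant_pct[sel] <- 100 * out$redundant[sel] / sum(out$redundant[sel])
    out$unique_pct[sel] <- 100 * out$unique[sel] / sum(out$unique[sel])
  }
  rownames(out) <- NULL
  out
}
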