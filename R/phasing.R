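# 21-nt phasing-register analysis: reads downstream (or between) miRNA
# cleavage sites are binned into the 21 residue classes of their 5'
# position relative to the cleavage anchor, the radial-graph registers.

#' Build a phasing window
#'
#' Admits only 21-nt reads whose 5' position falls inside the analysis
#' span. The default span runs from the anchor to `anchor + 21 * cycles`;
#' a `span_start` upstream of the anchor covers dual-cleavage (TAS3-like)
#' geometries where registers are anchored at the 3' cleavage site.
#'
#' @param transcript_id locus label.
#' @param anchor 1-based cleavage position on the transcript.
#' @param reads data.frame with `position` (read 5' end), `length`,
#'   `count` and optionally `library`.
#' @param cycles number of 21-nt cycles in the span.
#' @param span_start optional explicit span start (default: the anchor).
#' @return list of class `phasing_window` with the admitted reads and the
#'   count of excluded non-21-nt reads.
#' @export
phasing_window <- function(transcript_id, anchor, reads, cycles = 10L,
                           span_start = NULL) {
  if (is.null(reads$library)) reads$library <- "all"
  lo <- if (is.null(span_start)) anchor else span_start
  hi <- anchor + 21L * cycles
  in_span <- reads$position >= lo & reads$position <= hi
  not21 <- sum(reads$count[in_span & reads$length != 21L])
  keep <- reads[in_span & reads$length == 21L, , drop = FALSE]
  structure(list(transcript_id = transcript_id, anchor = as.integer(anchor),
                 span = c(lo, hi), reads = keep,
                 excluded_non21 = as.integer(not21)),
            class = "phasing_window")
}

#' Assign reads to the 21 phasing registers
#'
#' A read's register is `(position - anchor) mod 21`; register 0 is the
#' in-phase register of the cleavage site. Counts are accumulated per
#' register and per library; the dominant register is the argmax (ties ->
#' smallest index, flagged).
#'
#' @param window a [phasing_window()].
#' @return object of class `register_profile`: `counts` (length-21 named
#'   vector, registers 0-20), `by_library` (21 x libraries matrix),
#'   `dominant` (0-based register index), `tied`, `phase_fraction`,
#'   `total`.
#' @export
assign_registers <- function(window) {
  reads <- window$reads
  reg <- (reads$position - window$anchor) %% 21L
  libs <- sort(unique(reads$library))
  if (!length(libs)) libs <- "all"
  by_lib <- matrix(0L, nrow = 21L, ncol = length(libs),
                   dimnames = list(as.character(0:20), libs))
  if (nrow(reads)) {
    for (i in seq_len(nrow(reads)))
      by_lib[reg[i] + 1L, reads$library[i]] <-
        by_lib[reg[i] + 1L, reads$library[i]] + reads$count[i]
  }
  counts <- rowSums(by_lib)
  total <- sum(counts)
  dominant <- which.max(counts) - 1L
  tied <- sum(counts == max(counts)) > 1L
  structure(list(counts = counts, by_library = by_lib,
                 dominant = as.integer(dominant), tied = tied,
                 phase_fraction = if (total > 0) unname(counts[dominant + 1L] / total)
                 else NA_real_,
                 total = total, anchor = window$anchor,
                 transcript_id = window$transcript_id),
            class = "register_profile")
}

#' Phasing enrichment statistic
#'
#' Upper-tail binomial test of the dominant-register count against a
#' uniform success probability of 1/21, Bonferroni-corrected for the
#' selection of the dominant register among 21. An extension beyond the
#' radial-graph display; off by default in report output.
#'
#' @param profile a `register_profile`.
#' @return list: `phase_fraction`, `p_value` (corrected, capped at 1),
#'   `status` (`ok` or `under-supported` when fewer than 10 reads).
#' @export
phase_statistic <- function(profile) {
  if (profile$total < 10)
    return(list(phase_fraction = profile$phase_fraction, p_value = NA_real_,
                status = "under-supported"))
  k <- profile$counts[profile$dominant + 1L]
  p <- pbinom(k - 1, profile$total, 1 / 21, lower.tail = FALSE)
  list(phase_fraction = profile$phase_fraction,
       p_value = min(1, 21 * p), status = "ok")
}

#' Name a phased siRNA by its signed offset from the cleavage anchor
#'
#' @param locus locus label (e.g. `"TAS4"`).
#' @param position read 5' position.
#' @param anchor cleavage anchor position.
#' @return label like `"TAS4-siRNA(-81)"` or `"TAS4-siRNA(+42)"`;
#'   offset 0 prints as `"(+0)"`.
#' @export
name_phased_sirna <- function(locus, position, anchor) {
  off <- position - anchor
  sprintf("%s-siRNA(%+d)", locus, off)
}

#' Recover the offset from a phased-siRNA label
#'
#' Inverse of [name_phased_sirna()].
#'
#' @param label label produced by [name_phased_sirna()].
#' @return integer offset.
#' @export
parse_phased_sirna <- function(label) {
  m <- regmatches(label, regexpr("\\(([+-][0-9]+)\\)$", label))
  if (!length(m) || is.na(m)) stopf("not a phased-siRNA label: %s", label)
  as.integer(sub("[()]", "", sub("\\(", "", m)))
}

#' Per-tissue accumulation of in-register reads
#'
#' Totals register-0 (in-phase) reads per library; fractions sum to 1
#' across libraries for each locus with any phased reads.
#'
#' @param profile a `register_profile`.
#' @return data.frame: `library`, `in_register`, `fraction`.
#' @export
tissue_accumulation <- function(profile) {
  inreg <- profile$by_library["0", ]
  tot <- sum(inreg)
  data.frame(library = colnames(profile$by_library),
             in_register = as.integer(inreg),
             fraction = if (tot > 0) as.numeric(inreg / tot) else NA_real_,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Positions of 21-nt sRNA tags on a transcript
#'
#' Exact full-length matching of tags against one transcript; used to
#' populate [phasing_window()] from sRNA libraries.
#'
#' @param tags `tag_table` (see [collapse_reads()]).
#' @param transcript transcript sequence.
#' @param libraries library column names to extract counts from.
#' @return data.frame `position`, `length`, `count`, `library`.
#' @export
transcript_read_positions <- function(tags, transcript, libraries) {
  sel <- which(nchar(tags$sequence) == 21L)
  rows <- list()
  tx <- as_dna(transcript)
  if (length(sel)) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(as_dna(tags$sequence[sel])))
    m <- Biostrings::startIndex(Biostrings::matchPDict(pd, Biostrings::DNAString(tx)))
    nper <- lengths(m)
    st <- unlist(m, use.names = FALSE)
    hit_tag <- rep(sel, nper)
    for (lib in libraries) {
      cnt <- tags[[lib]][hit_tag]
      keep <- cnt > 0
      if (any(keep))
        rows[[length(rows) + 1L]] <- data.frame(
          position = st[keep], length = 21L, count = cnt[keep],
          library = lib, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(position = integer(0), length = integer(0),
                      count = integer(0), library = character(0)))
  do.call(rbind, rows)
}
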