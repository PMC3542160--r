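# Degradome (PARE) target validation: complementarity scoring of miRNA
# sites on transcripts, per-transcript t-plots of degradome tag 5' ends,
# and category 0-4 classification of cleavage signals.

#' Score one miRNA/target site alignment
#'
#' Penalties: mismatch 1.0, G:U wobble 0.5, gap (one bulged nucleotide on
#' either strand, interior only) 2.0; penalties are doubled at miRNA
#' positions 2-13 (5' end = position 1). The site is the transcript window
#' 5'->3'; its length may differ from the miRNA by at most one.
#'
#' @param mirna miRNA sequence (RNA).
#' @param site transcript window (DNA or RNA), length within miRNA +- 1.
#' @return list of class `target_alignment`: `score`, `mismatches`,
#'   `wobbles`, `gaps`, `gap_side`.
#' @export
score_target_site <- function(mirna, site) {
  res <- .score_site_cpp(as_rna(mirna), as_rna(site))
  structure(res, class = "target_alignment")
}

#' Scan a transcriptome for miRNA target sites
#'
#' Every window position is scored (ungapped and single-bulge
#' configurations; the ungapped width wins ties) and all sites at or below
#' `threshold` are reported, sorted by (score, transcript, position). The
#' guided-cleavage coordinate is the transcript base facing miRNA position
#' 10.
#'
#' @param mirna miRNA sequence.
#' @param transcripts named character vector of transcript sequences.
#' @param threshold maximum penalty score (4.5 for conserved and
#'   less-conserved miRNAs, 5 for novel and candidate ones).
#' @return data.frame: `transcript_id`, `start`, `width`, `score`,
#'   `cleavage_pos` (1-based transcript coordinates).
#' @export
scan_transcriptome <- function(mirna, transcripts, threshold) {
  rows <- lapply(names(transcripts), function(tx) {
    d <- .scan_transcript_cpp(as_rna(mirna), as_rna(transcripts[[tx]]),
                              threshold)
    if (nrow(d) == 0) return(NULL)
    cbind(transcript_id = tx, d, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(transcript_id = character(0), start = integer(0),
                      width = integer(0), score = numeric(0),
                      cleavage_pos = integer(0), stringsAsFactors = FALSE))
  out$cleavage_pos <- out$start + out$width - 10L
  out[order(out$score, out$transcript_id, out$start), , drop = FALSE]
}

#' Map degradome tags to transcripts by exact prefix match
#'
#' Each tag is placed at every transcript position where it matches
#' exactly; the matched position is the 5' end of a cleavage fragment.
#'
#' @param tags character vector of degradome tag sequences (redundant).
#' @param transcripts named character vector of transcript sequences.
#' @return list: `positions` (data.frame `transcript_id`, `position`,
#'   `count`) and `total` (total mapped tags, the tpb denominator).
#' @export
map_degradome <- function(tags, transcripts) {
  tb <- table(tags)
  uniq <- names(tb)
  cnt <- as.integer(tb)
  subj <- Biostrings::DNAStringSet(as_dna(transcripts))
  rows <- list()
  total <- 0
  for (w in unique(nchar(uniq))) {
    sel <- which(nchar(uniq) == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(as_dna(uniq[sel])))
    for (tx in names(transcripts)) {
      m <- Biostrings::startIndex(Biostrings::matchPDict(pd, subj[[tx]]))
      nper <- lengths(m)
      if (sum(nper) == 0) next
      st <- unlist(m, use.names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = tx, position = st,
        count = rep(cnt[sel], nper), stringsAsFactors = FALSE)
    }
  }
  pos <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript_id = character(0), position = integer(0),
               count = integer(0))
  if (nrow(pos)) {
    pos <- aggregate(count ~ transcript_id + position, pos, sum)
    pos <- pos[order(pos$transcript_id, pos$position), , drop = FALSE]
    total <- sum(pos$count)
  }
  list(positions = pos, total = total)
}

#' Build a transcript t-plot profile
#'
#' Per-position raw degradome tag counts (5' ends) and their tpb
#' normalization (`raw * 1e9 / total mapped tags`).
#'
#' @param transcript_id transcript to profile.
#' @param mapped result of [map_degradome()].
#' @param transcript_length transcript length in nt.
#' @return list of class `transcript_profile`: `transcript_id`, `raw`
#'   (integer vector over positions), `tpb`, `total`.
#' @export
build_tplot <- function(transcript_id, mapped, transcript_length) {
  if (mapped$total <= 0) stopf("no mapped degradome tags: tpb undefined")
  raw <- integer(transcript_length)
  sel <- mapped$positions$transcript_id == transcript_id
  raw[mapped$positions$position[sel]] <- mapped$positions$count[sel]
  structure(list(transcript_id = transcript_id, raw = raw,
                 tpb = raw * 1e9 / mapped$total, total = mapped$total),
            class = "transcript_profile")
}

#' Categorize a cleavage signal against its transcript profile
#'
#' With `r` the raw count at the cleavage position, `M` the transcript
#' maximum and `med` the median over covered positions (>= 1 tag):
#' category 4 if `r = 1`; else 0 if `r = M` and the maximum is unique;
#' else 1 if `r = M` (tied maximum); else 2 if `med < r < M`; else 3
#' (`1 < r <= med`). `r = 0` yields no category (status
#' `"no degradome evidence"`). The maximum is checked before the median
#' comparison so a transcript whose only covered position is the cleavage
#' site is category 0, not 3.
#'
#' @param profile a `transcript_profile`.
#' @param cleavage_pos 1-based transcript coordinate.
#' @return list: `category` (integer or NA), `status`, `raw`, `tpb`.
#' @export
categorize_cleavage <- function(profile, cleavage_pos) {
  raw <- profile$raw
  if (cleavage_pos < 1 || cleavage_pos > length(raw))
    stopf("cleavage position outside transcript")
  r <- raw[cleavage_pos]
  if (r == 0)
    return(list(category = NA_integer_, status = "no degradome evidence",
                raw = 0L, tpb = 0))
  covered <- raw[raw >= 1]
  M <- max(covered)
  med <- median(covered)
  category <- if (r == 1) 4L
  else if (r == M && sum(raw == M) == 1) 0L
  else if (r == M) 1L
  else if (r > med) 2L
  else 3L
  list(category = category, status = "ok", raw = r,
       tpb = profile$tpb[cleavage_pos])
}

#' Call degradome-validated targets
#'
#' For each alignment at or below its threshold, a call is emitted iff at
#' least one degradome tag starts at the guided-cleavage position.
#'
#' @param mirna_table data.frame with `mirna_id`, `sequence` and `class`
#'   (conserved / less-conserved / novel / candidate).
#' @param transcripts named character vector of transcript sequences.
#' @param tags degradome tag sequences (redundant vector).
#' @param thresholds named numeric, penalty ceiling per miRNA class.
#' @param annotations optional named character vector of transcript
#'   annotations passed through to the output.
#' @return list of class `target_calls`: `calls` (Table-style data.frame),
#'   `predictions` (all sites below threshold, with or without degradome
#'   support) and `mapped` (the [map_degradome()] result).
#' @export
call_targets <- function(mirna_table, transcripts, tags,
                         thresholds = c(conserved = 4.5,
                                        `less-conserved` = 4.5,
                                        novel = 5, candidate = 5),
                         annotations = NULL) {
  mapped <- map_degradome(tags, transcripts)
  profiles <- lapply(names(transcripts), function(tx)
    build_tplot(tx, mapped, nchar(transcripts[[tx]])))
  names(profiles) <- names(transcripts)
  pred_rows <- list(); call_rows <- list()
  for (i in seq_len(nrow(mirna_table))) {
    cls <- mirna_table$class[i]
    thr <- thresholds[[cls]]
    if (is.null(thr)) stopf("no alignment-score threshold for class '%s'", cls)
    sites <- scan_transcriptome(mirna_table$sequence[i], transcripts, thr)
    if (nrow(sites) == 0) next
    sites <- cbind(mirna_id = mirna_table$mirna_id[i], sites,
                   stringsAsFactors = FALSE)
    pred_rows[[length(pred_rows) + 1L]] <- sites
    for (j in seq_len(nrow(sites))) {
      prof <- profiles[[sites$transcript_id[j]]]
      cl <- categorize_cleavage(prof, sites$cleavage_pos[j])
      if (cl$status != "ok") next
      call_rows[[length(call_rows) + 1L]] <- data.frame(
        mirna_id = sites$mirna_id[j], target_gene = sites$transcript_id[j],
        align_score = sites$score[j], cleavage_pos = sites$cleavage_pos[j],
        raw = cl$raw, tpb = cl$tpb, category = cl$category,
        annotation = if (!is.null(annotations) &&
                         sites$transcript_id[j] %in% names(annotations))
          annotations[[sites$transcript_id[j]]] else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(call_rows)) do.call(rbind, call_rows) else
    data.frame(mirna_id = character(0), target_gene = character(0),
               align_score = numeric(0), cleavage_pos = integer(0),
               raw = integer(0), tpb = numeric(0), category = integer(0),
               annotation = character(0), stringsAsFactors = FALSE)
  preds <- if (length(pred_rows)) do.call(rbind, pred_rows) else
    data.frame(mirna_id = character(0))
  if (nrow(calls)) {
    # overlapping gapped/ungapped windows can hit the same cleavage site;
    # keep the best-scoring alignment per (miRNA, transcript, position)
    calls <- calls[order(calls$align_score), , drop = FALSE]
    calls <- calls[!duplicated(calls[, c("mirna_id", "target_gene",
                                         "cleavage_pos")]), , drop = FALSE]
    calls <- calls[order(calls$mirna_id, calls$target_gene), , drop = FALSE]
  }
  structure(list(calls = calls, predictions = preds, mapped = mapped,
                 profiles = profiles),
            class = "target_calls")
}
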