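# Readers, writers and tally summaries for the report-shaped tables: the
# novel/candidate miRNA table (per-tissue rpm, star sequence or "None
# detected") and the degradome target tables (align score, tpb, category).

#' Read a novel/candidate miRNA table
#'
#' Expected columns: `mirna`, `sequence`, `length`, `scaffold`,
#' `match_site`, `strand`, one rpm column per tissue, `total`,
#' `star_sequence` (`"None detected"` when no star read was found).
#'
#' @param path TSV file.
#' @param tissues tissue rpm column names.
#' @return data.frame.
#' @export
read_mirna_table <- function(path, tissues = c("root", "leaf", "flower", "fruit")) {
  d <- read_tsv(path)
  need <- c("mirna", "sequence", "length", "star_sequence", "total", tissues)
  if (!all(need %in% names(d)))
    stopf("miRNA table missing columns: %s",
          paste(setdiff(need, names(d)), collapse = ", "))
  d
}

#' Tally a novel/candidate miRNA table
#'
#' @param tab data.frame from [read_mirna_table()].
#' @param tissues tissue rpm column names.
#' @return list: `entries`, `novel` (star sequence reported), `candidate`
#'   (`"None detected"`), `by_length` (named vector), `row_total_consistent`
#'   (rows whose printed total equals the tissue rpm sum).
#' @export
mirna_table_summary <- function(tab, tissues = c("root", "leaf", "flower", "fruit")) {
  star <- tab$star_sequence != "None detected"
  bl <- table(tab$length)
  list(entries = nrow(tab),
       novel = sum(star),
       candidate = sum(!star),
       by_length = setNames(as.integer(bl), names(bl)),
       row_total_consistent =
         sum(rowSums(as.matrix(tab[, tissues])) == tab$total))
}

#' Read a degradome target table
#'
#' Expected columns: `mirna`, `target_gene`, `align_score`, `tpb`,
#' `category`, `annotation`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_target_table <- function(path) {
  d <- read_tsv(path)
  need <- c("mirna", "target_gene", "align_score", "category")
  if (!all(need %in% names(d)))
    stopf("target table missing columns: %s",
          paste(setdiff(need, names(d)), collapse = ", "))
  d
}

#' Tally a degradome target table
#'
#' @param tab data.frame from [read_target_table()].
#' @return list: `rows`, `unique_targets`, `distinct_mirnas`,
#'   `by_category` (named vector over categories present).
#' @export
target_table_summary <- function(tab) {
  bc <- table(tab$category[!is.na(tab$category)])
  list(rows = nrow(tab),
       unique_targets = length(unique(tab$target_gene)),
       distinct_mirnas = length(unique(tab$mirna)),
       by_category = setNames(as.integer(bc), names(bc)))
}

#' Write discovery calls as a report-shaped miRNA table
#'
#' rpm values are printed as rounded integers; full precision is kept in a
#' companion `<path>.full.tsv`.
#'
#' @param calls `mirna_calls` object from [discover_mirnas()].
#' @param path output TSV.
#' @param tissues tissue column names.
#' @return `path`, invisibly.
#' @export
write_mirna_table <- function(calls, path,
                              tissues = c("root", "leaf", "flower", "fruit")) {
  d <- calls$calls
  out <- data.frame(mirna = d$mirna_id, sequence = d$sequence,
                    length = d$length, scaffold = d$scaffold,
                    match_site = d$match_site, strand = d$strand,
                    stringsAsFactors = FALSE)
  for (t in tissues) out[[t]] <- round(d[[t]])
  out$total <- round(d$total_rpm)
  out$star_sequence <- d$star_sequence
  write_tsv(out, paste0(path))
  full <- out
  for (t in tissues) full[[t]] <- d[[t]]
  full$total <- d$total_rpm
  write_tsv(full, paste0(path, ".full.tsv"))
  invisible(path)
}

#' Write degradome calls as a report-shaped target table
#'
#' @param target_calls `target_calls` object from [call_targets()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_target_table <- function(target_calls, path) {
  d <- target_calls$calls
  out <- data.frame(mirna = d$mirna_id, target_gene = d$target_gene,
                    align_score = d$align_score, tpb = round(d$tpb, 1),
                    category = d$category, annotation = d$annotation,
                    stringsAsFactors = FALSE)
  write_tsv(out, path)
}

#' Export called miRNA loci as GFF3
#'
#' One `miRNA_primary_transcript` feature per accepted window and a child
#' `miRNA` feature for the mature match.
#'
#' @param calls `mirna_calls` object.
#' @param path output GFF3 file.
#' @return `path`, invisibly.
#' @export
write_locus_gff3 <- function(calls, path) {
  loci <- calls$loci
  ids <- calls$calls$mirna_id[match(loci$sequence, calls$calls$sequence)]
  prim <- GenomicRanges::GRanges(
    loci$scaffold,
    IRanges::IRanges(loci$window_start, loci$window_end),
    strand = loci$strand, type = "miRNA_primary_transcript",
    ID = paste0(ids, "_pri"))
  mat <- GenomicRanges::GRanges(
    loci$scaffold, IRanges::IRanges(loci$mature_start, loci$mature_end),
    strand = loci$strand, type = "miRNA",
    ID = ids, Parent = paste0(ids, "_pri"))
  rtracklayer::export(c(prim, mat), path, format = "gff3")
  invisible(path)
}

#' Export genome hits as BED (0-based half-open)
#'
#' @param hits data.frame from [map_tags()].
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  gr <- GenomicRanges::GRanges(hits$scaffold,
                               IRanges::IRanges(hits$start, hits$end),
                               strand = hits$strand)
  names(gr) <- hits$sequence
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write collapsed tags as FASTA with count headers
#'
#' Headers follow the `tag_N_xCOUNT` convention (total count across
#' libraries).
#'
#' @param tags `tag_table`.
#' @param path output FASTA.
#' @param libraries count columns to total.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(tags, path, libraries) {
  tot <- rowSums(as.matrix(tags[, libraries, drop = FALSE]))
  seqs <- setNames(as_dna(tags$sequence),
                   sprintf("tag_%d_x%d", seq_len(nrow(tags)), as.integer(tot)))
  write_fasta(seqs, path)
}
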