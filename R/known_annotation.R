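# Known-family assignment and non-coding-RNA screening: tags are compared
# to reference mature miRNAs and ncRNA fragments by ungapped alignment with
# up to two mismatches. All comparisons work in the RNA alphabet.

#' Read a reference set from FASTA with `name|family|class` headers
#'
#' @param path reference FASTA; headers of the form `name|family|class`
#'   (class `conserved` or `less-conserved`); family/class optional for
#'   ncRNA sets.
#' @return data.frame with `name`, `family`, `class`, `sequence` (RNA).
#' @export
read_reference_fasta <- function(path) {
  x <- read_fasta(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  data.frame(
    name = vapply(parts, `[`, character(1), 1),
    family = vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_,
                    character(1)),
    class = vapply(parts, function(p) if (length(p) >= 3) p[3] else NA_character_,
                   character(1)),
    sequence = as_rna(unname(x)), stringsAsFactors = FALSE)
}

#' Write a reference set as FASTA with `name|family|class` headers
#'
#' @param refs data.frame as produced by [read_reference_fasta()].
#' @param path output path.
#' @export
write_reference_fasta <- function(refs, path) {
  seqs <- setNames(as_dna(refs$sequence),
                   paste(refs$name, refs$family, refs$class, sep = "|"))
  write_fasta(seqs, path)
}

# minimum mismatches of each tag against each reference sequence;
# max_shift < 0 = free sliding (ncRNA rule), otherwise +-max_shift nt
min_mismatch_matrix <- function(tags, ref_seqs, max_overhang = 2L,
                                max_shift = -1L) {
  tags <- as_rna(tags)
  out <- matrix(NA_integer_, length(tags), length(ref_seqs))
  for (j in seq_along(ref_seqs))
    out[, j] <- .mismatch_scan_cpp(tags, as_rna(ref_seqs[[j]]),
                                   max_overhang, max_shift)
  out
}

#' Screen tags against a non-coding RNA reference set
#'
#' A tag is flagged for removal when it matches any ncRNA reference with at
#' most `max_mismatches` mismatches under ungapped alignment at any offset,
#' tolerating up to 2 nt of terminal overhang.
#'
#' @param tags character vector of tag sequences.
#' @param ncrna_refs named character vector (or data.frame with `sequence`)
#'   of ncRNA reference sequences.
#' @param max_mismatches mismatch tolerance (default 2).
#' @return logical vector, `TRUE` = remove.
#' @export
screen_ncrna <- function(tags, ncrna_refs, max_mismatches = 2L) {
  if (is.data.frame(ncrna_refs)) ncrna_refs <- ncrna_refs$sequence
  if (length(ncrna_refs) == 0) {
    warnf("empty ncRNA reference set: keeping all tags")
    return(rep(FALSE, length(tags)))
  }
  mm <- min_mismatch_matrix(tags, ncrna_refs, max_overhang = 2L, max_shift = -1L)
  apply(mm, 1, function(r) any(!is.na(r) & r <= max_mismatches))
}

#' Assign tags to known miRNA families
#'
#' Each 20-22 nt tag is compared to every reference mature sequence under
#' ungapped alignment with 5'-end offsets within 2 nt and reference length
#' within 2 nt of the tag. The best assignment minimises
#' (mismatches, |length difference|, reference name); tags whose minimum
#' exceeds `max_mismatches` are unassigned.
#'
#' @param tags character vector of tag sequences (20-22 nt).
#' @param refs reference data.frame (`name`, `family`, `class`,
#'   `sequence`), see [read_reference_fasta()].
#' @param max_mismatches mismatch tolerance (default 2).
#' @return data.frame with one row per assigned tag: `sequence`,
#'   `ref_name`, `family`, `class`, `mismatches`.
#' @export
assign_known <- function(tags, refs, max_mismatches = 2L) {
  len <- nchar(tags)
  if (any(len < 20 | len > 22))
    stopf("assign_known expects 20-22 nt tags")
  mm <- min_mismatch_matrix(tags, refs$sequence, max_overhang = 2L,
                            max_shift = 2L)
  lend <- abs(outer(nchar(tags), nchar(refs$sequence), `-`))
  mm[lend > 2L] <- NA_integer_
  rows <- lapply(seq_along(tags), function(i) {
    cand <- which(!is.na(mm[i, ]) & mm[i, ] <= max_mismatches)
    if (!length(cand)) return(NULL)
    ord <- order(mm[i, cand], lend[i, cand], refs$name[cand])
    j <- cand[ord[1]]
    data.frame(sequence = tags[i], ref_name = refs$name[j],
               family = refs$family[j], class = refs$class[j],
               mismatches = mm[i, j], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sequence = character(0), ref_name = character(0),
                      family = character(0), class = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE)
  out
}

#' Screen and assign tags with documented precedence
#'
#' A tag within two mismatches of both an ncRNA and a known miRNA reference
#' goes to whichever is closer; ties go to the miRNA. Tags closer to an
#' ncRNA are removed.
#'
#' @param tags character vector of 20-22 nt tag sequences.
#' @param known_refs known-miRNA reference data.frame.
#' @param ncrna_refs ncRNA reference sequences (vector or data.frame).
#' @param max_mismatches mismatch tolerance.
#' @return list with `assignments` (as [assign_known()]), `removed`
#'   (logical: ncRNA-matched), `unassigned` (logical).
#' @export
annotate_tags <- function(tags, known_refs, ncrna_refs,
                          max_mismatches = 2L) {
  if (is.data.frame(ncrna_refs)) ncrna_refs <- ncrna_refs$sequence
  asg <- assign_known(tags, known_refs, max_mismatches)
  known_mm <- rep(NA_integer_, length(tags))
  known_mm[match(asg$sequence, tags)] <- asg$mismatches
  nc_mm <- rep(NA_integer_, length(tags))
  if (length(ncrna_refs)) {
    m <- min_mismatch_matrix(tags, ncrna_refs, 2L, -1L)
    nc_mm <- apply(m, 1, min, na.rm = TRUE)
    nc_mm[!is.finite(nc_mm)] <- NA_integer_
  }
  nc_hit <- !is.na(nc_mm) & nc_mm <= max_mismatches
  removed <- nc_hit & (is.na(known_mm) | nc_mm < known_mm)   # tie -> miRNA
  assigned <- !is.na(known_mm) & !removed
  asg <- asg[asg$sequence %in% tags[assigned], , drop = FALSE]
  list(assignments = asg, removed = removed,
       unassigned = !assigned & !removed)
}

#' Family-level expression table
#'
#' Sums the rpm of each family's member tags, per library. Each tag belongs
#' to exactly one family, so per-library grand totals equal the sum of
#' assigned-tag rpm.
#'
#' @param assignments data.frame from [assign_known()].
#' @param rpm matrix of rpm values with rownames (or row order) matching
#'   `tag_sequences`.
#' @param tag_sequences tag sequences parallel to the rows of `rpm`.
#' @return data.frame: `family`, `class`, one rpm column per library, and
#'   `total`.
#' @export
family_expression_table <- function(assignments, rpm, tag_sequences) {
  idx <- match(assignments$sequence, tag_sequences)
  if (anyNA(idx)) stopf("assignments contain tags absent from the rpm table")
  libs <- colnames(rpm)
  fams <- unique(assignments[, c("family", "class")])
  out <- fams
  for (l in libs) {
    out[[l]] <- vapply(fams$family, function(f)
      sum(rpm[idx[assignments$family == f], l]), numeric(1))
  }
  out$total <- rowSums(as.matrix(out[, libs, drop = FALSE]))
  out[order(-out$total), , drop = FALSE]
}
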