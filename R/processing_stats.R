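# Precursor-processing statistics from RNA-blot band intensities:
# APE (arbitrary processing efficiency, %) and RTA (relative transcription
# activity), plus a rank-correlation summary of their coupling.

#' Arbitrary processing efficiency (APE, %)
#'
#' `APE = SFI * 100 / (LFI + SFI)`: the percentage of a locus' blot signal
#' found in the processed small (mature miRNA) fragment rather than the
#' unprocessed precursor fragment.
#'
#' @param sfi small-fragment intensity (arbitrary units, >= 0).
#' @param lfi large-fragment intensity (arbitrary units, >= 0).
#' @return APE in `[0, 100]`; `NA` with a warning when `SFI + LFI = 0`
#'   (no signal).
#' @export
ape <- function(sfi, lfi) {
  stopifnot(all(sfi >= 0), all(lfi >= 0))
  out <- sfi * 100 / (lfi + sfi)
  nosig <- (sfi + lfi) == 0
  if (any(nosig)) {
    warnf("no signal (SFI + LFI = 0) in %d record(s): APE undefined", sum(nosig))
    out[nosig] <- NA_real_
  }
  out
}

#' Relative transcription activity (RTA)
#'
#' `RTA = (LFI + SFI) / CFI`: total locus signal relative to the loading
#' control band.
#'
#' @param sfi,lfi as in [ape()].
#' @param cfi control-fragment intensity (> 0).
#' @return RTA ratio.
#' @export
rta <- function(sfi, lfi, cfi) {
  stopifnot(all(sfi >= 0), all(lfi >= 0))
  if (any(cfi <= 0)) stopf("CFI must be positive for RTA")
  (lfi + sfi) / cfi
}

#' Per-sample APE/RTA table with an uncoupling summary
#'
#' Computes APE and RTA for every sample and summarises whether processing
#' tracks transcription by the Spearman rank correlation between APE and
#' RTA across samples (intensities are arbitrary units, so only ranks are
#' meaningful). Zero variance in either statistic flags the correlation as
#' undefined.
#'
#' @param records data.frame with columns `sample`, `SFI`, `LFI`, `CFI`.
#' @return list of class `processing_report`: `table` (sample, APE, RTA),
#'   `rho`, `p_value`, `status`.
#' @export
processing_report <- function(records) {
  req <- c("sample", "SFI", "LFI", "CFI")
  if (!all(req %in% names(records)))
    stopf("records must have columns %s", paste(req, collapse = ", "))
  if (nrow(records) < 2) stopf("need at least two samples")
  tab <- data.frame(sample = records$sample,
                    APE = ape(records$SFI, records$LFI),
                    RTA = rta(records$SFI, records$LFI, records$CFI),
                    stringsAsFactors = FALSE)
  ok <- stats::complete.cases(tab[, c("APE", "RTA")])
  if (sum(ok) >= 2 && stats::sd(tab$APE[ok]) > 0 && stats::sd(tab$RTA[ok]) > 0) {
    ct <- suppressWarnings(cor.test(tab$APE[ok], tab$RTA[ok],
                                    method = "spearman", exact = FALSE))
    res <- list(table = tab, rho = unname(ct$estimate),
                p_value = ct$p.value, status = "ok")
  } else {
    res <- list(table = tab, rho = NA_real_, p_value = NA_real_,
                status = "correlation undefined (zero variance)")
  }
  structure(res, class = "processing_report")
}

#' Read a band-intensity TSV
#'
#' Expected columns: `sample`, `SFI`, `LFI`, `CFI`.
#'
#' @param path TSV file.
#' @return data.frame of intensity records.
#' @export
read_band_intensities <- function(path) {
  d <- read_tsv(path)
  if (!all(c("sample", "SFI", "LFI", "CFI") %in% names(d)))
    stopf("band-intensity table must have columns sample, SFI, LFI, CFI")
  d
}
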