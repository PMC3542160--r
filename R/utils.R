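#' @useDynLib mirphas, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import Biostrings
#' @importFrom stats rpois rbinom rnbinom median cor.test pbinom runif aggregate setNames
#' @importFrom utils write.table read.delim modifyList
NULL

# Run code with a temporarily fixed RNG seed, restoring the caller's RNG
# state afterwards. All stochastic generators funnel through this.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

RNA_BASES <- c("A", "C", "G", "U")
DNA_BASES <- c("A", "C", "G", "T")

#' Convert between DNA and RNA string alphabets
#'
#' Plain-character helpers used throughout: sequences at the miRNA level are
#' handled as RNA strings, genome/transcript sequences as DNA.
#'
#' @param x character vector of sequences.
#' @return character vector in the other alphabet.
#' @export
as_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' @rdname as_rna
#' @export
as_dna <- function(x) chartr("Uu", "Tt", toupper(x))

#' Reverse complement of plain character sequences
#'
#' Works on DNA or RNA strings (U is complemented to A and vice versa).
#'
#' @param x character vector.
#' @return character vector of reverse complements, same alphabet as input.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    s <- toupper(s)
    rna <- grepl("U", s, fixed = TRUE)
    comp <- if (rna) chartr("ACGU", "UGCA", s) else chartr("ACGT", "TGCA", s)
    paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# random sequence with a given GC fraction (DNA alphabet)
random_dna <- function(n_bases, gc_fraction) {
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  paste(sample(names(p), n_bases, replace = TRUE, prob = p), collapse = "")
}

# substring that tolerates 1-based inclusive coords
subseq_chr <- function(s, start, end) substr(s, start, end)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Write sequences as FASTA
#'
#' Thin wrapper around [Biostrings::writeXStringSet()] accepting named
#' character vectors (DNA alphabet).
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(as_dna(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a FASTA/FASTQ file into a named character vector
#'
#' Collapsed-count headers of the form `tag_12_x345` are recognised by
#' [parse_collapsed_counts()].
#'
#' @param path input FASTA or FASTQ file (plain or gzipped).
#' @param format `"fasta"` or `"fastq"`; guessed from the extension by default.
#' @return named character vector of upper-case DNA sequences.
#' @export
read_fasta <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  }
  x <- if (format == "fastq") Biostrings::readDNAStringSet(path, format = "fastq")
  else Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Expand collapsed-count FASTA headers into per-read multiplicities
#'
#' Collapsed sRNA FASTA conventionally encodes read counts in headers such
#' as `tag_7_x123` (tag number 7 seen 123 times). Headers without a `_xN`
#' suffix count as 1.
#'
#' @param headers character vector of FASTA headers.
#' @return integer vector of counts.
#' @export
parse_collapsed_counts <- function(headers) {
  m <- regmatches(headers, regexpr("_x([0-9]+)\\s*$", headers))
  counts <- rep(1L, length(headers))
  has <- lengths(regmatches(headers, gregexpr("_x([0-9]+)\\s*$", headers))) > 0
  counts[has] <- as.integer(sub("^_x", "", m))
  counts
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}
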