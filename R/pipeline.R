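# End-to-end orchestration: a single config drives simulation (or file
# input), preprocessing, known-family annotation, hairpin discovery,
# degradome validation, phasing and the APE/RTA report, with a manifest
# recording seeds, parameters and per-stage record counts.

#' Assemble a pipeline configuration
#'
#' All numeric criteria of the analysis live here: mismatch tolerance for
#' known-family assignment (2), duplex caps (4 mismatches, 1 bulge),
#' pair/uniqueness fractions (0.75, strict), alignment-score thresholds
#' (4.5 conserved/less-conserved, 5 novel/candidate), window flank, and
#' the master seed.
#'
#' @param out_dir output directory for result tables.
#' @param seed master seed.
#' @param simulate `TRUE` to generate inputs with [simulate_study()];
#'   otherwise supply file paths.
#' @param depth simulated reads per library.
#' @param genome_fasta,library_fastas,known_ref_fasta,ncrna_ref_fasta,degradome_fasta,transcriptome_fasta,intensity_tsv
#'   input files for non-simulated runs (`library_fastas`: named vector).
#' @param adapter 3' adapter (`NULL` = pre-trimmed input).
#' @param ... overrides for the threshold block (`mismatches`,
#'   `duplex_mismatches`, `bulges`, `pair_fraction`,
#'   `uniqueness_fraction`, `align_threshold_known`,
#'   `align_threshold_novel`, `flank`, `min_reads`, `min_len`, `max_len`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("mirphas_run_"), seed = 1,
                            simulate = TRUE, depth = 50000L,
                            genome_fasta = NULL, library_fastas = NULL,
                            known_ref_fasta = NULL, ncrna_ref_fasta = NULL,
                            degradome_fasta = NULL, transcriptome_fasta = NULL,
                            intensity_tsv = NULL,
                            adapter = DEFAULT_ADAPTER, ...) {
  thresholds <- modifyList(list(
    mismatches = 2L, duplex_mismatches = 4L, bulges = 1L,
    pair_fraction = 0.75, uniqueness_fraction = 0.75,
    align_threshold_known = 4.5, align_threshold_novel = 5,
    flank = 150L, min_reads = 5L, min_len = 15L, max_len = 31L), list(...))
  stopifnot(thresholds$pair_fraction >= 0, thresholds$pair_fraction <= 1,
            thresholds$uniqueness_fraction >= 0,
            thresholds$uniqueness_fraction <= 1,
            thresholds$duplex_mismatches >= 0, thresholds$bulges >= 0)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = isTRUE(simulate), depth = as.integer(depth),
                 inputs = list(genome_fasta = genome_fasta,
                               library_fastas = library_fastas,
                               known_ref_fasta = known_ref_fasta,
                               ncrna_ref_fasta = ncrna_ref_fasta,
                               degradome_fasta = degradome_fasta,
                               transcriptome_fasta = transcriptome_fasta,
                               intensity_tsv = intensity_tsv),
                 adapter = adapter, thresholds = thresholds),
            class = "pipeline_config")
}

#' Serialize / deserialize a pipeline configuration (JSON)
#'
#' @param config a `pipeline_config`.
#' @param path JSON file.
#' @return `read_config` returns the configuration; `write_config` the
#'   path, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$inputs <- lapply(x$inputs, function(v) if (length(v)) v else NULL)
  structure(x, class = "pipeline_config")
}

stage_fail <- function(stage, code, msg) {
  stopf("[stage:%s] [%s] %s", stage, code, msg)
}

#' Run the full pipeline
#'
#' Stages, in order: input (simulation or file parsing), preprocessing
#' (trim/collapse/map/rpm + length-distribution tables), known-family
#' annotation, novel/candidate miRNA discovery, degradome target
#' validation, phasing at validated cleavage sites, APE/RTA (when an
#' intensity table is supplied). Missing degradome input skips the target
#' and phasing stages (noted in the manifest). All tables are written to
#' `config$out_dir`; reruns with the same seed are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with the in-memory stage
#'   results and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   version = as.character(utils::packageVersion("mirphas")),
                   stages = list())
  note <- function(stage, ...) manifest$stages[[stage]] <<- list(...)

  # ---- inputs ----
  if (config$simulate) {
    sim <- simulate_study(seed = config$seed, depth = config$depth,
                          adapter = config$adapter)
    raw_reads <- sim$libraries$reads
    genome <- sim$genome
    known_refs <- sim$known_refs
    ncrna_refs <- sim$ncrna_refs
    degradome_tags <- sim$degradome$tags
    transcriptome <- sim$transcriptome
    intensities <- NULL
  } else {
    inp <- config$inputs
    if (is.null(inp$genome_fasta) || is.null(inp$library_fastas))
      stage_fail("input", "E_INPUT", "genome and library FASTA paths required")
    genome <- read_fasta(inp$genome_fasta)
    raw_reads <- lapply(inp$library_fastas, function(p) {
      x <- read_fasta(p)
      rep(unname(x), parse_collapsed_counts(names(x)))
    })
    known_refs <- if (!is.null(inp$known_ref_fasta))
      read_reference_fasta(inp$known_ref_fasta) else NULL
    ncrna_refs <- if (!is.null(inp$ncrna_ref_fasta))
      unname(read_fasta(inp$ncrna_ref_fasta)) else character(0)
    degradome_tags <- if (!is.null(inp$degradome_fasta)) {
      x <- read_fasta(inp$degradome_fasta)
      rep(unname(x), parse_collapsed_counts(names(x)))
    } else NULL
    transcriptome <- if (!is.null(inp$transcriptome_fasta))
      read_fasta(inp$transcriptome_fasta) else NULL
    intensities <- if (!is.null(inp$intensity_tsv))
      read_band_intensities(inp$intensity_tsv) else NULL
  }
  if (config$simulate) intensities <- NULL
  note("input", libraries = length(raw_reads),
       reads = sum(lengths(raw_reads)), scaffolds = length(genome))

  th <- config$thresholds
  # ---- preprocessing ----
  processed <- preprocess_libraries(raw_reads, genome,
                                    adapter = config$adapter,
                                    min_len = th$min_len, max_len = th$max_len)
  write_tsv(processed$stats, file.path(config$out_dir, "library_stats.tsv"))
  jsonlite::write_json(processed$stats, file.path(config$out_dir,
                                                  "library_stats.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  lt <- length_distribution(processed)
  write_tsv(lt, file.path(config$out_dir, "length_distribution.tsv"))
  note("preprocess", tags = nrow(processed$tags),
       matched_tags = sum(processed$tags$n_hits > 0))

  # ---- known annotation ----
  len <- nchar(processed$tags$sequence)
  cand_len <- len >= 20 & len <= 22
  annotation <- NULL
  if (!is.null(known_refs)) {
    annotation <- annotate_tags(processed$tags$sequence[cand_len],
                                known_refs, ncrna_refs,
                                max_mismatches = th$mismatches)
    fam <- family_expression_table(
      annotation$assignments,
      processed$rpm[cand_len, , drop = FALSE],
      processed$tags$sequence[cand_len])
    write_tsv(fam, file.path(config$out_dir, "known_family_rpm.tsv"))
    note("annotate_known", assigned = nrow(annotation$assignments),
         removed_ncrna = sum(annotation$removed), families = nrow(fam))
  } else note("annotate_known", skipped = TRUE)

  # ---- discovery ----
  calls <- discover_mirnas(processed, annotation, genome,
                           flank = th$flank, min_reads = th$min_reads,
                           max_mismatches = th$duplex_mismatches,
                           max_bulges = th$bulges,
                           pair_fraction = th$pair_fraction,
                           uniqueness_fraction = th$uniqueness_fraction)
  write_mirna_table(calls, file.path(config$out_dir, "novel_mirnas.tsv"))
  if (nrow(calls$loci))
    write_locus_gff3(calls, file.path(config$out_dir, "novel_mirnas.gff3"))
  note("discover", calls = nrow(calls$calls),
       novel = sum(calls$calls$class == "novel"),
       candidate = sum(calls$calls$class == "candidate"),
       loci = nrow(calls$loci))

  # ---- degradome targets ----
  targets <- NULL
  phasing_out <- NULL
  if (!is.null(degradome_tags) && !is.null(transcriptome)) {
    mt <- rbind(
      if (nrow(calls$calls)) data.frame(mirna_id = calls$calls$mirna_id,
                                        sequence = calls$calls$sequence,
                                        class = calls$calls$class,
                                        stringsAsFactors = FALSE),
      if (!is.null(annotation) && nrow(annotation$assignments))
        data.frame(mirna_id = annotation$assignments$ref_name,
                   sequence = annotation$assignments$sequence,
                   class = annotation$assignments$class,
                   stringsAsFactors = FALSE))
    if (is.null(mt) || nrow(mt) == 0)
      stage_fail("degradome", "E_NO_MIRNAS",
                 "no miRNAs available for target scanning")
    mt <- mt[!duplicated(mt$mirna_id), , drop = FALSE]
    targets <- call_targets(
      mt, transcriptome, degradome_tags,
      thresholds = c(conserved = th$align_threshold_known,
                     `less-conserved` = th$align_threshold_known,
                     novel = th$align_threshold_novel,
                     candidate = th$align_threshold_novel))
    write_target_table(targets, file.path(config$out_dir, "targets.tsv"))
    tp <- targets$mapped$positions
    write_tsv(tp, file.path(config$out_dir, "tplot_positions.tsv"))
    note("degradome", predictions = nrow(targets$predictions),
         calls = nrow(targets$calls),
         distinct_mirnas = length(unique(targets$calls$mirna_id)),
         distinct_targets = length(unique(targets$calls$target_gene)))

    # ---- phasing at validated cleavage sites ----
    prof_rows <- list()
    anchors <- unique(targets$calls[, c("target_gene", "cleavage_pos")])
    for (i in seq_len(nrow(anchors))) {
      tx <- anchors$target_gene[i]
      reads <- transcript_read_positions(processed$tags, transcriptome[[tx]],
                                         processed$libraries)
      win <- phasing_window(tx, anchors$cleavage_pos[i], reads)
      prof <- assign_registers(win)
      if (prof$total < 10) next
      acc <- tissue_accumulation(prof)
      prof_rows[[length(prof_rows) + 1L]] <- data.frame(
        transcript_id = tx, anchor = anchors$cleavage_pos[i],
        register = 0:20, count = as.integer(prof$counts),
        phase_fraction = prof$phase_fraction,
        dominant = prof$dominant, stringsAsFactors = FALSE)
      write_tsv(acc, file.path(config$out_dir,
                               sprintf("phasing_tissue_%s.tsv", tx)))
    }
    phasing_out <- if (length(prof_rows)) do.call(rbind, prof_rows) else NULL
    if (!is.null(phasing_out))
      write_tsv(phasing_out, file.path(config$out_dir, "phasing_registers.tsv"))
    note("phasing", loci = length(prof_rows))
  } else {
    note("degradome", skipped = TRUE)
    note("phasing", skipped = TRUE)
  }

  # ---- processing statistics ----
  if (!is.null(intensities)) {
    preport <- processing_report(intensities)
    write_tsv(preport$table, file.path(config$out_dir, "ape_rta.tsv"))
    note("processing_stats", samples = nrow(preport$table), rho = preport$rho)
  } else note("processing_stats", skipped = TRUE)

  cfg_path <- file.path(config$out_dir, "config.json")
  write_config(config, cfg_path)
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(processed = processed, annotation = annotation,
                 calls = calls, targets = targets, phasing = phasing_out,
                 manifest = manifest, out_dir = config$out_dir),
            class = "pipeline_result")
}

#' Summarize result tables into report totals
#'
#' @param mirna_table data.frame from [read_mirna_table()] (or NULL).
#' @param target_table data.frame from [read_target_table()] (or NULL).
#' @param loci optional loci data.frame (from `mirna_calls$loci`).
#' @return list of totals: miRNA calls by class, per-length counts,
#'   star-detected count, loci count, target counts and distinct targeted
#'   miRNAs.
#' @export
summarize_counts <- function(mirna_table = NULL, target_table = NULL,
                             loci = NULL) {
  out <- list(mirna_entries = 0L, novel = 0L, candidate = 0L,
              by_length = integer(0), star_detected = 0L, loci = 0L,
              target_rows = 0L, unique_targets = 0L, targeted_mirnas = 0L)
  if (!is.null(mirna_table) && nrow(mirna_table)) {
    s <- mirna_table_summary(mirna_table,
                             tissues = intersect(
                               c("root", "leaf", "flower", "fruit"),
                               names(mirna_table)))
    out$mirna_entries <- s$entries
    out$novel <- s$novel
    out$candidate <- s$candidate
    out$by_length <- s$by_length
    out$star_detected <- s$novel
  }
  if (!is.null(loci)) out$loci <- nrow(loci)
  if (!is.null(target_table) && nrow(target_table)) {
    t <- target_table_summary(target_table)
    out$target_rows <- t$rows
    out$unique_targets <- t$unique_targets
    out$targeted_mirnas <- t$distinct_mirnas
  }
  out
}
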