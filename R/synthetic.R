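# Synthetic-data generators: a toy genome with planted miRNA hairpins,
# TAS-like phased-siRNA loci and degradome cleavage signals, each with a
# ground-truth table, so the whole pipeline can be exercised and its
# recovery measured without any external data.

#' Specification of a toy genome
#'
#' @param scaffold_count number of scaffolds.
#' @param scaffold_length length of each scaffold in nt (>= 1000).
#' @param gc_fraction GC content of the random background sequence.
#' @param seed integer seed; identical seeds give byte-identical genomes.
#' @return an object of class `toy_genome_spec`.
#' @export
toy_genome_spec <- function(scaffold_count = 8, scaffold_length = 50000,
                            gc_fraction = 0.38, seed = 1) {
  if (scaffold_length < 1000) stopf("scaffold_length must be >= 1000")
  if (gc_fraction <= 0 || gc_fraction >= 1) stopf("gc_fraction must be in (0, 1)")
  structure(list(scaffold_count = as.integer(scaffold_count),
                 scaffold_length = as.integer(scaffold_length),
                 gc_fraction = gc_fraction, seed = as.integer(seed)),
            class = "toy_genome_spec")
}

# positions (1-based, within the mature) whose star partner is mutated to a
# non-pairing base; interior and spaced so the surrounding stem stays locked
MISMATCH_SLOTS <- c(5L, 8L, 11L, 14L, 17L)

# a base that pairs neither `m` (canonically or by wobble) nor anything in
# an A/C-alphabet loop; keeps planted defects from creating alternative
# pairings under maximum-base-pair folding (A/U -> C since C only pairs G;
# C/G -> A since A only pairs U)
inert_base <- function(m) ifelse(m %in% c("A", "U"), "C", "A")

# default terminal loop: folds into its own tight hairpin (random arm +
# GAAA apex + reverse complement), so under maximum-base-pair folding the
# loop pairs with itself and leaves the planted mature/star stem intact
random_loop <- function(n = 48L) {
  arm <- (n - 4L) %/% 2L
  l1 <- as_rna(random_dna(arm, 0.5))
  paste0(l1, "GAAA", revcomp(l1))
}

#' Construct a planted miRNA hairpin
#'
#' Builds a star strand as the duplex partner of `mature` with 2-nt 3'
#' overhangs on both strands, plants `duplex_mismatches` symmetric
#' mismatches and up to one asymmetric bulge, and assembles the precursor
#' (`mature + loop + star` for a 5' arm mature, the reverse for 3').
#'
#' @param id feature identifier.
#' @param mature mature miRNA sequence, RNA alphabet, 20-22 nt.
#' @param tissue_profile named numeric vector of expected rpm per library.
#' @param duplex_mismatches number of planted duplex mismatches (0-4, or 5
#'   when `negative_control = TRUE`).
#' @param bulges number of planted asymmetric bulges (0-1, or 2 when
#'   `negative_control = TRUE`).
#' @param arm which precursor arm carries the mature sequence.
#' @param loop_seq terminal loop sequence; random (48 nt) when `NULL`.
#' @param scaffold,start,strand optional genomic placement; filled in by
#'   [generate_genome()] when `NA`.
#' @param negative_control lift the canonical-hairpin caps so deliberately
#'   failing features can be planted.
#' @return an object of class `planted_mirna`.
#' @export
planted_mirna <- function(id, mature, tissue_profile,
                          duplex_mismatches = 0L, bulges = 0L,
                          arm = c("5p", "3p"), loop_seq = NULL,
                          scaffold = NA, start = NA, strand = "+",
                          negative_control = FALSE) {
  arm <- match.arg(arm)
  mature <- as_rna(mature)
  L <- nchar(mature)
  if (L < 20 || L > 22) stopf("mature sequence must be 20-22 nt (got %d)", L)
  if (!negative_control && duplex_mismatches > 4)
    stopf("duplex_mismatches must be <= 4 for a canonical hairpin")
  if (!negative_control && bulges > 1)
    stopf("bulges must be <= 1 for a canonical hairpin")
  if (is.null(loop_seq)) loop_seq <- random_loop()
  mb <- strsplit(mature, "")[[1]]
  # duplex geometry: star position j pairs mature position L-1-j, so the
  # star core is the reverse complement of mature[1..L-2]; two 3'-overhang
  # bases are appended (they stay unpaired at the hairpin base)
  core <- revcomp(substr(mature, 1, L - 2))
  sb <- strsplit(core, "")[[1]]
  mm_pos <- head(MISMATCH_SLOTS, duplex_mismatches)
  for (i in mm_pos) sb[L - 1 - i] <- inert_base(mb[i])
  if (bulges >= 1) sb <- append(sb, inert_base(mb[10]), after = L - 11L)
  if (bulges >= 2) sb <- append(sb, inert_base(mb[16]), after = L - 17L)
  overhang <- c("A", "A")
  star <- paste(c(sb, overhang), collapse = "")
  precursor <- if (arm == "5p") paste0(mature, loop_seq, star)
               else paste0(star, loop_seq, mature)
  structure(list(id = id, mature_seq = mature, star_seq = star,
                 loop_seq = loop_seq, precursor_seq = precursor,
                 duplex_mismatches = as.integer(duplex_mismatches),
                 bulges = as.integer(bulges), arm = arm,
                 scaffold = scaffold, start = start, strand = strand,
                 tissue_profile = tissue_profile),
            class = "planted_mirna")
}

#' Construct a planted TAS-like locus
#'
#' The transcript carries a trigger-miRNA binding site whose guided cleavage
#' point anchors 21-nt phased siRNA production downstream.
#'
#' @param id feature identifier.
#' @param trigger a [planted_mirna()] (or any object with `$mature_seq`)
#'   acting as the cleavage trigger.
#' @param cleavage_pos 1-based transcript coordinate of the 5' end of the 3'
#'   cleavage fragment (the base facing miRNA position 10).
#' @param phased_sirna_count number of consecutive 21-nt phase cycles that
#'   produce siRNAs.
#' @param off_phase_noise_fraction fraction of emitted TAS reads placed out
#'   of register (in `[0, 1)`).
#' @param tissue_profile named numeric vector, expected rpm of phased reads
#'   per library.
#' @param scaffold,start,strand optional genomic placement.
#' @return an object of class `planted_tas`.
#' @export
planted_tas <- function(id, trigger, cleavage_pos = 80L,
                        phased_sirna_count = 8L,
                        off_phase_noise_fraction = 0.1,
                        tissue_profile,
                        scaffold = NA, start = NA, strand = "+") {
  if (off_phase_noise_fraction < 0 || off_phase_noise_fraction >= 1)
    stopf("off_phase_noise_fraction must be in [0, 1)")
  mat <- trigger$mature_seq
  L <- nchar(mat)
  site_start <- cleavage_pos + 10L - L
  if (site_start < 1) stopf("cleavage_pos too close to the transcript 5' end")
  tx_len <- cleavage_pos + 21L * phased_sirna_count + 40L
  tx <- strsplit(random_dna(tx_len, 0.42), "")[[1]]
  site <- strsplit(as_dna(revcomp(mat)), "")[[1]]
  tx[site_start:(site_start + L - 1)] <- site
  structure(list(id = id, transcript_seq = paste(tx, collapse = ""),
                 trigger_id = trigger$id,
                 trigger_seq = mat, cleavage_pos = as.integer(cleavage_pos),
                 site_start = as.integer(site_start),
                 phased_sirna_count = as.integer(phased_sirna_count),
                 off_phase_noise_fraction = off_phase_noise_fraction,
                 tissue_profile = tissue_profile,
                 scaffold = scaffold, start = start, strand = strand),
            class = "planted_tas")
}

#' Construct a planted degradome target
#'
#' Builds a transcript containing a complementarity site for `mirna` whose
#' penalty score equals `intended_align_score` (achieved with 3'-region
#' mismatches and, for half points, one G:U wobble), plus the degradome
#' signal expected at the guided cleavage position.
#'
#' @param transcript_id identifier for the target transcript.
#' @param mirna a [planted_mirna()] or any object with `$mature_seq`/`$id`.
#' @param intended_align_score target alignment penalty, `<= 5`.
#' @param tag_count degradome tags planted at the guided-cleavage position.
#' @param background_tag_rate uniform background tags per transcript nt.
#' @param transcript_length transcript length in nt.
#' @param site_start 1-based position of the site on the transcript.
#' @return an object of class `planted_target`.
#' @export
planted_target <- function(transcript_id, mirna, intended_align_score = 0,
                           tag_count = 50L, background_tag_rate = 0.02,
                           transcript_length = 400L, site_start = 150L) {
  if (intended_align_score > 5) stopf("intended_align_score must be <= 5")
  mat <- mirna$mature_seq
  L <- nchar(mat)
  mb <- strsplit(mat, "")[[1]]
  site <- strsplit(as_dna(revcomp(mat)), "")[[1]]   # perfect complement
  # weight-1 miRNA positions, 3' region first (interior, outside 2-13 core)
  slots <- seq(L - 2L, 14L)
  n_mm <- floor(intended_align_score)
  if (intended_align_score %% 1 != 0) {
    # half point: one G:U wobble at a weight-1 position (needs G or U)
    wob <- slots[mb[slots] %in% c("G", "U")][1]
    if (is.na(wob))
      stopf("cannot plant a %s-score site for %s: no wobble-capable position",
            intended_align_score, mirna$id)
    site[L + 1 - wob] <- if (mb[wob] == "G") "T" else "G"
    slots <- setdiff(slots, wob)
  }
  if (n_mm > length(slots))
    stopf("cannot plant a site of score %s for %s", intended_align_score, mirna$id)
  for (i in head(slots, n_mm))
    site[L + 1 - i] <- as_dna(mb[i])                # same base: mismatch, 1.0
  tx <- strsplit(random_dna(transcript_length, 0.42), "")[[1]]
  tx[site_start:(site_start + L - 1)] <- site
  cleavage_pos <- site_start + L - 10L
  structure(list(transcript_id = transcript_id, mirna_id = mirna$id,
                 mirna_seq = mat,
                 transcript_seq = paste(tx, collapse = ""),
                 site_start = as.integer(site_start),
                 site_end = as.integer(site_start + L - 1L),
                 cleavage_pos = as.integer(cleavage_pos),
                 intended_align_score = intended_align_score,
                 tag_count = as.integer(tag_count),
                 background_tag_rate = background_tag_rate),
            class = "planted_target")
}

#' Generate a toy genome with planted features
#'
#' Writes every planted miRNA precursor and TAS transcript into random
#' scaffold sequence at recorded (or automatically assigned, non-overlapping)
#' coordinates, and returns the genome with a ground-truth table.
#'
#' @param spec a [toy_genome_spec()].
#' @param planted list of [planted_mirna()] / [planted_tas()] objects.
#' @return list with `genome` (named character vector of scaffold DNA),
#'   `truth` (data.frame, 1-based inclusive coordinates, strand-explicit)
#'   and the updated `planted` list.
#' @export
generate_genome <- function(spec, planted = list()) {
  stopifnot(inherits(spec, "toy_genome_spec"))
  with_seed(spec$seed, {
    genome <- setNames(
      vapply(seq_len(spec$scaffold_count), function(i)
        random_dna(spec$scaffold_length, spec$gc_fraction), character(1)),
      paste0("scaffold_", seq_len(spec$scaffold_count)))
    # auto-place features lacking coordinates: round-robin over scaffolds,
    # fixed stride so nothing can overlap
    needs <- which(vapply(planted, function(p) is.na(p$scaffold), logical(1)))
    stride <- 2000L
    for (k in seq_along(needs)) {
      i <- needs[k]
      sc <- ((k - 1L) %% spec$scaffold_count) + 1L
      slot <- (k - 1L) %/% spec$scaffold_count
      planted[[i]]$scaffold <- names(genome)[sc]
      planted[[i]]$start <- 1000L + slot * stride
    }
    occ <- list()
    rows <- list()
    for (p in planted) {
      seq_dna <- as_dna(if (inherits(p, "planted_mirna")) p$precursor_seq
                        else p$transcript_seq)
      len <- nchar(seq_dna)
      st <- p$start; en <- st + len - 1L
      if (en > nchar(genome[[p$scaffold]]))
        stopf("feature %s does not fit on %s", p$id, p$scaffold)
      for (o in occ) {
        if (o$scaffold == p$scaffold && st <= o$end && en >= o$start)
          stopf("planted features overlap: %s and %s", o$id, p$id)
      }
      occ[[length(occ) + 1L]] <- list(id = p$id, scaffold = p$scaffold,
                                      start = st, end = en)
      emb <- if (p$strand == "-") revcomp(seq_dna) else seq_dna
      g <- genome[[p$scaffold]]
      genome[[p$scaffold]] <- paste0(substr(g, 1, st - 1), emb,
                                     substr(g, en + 1, nchar(g)))
      if (inherits(p, "planted_mirna")) {
        # mature offset within the precursor (1-based)
        moff <- if (p$arm == "5p") 1L else len - nchar(p$mature_seq) + 1L
        soff <- if (p$arm == "5p") len - nchar(p$star_seq) + 1L else 1L
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = p$id, type = "mirna",
          class = if (p$duplex_mismatches <= 4 && p$bulges <= 1)
            "novel_expected" else "negative_control",
          scaffold = p$scaffold, start = st, end = en, strand = p$strand,
          mature_seq = p$mature_seq, star_seq = p$star_seq,
          mature_offset = moff, star_offset = soff,
          cleavage_pos = NA_integer_, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = p$id, type = "tas", class = "tas",
          scaffold = p$scaffold, start = st, end = en, strand = p$strand,
          mature_seq = NA_character_, star_seq = NA_character_,
          mature_offset = NA_integer_, star_offset = NA_integer_,
          cleavage_pos = p$cleavage_pos, stringsAsFactors = FALSE)
      }
    }
    truth <- if (length(rows)) do.call(rbind, rows) else
      data.frame(feature_id = character(0))
    list(genome = genome, truth = truth, planted = planted, spec = spec)
  })
}

# Figure-1-shaped background read length distribution (mode at 24 nt,
# secondary 21-nt mode), over the admissible 15-31 nt range
BACKGROUND_LENGTH_PROBS <- c(
  `15` = 0.005, `16` = 0.005, `17` = 0.010, `18` = 0.010, `19` = 0.015,
  `20` = 0.050, `21` = 0.180, `22` = 0.080, `23` = 0.120, `24` = 0.430,
  `25` = 0.040, `26` = 0.020, `27` = 0.015, `28` = 0.010, `29` = 0.008,
  `30` = 0.007, `31` = 0.005)

# default 3' sequencing adapter (fixed 15-nt literal)
DEFAULT_ADAPTER <- "TGGAATTCTCGGGTG"

#' Default per-tissue library specifications
#'
#' Four tissue libraries (root, leaf, flower, fruit) at a given depth and
#' background fraction.
#'
#' @param depth nominal reads per library (>= 1000).
#' @param background_fraction fraction of `depth` emitted as genomic
#'   background reads.
#' @return list of per-library specs.
#' @export
library_specs <- function(depth = 50000L, background_fraction = 0.9) {
  lapply(c("root", "leaf", "flower", "fruit"), function(t)
    list(name = t, depth = as.integer(depth),
         background_fraction = background_fraction))
}

draw_counts <- function(lambda, noise, nbinom_size) {
  if (noise == "poisson") rpois(length(lambda), lambda)
  else stats::rnbinom(length(lambda), mu = lambda, size = nbinom_size)
}

#' Generate small-RNA sequencing libraries from a planted genome
#'
#' Emits, per library: mature and star reads for each planted miRNA (counts
#' drawn around `tissue_profile` rpm expectations), 21-nt phased reads from
#' each TAS locus, and a 24-nt-dominant genomic background. Background
#' positions avoid planted loci (no cross-mapping) unless
#' `cross_mapping = TRUE`.
#'
#' @param world result of [generate_genome()].
#' @param specs per-library specifications, see [library_specs()].
#' @param seed integer seed.
#' @param adapter 3' adapter appended to every read; `NULL` emits inserts.
#' @param star_fraction expected star-read count as a fraction of the
#'   mature expectation.
#' @param noise count noise model around the rpm expectations.
#' @param nbinom_size dispersion parameter when `noise = "nbinom"`.
#' @param cross_mapping allow background reads inside planted loci.
#' @return object of class `srna_libraries`: per-library read vectors plus a
#'   feature-level truth count table.
#' @export
generate_srna_libraries <- function(world, specs = library_specs(),
                                    seed = 1, adapter = DEFAULT_ADAPTER,
                                    star_fraction = 0.3,
                                    noise = c("poisson", "nbinom"),
                                    nbinom_size = 20,
                                    cross_mapping = FALSE) {
  noise <- match.arg(noise)
  for (sp in specs) {
    if (sp$depth < 1000) stopf("library %s: depth must be >= 1000", sp$name)
    if (sp$background_fraction < 0 || sp$background_fraction > 1)
      stopf("library %s: background fraction must be in [0, 1]", sp$name)
  }
  genome <- world$genome
  planted <- world$planted
  # admissible background start positions per scaffold: everything at least
  # 200 nt away from a planted locus, and leaving room for a 31-nt read
  allowed <- lapply(genome, function(g) {
    ok <- rep(TRUE, nchar(g))
    ok[(nchar(g) - 30L):nchar(g)] <- FALSE
    ok
  })
  if (!cross_mapping && nrow(world$truth) > 0) {
    for (r in seq_len(nrow(world$truth))) {
      tr <- world$truth[r, ]
      span <- max(1, tr$start - 230L):min(nchar(genome[[tr$scaffold]]), tr$end + 200L)
      allowed[[tr$scaffold]][span] <- FALSE
    }
  }
  allowed <- lapply(allowed, which)
  with_seed(seed, {
    libs <- list()
    count_rows <- list()
    for (sp in specs) {
      reads <- character(0)
      lib <- sp$name
      for (p in planted) {
        if (inherits(p, "planted_mirna")) {
          lam <- p$tissue_profile[[lib]] * sp$depth / 1e6
          n_mat <- draw_counts(lam, noise, nbinom_size)
          n_star <- draw_counts(lam * star_fraction, noise, nbinom_size)
          reads <- c(reads, rep(as_dna(p$mature_seq), n_mat),
                     rep(as_dna(p$star_seq), n_star))
          count_rows[[length(count_rows) + 1L]] <- data.frame(
            library = lib, feature_id = p$id, part = c("mature", "star"),
            count = c(n_mat, n_star), stringsAsFactors = FALSE)
        } else if (inherits(p, "planted_tas")) {
          lam <- p$tissue_profile[[lib]] * sp$depth / 1e6
          n_tot <- draw_counts(lam, noise, nbinom_size)
          n_off <- rbinom(1, n_tot, p$off_phase_noise_fraction)
          n_in <- n_tot - n_off
          cyc <- sample.int(p$phased_sirna_count, n_in, replace = TRUE) - 1L
          pos_in <- p$cleavage_pos + 21L * cyc
          pos_off <- integer(0)
          if (n_off > 0) {
            cyc_o <- sample.int(p$phased_sirna_count - 1L, n_off, replace = TRUE) - 1L
            reg_o <- sample.int(20L, n_off, replace = TRUE)  # register 1..20
            pos_off <- p$cleavage_pos + 21L * cyc_o + reg_o
          }
          pos <- c(pos_in, pos_off)
          tx <- as_dna(p$transcript_seq)
          if (length(pos)) reads <- c(reads, substring(tx, pos, pos + 20L))
          count_rows[[length(count_rows) + 1L]] <- data.frame(
            library = lib, feature_id = p$id,
            part = c("tas_phased", "tas_offphase"),
            count = c(n_in, n_off), stringsAsFactors = FALSE)
        }
      }
      # genomic background
      n_bg <- round(sp$depth * sp$background_fraction)
      if (n_bg > 0) {
        lens <- as.integer(sample(names(BACKGROUND_LENGTH_PROBS), n_bg,
                                  replace = TRUE, prob = BACKGROUND_LENGTH_PROBS))
        scafs <- sample(names(genome), n_bg, replace = TRUE)
        strands <- sample(c("+", "-"), n_bg, replace = TRUE)
        bg <- character(n_bg)
        for (sc in names(genome)) {
          idx <- which(scafs == sc)
          if (!length(idx)) next
          st <- allowed[[sc]][sample.int(length(allowed[[sc]]), length(idx),
                                         replace = TRUE)]
          bg[idx] <- substring(genome[[sc]], st, st + lens[idx] - 1L)
        }
        neg <- strands == "-"
        if (any(neg)) bg[neg] <- revcomp(bg[neg])
        reads <- c(reads, bg)
        count_rows[[length(count_rows) + 1L]] <- data.frame(
          library = lib, feature_id = "background", part = "background",
          count = n_bg, stringsAsFactors = FALSE)
      }
      if (!is.null(adapter)) reads <- paste0(reads, adapter)
      libs[[lib]] <- reads
    }
    structure(list(reads = libs,
                   counts = do.call(rbind, count_rows),
                   adapter = if (is.null(adapter)) NA_character_ else adapter,
                   seed = seed),
              class = "srna_libraries")
  })
}

#' Generate a degradome tag library
#'
#' Tags are 20-nt 5' ends of 3' cleavage fragments: each planted target (and
#' each TAS trigger site) receives its specified tag count exactly at the
#' guided-cleavage position, plus Poisson background along each transcript.
#'
#' @param targets list of [planted_target()] objects.
#' @param tas list of [planted_tas()] objects (their trigger sites also
#'   receive tags).
#' @param depth nominal sequencing depth; must cover the planted tag total.
#' @param tas_tag_count tags planted at each TAS cleavage site.
#' @param seed integer seed.
#' @return object of class `degradome_library`: `tags` (character vector),
#'   `transcripts` (named DNA vector) and a per-position `truth` table.
#' @export
generate_degradome <- function(targets, tas = list(), depth = 20000L,
                               tas_tag_count = 80L, seed = 1) {
  if (length(targets) == 0 && length(tas) == 0)
    stopf("need at least one planted target or TAS locus")
  planted_total <- sum(vapply(targets, function(t) t$tag_count, numeric(1))) +
    length(tas) * tas_tag_count
  if (depth < planted_total)
    stopf("depth (%d) smaller than total planted tag count (%d)",
          depth, planted_total)
  transcripts <- c(
    setNames(vapply(targets, function(t) as_dna(t$transcript_seq), character(1)),
             vapply(targets, function(t) t$transcript_id, character(1))),
    setNames(vapply(tas, function(t) as_dna(t$transcript_seq), character(1)),
             vapply(tas, function(t) t$id, character(1))))
  transcripts <- transcripts[!duplicated(names(transcripts))]
  with_seed(seed, {
    tag_len <- 20L
    rows <- list(); tags <- character(0)
    emit <- function(tx_id, pos, n) {
      tx <- transcripts[[tx_id]]
      pos <- pos[pos + tag_len - 1L <= nchar(tx) & pos >= 1]
      if (!length(pos)) return(invisible(NULL))
      tb <- table(pos)
      rows[[length(rows) + 1L]] <<- data.frame(
        transcript_id = tx_id, position = as.integer(names(tb)),
        count = as.integer(tb), stringsAsFactors = FALSE)
      tags <<- c(tags, substring(tx, pos, pos + tag_len - 1L))
    }
    for (t in targets) {
      emit(t$transcript_id, rep(t$cleavage_pos, t$tag_count))
      nb <- rpois(1, t$background_tag_rate * nchar(transcripts[[t$transcript_id]]))
      if (nb > 0)
        emit(t$transcript_id,
             sample.int(nchar(transcripts[[t$transcript_id]]) - tag_len, nb))
    }
    for (t in tas) emit(t$id, rep(t$cleavage_pos, tas_tag_count))
    truth <- do.call(rbind, rows)
    truth <- stats::aggregate(count ~ transcript_id + position, truth, sum)
    truth <- truth[order(truth$transcript_id, truth$position), ]
    structure(list(tags = tags, transcripts = transcripts, truth = truth,
                   seed = seed),
              class = "degradome_library")
  })
}
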