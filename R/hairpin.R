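# De novo miRNA locus calling: fold candidate precursor windows by maximum
# base pairing, evaluate the mature/star duplex (<= 4 mismatches, <= 1
# asymmetric bulge), detect star reads, and require the miRNA/miRNA* pair
# and locus-unique reads each to exceed 75% of locus reads.

#' Fold an RNA sequence by maximum base pairing
#'
#' Nussinov-style dynamic programming with A-U/G-C/G-U pairs and a minimum
#' hairpin loop of 3 nt. The traceback is deterministic: the 5'-most
#' pairing partner is preferred on ties. This maximum-base-pair contract
#' (rather than a thermodynamic fold) keeps results exactly testable; a
#' thermodynamic backend can be substituted upstream of
#' [evaluate_hairpin()].
#'
#' @param sequence RNA (or DNA) string, length <= 400.
#' @param min_loop minimum hairpin loop length.
#' @return list of class `fold_result`: `structure` (dot-bracket),
#'   `partner` (integer vector, 0 = unpaired), `n_paired`.
#' @export
fold_rna <- function(sequence, min_loop = 3L) {
  if (nchar(sequence) > 400) stopf("fold input longer than 400 nt")
  res <- .nussinov_cpp(as_rna(sequence), min_loop)
  structure(c(res, list(sequence = as_rna(sequence))), class = "fold_result")
}

#' Extract candidate precursor windows around a genome hit
#'
#' Three windows per hit: the tag at the 5' end with a downstream flank,
#' the tag at the 3' end with an upstream flank, and a centered window.
#' Windows are clipped at scaffold ends, capped at `cap` nt and returned in
#' tag sense (minus-strand windows are reverse-complemented).
#'
#' @param hit one-row data.frame (or list) with `scaffold`, `start`, `end`,
#'   `strand` (1-based inclusive, forward-strand coordinates).
#' @param genome named character vector of scaffolds.
#' @param flank flank length in nt (>= 50).
#' @param cap maximum window length.
#' @return list of windows; each has `scaffold`, `start`, `end`, `strand`,
#'   `sequence` (window-sense RNA) and `tag_start`, `tag_end` (window
#'   coordinates of the anchor tag).
#' @export
extract_windows <- function(hit, genome, flank = 150L, cap = 400L) {
  if (flank < 50) stopf("flank must be >= 50 nt")
  g <- genome[[hit$scaffold]]
  if (is.null(g) || hit$start < 1 || hit$end > nchar(g))
    stopf("hit outside scaffold %s", hit$scaffold)
  up <- if (hit$strand == "+") 2L * flank else 0L   # genomic left extension
  spans <- if (hit$strand == "+") list(
    c(hit$start, hit$end + 2L * flank),              # tag at 5' end
    c(hit$start - 2L * flank, hit$end),              # tag at 3' end
    c(hit$start - flank, hit$end + flank))           # centered
  else list(
    c(hit$start - 2L * flank, hit$end),
    c(hit$start, hit$end + 2L * flank),
    c(hit$start - flank, hit$end + flank))
  lapply(spans, function(sp) {
    ws <- max(1L, sp[1]); we <- min(nchar(g), sp[2])
    if (we - ws + 1L > cap) {   # trim symmetrically around the tag
      extra <- (we - ws + 1L) - cap
      trim_l <- min(extra %/% 2L, hit$start - ws)
      ws <- ws + trim_l; we <- ws + cap - 1L
    }
    s <- substr(g, ws, we)
    if (hit$strand == "-") s <- revcomp(s)
    ts <- if (hit$strand == "+") hit$start - ws + 1L else we - hit$end + 1L
    list(scaffold = hit$scaffold, start = ws, end = we, strand = hit$strand,
         sequence = as_rna(s), tag_start = ts,
         tag_end = ts + (hit$end - hit$start))
  })
}

#' Evaluate a mature/star duplex on a folded window
#'
#' The mature sequence must lie wholly on one arm without overlapping the
#' terminal loop. The star interval is the region pairing the mature core
#' (all but its 2-nt 3' overhang), extended to give 2-nt 3' overhangs on
#' both duplex ends. Unpaired mature positions inside symmetric internal
#' loops count as mismatches; asymmetric unpaired runs on either strand
#' count as bulges. Accepted iff mismatches <= 4 and bulges <= 1.
#'
#' @param window a window from [extract_windows()] (only its sequence
#'   length is required).
#' @param fold a `fold_result` for the window sequence.
#' @param mature_start,mature_end 1-based mature interval in window
#'   coordinates.
#' @param max_mismatches,max_bulges acceptance caps.
#' @return list of class `duplex_evaluation` with `accepted`, `reason`,
#'   `arm` (`5p`/`3p`), `star_start`, `star_end`, `mismatches`, `bulges`.
#' @export
evaluate_hairpin <- function(window, fold, mature_start, mature_end,
                             max_mismatches = 4L, max_bulges = 1L) {
  n <- nchar(fold$sequence)
  if (!is.null(window$sequence) && nchar(window$sequence) != n)
    stopf("fold does not match window sequence")
  if (mature_start < 1 || mature_end > n)
    stopf("mature interval outside window")
  reject <- function(why) structure(
    list(accepted = FALSE, reason = why, arm = NA_character_,
         star_start = NA_integer_, star_end = NA_integer_,
         mismatches = NA_integer_, bulges = NA_integer_),
    class = "duplex_evaluation")
  partner <- fold$partner
  core <- mature_start:(mature_end - 2L)          # exclude 2-nt 3' overhang
  p <- partner[core]
  paired <- p > 0L
  if (!any(paired)) return(reject("mature entirely unpaired"))
  self <- p[paired] >= mature_start & p[paired] <= mature_end
  if (sum(self) > 3)                              # tolerate stray fold pairs
    return(reject("mature overlaps the terminal loop"))
  pp <- p[paired][!self]
  if (!length(pp)) return(reject("mature overlaps the terminal loop"))
  n3 <- sum(pp > mature_end)
  n5 <- sum(pp < mature_start)
  if (min(n3, n5) > 3) return(reject("mature spans both arms"))
  arm <- if (n3 >= n5) "5p" else "3p"             # partners downstream => 5' arm
  on_side <- if (arm == "5p") paired & p > mature_end else paired & p < mature_start
  if (!any(on_side)) return(reject("no duplex partner on a single arm"))
  idx <- core[on_side]
  # coarse duplex-end projection (median over anchors is robust to fold
  # pairs that wander off the stem), then a +-2 nt local refinement that
  # picks the star interval whose duplex alignment has fewest defects.
  # The fold fixes the arm and the neighbourhood; defect counting is done
  # on the duplex alignment itself, because maximum base pairing absorbs
  # planted mismatches by locally shifted re-pairing.
  Lc <- length(core)
  # candidate duplex registers supported by the fold: r = partner + offset
  # is constant along a clean (unbulged) duplex; wobble-rich stems let the
  # fold drift between registers, so the few most-supported registers are
  # each tried and the best-scoring interval wins
  regs <- partner[idx] + (idx - mature_start)
  tab <- sort(table(regs), decreasing = TRUE)
  cand_regs <- as.integer(names(tab))[seq_len(min(3L, length(tab)))]
  mcore <- strsplit(substr(fold$sequence, mature_start, mature_end - 2L), "")[[1]]
  best <- NULL
  grid <- unique(do.call(rbind, lapply(cand_regs, function(r) {
    se0 <- r + 2L; ss0 <- r - (Lc - 1L)
    expand.grid(ss = (ss0 - 2L):(ss0 + 2L), se = (se0 - 2L):(se0 + 2L),
                ss0 = ss0, se0 = se0)
  })))
  for (k in seq_len(nrow(grid))) {
    ss <- grid$ss[k]; se <- grid$se[k]
    ss0 <- grid$ss0[k]; se0 <- grid$se0[k]
    if (ss < 1L || se > n || se - 2L < ss) next
    dup_len <- (se - 2L) - ss + 1L
    if (abs(dup_len - Lc) > 3L) next
    # the duplex must not run into the mature itself
    if (!(se < mature_start || ss > mature_end)) next
    sdup <- strsplit(substr(fold$sequence, ss, se - 2L), "")[[1]]
    d <- duplex_align(mcore, rev(sdup))
    # the locus qualifies when ANY nearby interval forms a canonical duplex;
    # among candidates prefer qualifying ones, then lowest defect load
    # (a bulge weighing two mismatches), then proximity to the projection
    okd <- d$mismatches <= max_mismatches && d$bulges <= max_bulges
    key <- c(!okd, d$mismatches + 2L * d$bulges,
             abs(ss - ss0) + abs(se - se0), ss)
    if (is.null(best) || lex_less(key, best$key))
      best <- list(key = key, ss = ss, se = se, d = d)
  }
  if (is.null(best)) return(reject("no admissible star interval"))
  star_start <- best$ss; star_end <- best$se
  mism <- best$d$mismatches
  bulges <- best$d$bulges
  structure(list(accepted = mism <= max_mismatches && bulges <= max_bulges,
                 reason = if (mism <= max_mismatches && bulges <= max_bulges)
                   "ok" else "duplex defects exceed caps",
                 arm = arm, star_start = as.integer(star_start),
                 star_end = as.integer(star_end),
                 mismatches = as.integer(mism), bulges = bulges),
            class = "duplex_evaluation")
}

#' Detect star-strand reads at a predicted star interval
#'
#' A star is observed when at least one read's 5' end lies within 1 nt of
#' the predicted star 5' end and its length is within 2 nt of the predicted
#' star length.
#'
#' @param locus_reads data.frame of reads in the window, with window-sense
#'   columns `start`, `length`, `count`.
#' @param star_start,star_end predicted star interval (window coordinates).
#' @return list: `observed`, `count`, `sequence_start` (5' position of the
#'   best-supported star read, or NA).
#' @export
star_detection <- function(locus_reads, star_start, star_end) {
  star_len <- star_end - star_start + 1L
  sel <- abs(locus_reads$start - star_start) <= 1L &
    abs(locus_reads$length - star_len) <= 2L
  if (!any(sel)) return(list(observed = FALSE, count = 0L,
                             sequence_start = NA_integer_))
  best <- locus_reads[sel, , drop = FALSE]
  best <- best[order(-best$count), , drop = FALSE]
  list(observed = TRUE, count = sum(best$count),
       sequence_start = best$start[1])
}

#' Read-support fractions for a candidate locus
#'
#' @param locus_reads data.frame of reads in the window with columns
#'   `count` and `all_hits_inside` (logical: every genome hit of the read's
#'   tag lies inside the locus window family).
#' @param mature_count,star_count read counts attributed to the mature and
#'   star sequences.
#' @return list: `pair_fraction`, `uniqueness_fraction`, `total_reads`.
#' @export
locus_support <- function(locus_reads, mature_count, star_count) {
  total <- sum(locus_reads$count)
  if (total == 0) stopf("zero reads in locus window: cannot score support")
  list(pair_fraction = (mature_count + star_count) / total,
       uniqueness_fraction = sum(locus_reads$count[locus_reads$all_hits_inside]) / total,
       total_reads = total)
}

lex_less <- function(a, b) {
  i <- which(a != b)[1]
  !is.na(i) && a[i] < b[i]
}

# Antiparallel duplex alignment of mature core vs reversed star duplex
# region: maximise paired columns (canonical + G:U), tiny gap penalty so
# gaps appear only where the strands differ in length; diagonal preferred
# on ties. Returns mismatch columns and gap-run (bulge) counts.
duplex_align <- function(a, b) {
  can_pair <- function(x, y)
    (x == "A" & y == "U") | (x == "U" & (y == "A" | y == "G")) |
    (x == "G" & (y == "C" | y == "U")) | (x == "C" & y == "G")
  n <- length(a); m <- length(b)
  gp <- 0.6
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1] <- -gp * (0:n)
  S[1, ] <- -gp * (0:m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    diag <- S[i, j] + if (can_pair(a[i], b[j])) 1 else 0
    S[i + 1L, j + 1L] <- max(diag, S[i, j + 1L] - gp, S[i + 1L, j] - gp)
  }
  i <- n; j <- m; mism <- 0L; runs <- 0L; last <- "d"
  while (i > 0 || j > 0) {
    diag_ok <- i > 0 && j > 0 &&
      abs(S[i + 1L, j + 1L] -
            (S[i, j] + if (can_pair(a[i], b[j])) 1 else 0)) < 1e-9
    if (diag_ok) {
      if (!can_pair(a[i], b[j])) mism <- mism + 1L
      i <- i - 1L; j <- j - 1L; last <- "d"
    } else if (i > 0 && abs(S[i + 1L, j + 1L] - (S[i, j + 1L] - gp)) < 1e-9) {
      if (last != "gi") runs <- runs + 1L
      last <- "gi"; i <- i - 1L
    } else {
      if (last != "gj") runs <- runs + 1L
      last <- "gj"; j <- j - 1L
    }
  }
  list(mismatches = mism, bulges = runs)
}

# reads (hits + counts) falling inside one window, in window-sense coords
window_reads <- function(hits_aug, win) {
  sel <- hits_aug$scaffold == win$scaffold & hits_aug$strand == win$strand &
    hits_aug$start >= win$start & hits_aug$end <= win$end
  h <- hits_aug[sel, , drop = FALSE]
  if (nrow(h) == 0) return(h)
  h$wstart <- if (win$strand == "+") h$start - win$start + 1L else win$end - h$end + 1L
  h$length <- h$end - h$start + 1L
  h
}

#' Discover novel and candidate miRNA loci
#'
#' Runs the full discovery chain on preprocessed libraries: candidate tags
#' are unassigned 20-22 nt tags with at least `min_reads` total reads;
#' their genome hits seed precursor windows that are folded and evaluated;
#' loci passing the hairpin, pair-fraction (> 0.75) and uniqueness
#' (> 0.75) rules are called, `novel` when a star read is observed and
#' `candidate` otherwise.
#'
#' @param processed an `srna_processed` object.
#' @param annotation result of [annotate_tags()] for the candidate-length
#'   tags, or NULL when no references apply.
#' @param genome named character vector of scaffolds.
#' @param flank,cap window geometry, see [extract_windows()].
#' @param min_reads minimum total read count for a candidate tag.
#' @param max_mismatches,max_bulges duplex caps, see [evaluate_hairpin()].
#' @param pair_fraction,uniqueness_fraction strict lower support bounds.
#' @param max_loci maximum genome hits examined per tag.
#' @return object of class `mirna_calls`: data.frame `calls` (one row per
#'   called miRNA, Table-style) and data.frame `loci` (one row per accepted
#'   locus).
#' @export
discover_mirnas <- function(processed, annotation = NULL, genome,
                            flank = 150L, cap = 400L, min_reads = 5L,
                            max_mismatches = 4L, max_bulges = 1L,
                            pair_fraction = 0.75, uniqueness_fraction = 0.75,
                            max_loci = 20L) {
  tags <- processed$tags
  libs <- processed$libraries
  total_counts <- rowSums(as.matrix(tags[, libs, drop = FALSE]))
  len <- nchar(tags$sequence)
  cand <- len >= 20 & len <= 22 & tags$n_hits > 0 & total_counts >= min_reads
  if (!is.null(annotation)) {
    cand_seqs <- tags$sequence[len >= 20 & len <= 22]
    drop <- cand_seqs[annotation$removed |
                        cand_seqs %in% annotation$assignments$sequence]
    cand <- cand & !(tags$sequence %in% drop)
  }
  hits <- processed$hits
  hits_aug <- hits
  m <- match(hits_aug$sequence, tags$sequence)
  hits_aug$count <- total_counts[m]
  hits_aug$n_hits <- tags$n_hits[m]
  call_rows <- list(); locus_rows <- list()
  for (ti in which(cand)) {
    seq_i <- tags$sequence[ti]
    th <- hits[hits$sequence == seq_i, , drop = FALSE]
    if (nrow(th) > max_loci) next                  # repetitive: not a miRNA
    acc <- list()
    for (hi in seq_len(nrow(th))) {
      wins <- extract_windows(th[hi, ], genome, flank, cap)
      best <- NULL
      for (w in wins) {
        f <- fold_rna(w$sequence)
        ev <- evaluate_hairpin(w, f, w$tag_start, w$tag_end,
                               max_mismatches, max_bulges)
        if (!ev$accepted) next
        # judge each admissible window by its read support: the precursor
        # window should contain both duplex arms, so prefer windows with
        # observed star reads, then the highest miRNA/miRNA* pair fraction
        lr <- window_reads(hits_aug, w)
        star <- star_detection(
          data.frame(start = lr$wstart, length = lr$length, count = lr$count),
          ev$star_start, ev$star_end)
        mature_count <- sum(lr$count[lr$sequence == seq_i])
        pf <- (mature_count + star$count) / sum(lr$count)
        if (is.null(best) || (star$observed && !best$star$observed) ||
            (star$observed == best$star$observed && pf > best$pf))
          best <- list(win = w, ev = ev, star = star, reads = lr,
                       mature_count = mature_count, pf = pf)
      }
      if (is.null(best)) next
      if (best$pf <= pair_fraction) next
      best$hit <- th[hi, , drop = FALSE]
      acc[[length(acc) + 1L]] <- best
    }
    if (!length(acc)) next
    # uniqueness against the union of accepted windows for this tag
    spans <- lapply(acc, function(a) a$win)
    inside_family <- function(sc, st, en, strd) {
      any(vapply(spans, function(w) w$scaffold == sc & w$strand == strd &
                   st >= w$start & en <= w$end, logical(1)))
    }
    keep <- list()
    for (a in acc) {
      lr <- a$reads
      per_tag <- unique(lr$sequence)
      tag_unique <- vapply(per_tag, function(s) {
        hh <- hits_aug[hits_aug$sequence == s, , drop = FALSE]
        all(vapply(seq_len(nrow(hh)), function(r)
          inside_family(hh$scaffold[r], hh$start[r], hh$end[r], hh$strand[r]),
          logical(1)))
      }, logical(1))
      lr$all_hits_inside <- tag_unique[lr$sequence]
      sup <- locus_support(lr, a$mature_count, a$star$count)
      if (sup$uniqueness_fraction <= uniqueness_fraction) next
      a$support <- sup
      keep[[length(keep) + 1L]] <- a
    }
    if (!length(keep)) next
    star_observed <- any(vapply(keep, function(a) a$star$observed, logical(1)))
    star_seq <- NA_character_
    if (star_observed) {
      a <- keep[[which(vapply(keep, function(a) a$star$observed, logical(1)))[1]]]
      ss <- substr(a$win$sequence, a$ev$star_start, a$ev$star_end)
      star_seq <- as_rna(ss)
    }
    rpmrow <- processed$rpm[ti, , drop = TRUE]
    first <- keep[[1]]
    match_site <- if (first$win$strand == "+") first$hit$start else first$hit$end
    call_rows[[length(call_rows) + 1L]] <- data.frame(
      sequence = as_rna(seq_i), length = nchar(seq_i),
      scaffold = first$hit$scaffold,
      match_site = first$hit$start, strand = first$win$strand,
      n_loci = length(keep),
      t(rpmrow), total_rpm = sum(rpmrow),
      star_sequence = ifelse(star_observed, star_seq, "None detected"),
      class = ifelse(star_observed, "novel", "candidate"),
      pair_fraction = max(vapply(keep, function(a) a$pf, numeric(1))),
      uniqueness_fraction = max(vapply(keep, function(a)
        a$support$uniqueness_fraction, numeric(1))),
      stringsAsFactors = FALSE)
    for (a in keep) {
      locus_rows[[length(locus_rows) + 1L]] <- data.frame(
        sequence = as_rna(seq_i), scaffold = a$win$scaffold,
        window_start = a$win$start, window_end = a$win$end,
        strand = a$win$strand, mature_start = a$hit$start,
        mature_end = a$hit$end, arm = a$ev$arm,
        mismatches = a$ev$mismatches, bulges = a$ev$bulges,
        star_observed = a$star$observed, star_count = a$star$count,
        pair_fraction = a$pf,
        uniqueness_fraction = a$support$uniqueness_fraction,
        stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(call_rows)) do.call(rbind, call_rows) else
    data.frame(sequence = character(0), class = character(0))
  loci <- if (length(locus_rows)) do.call(rbind, locus_rows) else
    data.frame(sequence = character(0))
  if (nrow(calls)) {
    calls <- calls[order(-calls$total_rpm), , drop = FALSE]
    # one entry per duplex: a star strand abundant enough to qualify on its
    # own maps inside the precursor window of its (more expressed) partner
    # and is reported in the star column, not as a separate miRNA
    keep <- rep(TRUE, nrow(calls))
    for (i in seq_len(nrow(calls))) {
      if (!keep[i]) next
      wi <- loci[loci$sequence == calls$sequence[i], , drop = FALSE]
      for (j in seq_len(nrow(calls))) {
        if (j == i || !keep[j]) next
        lj <- loci[loci$sequence == calls$sequence[j], , drop = FALSE]
        inside <- any(vapply(seq_len(nrow(lj)), function(r)
          any(wi$scaffold == lj$scaffold[r] & wi$strand == lj$strand[r] &
                wi$window_start <= lj$mature_start[r] &
                wi$window_end >= lj$mature_end[r]), logical(1)))
        if (inside) keep[j] <- FALSE
      }
    }
    calls <- calls[keep, , drop = FALSE]
    loci <- loci[loci$sequence %in% calls$sequence, , drop = FALSE]
    calls <- cbind(mirna_id = paste0("mirN", seq_len(nrow(calls))), calls,
                   stringsAsFactors = FALSE)
    rownames(calls) <- NULL
  }
  structure(list(calls = calls, loci = loci), class = "mirna_calls")
}
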