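# Per-discSNP motif disruption scoring. For each motif with any placement
# containing the discSNP inside a 40-bp window centered on it, both alleles
# are scored at the single best placement; Score_max is the better allele's
# score there and DiffScore the difference between alleles.

#' Disruption-calling thresholds
#'
#' A motif/discSNP pair is called a disrupted binding site when the better
#' allele scores at least `score_thres` bits (a true predicted site) and the
#' allelic score difference is at least `diff_score_thres` bits (a real
#' disruption). Defaults are the values recovered by the random-walk
#' optimization.
#'
#' @param score_thres minimum Score_max in bits.
#' @param diff_score_thres minimum DiffScore in bits.
#' @return list of class `threshold_config`.
#' @export
threshold_config <- function(score_thres = 7.5, diff_score_thres = 2.5) {
  if (score_thres < 0 || diff_score_thres < 0)
    stopf("thresholds must be non-negative")
  structure(list(score_thres = score_thres,
                 diff_score_thres = diff_score_thres),
            class = "threshold_config")
}

# Best SNP-containing placement of one PWM across a pair of allele windows.
# Returns NULL when no placement is scoreable (Ns) or the window is too short.
best_disrupting_placement <- function(p, win_a, win_b, snp_off) {
  L <- pwm_length(p)
  n <- nchar(win_a)
  if (n < L) return(NULL)
  ca <- encode_dna(win_a)
  cb <- encode_dna(win_b)
  best <- NULL
  for (strand in c("+", "-")) {
    lo <- log_odds_matrix(if (strand == "+") p else revcomp_pwm(p))
    sa <- scan_scores(lo, ca)
    sb <- scan_scores(lo, cb)
    starts <- seq_along(sa)                       # 1-based placement starts
    keep <- starts <= snp_off & snp_off <= starts + L - 1L &
      !is.na(sa) & !is.na(sb)
    for (s in starts[keep]) {
      cand <- list(start = s, strand = strand,
                   score_a = sa[s], score_b = sb[s],
                   score_max = max(sa[s], sb[s]),
                   diff = abs(sa[s] - sb[s]))
      # ties on the better allele's score go to the larger allelic
      # difference, then '+' strand, then the leftmost placement;
      # tie detection uses a 1e-9-bit tolerance so that identical sums
      # reached in different accumulation orders still count as ties
      eps <- 1e-9
      if (is.null(best) || cand$score_max > best$score_max + eps ||
          (cand$score_max > best$score_max - eps &&
             cand$diff > best$diff + eps))
        best <- cand
    }
  }
  best
}

#' Score motif disruption at a discSNP
#'
#' Extracts a `window`-bp window centered on each discSNP (clipped at contig
#' ends) from both line sequences and, for every PWM with at least one
#' placement containing the SNP, finds the placement/strand maximizing the
#' better allele's log-odds score. Both alleles are scored at that single
#' placement. The motif-strand-oriented position of the SNP within the motif
#' and the intact/variant bases are reported.
#'
#' @param disc_snps data.frame from [find_disc_snps()] (contig, pos, base_a,
#'   base_b).
#' @param genome_a,genome_b named character vectors of line sequences (same
#'   coordinates).
#' @param pwms list of `pwm` objects.
#' @param window window size in bp (default 40).
#' @return data.frame of disruption events: contig, pos, motif_id, family,
#'   placement start/end (0-based), strand, score_allele_a, score_allele_b,
#'   score_max, diff_score, disrupted_line, position_in_motif, intact_base,
#'   variant_base.
#' @export
analyze_disc_snp <- function(disc_snps, genome_a, genome_b, pwms,
                             window = 40) {
  out <- list()
  for (i in seq_len(nrow(disc_snps))) {
    contig <- disc_snps$contig[i]
    pos <- disc_snps$pos[i]                       # 1-based
    len <- nchar(genome_a[[contig]])
    w_start <- max(1L, pos - window %/% 2L)       # 1-based inclusive
    w_end <- min(len, pos + window %/% 2L - 1L)   # truncated at contig ends
    win_a <- substr(genome_a[[contig]], w_start, w_end)
    win_b <- substr(genome_b[[contig]], w_start, w_end)
    snp_off <- pos - w_start + 1L                 # 1-based within window
    for (p in pwms) {
      b <- best_disrupting_placement(p, win_a, win_b, snp_off)
      if (is.null(b)) next
      L <- pwm_length(p)
      diff <- b$score_max - min(b$score_a, b$score_b)
      disrupted <- if (diff == 0) NA_character_ else
        if (b$score_a < b$score_b) "A" else "B"
      pim <- if (b$strand == "+") snp_off - b$start + 1L else
        L - (snp_off - b$start)
      ba <- substr(win_a, snp_off, snp_off)
      bb <- substr(win_b, snp_off, snp_off)
      if (b$strand == "-") { ba <- complement_base(ba); bb <- complement_base(bb) }
      intact <- if (identical(disrupted, "A")) bb else ba
      variant <- if (identical(disrupted, "A")) ba else bb
      out[[length(out) + 1L]] <- data.frame(
        contig = contig, pos = pos, motif_id = p$motif_id,
        family = p$family,
        start = w_start - 1L + b$start - 1L,      # back to 0-based genome
        end = w_start - 1L + b$start - 1L + L,
        strand = b$strand,
        score_allele_a = b$score_a, score_allele_b = b$score_b,
        score_max = b$score_max, diff_score = diff,
        disrupted_line = disrupted, position_in_motif = pim,
        intact_base = intact, variant_base = variant)
    }
  }
  if (length(out) == 0L)
    return(data.frame(contig = character(0), pos = integer(0),
                      motif_id = character(0), family = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), score_allele_a = numeric(0),
                      score_allele_b = numeric(0), score_max = numeric(0),
                      diff_score = numeric(0), disrupted_line = character(0),
                      position_in_motif = integer(0),
                      intact_base = character(0), variant_base = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call disruptions at fixed thresholds
#'
#' @param events disruption events from [analyze_disc_snp()].
#' @param thresholds a [threshold_config()].
#' @return events with an `is_called_disruption` logical column.
#' @export
call_disruptions <- function(events, thresholds = threshold_config()) {
  events$is_called_disruption <-
    events$score_max >= thresholds$score_thres &
    events$diff_score >= thresholds$diff_score_thres
  events
}

#' Collapse disruption events to motif families
#'
#' Per discSNP and family, keeps the single event with the highest
#' Score_max; ties broken by higher DiffScore, then lexicographically
#' smaller motif_id. Used e.g. to merge all GATA-family matrices into one
#' GATA event per SNP.
#'
#' @param events disruption events.
#' @param family_map optional data.frame (motif_id, family) overriding the
#'   events' own family column.
#' @return filtered events, one row per (discSNP, family).
#' @export
merge_motif_family <- function(events, family_map = NULL) {
  if (nrow(events) == 0L) return(events)
  fam <- events$family
  if (!is.null(family_map)) {
    i <- match(events$motif_id, family_map$motif_id)
    if (anyNA(i)) stopf("family map does not cover motif '%s'",
                        events$motif_id[which(is.na(i))[1]])
    fam <- family_map$family[i]
  }
  events$family <- fam
  key <- paste(events$contig, events$pos, fam)
  o <- order(key, -events$score_max, -events$diff_score, events$motif_id)
  ev <- events[o, , drop = FALSE]
  ev <- ev[!duplicated(paste(ev$contig, ev$pos, ev$family)), , drop = FALSE]
  ev <- ev[order(ev$contig, ev$pos, ev$family), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Motif enrichment in foreground versus background peaks
#'
#' A peak is motif-positive when any placement within it scores at least
#' `score_thres` bits. Per motif, a Fisher exact test compares
#' presence/absence between the two peak sets; q values are
#' Benjamini-Hochberg across motifs. The odds ratio is the sample odds
#' ratio (NA when a margin is empty).
#'
#' @param fg_peaks,bg_peaks peak data.frames (contig, start, end; 0-based).
#' @param genome named character vector of sequences.
#' @param pwms list of `pwm` objects.
#' @param score_thres presence threshold in bits.
#' @return data.frame with motif_id, fg_present, fg_total, bg_present,
#'   bg_total, odds_ratio, p, q.
#' @export
motif_enrichment <- function(fg_peaks, bg_peaks, genome, pwms,
                             score_thres = 7.5) {
  if (nrow(fg_peaks) == 0L || nrow(bg_peaks) == 0L)
    stopf("empty peak set")
  peak_seqs <- function(pk) {
    vapply(seq_len(nrow(pk)), function(i)
      substr(genome[[pk$contig[i]]], pk$start[i] + 1L, pk$end[i]),
      character(1))
  }
  fg <- peak_seqs(fg_peaks)
  bg <- peak_seqs(bg_peaks)
  present <- function(p, seqs) {
    vapply(seqs, function(s)
      nchar(s) >= pwm_length(p) &&
        nrow(score_pwm(p, s, min_score = score_thres)) > 0, logical(1))
  }
  rows <- lapply(pwms, function(p) {
    a <- sum(present(p, fg)); b <- length(fg) - a
    c_ <- sum(present(p, bg)); d <- length(bg) - c_
    or <- if ((a + c_) == 0 || (b + d) == 0) NA_real_ else
      (a * d) / max(b * c_, .Machine$double.xmin)
    pv <- stats::fisher.test(matrix(c(a, b, c_, d), 2))$p.value
    data.frame(motif_id = p$motif_id, fg_present = a, fg_total = length(fg),
               bg_present = c_, bg_total = length(bg),
               odds_ratio = or, p = pv)
  })
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}

#' Random-walk optimization of disruption-calling thresholds
#'
#' Searches for (Score_thres, DiffScore_thres) maximizing the median percent
#' signal loss (100 minus percent residual) of called events, judged on
#' held-out cross-validation folds. Each run initializes uniformly in
#' `score_range` x `diff_range`, takes Gaussian steps (sd `sigma`) and
#' accepts a step only when the objective on the current validation fold
#' improves; thresholds calling fewer than `min_called` events are invalid.
#' The reported thresholds are the across-run medians of each run's final
#' accepted position.
#'
#' @param events disruption events with `score_max` and `diff_score`.
#' @param residual percent residual signal per event (same order).
#' @param n_runs number of independent runs (default 100).
#' @param n_folds cross-validation folds per run (default 10).
#' @param n_steps proposal steps per run.
#' @param sigma Gaussian proposal standard deviation in bits.
#' @param score_range,diff_range initialization/search bounds.
#' @param min_called minimum number of called events for a valid objective.
#' @param seed integer seed.
#' @return list with `thresholds` (a [threshold_config()]), `per_run`
#'   data.frame of final positions and objectives, and `converged` (fraction
#'   of runs that accepted at least one step).
#' @export
optimize_thresholds <- function(events, residual, n_runs = 100, n_folds = 10,
                                n_steps = 50, sigma = 0.5,
                                score_range = c(0, 20), diff_range = c(0, 10),
                                min_called = 20, seed = NULL) {
  n <- nrow(events)
  if (n < 100L) stopf("need at least 100 events with signal, got %d", n)
  if (length(residual) != n) stopf("residual length mismatch")
  loss <- 100 - residual
  objective <- function(th, idx) {
    called <- events$score_max[idx] >= th[1] & events$diff_score[idx] >= th[2]
    if (sum(events$score_max >= th[1] & events$diff_score >= th[2]) <
        min_called || !any(called)) return(-Inf)
    stats::median(loss[idx][called])
  }
  with_seed_opt(seed, {
    per_run <- lapply(seq_len(n_runs), function(run) {
      fold <- sample(rep_len(seq_len(n_folds), n))
      # rejection-sample the initialization into the feasible region: a
      # start calling fewer than min_called events has a -Inf objective
      # everywhere nearby and the walk could never leave it
      for (try in 1:200) {
        th <- c(stats::runif(1, score_range[1], score_range[2]),
                stats::runif(1, diff_range[1], diff_range[2]))
        if (is.finite(objective(th, seq_len(n)))) break
        if (try == 200)
          stopf("no feasible starting thresholds call %d events", min_called)
      }
      accepted <- 0L
      for (step in seq_len(n_steps)) {
        k <- ((step - 1L) %% n_folds) + 1L
        idx <- which(fold == k)
        prop <- th + stats::rnorm(2, 0, sigma)
        prop[1] <- min(max(prop[1], score_range[1]), score_range[2])
        prop[2] <- min(max(prop[2], diff_range[1]), diff_range[2])
        if (objective(prop, idx) > objective(th, idx)) {
          th <- prop
          accepted <- accepted + 1L
        }
      }
      data.frame(score_thres = th[1], diff_score_thres = th[2],
                 objective = objective(th, seq_len(n)), accepted = accepted)
    })
    per_run <- do.call(rbind, per_run)
    list(thresholds = threshold_config(stats::median(per_run$score_thres),
                                       stats::median(per_run$diff_score_thres)),
         per_run = per_run,
         converged = mean(per_run$accepted > 0))
  })
}
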