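# Impact statistics for called motif disruptions: percent residual binding
# on the disrupted allele, grouped summaries with bootstrap confidence
# intervals and Wilcoxon tests against 100%, permutation (maxT) correction
# across groups, and sliding distance bins for contextual-motif analyses.

#' Percent residual signal on the disrupted allele
#'
#' 100 x intensity on the allele carrying the motif disruption divided by
#' intensity on the intact allele. Events whose denominator falls below
#' `min_intact` normalized units are excluded (NA): tiny denominators make
#' the percentage meaningless. With `denominator = "stronger"` the larger of
#' the two intensities is used as the reference instead, so the statistic
#' becomes percent signal retained relative to the stronger allele.
#'
#' @param intact intensity on the motif-intact allele.
#' @param disrupted intensity on the motif-disrupted allele.
#' @param min_intact exclusion floor for the reference intensity.
#' @param denominator "intact" (default) or "stronger".
#' @return numeric vector of percentages (may exceed 100); NA = excluded.
#' @export
percent_residual <- function(intact, disrupted, min_intact = 1,
                             denominator = c("intact", "stronger")) {
  denominator <- match.arg(denominator)
  if (denominator == "stronger") {
    ref <- pmax(intact, disrupted)
    num <- pmin(intact, disrupted)
  } else {
    ref <- intact
    num <- disrupted
  }
  ifelse(ref < min_intact, NA_real_, 100 * num / ref)
}

#' Grouped percent-residual summaries with bootstrap CIs
#'
#' Per group: the median percent residual, a 95% confidence interval from
#' the 2.5 and 97.5 percentiles of `n_boot` bootstrap medians, and a
#' two-sided one-sample Wilcoxon signed-rank test of the residuals against
#' `mu` (100% = no allelic effect). Groups with fewer than `min_n` events
#' are suppressed. Degenerate groups (all residuals equal to `mu`) report
#' p = 1.
#'
#' @param residual percent residual per event (NAs dropped).
#' @param group grouping key per event (motif, motif position, variant base,
#'   distance bin, peak class, ...).
#' @param n_boot bootstrap replicates (default 1000).
#' @param min_n minimum group size (default 5).
#' @param mu null value in percent (default 100).
#' @param conf confidence level.
#' @param seed integer seed for the bootstrap.
#' @return data.frame with group, n, median, ci_lo, ci_hi, p.
#' @export
group_impact <- function(residual, group, n_boot = 1000, min_n = 5,
                         mu = 100, conf = 0.95, seed = NULL) {
  keep <- !is.na(residual)
  residual <- residual[keep]
  group <- group[keep]
  alpha <- (1 - conf) / 2
  with_seed_opt(seed, {
    rows <- lapply(split(residual, group), function(x) {
      n <- length(x)
      if (n < min_n) return(NULL)
      boots <- matrix(sample(x, n * n_boot, replace = TRUE), nrow = n)
      bm <- apply(boots, 2, stats::median)
      p <- if (all(x == mu)) 1 else
        suppressWarnings(stats::wilcox.test(x, mu = mu, exact = FALSE,
                                            correct = TRUE)$p.value)
      data.frame(n = n, median = stats::median(x),
                 ci_lo = unname(stats::quantile(bm, alpha)),
                 ci_hi = unname(stats::quantile(bm, 1 - alpha)), p = p)
    })
    keep_g <- !vapply(rows, is.null, logical(1))
    out <- do.call(rbind, rows[keep_g])
    if (is.null(out)) return(data.frame(group = character(0), n = integer(0),
                                        median = numeric(0),
                                        ci_lo = numeric(0),
                                        ci_hi = numeric(0), p = numeric(0)))
    out <- cbind(group = names(rows)[keep_g], out)
    rownames(out) <- NULL
    out
  })
}

#' Permutation (maxT) multiple-testing correction across groups
#'
#' Group labels are permuted over the pooled events `n_perm` times,
#' preserving group sizes; each permutation records the smallest Wilcoxon
#' p value across groups. A group's q value is the (+1-smoothed) fraction of
#' null minimum p values at or below its observed p. This controls the
#' family-wise error rate across the dependent group tests.
#'
#' @param residual percent residual per event (NAs dropped).
#' @param group grouping key per event; at least 2 groups.
#' @param n_perm number of permutations (default 1000).
#' @param mu null value (default 100).
#' @param seed integer seed.
#' @return data.frame with group, p (observed), q.
#' @export
permutation_adjust <- function(residual, group, n_perm = 1000, mu = 100,
                               seed = NULL) {
  keep <- !is.na(residual)
  residual <- residual[keep]
  group <- as.character(group[keep])
  sizes <- table(group)
  if (length(sizes) < 2L) stopf("need at least 2 groups")
  if (length(residual) < length(sizes)) stopf("fewer events than groups")
  groups <- names(sizes)
  idx <- split(seq_along(residual), group)
  obs_p <- vapply(groups, function(g) wilcox_signed_p(residual[idx[[g]]], mu),
                  numeric(1))
  pool <- unlist(idx[groups], use.names = FALSE)
  x0 <- residual[pool]
  # fixed slot positions per group within the pooled vector; permuting the
  # pooled values and reading fixed slots is a label permutation that
  # preserves group sizes
  glab <- rep(seq_along(groups), times = as.integer(sizes[groups]))
  slots <- split(seq_along(x0), glab)
  min_p <- with_seed_opt(seed, {
    vapply(seq_len(n_perm), function(i) {
      xp <- x0[sample.int(length(x0))]
      m <- Inf
      for (sl in slots) {
        p <- wilcox_signed_p(xp[sl], mu)
        if (p < m) m <- p
      }
      m
    }, numeric(1))
  })
  q <- vapply(obs_p, function(p) (1 + sum(min_p <= p)) / (n_perm + 1),
              numeric(1))
  data.frame(group = groups, p = unname(obs_p), q = unname(q))
}

#' Sliding distance bins for contextual-motif analyses
#'
#' Bins of `width` bp sliding by `step` bp over `[from, to]` bp: with the
#' defaults, [0,10), [5,15), ..., [95,105) — exactly 20 bins for the
#' 0-100 bp range. An event whose distance falls in two overlapping bins is
#' assigned to both. Distances are edge-to-edge gaps (0 when the contextual
#' motif overlaps the anchor motif).
#'
#' @param distance non-negative distances in bp, one per event.
#' @param from,to range of bin start positions (defaults 0 and 100).
#' @param width bin width in bp (default 10).
#' @param step bin offset in bp (default 5).
#' @return list with `bins` (data.frame bin_id, lo, hi) and `assignment`
#'   (data.frame event, bin_id; long format).
#' @export
distance_bins <- function(distance, from = 0, to = 100, width = 10,
                          step = 5) {
  if (any(distance < 0)) stopf("negative distance")
  starts <- seq(from, to - step, by = step)
  bins <- data.frame(bin_id = seq_along(starts), lo = starts,
                     hi = starts + width)
  hits <- lapply(seq_along(distance), function(i) {
    b <- bins$bin_id[distance[i] >= bins$lo & distance[i] < bins$hi]
    if (length(b)) data.frame(event = i, bin_id = b) else NULL
  })
  assignment <- do.call(rbind, hits)
  if (is.null(assignment))
    assignment <- data.frame(event = integer(0), bin_id = integer(0))
  list(bins = bins, assignment = assignment)
}

#' Edge-to-edge distance between two intervals
#'
#' 0 when the intervals overlap or touch; otherwise the gap in bp.
#' Intervals are 0-based half-open.
#'
#' @param start1,end1,start2,end2 interval coordinates (vectorized).
#' @return non-negative integer distances.
#' @export
interval_gap <- function(start1, end1, start2, end2) {
  pmax(0, pmax(start2 - end1, start1 - end2))
}
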