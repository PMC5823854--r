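# Signal-level preprocessing: consensus peak construction from summits,
# input-subtracted library-size normalization of ChIP counts, and quantile
# normalization of accessibility signal.

#' Build consensus peaks from summit-annotated peak sets
#'
#' Takes the union of the supplied peak sets (every peak participates,
#' i.e. a minimum overlap of one set), recenters each peak on its summit
#' plus/minus `half_width` bp, and resolves overlapping consensus intervals
#' by keeping the interval anchored at the strongest summit.
#'
#' @param peak_sets list of data.frames with contig, summit (0-based bp) and
#'   signal columns; start/end are optional and only sanity-checked.
#' @param half_width half-width around the summit (default 100, giving
#'   200-bp consensus peaks).
#' @return data.frame with contig, start, end, summit, signal; intervals are
#'   disjoint and sorted.
#' @export
merge_peaks <- function(peak_sets, half_width = 100) {
  all <- do.call(rbind, lapply(peak_sets, function(pk) {
    if (!is.null(pk$start) &&
        any(pk$summit < pk$start | pk$summit >= pk$end))
      stopf("summit outside its peak")
    data.frame(contig = pk$contig, summit = pk$summit, signal = pk$signal)
  }))
  all <- all[order(-all$signal), , drop = FALSE]
  all$start <- pmax(0, all$summit - half_width)
  all$end <- all$summit + half_width
  kept <- list()
  for (i in seq_len(nrow(all))) {
    row <- all[i, ]
    clash <- any(vapply(kept, function(k)
      k$contig == row$contig && k$start < row$end && row$start < k$end,
      logical(1)))
    if (!clash) kept[[length(kept) + 1L]] <- row
  }
  out <- do.call(rbind, kept)
  out <- out[order(out$contig, out$start),
             c("contig", "start", "end", "summit", "signal")]
  rownames(out) <- NULL
  out
}

#' Input-subtracted, library-size-normalized ChIP intensity
#'
#' Scales IP and input counts to a common reference library size (the mean
#' of the supplied library sizes), subtracts the scaled input from the
#' scaled IP and floors at zero.
#'
#' @param ip,input count vectors over the same keys.
#' @param lib_ip,lib_input library sizes (total mapped reads).
#' @param ref reference library size; default mean of the two.
#' @return numeric vector of non-negative intensities.
#' @export
normalize_chip <- function(ip, input, lib_ip, lib_input,
                           ref = mean(c(lib_ip, lib_input))) {
  if (any(c(lib_ip, lib_input) <= 0)) stopf("zero library size")
  if (length(input) != length(ip)) stopf("ip/input key mismatch")
  pmax(0, ip * (ref / lib_ip) - input * (ref / lib_input))
}

#' Quantile normalization across samples
#'
#' Classic rank-mean quantile normalization (ties receive the mean of the
#' pooled quantile means), as used to make accessibility signal
#' distributions comparable across samples.
#'
#' @param mat numeric matrix, one column per sample.
#' @return matrix of the same shape; all columns share the same sorted
#'   values.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stopf("need at least 2 samples")
  if (any(apply(mat, 2, stats::sd) == 0)) stopf("constant column")
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Classify peaks by tissue occupancy
#'
#' Constitutive peaks are occupied in more than 60% of tissues, variable
#' peaks in fewer than 20%. Variable peaks occupied in every erythroid
#' tissue and in no non-erythroid tissue are erythroid-specific;
#' erythroid-specific peaks additionally absent in the undifferentiated and
#' present in the differentiated member of every supplied differentiation
#' pair are differentiation-induced. Everything else is "other".
#'
#' @param occupancy logical matrix, peaks x tissues (colnames = tissue ids).
#' @param erythroid character vector of erythroid tissue ids.
#' @param diff_pairs optional list of c(undifferentiated, differentiated)
#'   tissue-id pairs.
#' @param constitutive_min,variable_max occupancy-fraction cutoffs.
#' @return data.frame with occupancy fraction and class per peak.
#' @export
classify_peaks <- function(occupancy, erythroid, diff_pairs = NULL,
                           constitutive_min = 0.6, variable_max = 0.2) {
  occupancy <- as.matrix(occupancy)
  if (ncol(occupancy) < 5L) stopf("need at least 5 tissues")
  tissues <- colnames(occupancy)
  unknown <- setdiff(c(erythroid, unlist(diff_pairs)), tissues)
  if (length(unknown)) stopf("unknown tissue id: %s", unknown[1])
  frac <- rowMeans(occupancy)
  non_ery <- setdiff(tissues, erythroid)
  cls <- rep("other", nrow(occupancy))
  cls[frac > constitutive_min] <- "constitutive"
  variable <- frac < variable_max
  cls[variable] <- "variable"
  ery_spec <- variable &
    rowSums(!occupancy[, erythroid, drop = FALSE]) == 0 &
    rowSums(occupancy[, non_ery, drop = FALSE]) == 0
  cls[ery_spec] <- "erythroid_specific"
  if (!is.null(diff_pairs) && length(diff_pairs)) {
    induced <- ery_spec
    for (pr in diff_pairs)
      induced <- induced & !occupancy[, pr[1]] & occupancy[, pr[2]]
    cls[induced] <- "differentiation_induced"
  }
  data.frame(fraction = frac, class = cls)
}

#' Pearson correlation with Fisher-Z confidence interval
#'
#' Computes r with a 95% CI from the Fisher Z transform
#' (z plus/minus 1.96/sqrt(n-3), back-transformed). When a second pair of
#' vectors is supplied, the two correlations are compared with the two-sided
#' Z-difference test.
#'
#' @param x,y numeric vectors (n >= 4).
#' @param x2,y2 optional second pair for a correlation comparison.
#' @param conf confidence level.
#' @return list with r, ci (length 2), n, and — when comparing —
#'   r2, n2 and comparison_p.
#' @export
fisher_z_corr <- function(x, y, x2 = NULL, y2 = NULL, conf = 0.95) {
  n <- length(x)
  if (n < 4L) stopf("need n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stopf("zero variance input")
  r <- stats::cor(x, y)
  zcrit <- stats::qnorm(1 - (1 - conf) / 2)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  ci <- tanh(z + c(-1, 1) * zcrit / sqrt(n - 3))
  out <- list(r = r, ci = ci, n = n)
  if (!is.null(x2)) {
    n2 <- length(x2)
    if (n2 < 4L) stopf("need n >= 4 in second sample")
    r2 <- stats::cor(x2, y2)
    z2 <- atanh(min(max(r2, -1 + 1e-15), 1 - 1e-15))
    stat <- (z - z2) / sqrt(1 / (n - 3) + 1 / (n2 - 3))
    out$r2 <- r2
    out$n2 <- n2
    out$comparison_p <- 2 * stats::pnorm(-abs(stat))
  }
  out
}

#' Correlate allelic binding change with transcription change across FDR
#' cutoffs
#'
#' Per peak, a two-sided binomial test of the line-A IP count against the
#' library-size ratio gives a differential-binding p value (BH-corrected to
#' q). At each FDR cutoff (and optional maximum peak-to-TSS distance) the
#' peaks passing are restricted and their binding deltas are correlated with
#' the expression deltas of their assigned genes, with Fisher-Z confidence
#' intervals.
#'
#' @param peaks data.frame with ip_a, ip_b, lib_a, lib_b, delta_signal,
#'   gene and optionally tss_distance columns.
#' @param expr_delta named numeric vector of per-gene expression deltas.
#' @param fdr_grid FDR cutoffs to scan.
#' @param dist_grid maximum TSS distances to scan (default Inf only).
#' @return data.frame with fdr, max_dist, n, r, ci_lo, ci_hi (NA rows where
#'   fewer than 4 pairs pass).
#' @export
delta_vs_expression <- function(peaks, expr_delta,
                                fdr_grid = c(0.01, 0.05, 0.1, 0.2),
                                dist_grid = Inf) {
  p_allele <- mapply(function(a, b, la, lb) {
    if (a + b == 0) return(1)
    stats::binom.test(a, a + b, p = la / (la + lb))$p.value
  }, peaks$ip_a, peaks$ip_b, peaks$lib_a, peaks$lib_b)
  q <- stats::p.adjust(p_allele, method = "BH")
  dist <- if (is.null(peaks$tss_distance)) rep(0, nrow(peaks)) else
    peaks$tss_distance
  de <- expr_delta[peaks$gene]
  grid <- expand.grid(fdr = fdr_grid, max_dist = dist_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    keep <- q <= grid$fdr[i] & dist <= grid$max_dist[i] & !is.na(de)
    if (sum(keep) < 4L)
      return(data.frame(fdr = grid$fdr[i], max_dist = grid$max_dist[i],
                        n = sum(keep), r = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_))
    fz <- fisher_z_corr(peaks$delta_signal[keep], de[keep])
    data.frame(fdr = grid$fdr[i], max_dist = grid$max_dist[i], n = fz$n,
               r = fz$r, ci_lo = fz$ci[1], ci_hi = fz$ci[2])
  })
  out <- do.call(rbind, rows)
  attr(out, "q") <- q
  out
}

#' Aggregate signal profile around anchor positions
#'
#' Extracts a window of `flank` bp either side of each anchor from per-bp
#' coverage tracks, flips windows on minus-strand anchors, and summarizes
#' per offset with the median (or mean) across anchors.
#'
#' @param tracks named list of per-bp numeric coverage vectors (1-based),
#'   one per contig.
#' @param anchors data.frame with contig, pos (1-based) and optional strand.
#' @param flank flank size in bp (default 400).
#' @param summary "median" or "mean".
#' @return numeric vector of length 2*flank+1, names are offsets.
#' @export
aggregate_profile <- function(tracks, anchors, flank = 400,
                              summary = c("median", "mean")) {
  summary <- match.arg(summary)
  if (nrow(anchors) == 0L) stopf("empty anchor set")
  wins <- vapply(seq_len(nrow(anchors)), function(i) {
    tr <- tracks[[anchors$contig[i]]]
    p <- anchors$pos[i]
    if (p - flank < 1L || p + flank > length(tr))
      stopf("anchor at %s:%d outside track bounds", anchors$contig[i], p)
    w <- tr[(p - flank):(p + flank)]
    if (!is.null(anchors$strand) && anchors$strand[i] == "-") w <- rev(w)
    w
  }, numeric(2 * flank + 1))
  f <- if (summary == "median") stats::median else mean
  prof <- apply(wins, 1, f)
  names(prof) <- as.character(seq(-flank, flank))
  prof
}
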