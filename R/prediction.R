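# Contextual-motif prediction of TF occupancy at anchor-motif hits:
# composition-matched training sets, contextual feature extraction,
# shuffled-PWM motif selection, cross-validated logistic regression, DeLong
# ROC comparison, and sensitivity at a target FDR.

# 4 mononucleotide + 16 dinucleotide frequencies of a sequence.
composition_vector <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  ch <- ch[ch %in% DNA_BASES]
  mono <- tabulate(match(ch, DNA_BASES), 4) / max(length(ch), 1)
  di_lab <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))
  if (length(ch) > 1) {
    di <- paste0(ch[-length(ch)], ch[-1])
    dif <- tabulate(match(di, di_lab), 16) / length(di)
  } else dif <- numeric(16)
  stats::setNames(c(mono, dif), c(DNA_BASES, di_lab))
}

#' Build composition-matched positive/negative training sets
#'
#' Positives are anchor-motif hits inside peaks; candidate negatives are
#' hits outside all peaks whose library-normalized IP read count in a
#' `window`-bp window centered on the hit does not exceed the normalized
#' input count. Negatives are matched 1:1 to positives by greedy
#' nearest-neighbor search (without replacement, Euclidean distance) on the
#' 20-dimensional mono+dinucleotide composition of the hit plus/minus
#' `comp_flank` bp. Hits inside `excluded_peaks` (peaks containing anchor
#' discSNP disruptions) are dropped from both classes.
#'
#' @param hits anchor-motif hit data.frame (contig, start, end, strand,
#'   score).
#' @param peaks peak data.frame (contig, start, end).
#' @param ip_win,input_win read counts in the window around each hit
#'   (aligned with `hits`).
#' @param lib_ip,lib_input library sizes for normalization.
#' @param genome named character vector of sequences.
#' @param excluded_peaks optional peaks to blacklist entirely.
#' @param n_per_class optional cap on class size (positives subsampled).
#' @param comp_flank flank for the composition vector (default 100).
#' @param seed integer seed (subsampling).
#' @return data.frame of hits with label ("bound"/"unbound"),
#'   anchor_score, and match_dist for negatives.
#' @export
build_training_sets <- function(hits, peaks, ip_win, input_win, lib_ip,
                                lib_input, genome, excluded_peaks = NULL,
                                n_per_class = NULL, comp_flank = 100,
                                seed = NULL) {
  overlaps_any <- function(pk) {
    if (is.null(pk) || nrow(pk) == 0L) return(rep(FALSE, nrow(hits)))
    vapply(seq_len(nrow(hits)), function(i)
      any(pk$contig == hits$contig[i] & pk$start < hits$end[i] &
            hits$start[i] < pk$end), logical(1))
  }
  in_peak <- overlaps_any(peaks)
  excluded <- overlaps_any(excluded_peaks)
  norm_ip <- ip_win / lib_ip
  norm_input <- input_win / lib_input
  pos_idx <- which(in_peak & !excluded)
  neg_idx <- which(!in_peak & !excluded & norm_ip <= norm_input)
  with_seed_opt(seed, {
    if (!is.null(n_per_class) && length(pos_idx) > n_per_class)
      pos_idx <- sort(sample(pos_idx, n_per_class))
    if (length(neg_idx) < length(pos_idx))
      stopf("cannot match %d positives from %d candidate negatives",
            length(pos_idx), length(neg_idx))
    comp_of <- function(i) {
      contig <- hits$contig[i]
      lo <- max(1L, hits$start[i] + 1L - comp_flank)
      hi <- min(nchar(genome[[contig]]), hits$end[i] + comp_flank)
      composition_vector(substr(genome[[contig]], lo, hi))
    }
    pos_comp <- t(vapply(pos_idx, comp_of, numeric(20)))
    neg_comp <- t(vapply(neg_idx, comp_of, numeric(20)))
    avail <- rep(TRUE, length(neg_idx))
    picked <- integer(length(pos_idx))
    pick_dist <- numeric(length(pos_idx))
    for (k in seq_along(pos_idx)) {
      d2 <- colSums((t(neg_comp) - pos_comp[k, ])^2)
      d2[!avail] <- Inf
      j <- which.min(d2)
      picked[k] <- j
      pick_dist[k] <- sqrt(d2[j])
      avail[j] <- FALSE
    }
    pos <- hits[pos_idx, , drop = FALSE]
    pos$label <- "bound"
    pos$match_dist <- NA_real_
    neg <- hits[neg_idx[picked], , drop = FALSE]
    neg$label <- "unbound"
    neg$match_dist <- pick_dist
    out <- rbind(pos, neg)
    out$anchor_score <- out$score
    rownames(out) <- NULL
    out
  })
}

#' Extract contextual-motif features around anchor hits
#'
#' Per example and contextual PWM, the best log-odds score over placements
#' whose edge-to-edge distance to the anchor placement is at most `radius`
#' bp; 0 when no placement reaches `floor`. 0 therefore encodes "no match
#' above the score floor", keeping the feature space dense.
#'
#' @param examples data.frame with contig, start, end (anchor placement,
#'   0-based).
#' @param context_pwms list of `pwm` objects.
#' @param genome named character vector of sequences.
#' @param radius maximum edge-to-edge distance in bp (default 100).
#' @param floor minimum score to count as a match (default 0 bits).
#' @return numeric matrix, one column per contextual motif.
#' @export
extract_context_features <- function(examples, context_pwms, genome,
                                     radius = 100, floor = 0) {
  feat <- matrix(0, nrow(examples), length(context_pwms),
                 dimnames = list(NULL, vapply(context_pwms,
                                              function(p) p$motif_id,
                                              character(1))))
  for (j in seq_along(context_pwms)) {
    p <- context_pwms[[j]]
    L <- pwm_length(p)
    for (i in seq_len(nrow(examples))) {
      contig <- examples$contig[i]
      glen <- nchar(genome[[contig]])
      lo <- max(0L, examples$start[i] - radius - L)        # 0-based
      hi <- min(glen, examples$end[i] + radius + L)
      if (hi - lo < L) next
      s <- substr(genome[[contig]], lo + 1L, hi)
      hits <- score_pwm(p, s, min_score = floor)
      if (nrow(hits) == 0L) next
      gap <- interval_gap(hits$start + lo, hits$end + lo,
                          examples$start[i], examples$end[i])
      hits <- hits[gap <= radius, , drop = FALSE]
      if (nrow(hits)) feat[i, j] <- max(hits$score)
    }
  }
  feat
}

#' Cross-validated logistic-regression binding predictor
#'
#' Fits a plain maximum-likelihood logistic regression on the specified
#' feature columns under stratified `n_folds`-fold cross-validation,
#' pooling out-of-fold scores into one ROC per run; `n_runs` runs redraw
#' the fold assignment. AUC is the trapezoidal-rule area.
#'
#' @param features numeric matrix or data.frame of predictors.
#' @param labels logical (or "bound"/"unbound") outcome per row.
#' @param model_id identifier ("anchor_only", "contextual",
#'   "shuffled_control", ...).
#' @param columns feature columns to use (default all).
#' @param n_folds folds per run (default 10).
#' @param n_runs independent CV runs (default 10).
#' @param seed integer seed.
#' @return object of class `model_report`: model_id, auc (per run), roc
#'   (list of per-run data.frames), scores (n x n_runs out-of-fold scores),
#'   labels, columns.
#' @export
fit_predict_cv <- function(features, labels, model_id = "model",
                           columns = NULL, n_folds = 10, n_runs = 10,
                           seed = NULL) {
  features <- as.matrix(features)
  if (is.character(labels)) labels <- labels == "bound"
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stopf("need both classes")
  if (!is.null(columns)) features <- features[, columns, drop = FALSE]
  n <- length(labels)
  with_seed_opt(seed, {
    scores <- matrix(NA_real_, n, n_runs)
    for (run in seq_len(n_runs)) {
      fold <- integer(n)
      fold[labels] <- sample(rep_len(seq_len(n_folds), sum(labels)))
      fold[!labels] <- sample(rep_len(seq_len(n_folds), sum(!labels)))
      for (k in seq_len(n_folds)) {
        tr <- fold != k
        if (length(unique(labels[tr])) < 2L)
          stopf("single-class training fold")
        df_tr <- data.frame(y = labels[tr], features[tr, , drop = FALSE])
        fit <- suppressWarnings(
          stats::glm(y ~ ., data = df_tr, family = stats::binomial()))
        df_te <- data.frame(features[!tr, , drop = FALSE])
        scores[!tr, run] <- suppressWarnings(
          stats::predict(fit, newdata = df_te, type = "link"))
      }
    }
    structure(list(
      model_id = model_id,
      auc = apply(scores, 2, auc_trapezoid, labels = labels),
      roc = lapply(seq_len(n_runs),
                   function(r) roc_points(scores[, r], labels)),
      scores = scores, labels = labels,
      columns = colnames(features)), class = "model_report")
  })
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("model '%s': median AUC %.3f over %d CV runs (features: %s)\n",
              x$model_id, stats::median(x$auc), length(x$auc),
              paste(x$columns, collapse = ", ")))
  invisible(x)
}

#' Compare two ROC curves with DeLong's paired test
#'
#' Uses each report's out-of-fold scores averaged over CV runs; the two
#' reports must come from the same examples (identical labels). Identical
#' score vectors give p = 1 by convention.
#'
#' @param report_a,report_b `model_report` objects on the same example set.
#' @return two-sided p value for the AUC difference.
#' @export
compare_roc <- function(report_a, report_b) {
  if (!identical(report_a$labels, report_b$labels))
    stopf("reports are not paired (labels differ)")
  sa <- rowMeans(report_a$scores)
  sb <- rowMeans(report_b$scores)
  if (isTRUE(all.equal(sa, sb))) return(1)
  r <- factor(report_a$labels, levels = c(FALSE, TRUE))
  test <- pROC::roc.test(
    pROC::roc(r, sa, quiet = TRUE, direction = "<"),
    pROC::roc(r, sb, quiet = TRUE, direction = "<"),
    method = "delong", paired = TRUE)
  unname(test$p.value)
}

#' Select contextual motifs against shuffled-PWM controls
#'
#' Per candidate motif: across `n_runs` example sets (each a fresh draw of
#' negatives) and `n_shuffles` column-shuffles per run, compares the
#' cross-validated AUC of an anchor+candidate logistic model against the
#' anchor+shuffle model. A candidate is selected when it outperforms its
#' shuffles in more than `win_threshold` of all runs x shuffles.
#'
#' @param runs list of example data.frames (each with contig, start, end,
#'   anchor_score, label), one per run.
#' @param candidate_pwms list of candidate contextual `pwm` objects.
#' @param genome named character vector of sequences.
#' @param n_shuffles shuffles per run (default 100).
#' @param radius contextual search radius in bp.
#' @param floor contextual score floor.
#' @param n_folds CV folds for each AUC.
#' @param win_threshold selection threshold on the win fraction (default
#'   0.9, i.e. selected when strictly exceeded).
#' @param seed integer seed.
#' @return data.frame with motif_id, win_fraction, selected.
#' @export
select_context_motifs <- function(runs, candidate_pwms, genome,
                                  n_shuffles = 100, radius = 100, floor = 0,
                                  n_folds = 10, win_threshold = 0.9,
                                  seed = NULL) {
  if (length(candidate_pwms) < 1L) stopf("no candidate motifs")
  with_seed_opt(seed, {
    rows <- lapply(candidate_pwms, function(p) {
      wins <- 0L
      total <- 0L
      for (ex in runs) {
        feat_cand <- extract_context_features(ex, list(p), genome,
                                              radius, floor)
        base <- cbind(anchor_score = ex$anchor_score)
        auc_cand <- stats::median(fit_predict_cv(
          cbind(base, ctx = feat_cand[, 1]), ex$label,
          n_folds = n_folds, n_runs = 1)$auc)
        for (s in seq_len(n_shuffles)) {
          ps <- shuffle_pwm(p)
          feat_sh <- extract_context_features(ex, list(ps), genome,
                                              radius, floor)
          auc_sh <- stats::median(fit_predict_cv(
            cbind(base, ctx = feat_sh[, 1]), ex$label,
            n_folds = n_folds, n_runs = 1)$auc)
          wins <- wins + (auc_cand > auc_sh)
          total <- total + 1L
        }
      }
      data.frame(motif_id = p$motif_id, win_fraction = wins / total)
    })
    out <- do.call(rbind, rows)
    out$selected <- out$win_fraction > win_threshold
    rownames(out) <- NULL
    out
  })
}

#' Sensitivity at a target empirical FDR
#'
#' Sweeps unique score thresholds descending; among thresholds whose
#' empirical FDR (FP/(FP+TP)) is at or below `fdr_target`, reports the
#' maximum sensitivity and the corresponding threshold. NA when no
#' threshold reaches the target.
#'
#' @param scores numeric prediction scores.
#' @param labels logical (or "bound"/"unbound") truth.
#' @param fdr_target target FDR (default 0.3).
#' @return list with sensitivity, threshold, fdr.
#' @export
sensitivity_at_fdr <- function(scores, labels, fdr_target = 0.3) {
  if (is.character(labels)) labels <- labels == "bound"
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stopf("need both classes")
  o <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[o])
  fp <- cumsum(!labels[o])
  last <- !duplicated(scores[o], fromLast = TRUE)   # complete threshold sets
  fdr <- fp[last] / pmax(fp[last] + tp[last], 1)
  sens <- tp[last] / sum(labels)
  thr <- scores[o][last]
  ok <- fdr <= fdr_target
  if (!any(ok)) return(list(sensitivity = NA_real_, threshold = NA_real_,
                            fdr = NA_real_))
  best <- which(ok)[which.max(sens[ok])]
  list(sensitivity = sens[best], threshold = thr[best], fdr = fdr[best])
}
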