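test_that("training sets follow the peak/IP rules and match composition", {
  set.seed(31)
  glen <- 60000
  genome <- c(chr = random_seq(glen))
  starts <- seq(200, glen - 400, by = 400)
  hits <- data.frame(contig = "chr", start = starts, end = starts + 6,
                     strand = "+", score = rnorm(length(starts), 8, 2))
  n <- nrow(hits)
  peaks <- data.frame(contig = "chr", start = hits$start[1:40] - 80,
                      end = hits$end[1:40] + 80)
  ip <- c(rpois(40, 200), rpois(n - 40, 30))
  input <- rep(50, n)
  ex <- build_training_sets(hits, peaks, ip, input, 2e6, 1e6, genome,
                            seed = 4)
  expect_equal(sum(ex$label == "bound"), 40)
  expect_equal(sum(ex$label == "unbound"), 40)
  # negatives obey the normalized IP <= input rule
  neg_rows <- match(
    paste(ex$start[ex$label == "unbound"]), paste(hits$start))
  expect_true(all(ip[neg_rows] / 2e6 <= input[neg_rows] / 1e6))
  # composition matching keeps mean GC close
  gc_of <- function(idx) {
    mean(vapply(idx, function(i) {
      s <- substr(genome[["chr"]], hits$start[i] - 99, hits$end[i] + 100)
      mean(strsplit(s, "")[[1]] %in% c("G", "C"))
    }, numeric(1)))
  }
  pos_rows <- match(paste(ex$start[ex$label == "bound"]), paste(hits$start))
  expect_lt(abs(gc_of(pos_rows) - gc_of(neg_rows)), 0.02)
  # blacklisted peaks drop their hits from both classes
  ex2 <- build_training_sets(hits, peaks, ip, input, 2e6, 1e6, genome,
                             excluded_peaks = peaks[1:10, ], seed = 4)
  expect_equal(sum(ex2$label == "bound"), 30)
})

test_that("contextual features report best in-radius score or zero", {
  ctx <- consensus_pwm("GCGCGC", "ctx", 0.95)
  win <- paste0(random_seq(120), "AGATAA", random_seq(120))
  # no context motif planted: expect 0 at a sensible floor
  genome <- c(s1 = win)
  ex <- data.frame(contig = "s1", start = 120L, end = 126L)
  f0 <- extract_context_features(ex, list(ctx), genome, floor = 8)
  expect_equal(unname(f0[1, 1]), 0)
  # planted at 50 bp: its score appears
  g2 <- genome
  substr(g2["s1"], 120 + 6 + 50 + 1, 120 + 6 + 50 + 6) <- "GCGCGC"
  f1 <- extract_context_features(ex, list(ctx), g2, floor = 8)
  expect_equal(unname(f1[1, 1]), 6 * log2(0.95 / 0.25), tolerance = 1e-9)
  # radius 0: only overlapping/touching placements count
  f2 <- extract_context_features(ex, list(ctx), g2, radius = 0, floor = 8)
  expect_equal(unname(f2[1, 1]), 0)
})

test_that("cross-validated logistic predictor behaves at the null and the separable limit", {
  set.seed(41)
  n <- 2000
  feats <- cbind(anchor_score = rnorm(n), ctx = rnorm(n))
  y_null <- sample(c(TRUE, FALSE), n, replace = TRUE)
  rep_null <- fit_predict_cv(feats, y_null, n_runs = 3, seed = 2)
  expect_lt(abs(median(rep_null$auc) - 0.5), 0.05)

  y_sep <- feats[, 1] > 0.3
  rep_sep <- fit_predict_cv(feats, y_sep, columns = "anchor_score",
                            n_runs = 2, seed = 2)
  # pooling out-of-fold scores mixes per-fold calibrations, so the pooled
  # ROC can dip infinitesimally below 1 even for separable data
  expect_gt(median(rep_sep$auc), 0.999)

  # sign flip of a feature leaves the refit AUC unchanged
  y <- runif(n) < plogis(feats[, 1])
  a1 <- fit_predict_cv(feats, y, n_runs = 2, seed = 3)
  feats_f <- feats; feats_f[, 1] <- -feats_f[, 1]
  a2 <- fit_predict_cv(feats_f, y, n_runs = 2, seed = 3)
  expect_equal(median(a1$auc), median(a2$auc), tolerance = 1e-9)
  expect_error(fit_predict_cv(feats, rep(TRUE, n)), "both classes")
})

test_that("DeLong comparison matches hand-computed structural components", {
  mk_report <- function(scores, labels)
    structure(list(labels = labels, scores = matrix(scores, ncol = 1)),
              class = "model_report")
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  sa <- c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2)
  sb <- c(0.6, 0.9, 0.5, 0.8, 0.4, 0.1)
  delong_by_hand <- function(s1, s2, y) {
    comp <- function(s) {
      pos <- s[y]; neg <- s[!y]
      v10 <- vapply(pos, function(p)
        mean((p > neg) + 0.5 * (p == neg)), numeric(1))
      v01 <- vapply(neg, function(q)
        mean((pos > q) + 0.5 * (pos == q)), numeric(1))
      list(a = mean(v10), v10 = v10, v01 = v01)
    }
    c1 <- comp(s1); c2 <- comp(s2)
    s10 <- cov(cbind(c1$v10, c2$v10))
    s01 <- cov(cbind(c1$v01, c2$v01))
    S <- s10 / length(c1$v10) + s01 / length(c1$v01)
    z <- (c1$a - c2$a) / sqrt(S[1, 1] + S[2, 2] - 2 * S[1, 2])
    2 * pnorm(-abs(z))
  }
  p_pkg <- compare_roc(mk_report(sa, labels), mk_report(sb, labels))
  expect_equal(p_pkg, delong_by_hand(sa, sb, labels), tolerance = 1e-9)
  # symmetric, and identical scores give p = 1
  expect_equal(p_pkg, compare_roc(mk_report(sb, labels),
                                  mk_report(sa, labels)))
  expect_equal(compare_roc(mk_report(sa, labels), mk_report(sa, labels)), 1)
  expect_error(compare_roc(mk_report(sa, labels),
                           mk_report(sa, !labels)), "not paired")
})

test_that("sensitivity at target FDR matches an exhaustive threshold sweep", {
  # perfectly separating scores
  s <- c(5, 4, 3, 2, 1, 0)
  y <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(sensitivity_at_fdr(s, y, 0.01)$sensitivity, 1)

  # all scores equal and pooled FDR above target -> NA
  expect_true(is.na(sensitivity_at_fdr(rep(1, 6), y, 0.3)$sensitivity))

  # 10-point case vs brute force
  set.seed(51)
  s10 <- sample(10)
  y10 <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE)
  brute <- function(scores, labels, target) {
    best <- NA_real_
    for (t in unique(scores)) {
      call <- scores >= t
      tp <- sum(call & labels); fp <- sum(call & !labels)
      if (fp + tp == 0) next
      if (fp / (fp + tp) <= target)
        best <- max(best, tp / sum(labels), na.rm = TRUE)
    }
    best
  }
  for (target in c(0.1, 0.3, 0.5))
    expect_equal(sensitivity_at_fdr(s10, y10, target)$sensitivity,
                 brute(s10, y10, target))
})

test_that("shuffled-control selection keeps planted context, rejects null", {
  anchor <- consensus_pwm("AGATAA", "anchor", 0.8)
  ctx <- consensus_pwm("CCGGTACG", "ctx", 0.95)
  # independent example draws per run (fresh sites and labels)
  sims <- lapply(1:6, function(i)
    simulate_binding_sites(250, anchor, ctx, context_effect = 3,
                           anchor_coef = 0.7, context_prob = 0.5,
                           seed = 600 + i))
  genome <- character(0)
  runs <- list()
  for (i in seq_along(sims)) {
    g <- sims[[i]]$genome
    names(g) <- paste0("r", i, "_", names(g))
    ex <- sims[[i]]$examples
    ex$contig <- paste0("r", i, "_", ex$contig)
    genome <- c(genome, g)
    runs[[i]] <- ex
  }
  sel <- select_context_motifs(runs[1:2], list(ctx), genome,
                               n_shuffles = 12, n_folds = 5, seed = 63)
  expect_true(sel$selected)
  expect_gt(sel$win_fraction, 0.9)

  # a motif with no planted signal: wins only by chance, not selected
  null_ctx <- consensus_pwm("TTAACGTT", "null_ctx", 0.95)
  sel0 <- select_context_motifs(runs, list(null_ctx), genome,
                                n_shuffles = 8, n_folds = 5, seed = 64)
  expect_false(sel0$selected)
  expect_lt(sel0$win_fraction, 0.9)
})
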