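# Benchmark experiments run on synthetic data with known ground truth.
# These encode the package's reference study conditions (peak counts, event
# counts per motif position, planted effect sizes, dispersion, depths) and
# are consumed both by the test suite and by scripts/acceptance.R.

# the default anchor motif used by the benchmarks: a GATA-factor-like
# 6-mer (AGATAA) with a sharp consensus
benchmark_anchor_pwm <- function() {
  consensus <- c("A", "G", "A", "T", "A", "A")
  mat <- vapply(consensus, function(b) {
    col <- rep(0.03, 4)
    col[match(b, DNA_BASES)] <- 0.91
    col
  }, numeric(4))
  pwm(mat, motif_id = "Gata1", tf_name = "Gata1", family = "GATA")
}

#' Parameter-recovery experiment for grouped impact statistics
#'
#' Repeatedly simulates an allele-resolved ChIP experiment in which
#' discSNPs disrupt the anchor motif at chosen positions with known
#' multiplicative effects, runs the signal pipeline (library-size
#' normalization, input subtraction, percent residual binding, grouped
#' bootstrap summaries) and records whether each group's 95% bootstrap CI
#' covers the planted value (100 x effect). On the first replicate the
#' full sequence-level path — pileup simulation, zygosity calling, discSNP
#' pairing and per-SNP motif disruption scoring — is run and checked
#' against the truth bookkeeping before the count-level replicates proceed.
#'
#' @param n_reps simulation replicates (default 100).
#' @param n_peaks peaks per replicate (default 2000).
#' @param events_per_position disruption events per motif position.
#' @param effects planted multiplicative effects, one per entry of
#'   `positions`.
#' @param positions anchor-motif positions carrying the planted SNPs.
#' @param dispersion negative-binomial dispersion of the counts.
#' @param n_boot bootstrap replicates per group.
#' @param seed integer seed.
#' @return list with `coverage` (per position), `coverage_overall`,
#'   `pipeline_check` (events recovered by the sequence-level path on
#'   replicate 1 / events planted) and `details` (per rep x position).
#' @export
impact_recovery_experiment <- function(n_reps = 100, n_peaks = 2000,
                                       events_per_position = 200,
                                       effects = c(1, 0.7, 0.5, 0.2),
                                       positions = 2:5, dispersion = 0.2,
                                       n_boot = 1000, seed = 1) {
  anchor <- benchmark_anchor_pwm()
  eff_vec <- rep(1, pwm_length(anchor))
  eff_vec[positions] <- effects
  n_events <- events_per_position * length(positions)
  glen <- 10 * n_peaks * 200
  rows <- list()
  pipeline_check <- NA_real_
  # independent sub-seeds per replicate and stage, drawn from the master
  # seed so that different master seeds share no replicate randomness
  sub <- withr::with_seed(seed,
                          matrix(sample.int(2^30, 3 * (n_reps + 1)),
                                 ncol = 3, nrow = n_reps + 1))
  for (r in seq_len(n_reps)) {
    tr <- simulate_genome_pair(glen, n_peaks, n_events, list(anchor),
                               motif_effects = eff_vec, frac_in_motif = 1,
                               motif_offsets = positions,
                               sequences = (r == 1L), seed = sub[r, 1])
    if (r == 1L)
      pipeline_check <- check_sequence_pipeline(tr, anchor,
                                                seed = sub[n_reps + 1, 1])
    cc <- simulate_chip_counts(tr, dispersion = dispersion,
                               seed = sub[r, 2])
    int_a <- normalize_chip(cc$counts$ip_a, cc$counts$input_a,
                            cc$lib_sizes[["ip_a"]],
                            cc$lib_sizes[["input_a"]])
    int_b <- normalize_chip(cc$counts$ip_b, cc$counts$input_b,
                            cc$lib_sizes[["ip_b"]],
                            cc$lib_sizes[["input_b"]])
    s <- tr$snps[tr$snps$in_motif, ]
    intact <- ifelse(s$disrupted_line == "A", int_b[s$peak], int_a[s$peak])
    disrupted <- ifelse(s$disrupted_line == "A", int_a[s$peak],
                        int_b[s$peak])
    gi <- group_impact(percent_residual(intact, disrupted),
                       s$motif_position, n_boot = n_boot,
                       seed = sub[r, 3])
    truth_val <- 100 * eff_vec[as.integer(gi$group)]
    rows[[r]] <- data.frame(rep = r, position = as.integer(gi$group),
                            median = gi$median, ci_lo = gi$ci_lo,
                            ci_hi = gi$ci_hi,
                            covered = gi$ci_lo <= truth_val &
                              truth_val <= gi$ci_hi)
  }
  details <- do.call(rbind, rows)
  coverage <- tapply(details$covered, details$position, mean)
  list(coverage = coverage, coverage_overall = mean(details$covered),
       pipeline_check = pipeline_check, details = details)
}

# Sequence-level pipeline check: pileups -> zygosity calls -> discSNPs ->
# disruption scoring, compared against the same disruption scoring run
# from perfect variant knowledge (the generator's SNP list). Restricted to
# qualified sites — depth above the gate and a confident (non-ambiguous)
# zygosity call in both lines; ambiguous calls are the caller declining,
# not a pipeline failure. Returns the fraction of truth-side events
# reproduced identically through the calling front end. The scoring layer
# itself is validated separately against exhaustive placement enumeration;
# this check isolates what the simplified caller loses or distorts.
check_sequence_pipeline <- function(tr, anchor, mean_depth = 30,
                                    error_rate = 0.003, seed = 1) {
  pile <- simulate_pileups(tr, mean_depth = mean_depth,
                           error_rate = error_rate, seed = seed)
  calls_a <- call_variant_table(pile$line_a)
  calls_b <- call_variant_table(pile$line_b)
  disc <- find_disc_snps(calls_a, calls_b)
  qualified <- calls_a$depth > 5 & calls_b$depth > 5 &
    calls_a$zygosity != "ambiguous" & calls_b$zygosity != "ambiguous"
  s <- tr$snps[tr$snps$in_motif & qualified, ]
  event_key <- function(ev) {
    ev <- ev[ev$is_called_disruption, ]
    paste(ev$pos, ev$motif_id, ev$start, ev$strand,
          ev$position_in_motif, ev$disrupted_line,
          signif(ev$score_max, 10), signif(ev$diff_score, 10))
  }
  ev_pipe <- event_key(call_disruptions(
    analyze_disc_snp(disc, tr$line_a, tr$line_b, list(anchor))))
  ev_truth <- event_key(call_disruptions(
    analyze_disc_snp(s[c("contig", "pos")], tr$line_a, tr$line_b,
                     list(anchor))))
  mean(ev_truth %in% ev_pipe)
}

#' Family-wise error of the permutation correction under the null
#'
#' Repeatedly draws residuals with no group effect (all groups share one
#' null distribution centered at 100%), applies the maxT permutation
#' adjustment and records how often any group reaches q below `alpha`.
#'
#' @param n_reps null replicates (default 200).
#' @param n_groups groups per replicate (default 10).
#' @param events_per_group events per group (default 50).
#' @param n_perm permutations (default 1000).
#' @param alpha nominal level (default 0.05).
#' @param null_sd standard deviation of the null residuals (percent).
#' @param seed integer seed.
#' @return list with `fwer` (fraction of replicates with any q <= alpha)
#'   and `min_q` per replicate.
#' @export
fwer_null_experiment <- function(n_reps = 200, n_groups = 10,
                                 events_per_group = 50, n_perm = 1000,
                                 alpha = 0.05, null_sd = 15, seed = 1) {
  sub <- withr::with_seed(seed, matrix(sample.int(2^30, 2 * n_reps),
                                       ncol = 2, nrow = n_reps))
  min_q <- vapply(seq_len(n_reps), function(r) {
    x <- withr::with_seed(sub[r, 1],
                          stats::rnorm(n_groups * events_per_group, 100,
                                       null_sd))
    g <- rep(paste0("g", seq_len(n_groups)), each = events_per_group)
    min(permutation_adjust(x, g, n_perm = n_perm, seed = sub[r, 2])$q)
  }, numeric(1))
  list(fwer = mean(min_q <= alpha), min_q = min_q)
}

#' Contextual-predictor discrimination benchmark
#'
#' Simulates labeled anchor-motif sites with (or without) one planted
#' contextual motif influencing occupancy, extracts anchor and contextual
#' features (real and column-shuffled control), fits the three
#' cross-validated logistic models and compares their ROC curves with
#' DeLong's paired test.
#'
#' @param n_sites sites (default 4000).
#' @param context_effect log-odds effect of the planted contextual motif
#'   (0 removes the signal).
#' @param n_runs,n_folds cross-validation layout.
#' @param seed integer seed.
#' @return list with per-model median AUCs, the three `model_report`
#'   objects and DeLong p values (contextual vs anchor-only, contextual vs
#'   shuffled control).
#' @export
predictor_benchmark <- function(n_sites = 4000, context_effect = 2,
                                n_runs = 10, n_folds = 10, seed = 1) {
  anchor <- benchmark_anchor_pwm()
  ctx <- pwm(vapply(c("C", "C", "G", "G", "T", "A", "C", "G"),
                    function(b) {
                      col <- rep(0.02, 4)
                      col[match(b, DNA_BASES)] <- 0.94
                      col
                    }, numeric(4)), motif_id = "ctx", tf_name = "CTX")
  sub <- withr::with_seed(seed, sample.int(2^30, 5))
  sim <- simulate_binding_sites(n_sites, anchor, ctx,
                                context_effect = context_effect,
                                anchor_coef = 1, context_prob = 0.5,
                                seed = sub[1])
  ctx_shuf <- shuffle_pwm(ctx, seed = sub[2])
  feats <- cbind(
    anchor_score = sim$examples$anchor_score,
    ctx = extract_context_features(sim$examples, list(ctx), sim$genome,
                                   radius = 100, floor = 0)[, 1],
    ctx_shuf = extract_context_features(sim$examples, list(ctx_shuf),
                                        sim$genome, radius = 100,
                                        floor = 0)[, 1])
  labels <- sim$examples$label
  anchor_only <- fit_predict_cv(feats, labels, "anchor_only",
                                columns = "anchor_score",
                                n_folds = n_folds, n_runs = n_runs,
                                seed = sub[3])
  contextual <- fit_predict_cv(feats, labels, "contextual",
                               columns = c("anchor_score", "ctx"),
                               n_folds = n_folds, n_runs = n_runs,
                               seed = sub[4])
  shuffled <- fit_predict_cv(feats, labels, "shuffled_control",
                             columns = c("anchor_score", "ctx_shuf"),
                             n_folds = n_folds, n_runs = n_runs,
                             seed = sub[5])
  list(auc = c(anchor_only = stats::median(anchor_only$auc),
               contextual = stats::median(contextual$auc),
               shuffled_control = stats::median(shuffled$auc)),
       reports = list(anchor_only = anchor_only, contextual = contextual,
                      shuffled_control = shuffled),
       p_vs_anchor = compare_roc(contextual, anchor_only),
       p_vs_shuffled = compare_roc(contextual, shuffled))
}

#' Variant-calling benchmark on synthetic pileups
#'
#' Plants background discSNPs, simulates pileups at the stated depth and
#' error rate for both lines, calls zygosity, pairs the lines into
#' discSNPs and reports homozygous-variant precision/recall plus the
#' recovery rate of planted discSNPs among qualified sites: depth above
#' the ambiguity gate and a confident (non-ambiguous) zygosity call in
#' both lines. An ambiguous call is the caller declining to decide (e.g.
#' an error read at marginal depth lifting the variant fraction just past
#' a band edge); a confident miscall (het or the wrong homozygous class)
#' still counts as a recovery failure.
#'
#' @param n_sites planted discSNPs (default 10000).
#' @param mean_depth mean pileup depth (default 30).
#' @param error_rate sequencing error rate (default 0.003).
#' @param seed integer seed.
#' @return list with precision, recall, discsnp_recovery and counts.
#' @export
variant_benchmark <- function(n_sites = 10000, mean_depth = 30,
                              error_rate = 0.003, seed = 1) {
  anchor <- benchmark_anchor_pwm()
  sub <- withr::with_seed(seed, sample.int(2^30, 2))
  tr <- simulate_genome_pair(1.5e6, 50, n_sites, list(anchor),
                             frac_in_motif = 0, min_snp_spacing = 60,
                             sequences = FALSE, seed = sub[1])
  pile <- simulate_pileups(tr, mean_depth = mean_depth,
                           error_rate = error_rate, seed = sub[2])
  calls_a <- call_variant_table(pile$line_a)
  calls_b <- call_variant_table(pile$line_b)
  s <- tr$snps
  truth_a <- data.frame(contig = s$contig, pos = s$pos,
                        alt = s$base_a)[s$base_a != s$base_ref, ]
  ev <- evaluate_calls(calls_a, truth_a)
  disc <- find_disc_snps(calls_a, calls_b)
  qualified <- calls_a$depth > 5 & calls_b$depth > 5 &
    calls_a$zygosity != "ambiguous" & calls_b$zygosity != "ambiguous"
  key <- function(contig, pos) paste(contig, pos)
  recovered <- key(s$contig, s$pos)[qualified] %in%
    key(disc$contig, disc$pos)
  list(precision = ev$precision, recall = ev$recall,
       discsnp_recovery = mean(recovered),
       n_qualified = sum(qualified), n_called = nrow(disc))
}
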