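anchor6 <- function() consensus_pwm("AGATAA", "Gata1", 0.95)

test_that("genome pair generator keeps lines equal to reference off-SNP", {
  tr <- simulate_genome_pair(50000, n_peaks = 10, n_snps = 8,
                             pwms = list(anchor6()), min_snp_spacing = 500,
                             seed = 1)
  # differences between the two lines sit exactly at the planted discSNPs
  a <- strsplit(tr$line_a[[1]], "")[[1]]
  b <- strsplit(tr$line_b[[1]], "")[[1]]
  r <- strsplit(tr$reference[[1]], "")[[1]]
  expect_identical(sort(which(a != b)),
                   sort(tr$snps$pos[tr$snps$base_a != tr$snps$base_b]))
  off <- setdiff(seq_along(r), tr$snps$pos)
  expect_identical(a[off], r[off])
  expect_identical(b[off], r[off])
  # every planted SNP is a true homozygous divergence
  expect_true(all(tr$snps$base_a != tr$snps$base_b))
  # each peak contains its anchor instance
  anchors <- tr$motifs[tr$motifs$type == "anchor", ]
  expect_true(all(anchors$start >= tr$peaks$start &
                    anchors$end <= tr$peaks$end))
})

test_that("generator is a pure function of (config, seed)", {
  t1 <- simulate_genome_pair(50000, 10, 8, list(anchor6()),
                             min_snp_spacing = 500, seed = 9)
  t2 <- simulate_genome_pair(50000, 10, 8, list(anchor6()),
                             min_snp_spacing = 500, seed = 9)
  expect_identical(t1$snps, t2$snps)
  expect_identical(t1$reference, t2$reference)

  # no SNPs: both lines equal the reference
  t0 <- simulate_genome_pair(50000, 10, 0, list(anchor6()), seed = 2)
  expect_identical(t0$line_a, t0$reference)
  expect_identical(t0$line_b, t0$reference)

  # bookkeeping: one SNP forced into motif position 3
  tm <- simulate_genome_pair(50000, 10, 1, list(anchor6()),
                             frac_in_motif = 1, motif_offsets = 3, seed = 3)
  expect_equal(tm$snps$motif_position, 3)
  expect_true(tm$snps$in_motif)
  m <- tm$motifs[tm$motifs$peak == tm$snps$peak &
                   tm$motifs$type == "anchor", ]
  expect_equal(tm$snps$pos, m$start + 3)

  expect_error(simulate_genome_pair(100, 10, 0, list(anchor6())),
               "too short")
})

test_that("pileup simulation honors the noiseless limits and mean depth", {
  tr <- simulate_genome_pair(50000, 10, 10, list(anchor6()),
                             min_snp_spacing = 300, seed = 4)
  p0 <- simulate_pileups(tr, mean_depth = 20, error_rate = 0, seed = 5)
  carries_a <- tr$snps$base_a != tr$snps$base_ref
  expect_true(all(p0$line_a$alt_reads[carries_a] ==
                    p0$line_a$depth[carries_a]))
  expect_true(all(p0$line_a$alt_reads[!carries_a] == 0))

  # law of large numbers on the Poisson depth (10,000 draws via recycling)
  tr2 <- simulate_genome_pair(1.6e6, 20, 1000, list(anchor6()),
                              min_snp_spacing = 100, frac_in_motif = 0,
                              seed = 6)
  deps <- replicate(10, simulate_pileups(tr2, 30, 0.001)$line_a$depth)
  expect_lt(abs(mean(deps) - 30) / 30, 0.01)
  expect_error(simulate_pileups(tr, mean_depth = 0), "mean_depth")
  expect_error(simulate_pileups(tr, 30, error_rate = 0.5), "error_rate")
})

test_that("ChIP counts carry planted effects only on the disrupted allele", {
  # null effects: per-allele means equal up to library scale
  tr <- simulate_genome_pair(5e5, 100, 50, list(anchor6()),
                             motif_effects = rep(1, 6),
                             min_snp_spacing = 100, seed = 7)
  cc <- simulate_chip_counts(tr, dispersion = 0,
                             lib_scale = c(ip_a = 2, ip_b = 1,
                                           input_a = 1, input_b = 1),
                             seed = 8)
  expect_true(all(cc$effect_a == 1) && all(cc$effect_b == 1))
  expect_equal(mean(cc$counts$ip_a) / mean(cc$counts$ip_b), 2,
               tolerance = 0.05)

  # same seed, same table
  cc2 <- simulate_chip_counts(tr, dispersion = 0,
                              lib_scale = c(ip_a = 2, ip_b = 1,
                                            input_a = 1, input_b = 1),
                              seed = 8)
  expect_identical(cc$counts, cc2$counts)

  # planted effect 0.5 at motif position 2, Poisson limit, many peaks:
  # disrupted/intact mean count ratio (input-subtracted) within 5% of 0.5
  tr2 <- simulate_genome_pair(4e6, 800, 800, list(anchor6()),
                              motif_effects = c(1, 0.5, 1, 1, 1, 1),
                              frac_in_motif = 1, motif_offsets = 2,
                              min_snp_spacing = 1500,
                              base_intensity_sdlog = 0, seed = 9)
  cc3 <- simulate_chip_counts(tr2, dispersion = 0, input_base = 20,
                              seed = 10)
  s <- tr2$snps
  dis_a <- s$disrupted_line == "A"
  ratio <- (mean(cc3$counts$ip_a[s$peak[dis_a]]) - 20) /
    (mean(cc3$counts$ip_b[s$peak[dis_a]]) - 20)
  expect_equal(ratio, 0.5, tolerance = 0.05)
})

test_that("contextual effects are gated by the planted distance window", {
  ctx <- context_config(consensus_pwm("CCGGTACG", "ctx", 0.95),
                        effect = 0.4, dist_lo = 0, dist_hi = 50,
                        prob = 1, plant_range = c(0, 150))
  tr <- simulate_genome_pair(3e5, 40, 0, list(anchor6()),
                             motif_effects = rep(1, 6),
                             contexts = list(ctx), seed = 11)
  m <- tr$motifs[tr$motifs$type == "context", ]
  s <- tr$snps[tr$snps$context, ]
  expect_gt(nrow(s), 0)
  cc <- simulate_chip_counts(tr, dispersion = 0, seed = 12)
  eff <- ifelse(s$disrupted_line == "A", cc$effect_a[s$peak],
                cc$effect_b[s$peak])
  gap <- m$gap[match(s$peak, m$peak)]
  expect_true(all(eff[gap <= 50] == 0.4))
  expect_true(all(eff[gap > 50] == 1))
})

test_that("deletion libraries honor the null and full-knockout limits", {
  ref <- paste0(strrep("ACGT", 20), "AGATAA", strrep("TGCA", 20))
  # retention 1 for every allele: expected IP/Input ratios equal
  lib1 <- simulate_deletion_library(ref, 80, 86, n_alleles = 10,
                                    retention = function(s, e) rep(1,
                                      length(s)),
                                    input_depth = 50000, ip_depth = 50000,
                                    n_replicates = 1, seed = 13)
  expect_identical(sort(names(lib1$reads)), c("input_1", "ip_1"))
  # the WT read is the reference itself
  expect_true(ref %in% lib1$reads$input_1)
  # per-sequence IP and Input frequencies agree under uniform retention
  seqs <- unique(lib1$reads$input_1)
  f_in <- table(factor(lib1$reads$input_1, levels = seqs)) / 50000
  f_ip <- table(factor(lib1$reads$ip_1, levels = seqs)) / 50000
  expect_lt(max(abs(f_in - f_ip)), 0.02)

  # allele deleting the whole motif with retention ~0 almost never in IP
  strong <- function(s, e) ifelse(!is.na(s) & s <= 80 & e >= 86, 1e-6, 1)
  lib2 <- simulate_deletion_library(ref, 80, 86, n_alleles = 15,
                                    del_len_sampler = function(n)
                                      rep(20L, n),
                                    retention = function(s, e)
                                      strong(s, e),
                                    input_depth = 20000, ip_depth = 20000,
                                    n_replicates = 1, seed = 14)
  full <- which(!is.na(lib2$truth$start) & lib2$truth$start <= 80 &
                  lib2$truth$end >= 86)
  if (length(full)) {
    del_seq <- paste0(substr(ref, 1, lib2$truth$start[full[1]]),
                      substring(ref, lib2$truth$end[full[1]] + 1))
    expect_equal(sum(lib2$reads$ip_1 == del_seq), 0)
    expect_gt(sum(lib2$reads$input_1 == del_seq), 0)
  }
  # determinism
  lib3 <- simulate_deletion_library(ref, 80, 86, n_alleles = 15,
                                    del_len_sampler = function(n)
                                      rep(20L, n),
                                    retention = function(s, e)
                                      strong(s, e),
                                    input_depth = 20000, ip_depth = 20000,
                                    n_replicates = 1, seed = 14)
  expect_identical(lib2$truth, lib3$truth)
  expect_identical(lib2$reads, lib3$reads)
  expect_error(simulate_deletion_library(ref, 80, 300), "outside amplicon")
})

test_that("random-walk threshold search recovers a planted DiffScore cut", {
  set.seed(1)
  n <- 600
  ev <- data.frame(score_max = runif(n, 8, 18), diff_score = rexp(n, 1))
  res <- ifelse(ev$diff_score >= 2.5, rnorm(n, 45, 8), rnorm(n, 100, 5))
  opt <- optimize_thresholds(ev, res, n_runs = 40, n_steps = 40, seed = 5)
  expect_lt(abs(opt$thresholds$diff_score_thres - 2.5), 1.0)
  # deterministic under a fixed seed
  opt2 <- optimize_thresholds(ev, res, n_runs = 40, n_steps = 40, seed = 5)
  expect_identical(opt$per_run, opt2$per_run)

  # zero-effect data: flat objective near zero loss, thresholds in bounds
  res0 <- rnorm(n, 100, 5)
  opt0 <- optimize_thresholds(ev, res0, n_runs = 20, n_steps = 30,
                              seed = 6)
  expect_lt(abs(median(opt0$per_run$objective)), 5)
  expect_true(opt0$thresholds$score_thres >= 0 &&
                opt0$thresholds$score_thres <= 20)
  expect_error(optimize_thresholds(ev[1:50, ], res[1:50]), "at least 100")
})
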