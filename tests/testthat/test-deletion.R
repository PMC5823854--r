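test_that("global alignment recovers simple deletions with EMBOSS-style scoring", {
  ref <- "ACGTACGT"
  a0 <- global_align(ref, ref)
  expect_equal(a0$pct_identity, 100)
  expect_equal(nrow(a0$deletions), 0)
  expect_equal(a0$score, 8 * 5)

  a1 <- global_align("ACGACGT", ref)
  expect_equal(nrow(a1$deletions), 1)
  expect_equal(a1$deletions$length, 1)
  expect_equal(a1$score, 7 * 5 - 10.5)
  expect_equal(a1$score, oracle_align_score("ACGACGT", ref))

  expect_error(global_align("ACGX", ref), "non-DNA")
  expect_error(global_align("", ref), "empty")
})

test_that("alignment scores match the brute-force affine DP on short pairs", {
  set.seed(71)
  for (i in 1:40) {
    read <- random_seq(sample(3:10, 1))
    ref <- random_seq(sample(4:12, 1))
    a <- global_align(read, ref)
    expect_equal(a$score, oracle_align_score(read, ref), tolerance = 1e-9)
    # the reported alignment itself attains the optimal score
    expect_equal(score_of_alignment(a$read_aln, a$ref_aln), a$score,
                 tolerance = 1e-9)
  }
})

test_that("allele classification keeps WT and single deletions only", {
  ref <- paste0(strrep("ACGT", 20), "AGATAA", strrep("TGCA", 20))
  expect_identical(classify_allele(global_align(ref, ref))$class, "WT")

  # one 26-bp deletion
  del1 <- paste0(substr(ref, 1, 60), substring(ref, 87))
  c1 <- classify_allele(global_align(del1, ref))
  expect_identical(c1$class, "single_deletion")
  expect_equal(c1$end - c1$start, 26)

  # two separate deletions -> discard
  del2 <- paste0(substr(ref, 1, 20), substring(ref, 31, 90),
                 substring(ref, 101))
  expect_identical(classify_allele(global_align(del2, ref))$class,
                   "discard")

  # garbage read fails the identity filter
  expect_identical(classify_allele(global_align(random_seq(166),
                                                ref))$class, "discard")
})

test_that("allele tallies key on exact deletion intervals, WT always present", {
  cl <- data.frame(library = rep("input_1", 15),
                   class = c(rep("WT", 10), rep("single_deletion", 5)),
                   start = c(rep(NA, 10), rep(20, 5)),
                   end = c(rep(NA, 10), rep(46, 5)))
  t1 <- tally_alleles(cl)
  expect_equal(nrow(t1), 2)
  expect_equal(t1$input_1, c(10L, 5L))

  # off-by-one deletions are distinct alleles
  cl2 <- rbind(cl, data.frame(library = "input_1",
                              class = "single_deletion", start = 21,
                              end = 47))
  expect_equal(nrow(tally_alleles(cl2)), 3)

  expect_error(tally_alleles(cl[0, ]), "no reads")
})

test_that("WT-normalized enrichment is exactly 1 for WT and scale invariant", {
  tally <- data.frame(allele = c("WT", "10:36", "40:42", "50:80"),
                      start = c(NA, 10, 40, 50), end = c(NA, 36, 42, 80),
                      input_1 = c(1000L, 400L, 300L, 30L),
                      ip_1 = c(2000L, 100L, 650L, 20L))
  e <- compute_enrichment(tally, "input_1", "ip_1", min_input_count = 50)
  expect_identical(e$enrichment[e$allele == "WT"], 1)
  # proportional counts give enrichment 1
  expect_equal(e$enrichment[e$allele == "40:42"],
               (650 / 2000) / (300 / 1000), tolerance = 1e-12)
  expect_true(e$low_coverage[e$allele == "50:80"])
  # zero IP -> zero enrichment
  tally$ip_1[2] <- 0L
  e2 <- compute_enrichment(tally, "input_1", "ip_1")
  expect_equal(e2$enrichment[2], 0)
  # scale invariance per library
  tally3 <- tally
  tally3$input_1 <- tally3$input_1 * 7L
  e3 <- compute_enrichment(tally3, "input_1", "ip_1")
  expect_equal(e3$enrichment, e2$enrichment, tolerance = 1e-12)
  # WT missing or zero
  expect_error(compute_enrichment(tally[-1, ], "input_1", "ip_1"),
               "missing")
})

test_that("deletion/motif overlap classes partition all cases", {
  expect_identical(overlap_class(10, 40, 15, 21), "full")
  expect_identical(overlap_class(18, 25, 15, 21), "partial")
  expect_identical(overlap_class(30, 40, 15, 21), "none")
  expect_identical(overlap_class(NA, NA, 15, 21), "none")   # WT
  expect_error(overlap_class(0, 5, 10, 10), "empty motif")
  set.seed(81)
  s <- sample(0:50, 30, replace = TRUE)
  e <- s + sample(1:20, 30, replace = TRUE)
  cls <- overlap_class(s, e, 20, 26)
  expect_true(all(cls %in% c("full", "partial", "none")))
})

test_that("2-bp sliding windows localize short-deletion effects", {
  # a 1-bp deletion at p intersects windows [p-1, p+1) and [p, p+2)
  al <- data.frame(start = 10, end = 11, enrichment = 0.5)
  w <- window_deletion_impact(al, ref_length = 20)
  expect_equal(w$win_start, c(9, 10))

  # null: all enrichments 1 -> p >= 0.5 everywhere
  al0 <- data.frame(start = c(5, 6, 7, 5, 6), end = c(6, 7, 8, 7, 8),
                    enrichment = 1)
  w0 <- window_deletion_impact(al0, ref_length = 20)
  expect_true(all(w0$p >= 0.5))

  # planted core effect: core windows significant, flanks not
  set.seed(91)
  core <- data.frame(start = rep(30:35, each = 8))
  core$end <- core$start + 1
  core$enrichment <- runif(nrow(core), 0.05, 0.2)
  flank <- data.frame(start = rep(c(10:15, 50:55), each = 8))
  flank$end <- flank$start + 1
  flank$enrichment <- runif(nrow(flank), 0.95, 1.25)
  wi <- window_deletion_impact(rbind(core, flank), ref_length = 80)
  expect_lt(max(wi$p[wi$win_start %in% 30:34]), 0.01)
  expect_gt(min(wi$p[wi$win_start %in% c(10:14, 50:54)]), 0.05)

  # no qualifying alleles -> empty table
  expect_equal(nrow(window_deletion_impact(
    data.frame(start = 5, end = 30, enrichment = 0.2), ref_length = 40)), 0)
})

test_that("the full scanner pipeline recovers true binding retention", {
  set.seed(101)
  ref <- paste0(random_seq(90), "AGATAA", random_seq(90))
  # graded retention: decays with proximity of the deletion to the motif,
  # so that rank recovery is informative (not a near-binary truth)
  graded <- function(s, e) {
    d <- pmax(0, pmax(90 - e, s - 96))
    pmin(1, 0.05 + 0.95 * d / 40)
  }
  lib <- simulate_deletion_library(ref, motif_start = 90, motif_end = 96,
                                   n_alleles = 30, retention = graded,
                                   input_depth = 25000,
                                   ip_depth = 25000, n_replicates = 2,
                                   seed = 102)
  res <- deletion_scan(lib$reads, ref,
                       input_cols = c("input_1", "input_2"),
                       ip_cols = c("ip_1", "ip_2"), min_input_count = 50)
  al <- res$alleles[!res$alleles$low_coverage, ]
  truth <- lib$truth
  # gap placement inside repeats is ambiguous, so alleles are matched by
  # the read sequence the keyed deletion produces, not by the raw interval
  seq_of <- function(s, e) ifelse(is.na(s), ref,
    paste0(substr(ref, 1, s), substring(ref, e + 1)))
  truth$read_seq <- mapply(seq_of, truth$start, truth$end)
  al$read_seq <- mapply(seq_of, al$start, al$end)
  agg <- do.call(rbind, lapply(split(truth, truth$read_seq), function(d)
    data.frame(read_seq = d$read_seq[1],
               retention = sum(d$retention * d$abundance) /
                 sum(d$abundance))))
  m <- match(al$read_seq, agg$read_seq)
  expect_true(all(!is.na(m)))
  keep <- al$allele != "WT"
  rc <- cor(al$enrichment[keep], agg$retention[m][keep],
            method = "spearman")
  expect_gte(rc, 0.9)
  # wild-type allele normalized to exactly 1
  expect_equal(al$enrichment[al$allele == "WT"], 1)
})
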