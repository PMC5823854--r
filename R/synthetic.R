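# Synthetic-data generator. Produces a pair of homozygous diploid "cell
# line" genomes differing by planted discriminatory SNPs, motif instances
# inside peaks, sequencing pileups with error, allele-resolved overdispersed
# ChIP/input counts whose means respond to planted motif-disruption effects
# (with distance-gated contextual effects), CRISPR deletion-allele
# libraries, and labeled motif-site sets for the binding predictor — all as
# pure functions of (configuration, seed), with the ground truth emitted
# machine-readably.

random_dna <- function(n) {
  paste(DNA_BASES[sample.int(4, n, replace = TRUE)], collapse = "")
}

splice <- function(s, start, value) {           # start 1-based
  substr(s, start, start + nchar(value) - 1L) <- value
  s
}

# the base at a PWM column with the lowest probability that differs from
# `keep_not` — the maximally disruptive substitution
worst_base <- function(p, col, keep_not) {
  pr <- p$mat[, col]
  cand <- setdiff(DNA_BASES[order(pr)], keep_not)
  cand[1]
}

#' Configuration for a planted contextual motif
#'
#' @param p contextual `pwm`.
#' @param effect multiplicative binding effect of disrupting the contextual
#'   motif, in `[0, 1]` (applies to the disrupted line's mean intensity).
#' @param dist_lo,dist_hi active edge-to-edge distance range in bp: the
#'   effect only acts when the planted gap falls inside `[dist_lo, dist_hi]`.
#' @param prob probability that a peak carries the contextual motif.
#' @param plant_range range the planted gap is drawn from (uniform integer);
#'   defaults to `c(0, 150)` so some instances fall outside the active range.
#' @return list describing one contextual motif.
#' @export
context_config <- function(p, effect, dist_lo = 0, dist_hi = 50,
                           prob = 0.5, plant_range = c(0, 150)) {
  if (effect < 0 || effect > 1) stopf("effect must be in [0, 1]")
  list(pwm = p, effect = effect, dist_lo = dist_lo, dist_hi = dist_hi,
       prob = prob, plant_range = plant_range)
}

#' Simulate a pair of cell-line genomes with planted discSNPs
#'
#' Builds one reference contig carrying `n_peaks` equally spaced peaks
#' (width `peak_width`, summit at the center) each with one anchor-motif
#' consensus instance at the summit, optional contextual-motif instances at
#' known edge-to-edge distances, and `n_snps` discriminatory SNPs: a
#' fraction inside anchor motifs at chosen offsets (maximally disruptive
#' base, carried by a random line), the rest in background sequence. Both
#' line genomes are the reference with the SNP substitutions applied; SNPs
#' never fall closer together than `min_snp_spacing`.
#'
#' @param length contig length in bp (must be at least
#'   `10 * n_peaks * peak_width`).
#' @param n_peaks number of peaks.
#' @param n_snps number of planted discSNPs.
#' @param pwms list of `pwm` objects; the first is the anchor motif.
#' @param motif_effects numeric vector of multiplicative binding effects per
#'   anchor-motif position (length = motif width, values in `[0, 1]`);
#'   default 0.5 everywhere.
#' @param contexts optional list of [context_config()] entries.
#' @param frac_in_motif fraction of discSNPs planted inside anchor motifs.
#' @param motif_offsets anchor-motif positions (1-based) to plant SNPs at,
#'   cycled; default all positions.
#' @param peak_width peak width in bp (default 200).
#' @param min_snp_spacing minimum distance between planted SNPs.
#' @param base_intensity_meanlog,base_intensity_sdlog log-normal parameters
#'   of per-peak true mean intensity.
#' @param sequences build the actual genome strings (default TRUE). With
#'   FALSE only the truth tables are produced — planted bases still come
#'   from the motif consensus — which is much faster at Mb scale when the
#'   downstream analysis consumes counts, not sequence.
#' @param seed integer seed.
#' @return object of class `sim_truth`: reference/line_a/line_b genomes
#'   (NA when `sequences = FALSE`), `snps`, `peaks`, `motifs`,
#'   `effect_truth`, `context_truth` tables.
#' @export
simulate_genome_pair <- function(length, n_peaks, n_snps, pwms,
                                 motif_effects = NULL, contexts = NULL,
                                 frac_in_motif = 0.5, motif_offsets = NULL,
                                 peak_width = 200, min_snp_spacing = 1500,
                                 base_intensity_meanlog = log(100),
                                 base_intensity_sdlog = 0.4,
                                 sequences = TRUE, seed = NULL) {
  anchor <- pwms[[1]]
  L <- pwm_length(anchor)
  if (length < 10 * n_peaks * peak_width)
    stopf("contig too short: need >= %d bp for %d peaks",
          10 * n_peaks * peak_width, n_peaks)
  if (L > peak_width) stopf("motif longer than peak")
  if (is.null(motif_effects)) motif_effects <- rep(0.5, L)
  if (length(motif_effects) != L)
    stopf("motif_effects must have one entry per motif position")
  if (any(motif_effects < 0 | motif_effects > 1))
    stopf("motif_effects must lie in [0, 1]")
  if (is.null(motif_offsets)) motif_offsets <- seq_len(L)
  n_in_motif <- round(frac_in_motif * n_snps)
  if (n_in_motif > n_peaks)
    stopf("infeasible SNP density: %d motif SNPs for %d peaks",
          n_in_motif, n_peaks)
  with_seed_opt(seed, {
    # the genome lives as a character vector until the very end: splicing
    # motifs and SNPs into a multi-Mb string would copy it once per edit
    refv <- if (sequences) DNA_BASES[sample.int(4, length, replace = TRUE)]
      else character(0)
    spacing <- length %/% n_peaks
    summit <- as.integer(spacing * (seq_len(n_peaks) - 0.5))   # 0-based
    peaks <- data.frame(contig = "chr_sim",
                        start = summit - peak_width %/% 2L,
                        end = summit + peak_width %/% 2L,
                        summit = summit,
                        base_intensity = stats::rlnorm(
                          n_peaks, base_intensity_meanlog,
                          base_intensity_sdlog))
    # anchor motif instance centered on every summit
    cons <- strsplit(pwm_consensus(anchor), "")[[1]]
    m_start <- summit - L %/% 2L                               # 0-based
    if (sequences)
      for (i in seq_len(n_peaks))
        refv[(m_start[i] + 1L):(m_start[i] + L)] <- cons
    motifs <- data.frame(motif_id = anchor$motif_id, peak = seq_len(n_peaks),
                         start = m_start, end = m_start + L, strand = "+",
                         type = "anchor", gap = NA_real_)
    # contextual motif instances at known edge-to-edge gaps
    ctx_rows <- list()
    if (!is.null(contexts)) {
      for (cc in contexts) {
        Lc <- pwm_length(cc$pwm)
        ccons <- strsplit(pwm_consensus(cc$pwm), "")[[1]]
        carry <- which(stats::runif(n_peaks) < cc$prob)
        for (i in carry) {
          gap <- sample(seq(cc$plant_range[1], cc$plant_range[2]), 1)
          side <- sample(c(-1, 1), 1)
          cstart <- if (side > 0) motifs$end[i] + gap else
            m_start[i] - gap - Lc
          if (cstart < 0 || cstart + Lc > length) next
          if (sequences) refv[(cstart + 1L):(cstart + Lc)] <- ccons
          ctx_rows[[length(ctx_rows) + 1L]] <- data.frame(
            motif_id = cc$pwm$motif_id, peak = i, start = cstart,
            end = cstart + Lc, strand = "+", type = "context", gap = gap)
        }
      }
      motifs <- rbind(motifs, do.call(rbind, ctx_rows))
    }
    # discSNPs inside anchor motifs: maximally disruptive base, random line
    snp_rows <- list()
    motif_peaks <- sample(n_peaks, n_in_motif)
    offs <- rep_len(motif_offsets, n_in_motif)
    for (k in seq_len(n_in_motif)) {
      i <- motif_peaks[k]
      off <- offs[k]
      pos <- m_start[i] + off                                 # 1-based
      intact <- cons[off]
      var <- worst_base(anchor, off, intact)
      dline <- sample(c("A", "B"), 1)
      snp_rows[[length(snp_rows) + 1L]] <- data.frame(
        contig = "chr_sim", pos = pos, base_ref = intact,
        base_a = if (dline == "A") var else intact,
        base_b = if (dline == "B") var else intact,
        is_disc = TRUE, in_motif = TRUE, context = FALSE,
        motif_id = anchor$motif_id, motif_position = off, peak = i,
        disrupted_line = dline)
    }
    # discSNPs disrupting planted contextual motifs (center position)
    if (length(ctx_rows)) {
      for (cr in ctx_rows) {
        cc <- contexts[[which(vapply(contexts, function(z)
          z$pwm$motif_id == cr$motif_id, logical(1)))[1]]]
        off <- (pwm_length(cc$pwm) + 1L) %/% 2L
        pos <- cr$start + off
        intact <- strsplit(pwm_consensus(cc$pwm), "")[[1]][off]
        var <- worst_base(cc$pwm, off, intact)
        dline <- sample(c("A", "B"), 1)
        snp_rows[[length(snp_rows) + 1L]] <- data.frame(
          contig = "chr_sim", pos = pos, base_ref = intact,
          base_a = if (dline == "A") var else intact,
          base_b = if (dline == "B") var else intact,
          is_disc = TRUE, in_motif = FALSE, context = TRUE,
          motif_id = cr$motif_id, motif_position = off, peak = cr$peak,
          disrupted_line = dline)
      }
    }
    # background discSNPs between peaks: sample candidates from the
    # intergenic gaps (200-bp margins around peaks) and thin them greedily
    # against the spacing constraint — O(n log n), not rejection sampling
    n_bg <- n_snps - n_in_motif
    if (n_bg > 0L) {
      taken <- if (length(snp_rows))
        vapply(snp_rows, function(r) r$pos, numeric(1)) else numeric(0)
      gaps_lo <- c(0, peaks$end + 200)
      gaps_hi <- c(peaks$start - 200, length) - 1
      ok <- which(gaps_hi - gaps_lo > 2)
      widths <- gaps_hi[ok] - gaps_lo[ok]
      n_cand <- 20L * n_bg + 200L
      g <- sample(seq_along(ok), n_cand, replace = TRUE,
                  prob = widths / sum(widths))
      cand <- unique(as.integer(floor(gaps_lo[ok][g] + 1 +
                             stats::runif(n_cand) * (widths[g] - 1))))
      cand <- sort(setdiff(cand, taken))
      blocked <- sort(taken)
      pos_bg <- integer(0)
      last <- -Inf
      for (p in cand) {
        if (length(pos_bg) >= n_bg) break
        if (p - last < min_snp_spacing) next
        if (length(blocked) &&
            min(abs(blocked - p)) < min_snp_spacing) next
        pos_bg <- c(pos_bg, p)
        last <- p
      }
      if (length(pos_bg) < n_bg)
        stopf("infeasible SNP density: placed %d of %d background SNPs",
              length(pos_bg), n_bg)
      intact <- if (sequences) refv[pos_bg] else
        DNA_BASES[sample.int(4, n_bg, replace = TRUE)]
      var <- vapply(intact, function(b)
        sample(setdiff(DNA_BASES, b), 1), character(1))
      dline <- sample(c("A", "B"), n_bg, replace = TRUE)
      snp_rows[[length(snp_rows) + 1L]] <- data.frame(
        contig = "chr_sim", pos = pos_bg, base_ref = intact,
        base_a = ifelse(dline == "A", var, intact),
        base_b = ifelse(dline == "B", var, intact),
        is_disc = TRUE, in_motif = FALSE, context = FALSE,
        motif_id = NA_character_, motif_position = NA_integer_,
        peak = NA_integer_, disrupted_line = dline)
    }
    snps <- if (length(snp_rows)) do.call(rbind, snp_rows) else
      data.frame(contig = character(0), pos = integer(0),
                 base_ref = character(0), base_a = character(0),
                 base_b = character(0), is_disc = logical(0),
                 in_motif = logical(0), context = logical(0),
                 motif_id = character(0), motif_position = integer(0),
                 peak = integer(0), disrupted_line = character(0))
    if (nrow(snps)) {
      snps <- snps[order(snps$pos), ]
      rownames(snps) <- NULL
    }
    if (sequences) {
      av <- refv
      bv <- refv
      av[snps$pos] <- snps$base_a
      bv[snps$pos] <- snps$base_b
      ref_str <- c(chr_sim = paste(refv, collapse = ""))
      a_str <- c(chr_sim = paste(av, collapse = ""))
      b_str <- c(chr_sim = paste(bv, collapse = ""))
    } else {
      ref_str <- a_str <- b_str <- c(chr_sim = NA_character_)
    }
    structure(list(
      reference = ref_str,
      line_a = a_str,
      line_b = b_str,
      snps = snps, peaks = peaks, motifs = motifs,
      effect_truth = data.frame(motif_id = anchor$motif_id,
                                position = seq_len(L),
                                effect = motif_effects),
      context_truth = if (is.null(contexts)) NULL else
        do.call(rbind, lapply(contexts, function(cc)
          data.frame(motif_id = cc$pwm$motif_id, effect = cc$effect,
                     dist_lo = cc$dist_lo, dist_hi = cc$dist_hi)))),
      class = "sim_truth")
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "synthetic genome pair: %d bp, %d peaks, %d discSNPs (%d in anchor motifs, %d contextual)\n",
    nchar(x$reference[[1]]), nrow(x$peaks), nrow(x$snps),
    sum(x$snps$in_motif), sum(x$snps$context)))
  invisible(x)
}

#' Simulate sequencing pileups at planted SNP sites
#'
#' For each line and planted SNP: total depth is Poisson(`mean_depth`);
#' variant-supporting reads are Binomial(depth, 1 - error_rate) when the
#' line carries the variant and Binomial(depth, error_rate) when it is
#' homozygous reference at the site.
#'
#' @param truth a `sim_truth` object.
#' @param mean_depth mean sequencing depth (>= 1).
#' @param error_rate per-base sequencing error probability (in `[0, 0.1]`).
#' @param seed integer seed.
#' @return list with `line_a` and `line_b` variant tables.
#' @export
simulate_pileups <- function(truth, mean_depth = 30, error_rate = 0.003,
                             seed = NULL) {
  if (mean_depth < 1) stopf("mean_depth must be >= 1")
  if (error_rate < 0 || error_rate > 0.1)
    stopf("error_rate must be in [0, 0.1]")
  snps <- truth$snps
  with_seed_opt(seed, {
    one_line <- function(base_line) {
      carries <- base_line != snps$base_ref
      var_base <- ifelse(snps$base_a != snps$base_ref,
                         snps$base_a, snps$base_b)
      depth <- stats::rpois(nrow(snps), mean_depth)
      p_alt <- ifelse(carries, 1 - error_rate, error_rate)
      alt <- stats::rbinom(nrow(snps), depth, p_alt)
      data.frame(contig = snps$contig, pos = snps$pos, ref = snps$base_ref,
                 alt = var_base, depth = depth, alt_reads = alt)
    }
    list(line_a = one_line(snps$base_a), line_b = one_line(snps$base_b))
  })
}

# multiplicative disruption effect on one line's mean intensity at one peak
line_effect <- function(truth, peak_idx, line) {
  eff <- 1
  s <- truth$snps
  hit <- which(!is.na(s$peak) & s$peak == peak_idx &
                 s$disrupted_line == line)
  for (i in hit) {
    if (s$in_motif[i]) {
      e <- truth$effect_truth$effect[
        truth$effect_truth$motif_id == s$motif_id[i] &
          truth$effect_truth$position == s$motif_position[i]]
      eff <- eff * e
    } else if (s$context[i]) {
      ct <- truth$context_truth[truth$context_truth$motif_id ==
                                  s$motif_id[i], , drop = FALSE]
      m <- truth$motifs[truth$motifs$type == "context" &
                          truth$motifs$peak == peak_idx &
                          truth$motifs$motif_id == s$motif_id[i], ,
                        drop = FALSE]
      if (nrow(m) && nrow(ct) &&
          m$gap[1] >= ct$dist_lo[1] && m$gap[1] <= ct$dist_hi[1])
        eff <- eff * ct$effect[1]
    }
  }
  eff
}

#' Simulate allele-resolved ChIP and input counts at peaks
#'
#' Mean IP count at a peak for a line is
#' `lib_scale * (input_base + base_intensity * effect(line))`, where
#' `effect(line)` multiplies the planted per-position effects of every
#' anchor-motif disruption carried by that line at the peak and the
#' contextual effects whose planted distance falls inside their active
#' range. Input means are effect-free (`lib_scale * input_base`). Counts
#' are negative binomial with the stated dispersion (`dispersion = 0`
#' gives the Poisson limit).
#'
#' @param truth a `sim_truth` object.
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); default 0.2.
#' @param lib_scale named numeric scales for ip_a, ip_b, input_a, input_b.
#' @param input_base mean input (background) count at reference scale.
#' @param nominal_lib nominal library size corresponding to scale 1
#'   (reported for normalization).
#' @param seed integer seed.
#' @return list with `counts` (data.frame ip_a, ip_b, input_a, input_b per
#'   peak) and `lib_sizes` (named, for [normalize_chip()]).
#' @export
simulate_chip_counts <- function(truth, dispersion = 0.2,
                                 lib_scale = c(ip_a = 1, ip_b = 1,
                                               input_a = 1, input_b = 1),
                                 input_base = 20, nominal_lib = 1e6,
                                 seed = NULL) {
  n <- nrow(truth$peaks)
  eff_a <- vapply(seq_len(n), line_effect, numeric(1), truth = truth,
                  line = "A")
  eff_b <- vapply(seq_len(n), line_effect, numeric(1), truth = truth,
                  line = "B")
  base <- truth$peaks$base_intensity
  mu <- cbind(ip_a = lib_scale[["ip_a"]] * (input_base + base * eff_a),
              ip_b = lib_scale[["ip_b"]] * (input_base + base * eff_b),
              input_a = lib_scale[["input_a"]] * input_base,
              input_b = lib_scale[["input_b"]] * input_base)
  with_seed_opt(seed, {
    draw <- function(m) {
      if (dispersion <= 0) stats::rpois(length(m), m) else
        stats::rnbinom(length(m), size = 1 / dispersion, mu = m)
    }
    counts <- as.data.frame(apply(mu, 2, draw))
    rownames(counts) <- paste0("peak_", seq_len(n))
    list(counts = counts,
         lib_sizes = nominal_lib * lib_scale,
         effect_a = eff_a, effect_b = eff_b)
  })
}

#' Simulate a CRISPR deletion-allele amplicon library
#'
#' Draws `n_alleles` distinct deletion alleles (lengths from
#' `del_len_sampler`, positions uniform within the amplicon), assigns each
#' an abundance (Gamma-distributed; the wild-type allele receives
#' `wt_frac` of the pool) and a true binding retention from `retention`
#' (default: linear in the deleted fraction of the motif, down to 0.05 for
#' full motif deletion, 1 away from it). Input libraries sample alleles by
#' abundance; IP libraries by abundance times retention. Reads are the
#' amplicon with the deletion applied.
#'
#' @param reference wild-type amplicon sequence.
#' @param motif_start,motif_end motif interval (0-based half-open).
#' @param n_alleles number of distinct deletion alleles.
#' @param del_len_sampler function(n) -> deletion lengths in bp.
#' @param retention function(start, end) -> retention in `[0, 1]`, or NULL
#'   for the default overlap-based model.
#' @param input_depth,ip_depth reads per library.
#' @param n_replicates paired input/IP replicates.
#' @param wt_frac wild-type fraction of the allele pool.
#' @param seed integer seed.
#' @return list with `reads` (named list input_1, ip_1, ...), `truth`
#'   (allele, start, end, abundance, retention) and `reference`.
#' @export
simulate_deletion_library <- function(reference, motif_start, motif_end,
                                      n_alleles = 50,
                                      del_len_sampler = function(n)
                                        pmax(1, stats::rpois(n, 26)),
                                      retention = NULL,
                                      input_depth = 20000, ip_depth = 20000,
                                      n_replicates = 2, wt_frac = 0.3,
                                      seed = NULL) {
  len <- nchar(reference)
  if (motif_start < 0 || motif_end > len || motif_start >= motif_end)
    stopf("motif interval outside amplicon")
  if (is.null(retention))
    retention <- function(start, end) {
      ov <- pmax(0, pmin(end, motif_end) - pmax(start, motif_start))
      1 - 0.95 * ov / (motif_end - motif_start)
    }
  with_seed_opt(seed, {
    seen <- character(0)
    rows <- list()
    while (length(rows) < n_alleles) {
      dlen <- del_len_sampler(1)
      if (dlen >= len) next
      s <- sample.int(len - dlen + 1L, 1) - 1L               # 0-based
      key <- paste0(s, ":", s + dlen)
      if (key %in% seen) next
      seen <- c(seen, key)
      rows[[length(rows) + 1L]] <- data.frame(
        allele = key, start = s, end = s + dlen,
        retention = retention(s, s + dlen))
    }
    truth <- rbind(data.frame(allele = "WT", start = NA_integer_,
                              end = NA_integer_, retention = 1),
                   do.call(rbind, rows))
    ab <- stats::rgamma(n_alleles, shape = 2)
    truth$abundance <- c(wt_frac, (1 - wt_frac) * ab / sum(ab))
    allele_seq <- c(reference, vapply(seq_len(n_alleles), function(i)
      paste0(substr(reference, 1, truth$start[i + 1]),
             substring(reference, truth$end[i + 1] + 1)), character(1)))
    reads <- list()
    for (r in seq_len(n_replicates)) {
      n_in <- stats::rmultinom(1, input_depth, truth$abundance)[, 1]
      w_ip <- truth$abundance * truth$retention
      n_ip <- stats::rmultinom(1, ip_depth, w_ip / sum(w_ip))[, 1]
      reads[[paste0("input_", r)]] <- rep(allele_seq, n_in)
      reads[[paste0("ip_", r)]] <- rep(allele_seq, n_ip)
    }
    list(reads = reads, truth = truth, reference = reference)
  })
}

#' Simulate labeled motif sites for the binding predictor
#'
#' Generates `n_sites` independent sequence windows, each with one anchor
#' motif instance at the center sampled from the anchor PWM (so the anchor
#' score varies) and, with probability `context_prob`, one contextual-motif
#' consensus planted at a uniform edge-to-edge gap within `radius` bp.
#' Site labels are Bernoulli with
#' `logit P(bound) = intercept + anchor_coef * z(anchor score) +
#' context_effect * planted`, so `context_effect = 0` removes the
#' contextual signal while leaving the sequence composition untouched.
#'
#' @param n_sites number of sites.
#' @param anchor_pwm anchor `pwm`.
#' @param context_pwm contextual `pwm` (or NULL for none).
#' @param context_effect log-odds effect of a planted contextual motif.
#' @param anchor_coef log-odds effect per SD of anchor score.
#' @param intercept baseline log-odds of being bound.
#' @param context_prob probability a site carries the contextual motif.
#' @param radius maximum planted gap in bp.
#' @param seed integer seed.
#' @return list with `examples` (contig, start, end, anchor_score, label,
#'   context_planted, gap) and `genome` (named vector of site sequences).
#' @export
simulate_binding_sites <- function(n_sites, anchor_pwm, context_pwm = NULL,
                                   context_effect = 2, anchor_coef = 1,
                                   intercept = 0, context_prob = 0.5,
                                   radius = 100, seed = NULL) {
  La <- pwm_length(anchor_pwm)
  Lc <- if (is.null(context_pwm)) 0L else pwm_length(context_pwm)
  win <- 2L * (radius + Lc + 5L) + La
  a_start <- radius + Lc + 5L                                  # 0-based
  with_seed_opt(seed, {
    seqs <- character(n_sites)
    anchor_score <- numeric(n_sites)
    planted <- stats::runif(n_sites) < context_prob &
      !is.null(context_pwm)
    gap <- rep(NA_integer_, n_sites)
    lo <- log_odds_matrix(anchor_pwm)
    for (i in seq_len(n_sites)) {
      s <- random_dna(win)
      inst <- sample_pwm(anchor_pwm)
      s <- splice(s, a_start + 1L, inst)
      anchor_score[i] <- sum(lo[cbind(match(
        strsplit(inst, "")[[1]], DNA_BASES), seq_len(La))])
      if (planted[i]) {
        g <- sample.int(radius - Lc, 1)
        side <- sample(c(-1, 1), 1)
        cstart <- if (side > 0) a_start + La + g else a_start - g - Lc
        s <- splice(s, cstart + 1L, pwm_consensus(context_pwm))
        gap[i] <- g
      }
      seqs[i] <- s
    }
    z <- as.numeric(scale(anchor_score))
    p_bound <- stats::plogis(intercept + anchor_coef * z +
                               context_effect * planted)
    label <- ifelse(stats::rbinom(n_sites, 1, p_bound) == 1,
                    "bound", "unbound")
    ids <- sprintf("site_%05d", seq_len(n_sites))
    names(seqs) <- ids
    list(examples = data.frame(contig = ids, start = a_start,
                               end = a_start + La,
                               anchor_score = anchor_score, label = label,
                               context_planted = planted, gap = gap),
         genome = seqs)
  })
}
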