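# Simplified zygosity calling from input ChIP-seq pileups, block smoothing
# of ambiguous calls, pairing of two cell lines into discriminatory SNPs
# (discSNPs), and precision/recall evaluation against a truth set.

#' Default zygosity thresholds
#'
#' Sites at total read depth <= `min_depth` are ambiguous. Above that, the
#' variant read fraction is banded: >= `hom_var_min` homozygous variant,
#' <= `hom_ref_max` homozygous reference, within `[het_lo, het_hi]`
#' heterozygous, anything else ambiguous. The bands deliberately favor
#' precision over recall.
#'
#' @param min_depth depth at or below which a site is ambiguous.
#' @param hom_var_min minimum variant fraction for a homozygous variant call.
#' @param hom_ref_max maximum variant fraction for a homozygous reference call.
#' @param het_lo,het_hi variant-fraction band for heterozygous calls.
#' @return list of thresholds.
#' @export
zygosity_thresholds <- function(min_depth = 5, hom_var_min = 0.9,
                                hom_ref_max = 0.1, het_lo = 0.35,
                                het_hi = 0.65) {
  list(min_depth = min_depth, hom_var_min = hom_var_min,
       hom_ref_max = hom_ref_max, het_lo = het_lo, het_hi = het_hi)
}

#' Call per-site zygosity from pileup counts
#'
#' @param depth integer vector of total read depths (>= 0).
#' @param alt_reads integer vector of variant-supporting read counts.
#' @param thresholds see [zygosity_thresholds()].
#' @return character vector in \{hom_ref, hom_var, het, ambiguous\}.
#' @export
call_zygosity <- function(depth, alt_reads,
                          thresholds = zygosity_thresholds()) {
  if (any(depth < 0)) stopf("negative depth")
  if (any(alt_reads > depth)) stopf("alt_reads > depth")
  if (any(alt_reads < 0)) stopf("negative alt_reads")
  frac <- ifelse(depth > 0, alt_reads / depth, NA_real_)
  z <- rep("ambiguous", length(depth))
  ok <- depth > thresholds$min_depth
  z[ok & frac >= thresholds$hom_var_min] <- "hom_var"
  z[ok & frac <= thresholds$hom_ref_max] <- "hom_ref"
  z[ok & frac >= thresholds$het_lo & frac <= thresholds$het_hi] <- "het"
  z
}

#' Call zygosity for every row of a variant table
#'
#' @param df variant table (contig, pos, ref, alt, depth, alt_reads).
#' @param thresholds see [zygosity_thresholds()].
#' @return the table with a `zygosity` column.
#' @export
call_variant_table <- function(df, thresholds = zygosity_thresholds()) {
  validate_variant_table(df)
  df$zygosity <- call_zygosity(df$depth, df$alt_reads, thresholds)
  df
}

#' Rescue ambiguous calls inside homozygous-variant blocks
#'
#' The genome is segmented into runs of consecutive calls (same contig, gaps
#' of at most `max_gap` bp). Any run holding at least `min_calls` calls of
#' which at least `min_frac` are homozygous variant has its ambiguous members
#' reassigned to homozygous variant; calls that already carry a non-ambiguous
#' zygosity are never changed. The operation is idempotent.
#'
#' @param calls variant table with `zygosity`, sorted by (contig, pos).
#' @param min_calls minimum calls per block (default 10).
#' @param min_frac minimum fraction of homozygous-variant calls (default 0.9).
#' @param max_gap maximum bp gap between consecutive calls in one block.
#' @return the table with block-rescued zygosities.
#' @export
smooth_zygosity_blocks <- function(calls, min_calls = 10, min_frac = 0.9,
                                   max_gap = 50000) {
  if (nrow(calls) == 0L) return(calls)
  o <- order(calls$contig, calls$pos)
  if (!identical(o, seq_len(nrow(calls))))
    stopf("calls must be sorted by (contig, pos)")
  new_block <- c(TRUE, calls$contig[-1] != calls$contig[-nrow(calls)] |
                   diff(calls$pos) > max_gap)
  block <- cumsum(new_block)
  for (b in unique(block)) {
    i <- which(block == b)
    if (length(i) < min_calls) next
    if (mean(calls$zygosity[i] == "hom_var") >= min_frac)
      calls$zygosity[i][calls$zygosity[i] == "ambiguous"] <- "hom_var"
  }
  calls
}

#' Find discriminatory SNPs between two cell lines
#'
#' A discSNP is a site where one line is called homozygous variant and the
#' other homozygous reference. Sites present in only one line's table are
#' treated as homozygous reference in the other line only when that line's
#' pileup covers them with at least `min_absent_depth` reads (supplied via
#' `depth_a`/`depth_b` lookup tables); otherwise they are skipped. The
#' `isolated` flag marks discSNPs with no other discSNP within `isolation_bp`.
#'
#' @param calls_a,calls_b zygosity-annotated variant tables for lines A and B.
#' @param depth_a,depth_b optional data.frames (contig, pos, depth) giving
#'   pileup coverage at sites absent from the respective call table.
#' @param min_absent_depth coverage needed to assume hom_ref at absent sites.
#' @param isolation_bp isolation radius in bp (default 1000).
#' @param peaks optional peak data.frame (contig, start, end); adds an
#'   `in_peak` index column (NA when outside all peaks).
#' @return data.frame with contig, pos, ref, base_a, base_b, isolated and
#'   optionally in_peak.
#' @export
find_disc_snps <- function(calls_a, calls_b, depth_a = NULL, depth_b = NULL,
                           min_absent_depth = 6, isolation_bp = 1000,
                           peaks = NULL) {
  key <- function(df) paste(df$contig, df$pos)
  lookup_depth <- function(tab, contig, pos) {
    if (is.null(tab)) return(0)
    i <- match(paste(contig, pos), paste(tab$contig, tab$pos))
    ifelse(is.na(i), 0, tab$depth[i])
  }
  all_sites <- unique(rbind(calls_a[c("contig", "pos", "ref")],
                            calls_b[c("contig", "pos", "ref")]))
  ia <- match(key(all_sites), key(calls_a))
  ib <- match(key(all_sites), key(calls_b))
  za <- ifelse(is.na(ia), NA_character_, calls_a$zygosity[ia])
  zb <- ifelse(is.na(ib), NA_character_, calls_b$zygosity[ib])
  # absent sites: hom_ref when sufficiently covered, else unusable
  absent_a <- is.na(za)
  za[absent_a] <- ifelse(
    lookup_depth(depth_a, all_sites$contig[absent_a],
                 all_sites$pos[absent_a]) >= min_absent_depth,
    "hom_ref", NA_character_)
  absent_b <- is.na(zb)
  zb[absent_b] <- ifelse(
    lookup_depth(depth_b, all_sites$contig[absent_b],
                 all_sites$pos[absent_b]) >= min_absent_depth,
    "hom_ref", NA_character_)
  alt_a <- ifelse(is.na(ia), NA_character_, calls_a$alt[ia])
  alt_b <- ifelse(is.na(ib), NA_character_, calls_b$alt[ib])
  disc <- (!is.na(za) & !is.na(zb)) &
    ((za == "hom_var" & zb == "hom_ref") |
     (za == "hom_ref" & zb == "hom_var"))
  out <- all_sites[disc, , drop = FALSE]
  if (nrow(out) == 0L) {
    out$base_a <- character(0); out$base_b <- character(0)
    out$isolated <- logical(0)
    return(out)
  }
  za <- za[disc]; alt_a <- alt_a[disc]; alt_b <- alt_b[disc]
  out$base_a <- ifelse(za == "hom_var", alt_a, out$ref)
  out$base_b <- ifelse(za == "hom_var", out$ref, alt_b)
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  d_prev <- c(Inf, ifelse(out$contig[-1] == out$contig[-nrow(out)],
                          diff(out$pos), Inf))
  d_next <- c(d_prev[-1], Inf)
  out$isolated <- d_prev > isolation_bp & d_next > isolation_bp
  if (!is.null(peaks)) {
    out$in_peak <- vapply(seq_len(nrow(out)), function(i) {
      hit <- which(peaks$contig == out$contig[i] &
                     peaks$start < out$pos[i] & peaks$end >= out$pos[i])
      if (length(hit)) hit[1] else NA_integer_
    }, integer(1))
  }
  out
}

#' Precision and recall of homozygous-variant calls against a truth set
#'
#' Matching is on (contig, pos, alt). Precision is NA when nothing is called.
#'
#' @param calls zygosity-annotated variant table.
#' @param truth data.frame with contig, pos, alt of true homozygous variants.
#' @return list with precision, recall, tp, fp, fn.
#' @export
evaluate_calls <- function(calls, truth) {
  if (nrow(truth) == 0L) stopf("empty truth set")
  called <- calls[calls$zygosity == "hom_var", , drop = FALSE]
  key <- function(df) paste(df$contig, df$pos, df$alt)
  tp <- sum(key(called) %in% key(truth))
  fp <- nrow(called) - tp
  fn <- nrow(truth) - tp
  list(precision = if (nrow(called) == 0L) NA_real_ else tp / (tp + fp),
       recall = tp / (tp + fn), tp = tp, fp = fp, fn = fn)
}
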