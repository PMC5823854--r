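# CRISPR amplicon deletion scanner: global alignment of merged amplicon
# reads to the wild-type sequence, single-deletion allele classification,
# per-allele tallies, wild-type-normalized IP/Input enrichment, and
# deletion-geometry analyses (motif overlap classes, 2-bp sliding windows).

#' Global alignment of a read against the wild-type amplicon
#'
#' Needleman-Wunsch global alignment with affine gap penalties (a gap of
#' length L costs `gap_open + L * gap_extend`) and +5/-4 match/mismatch
#' scoring (EMBOSS DNA defaults). Percent identity is matches divided by
#' alignment length (gap columns included in the denominator). Gap events
#' are reported in 0-based half-open reference coordinates: `deletions` are
#' reference segments missing from the read, `insertions` read segments
#' absent from the reference.
#'
#' @param read,reference DNA strings over A/C/G/T.
#' @param gap_open,gap_extend affine gap penalties (defaults 10 and 0.5).
#' @param match,mismatch substitution scores (defaults +5/-4).
#' @return object of class `alignment_result`: read_aln, ref_aln, score,
#'   pct_identity, deletions (data.frame start, end, length), insertions.
#' @export
global_align <- function(read, reference, gap_open = 10, gap_extend = 0.5,
                         match = 5, mismatch = -4) {
  if (nchar(read) == 0L || nchar(reference) == 0L)
    stopf("empty sequence")
  if (grepl("[^ACGTacgt]", read) || grepl("[^ACGTacgt]", reference))
    stopf("non-DNA characters in input")
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    toupper(read), toupper(reference), type = "global",
    substitutionMatrix = sub_mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  read_aln <- as.character(Biostrings::alignedPattern(aln))
  ref_aln <- as.character(Biostrings::alignedSubject(aln))
  ra <- strsplit(read_aln, "", fixed = TRUE)[[1]]
  fa <- strsplit(ref_aln, "", fixed = TRUE)[[1]]
  matches <- sum(ra == fa & ra != "-")
  gap_events <- function(is_gap, ref_pos) {
    r <- rle(is_gap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    data.frame(start = ref_pos[starts[keep]] - 1L,
               end = ref_pos[ends[keep]] - 1L + 1L,
               length = r$lengths[keep])
  }
  ref_pos <- cumsum(fa != "-")              # 1-based ref coordinate per column
  dels <- gap_events(ra == "-", ref_pos)
  # insertions sit between reference bases; anchor at the following ref base
  ins_pos <- ref_pos + 1L
  ins <- gap_events(fa == "-", ins_pos)
  ins$end <- ins$start                      # zero-width on the reference
  structure(list(read_aln = read_aln, ref_aln = ref_aln,
                 score = Biostrings::score(aln),
                 pct_identity = 100 * matches / length(ra),
                 deletions = dels, insertions = ins),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("global alignment: score %.1f, identity %.1f%%, %d deletion(s), %d insertion(s)\n",
              x$score, x$pct_identity, nrow(x$deletions), nrow(x$insertions)))
  invisible(x)
}

#' Classify an aligned amplicon read
#'
#' Reads with identity at or below `min_identity` are discarded. A read
#' with no gap events is wild type (substitutions are tolerated by the
#' identity filter); a read with exactly one deletion and no insertions is
#' a single-deletion allele; anything else is discarded.
#'
#' @param aln an `alignment_result`.
#' @param min_identity identity threshold in percent (default 80; reads
#'   must exceed it).
#' @return list with `class` in \{"WT", "single_deletion", "discard"\} and,
#'   for deletions, `start`/`end` (0-based half-open reference interval).
#' @export
classify_allele <- function(aln, min_identity = 80) {
  if (aln$pct_identity <= min_identity) return(list(class = "discard"))
  nd <- nrow(aln$deletions)
  ni <- nrow(aln$insertions)
  if (nd == 0L && ni == 0L) return(list(class = "WT"))
  if (nd == 1L && ni == 0L)
    return(list(class = "single_deletion",
                start = aln$deletions$start[1], end = aln$deletions$end[1]))
  list(class = "discard")
}

#' Tally classified reads into a per-allele count table
#'
#' @param classified data.frame with columns library, class, start, end
#'   (start/end NA for WT and discarded reads).
#' @return data.frame keyed by allele ("WT" or "start:end") with one count
#'   column per library; the WT row is always present.
#' @export
tally_alleles <- function(classified) {
  libs <- unique(classified$library)
  if (length(libs) == 0L) stopf("no reads to tally")
  for (lb in libs)
    if (sum(classified$library == lb) == 0L) stopf("empty library %s", lb)
  keep <- classified$class %in% c("WT", "single_deletion")
  cl <- classified[keep, , drop = FALSE]
  key <- ifelse(cl$class == "WT", "WT", paste0(cl$start, ":", cl$end))
  alleles <- union("WT", sort(unique(key)))
  out <- data.frame(row.names = alleles)
  for (lb in libs)
    out[[lb]] <- as.integer(table(factor(key[cl$library == lb],
                                         levels = alleles)))
  starts <- suppressWarnings(as.integer(sub(":.*", "", alleles)))
  ends <- suppressWarnings(as.integer(sub(".*:", "", alleles)))
  cbind(data.frame(allele = alleles, start = starts, end = ends,
                   row.names = NULL), out)
}

#' Wild-type-normalized IP/Input enrichment per deletion allele
#'
#' Per replicate, enrichment(d) = (IP_d / IP_WT) / (Input_d / Input_WT), so
#' the wild-type allele's ratio is exactly 1 by construction. Alleles whose
#' mean input count falls below `min_input_count` are flagged low-coverage
#' (to be excluded from statistics). Enrichment is scale-invariant in each
#' library's sequencing depth.
#'
#' @param tally allele count table from [tally_alleles()].
#' @param input_cols,ip_cols paired column names (replicate order).
#' @param min_input_count low-coverage flag threshold (default 50).
#' @return data.frame with allele, start, end, per-replicate enrichment
#'   columns, mean `enrichment`, `input_mean` and `low_coverage`.
#' @export
compute_enrichment <- function(tally, input_cols, ip_cols,
                               min_input_count = 50) {
  if (length(input_cols) != length(ip_cols))
    stopf("input/ip replicate columns must pair up")
  wt <- which(tally$allele == "WT")
  if (length(wt) != 1L) stopf("wild-type allele missing from tally")
  out <- tally[c("allele", "start", "end")]
  enr <- matrix(NA_real_, nrow(tally), length(ip_cols))
  for (r in seq_along(ip_cols)) {
    ip <- tally[[ip_cols[r]]]
    input <- tally[[input_cols[r]]]
    if (ip[wt] <= 0 || input[wt] <= 0)
      stopf("wild-type allele has zero reads in replicate %d", r)
    enr[, r] <- (ip / ip[wt]) / (input / input[wt])
    out[[paste0("enrichment_", r)]] <- enr[, r]
  }
  out$enrichment <- rowMeans(enr)
  out$input_mean <- rowMeans(as.matrix(tally[input_cols]))
  out$low_coverage <- out$input_mean < min_input_count
  out
}

#' Overlap class of a deletion against a motif
#'
#' "full" when the motif lies entirely inside the deletion, "none" when
#' they are disjoint, "partial" otherwise. The classes partition all
#' (deletion, motif) pairs. Intervals are 0-based half-open; an NA or
#' empty deletion (wild type) is "none".
#'
#' @param del_start,del_end deletion interval (vectorized).
#' @param motif_start,motif_end motif interval.
#' @return character vector in \{"full", "partial", "none"\}.
#' @export
overlap_class <- function(del_start, del_end, motif_start, motif_end) {
  if (motif_end <= motif_start) stopf("empty motif interval")
  full <- del_start <= motif_start & del_end >= motif_end
  disjoint <- is.na(del_start) | del_end <= motif_start |
    del_start >= motif_end
  ifelse(disjoint, "none", ifelse(full, "full", "partial"))
}

#' Sliding-window impact of short deletions
#'
#' Restricts to 1-2 bp deletions, assigns each to every `width`-bp window
#' it intersects (windows slide by `step` bp across the reference span),
#' and per window reports the mean enrichment, its SEM and a one-sided
#' Wilcoxon test of enrichment below 1 (loss of binding).
#'
#' @param alleles enrichment table from [compute_enrichment()] (low-coverage
#'   alleles should be filtered out beforehand).
#' @param ref_length reference amplicon length in bp.
#' @param width window width (default 2).
#' @param step window step (default 1).
#' @param max_del_len largest deletion length analyzed (default 2).
#' @return data.frame with win_start, win_end, n, mean_enrichment, sem, p;
#'   empty when no qualifying alleles exist.
#' @export
window_deletion_impact <- function(alleles, ref_length, width = 2, step = 1,
                                   max_del_len = 2) {
  del <- alleles[!is.na(alleles$start) &
                   (alleles$end - alleles$start) <= max_del_len &
                   (alleles$end - alleles$start) >= 1, , drop = FALSE]
  starts <- seq(0, ref_length - width, by = step)
  if (nrow(del) == 0L)
    return(data.frame(win_start = integer(0), win_end = integer(0),
                      n = integer(0), mean_enrichment = numeric(0),
                      sem = numeric(0), p = numeric(0)))
  rows <- lapply(starts, function(s) {
    hit <- del$start < s + width & del$end > s
    n <- sum(hit)
    if (n == 0L) return(NULL)
    x <- del$enrichment[hit]
    p <- if (all(x == 1)) 1 else
      suppressWarnings(stats::wilcox.test(x, mu = 1, alternative = "less",
                                          exact = FALSE)$p.value)
    data.frame(win_start = s, win_end = s + width, n = n,
               mean_enrichment = mean(x),
               sem = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_, p = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full deletion-scanner pipeline on read sets
#'
#' Aligns every distinct read sequence once, classifies it, tallies counts
#' per library, and computes wild-type-normalized enrichment.
#'
#' @param reads named list of character vectors of merged read sequences,
#'   one element per library (e.g. input_1, ip_1, ...).
#' @param reference wild-type amplicon sequence.
#' @param input_cols,ip_cols paired library names.
#' @param min_identity identity filter in percent.
#' @param min_input_count low-coverage threshold.
#' @param gap_open,gap_extend alignment gap penalties.
#' @return list with `tally` and `alleles` (enrichment table).
#' @export
deletion_scan <- function(reads, reference, input_cols, ip_cols,
                          min_identity = 80, min_input_count = 50,
                          gap_open = 10, gap_extend = 0.5) {
  uniq <- unique(unlist(reads, use.names = FALSE))
  cls <- lapply(uniq, function(s)
    classify_allele(global_align(s, reference, gap_open, gap_extend),
                    min_identity))
  cls_df <- data.frame(
    read = uniq,
    class = vapply(cls, `[[`, character(1), "class"),
    start = vapply(cls, function(c_)
      if (c_$class == "single_deletion") c_$start else NA_integer_,
      numeric(1)),
    end = vapply(cls, function(c_)
      if (c_$class == "single_deletion") c_$end else NA_integer_, numeric(1)))
  per_lib <- do.call(rbind, lapply(names(reads), function(lb) {
    i <- match(reads[[lb]], cls_df$read)
    data.frame(library = lb, class = cls_df$class[i],
               start = cls_df$start[i], end = cls_df$end[i])
  }))
  tally <- tally_alleles(per_lib)
  alleles <- compute_enrichment(tally, input_cols, ip_cols, min_input_count)
  list(tally = tally, alleles = alleles)
}
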