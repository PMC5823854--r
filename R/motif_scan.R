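# PWM log-odds scanning (FIMO-style, uniform background) and PWM utilities.
# Scores are log2( P(base | position) / 0.25 ) summed over motif positions;
# the reverse strand is scored by scanning the reverse-complement matrix.

log_odds_matrix <- function(p) log2(p$mat / 0.25)

#' Reverse complement of a PWM
#' @param p a `pwm` object.
#' @return `pwm` with columns reversed and bases complemented.
#' @export
revcomp_pwm <- function(p) {
  m <- p$mat[4:1, rev(seq_len(ncol(p$mat))), drop = FALSE]
  rownames(m) <- DNA_BASES
  pwm(m, motif_id = p$motif_id, tf_name = p$tf_name, family = p$family)
}

# integer codes 1..4 for A,C,G,T; NA for N
encode_dna <- function(sequence) {
  match(strsplit(sequence, "", fixed = TRUE)[[1]], DNA_BASES)
}

# log-odds score for every placement start (1-based) on one strand;
# NA where the window touches an N.
scan_scores <- function(lo, codes) {
  L <- ncol(lo)
  n <- length(codes)
  if (n < L) stopf("sequence shorter than PWM")
  ns <- n - L + 1L
  sc <- numeric(ns)
  for (i in seq_len(L)) sc <- sc + lo[, i][codes[i:(ns + i - 1L)]]
  sc
}

#' Scan a sequence with a PWM
#'
#' Scores every placement on both strands with the log2 odds against a
#' uniform background and returns hits at or above `min_score`. Placements
#' covering an N are skipped. Coordinates are 0-based half-open on the
#' forward sequence; a `-` strand hit means the motif matches the reverse
#' complement at that location.
#'
#' @param p a `pwm` object.
#' @param sequence DNA string over A/C/G/T/N.
#' @param min_score minimum reported score in bits.
#' @param both_strands scan the reverse strand as well.
#' @return data.frame with motif_id, start, end, strand, score, sorted by
#'   position.
#' @export
score_pwm <- function(p, sequence, min_score = -Inf, both_strands = TRUE) {
  codes <- encode_dna(clean_dna(sequence))
  L <- pwm_length(p)
  fwd <- scan_scores(log_odds_matrix(p), codes)
  starts <- seq_along(fwd) - 1L
  hits <- data.frame(motif_id = p$motif_id, start = starts,
                     end = starts + L, strand = "+", score = fwd)
  if (both_strands) {
    rev <- scan_scores(log_odds_matrix(revcomp_pwm(p)), codes)
    hits <- rbind(hits,
                  data.frame(motif_id = p$motif_id, start = starts,
                             end = starts + L, strand = "-", score = rev))
  }
  hits <- hits[!is.na(hits$score) & hits$score >= min_score, , drop = FALSE]
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Shuffle PWM columns
#'
#' Uniformly permutes the columns of a PWM, leaving each column's contents
#' (and hence its information content) untouched. Used to build matched
#' null motifs for the contextual-motif selection control.
#'
#' @param p a `pwm` object.
#' @param seed optional integer seed.
#' @return shuffled `pwm` (motif_id suffixed with "_shuf").
#' @export
shuffle_pwm <- function(p, seed = NULL) {
  L <- pwm_length(p)
  perm <- with_seed_opt(seed, sample.int(L))
  m <- p$mat[, perm, drop = FALSE]
  pwm(m, motif_id = paste0(p$motif_id, "_shuf"),
      tf_name = p$tf_name, family = p$family)
}

#' Per-column information content of a PWM
#' @param p a `pwm` object.
#' @return numeric vector, bits per column.
#' @export
pwm_information <- function(p) {
  apply(p$mat, 2, function(col) 2 + sum(ifelse(col > 0, col * log2(col), 0)))
}

#' Sample a sequence from a PWM
#'
#' Draws one base per column from the column's probabilities. Used by the
#' synthetic-data generator to plant motif instances of graded strength.
#'
#' @param p a `pwm` object.
#' @param n number of sequences.
#' @return character vector of length `n`.
#' @export
sample_pwm <- function(p, n = 1) {
  vapply(seq_len(n), function(i) {
    paste(apply(p$mat, 2, function(col) sample(DNA_BASES, 1, prob = col)),
          collapse = "")
  }, character(1))
}

#' Consensus sequence of a PWM
#' @param p a `pwm` object.
#' @return character consensus (argmax base per column).
#' @export
pwm_consensus <- function(p) {
  paste(DNA_BASES[apply(p$mat, 2, which.max)], collapse = "")
}
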