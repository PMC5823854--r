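#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Operates on plain uppercase character strings over \{A,C,G,T,N\}.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

complement_base <- function(b) chartr("ACGTN", "TGCAN", b)

#' Clean a DNA string to the \{A,C,G,T,N\} alphabet
#'
#' Uppercases and maps every non-ACGT character to N.
#' @param x character vector.
#' @return cleaned character vector.
#' @keywords internal
clean_dna <- function(x) {
  x <- toupper(x)
  gsub("[^ACGTN]", "N", x)
}

# Run `code` under a fixed RNG state when seed is non-NULL, leaving the
# caller's RNG untouched; plain evaluation otherwise.
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# One-sample two-sided Wilcoxon signed-rank p value, normal approximation with
# tie correction and continuity correction. Agrees with
# stats::wilcox.test(x, mu = mu, exact = FALSE, correct = TRUE)$p.value and is
# fast enough to sit inside permutation loops.
wilcox_signed_p <- function(x, mu) {
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  ad <- abs(d)
  r <- rank(ad)
  W <- sum(r[d > 0])
  mu_w <- n * (n + 1) / 4
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24
  if (anyDuplicated(ad)) {                 # tie correction only when needed
    ties <- table(r)
    sigma2 <- sigma2 - sum(ties^3 - ties) / 48
  }
  if (sigma2 <= 0) return(1)
  z <- W - mu_w
  corr <- sign(z) * 0.5
  z <- (z - corr) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

# Trapezoidal-rule AUC of an ROC curve, computed through the rank (Mann-
# Whitney) identity with tie handling; labels are logical/0-1.
auc_trapezoid <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stopf("both classes required to compute an AUC")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ROC points (FPR, TPR) sweeping unique score thresholds descending.
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  o <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[o])
  fp <- cumsum(!labels[o])
  keep <- !duplicated(scores[o], fromLast = TRUE)
  data.frame(
    fpr = c(0, fp[keep] / sum(!labels)),
    tpr = c(0, tp[keep] / sum(labels))
  )
}
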