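# Fixture builders and independent oracles used across the test files.

# PWM with probability `p_major` on the consensus base per column.
consensus_pwm <- function(consensus, motif_id = "M1", p_major = 0.91,
                          family = motif_id) {
  bases <- strsplit(consensus, "")[[1]]
  mat <- vapply(bases, function(b) {
    col <- rep((1 - p_major) / 3, 4)
    col[match(b, c("A", "C", "G", "T"))] <- p_major
    col
  }, numeric(4))
  pwm(mat, motif_id = motif_id, family = family)
}

gata_pwm <- function(id = "Gata1", p_major = 0.95)
  consensus_pwm("AGATAA", motif_id = id, p_major = p_major, family = "GATA")

uniform_pwm <- function(L = 4, motif_id = "UNI")
  pwm(matrix(0.25, 4, L), motif_id = motif_id)

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

write_meme_file <- function(pwms_mats, path = tempfile(fileext = ".meme")) {
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "",
             "strands: + -", "")
  for (nm in names(pwms_mats)) {
    m <- pwms_mats[[nm]]
    lines <- c(lines, paste("MOTIF", nm, nm),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       ncol(m)),
               apply(m, 2, function(col) paste(sprintf("%.6f", col),
                                               collapse = " ")),
               "")
  }
  writeLines(lines, path)
  path
}

# Exhaustive disruption-scoring oracle: every placement x strand containing
# the SNP, direct per-base log-odds sums, no shared code with the package
# scanner.
oracle_disruption <- function(p, win_a, win_b, snp_off) {
  L <- ncol(p$mat)
  n <- nchar(win_a)
  score_at <- function(mat, s, win) {
    bases <- strsplit(substr(win, s, s + L - 1), "")[[1]]
    idx <- match(bases, c("A", "C", "G", "T"))
    if (anyNA(idx)) return(NA_real_)
    sum(log2(mat[cbind(idx, seq_len(L))] / 0.25))
  }
  rc_mat <- p$mat[4:1, L:1, drop = FALSE]
  rownames(rc_mat) <- c("A", "C", "G", "T")
  best <- NULL
  for (strand in c("+", "-")) {
    m <- if (strand == "+") p$mat else rc_mat
    for (s in seq_len(max(0, n - L + 1))) {
      if (!(s <= snp_off && snp_off <= s + L - 1)) next
      sa <- score_at(m, s, win_a)
      sb <- score_at(m, s, win_b)
      if (is.na(sa) || is.na(sb)) next
      cand <- list(score_max = max(sa, sb),
                   diff = max(sa, sb) - min(sa, sb))
      eps <- 1e-9
      if (is.null(best) || cand$score_max > best$score_max + eps ||
          (cand$score_max > best$score_max - eps &&
             cand$diff > best$diff + eps))
        best <- cand
    }
  }
  best
}

# Independent affine-gap global alignment DP (Gotoh). A gap of length L
# costs open + L * ext, matching the package's alignment convention.
oracle_align_score <- function(read, ref, open = 10, ext = 0.5,
                               match = 5, mismatch = -4) {
  a <- strsplit(read, "")[[1]]
  b <- strsplit(ref, "")[[1]]
  n <- length(a)
  m <- length(b)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in read (ref base unmatched)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in ref (read base unmatched)
  M[1, 1] <- 0
  for (j in 2:(m + 1)) X[1, j] <- -(open + ext * (j - 1))
  for (i in 2:(n + 1)) Y[i, 1] <- -(open + ext * (i - 1))
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- if (a[i - 1] == b[j - 1]) match else mismatch
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i, j - 1] - open - ext, X[i, j - 1] - ext,
                   Y[i, j - 1] - open - ext)
    Y[i, j] <- max(M[i - 1, j] - open - ext, Y[i - 1, j] - ext,
                   X[i - 1, j] - open - ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Score of a finished alignment (two gapped strings) under the same
# convention; used to confirm a reported alignment attains the DP optimum.
score_of_alignment <- function(read_aln, ref_aln, open = 10, ext = 0.5,
                               match = 5, mismatch = -4) {
  a <- strsplit(read_aln, "")[[1]]
  b <- strsplit(ref_aln, "")[[1]]
  sc <- 0
  state <- "none"
  for (k in seq_along(a)) {
    if (a[k] == "-") {
      sc <- sc - ext - (if (state != "ga") open else 0)
      state <- "ga"
    } else if (b[k] == "-") {
      sc <- sc - ext - (if (state != "gb") open else 0)
      state <- "gb"
    } else {
      sc <- sc + (if (a[k] == b[k]) match else mismatch)
      state <- "none"
    }
  }
  sc
}
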