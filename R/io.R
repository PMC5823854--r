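# Readers and writers for the plain-text formats the pipeline exchanges:
# FASTA genomes, MEME minimal motifs, BED intervals, TSV variant tables and
# TSV count tables. Coordinate conventions: BED intervals are 0-based
# half-open; variant tables are 1-based (VCF-like) and are converted to
# 0-based only at sequence-indexing boundaries.

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and any character outside A/C/G/T/N is replaced
#' by N. Order of records is preserved.
#'
#' @param path path to a FASTA file.
#' @return named character vector, one element per contig.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stopf("empty FASTA file: %s", path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) stopf("duplicate contig names in %s", path)
  out <- clean_dna(as.character(seqs))
  names(out) <- nm
  if (any(nchar(out) == 0L)) stopf("empty sequence in %s", path)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of DNA strings.
#' @param path output path.
#' @param width line width for wrapping.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Construct a position weight matrix object
#'
#' @param mat 4 x L numeric matrix of base probabilities, rows A,C,G,T.
#' @param motif_id motif identifier.
#' @param tf_name transcription factor name.
#' @param family motif family label (e.g. "GATA"); defaults to `tf_name`.
#' @return an object of class `pwm`.
#' @export
pwm <- function(mat, motif_id, tf_name = motif_id, family = tf_name) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) stopf("PWM matrix must have 4 rows (A,C,G,T)")
  if (ncol(mat) < 1L) stopf("PWM must have at least one column")
  rownames(mat) <- DNA_BASES
  sums <- colSums(mat)
  if (any(abs(sums - 1) > 1e-9))
    stopf("PWM '%s': columns must sum to 1 (max deviation %.3g)",
          motif_id, max(abs(sums - 1)))
  structure(list(motif_id = motif_id, tf_name = tf_name, family = family,
                 mat = mat),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s (%s, family %s), length %d\n",
              x$motif_id, x$tf_name, x$family, ncol(x$mat)))
  print(round(x$mat, 3))
  invisible(x)
}

#' Motif length of a PWM
#' @param x a `pwm` object.
#' @return integer motif width.
#' @export
pwm_length <- function(x) ncol(x$mat)

# Pseudocount regularization: (p + pc) / (1 + 4 pc), per column.
regularize_pwm_matrix <- function(mat, pseudocount = 0.001) {
  sweep(mat + pseudocount, 2, colSums(mat) + 4 * pseudocount, "/")
}

#' Read motifs in MEME minimal format
#'
#' Parses the MEME minimal motif format (version header, `MOTIF` records,
#' `letter-probability matrix` blocks). Probabilities are regularized with a
#' pseudocount of 0.001 and renormalized per position, so that log-odds
#' scores stay finite even for consensus-only matrices.
#'
#' @param path path to a MEME minimal-format motif file.
#' @param family_map optional data.frame with columns `motif_id`, `family`.
#' @param pseudocount pseudocount added to each probability before
#'   renormalization.
#' @return list of `pwm` objects.
#' @export
read_meme_motifs <- function(path, family_map = NULL, pseudocount = 0.001) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  midx <- grep("^MOTIF\\b", lines)
  if (length(midx) == 0L) stopf("no MOTIF record found in %s", path)
  alpha <- grep("^ALPHABET", lines, value = TRUE)
  if (length(alpha) > 0 && !grepl("ACGT", gsub("[^A-Z]", "", alpha[1])))
    stopf("unknown alphabet in %s: %s", path, alpha[1])
  out <- vector("list", length(midx))
  bounds <- c(midx, length(lines) + 1L)
  for (k in seq_along(midx)) {
    block <- lines[midx[k]:(bounds[k + 1L] - 1L)]
    toks <- strsplit(block[1], "\\s+")[[1]]
    motif_id <- toks[2]
    tf_name <- if (length(toks) >= 3) toks[3] else toks[2]
    hdr <- grep("^letter-probability matrix", block)
    if (length(hdr) == 0L)
      stopf("motif %s: missing letter-probability matrix", motif_id)
    w <- suppressWarnings(as.integer(sub(".*w=\\s*(\\d+).*", "\\1", block[hdr[1]])))
    rows <- block[-seq_len(hdr[1])]
    rows <- rows[grepl("^[0-9.eE+-]", rows)]
    if (!is.na(w)) rows <- utils::head(rows, w)
    mat <- t(vapply(strsplit(rows, "\\s+"),
                    function(v) as.numeric(v[1:4]), numeric(4)))
    if (!is.na(w) && nrow(mat) != w)
      stopf("motif %s: expected %d rows, found %d", motif_id, w, nrow(mat))
    bad <- abs(rowSums(mat) - 1) > 0.01
    if (any(bad))
      stopf("motif %s: probability row %d sums to %.4f",
            motif_id, which(bad)[1], rowSums(mat)[which(bad)[1]])
    fam <- tf_name
    if (!is.null(family_map)) {
      hit <- match(motif_id, family_map$motif_id)
      if (!is.na(hit)) fam <- family_map$family[hit]
    }
    out[[k]] <- pwm(regularize_pwm_matrix(t(mat), pseudocount),
                    motif_id = motif_id, tf_name = tf_name, family = fam)
  }
  out
}

#' Read a BED file of intervals
#'
#' BED3/BED6; coordinates are kept 0-based half-open.
#'
#' @param path BED file path.
#' @return data.frame with columns contig, start, end, and (when present)
#'   name, score, strand. Missing strand is ".".
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, fill = TRUE)
  if (ncol(df) < 3L) stopf("BED file %s has fewer than 3 columns", path)
  names(df) <- c("contig", "start", "end", "name", "score",
                 "strand")[seq_len(min(ncol(df), 6L))]
  df <- df[seq_len(min(ncol(df), 6L))]
  if (any(df$start >= df$end))
    stopf("BED interval with start >= end at line %d",
          which(df$start >= df$end)[1])
  if (is.null(df$strand)) df$strand <- "."
  df$strand[is.na(df$strand) | df$strand == ""] <- "."
  if (is.null(df$name)) df$name <- "."
  if (is.null(df$score)) df$score <- 0
  df
}

#' Write intervals to BED
#'
#' @param intervals data.frame with contig, start, end and optional name,
#'   score, strand columns.
#' @param path output path.
#' @param bed6 write six columns rather than three.
#' @export
write_bed <- function(intervals, path, bed6 = FALSE) {
  if (any(intervals$start >= intervals$end))
    stopf("refusing to write interval with start >= end")
  cols <- if (bed6) {
    data.frame(intervals$contig, intervals$start, intervals$end,
               if (is.null(intervals$name)) "." else intervals$name,
               if (is.null(intervals$score)) 0 else intervals$score,
               if (is.null(intervals$strand)) "." else intervals$strand)
  } else {
    data.frame(intervals$contig, intervals$start, intervals$end)
  }
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a variant table
#'
#' Tab-delimited with header: contig, pos (1-based), ref, alt, depth,
#' alt_reads and optionally zygosity.
#'
#' @param path TSV path.
#' @return data.frame of per-site records.
#' @export
read_variant_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  validate_variant_table(df)
  df
}

validate_variant_table <- function(df) {
  req <- c("contig", "pos", "ref", "alt", "depth", "alt_reads")
  miss <- setdiff(req, names(df))
  if (length(miss)) stopf("variant table missing columns: %s",
                          paste(miss, collapse = ", "))
  if (any(df$ref == df$alt)) stopf("variant with alt == ref at row %d",
                                   which(df$ref == df$alt)[1])
  if (any(df$alt_reads > df$depth))
    stopf("alt_reads > depth at row %d", which(df$alt_reads > df$depth)[1])
  invisible(df)
}

#' Write a variant table
#' @param df variant data.frame (1-based positions).
#' @param path output path.
#' @export
write_variant_table <- function(df, path) {
  validate_variant_table(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count table
#'
#' Plain TSV with a header row; first column holds row keys (interval or
#' allele ids), remaining columns are per-sample non-negative integer read
#' counts.
#'
#' @param path TSV path.
#' @return data.frame with rownames set to the keys.
#' @export
read_count_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df)
  if (any(m < 0)) stopf("negative count in %s", path)
  if (any(colSums(m) <= 0)) stopf("column with zero library size in %s", path)
  df
}

#' Write a count table
#' @param counts data.frame or matrix with row keys as rownames.
#' @param path output path.
#' @param key_name header name for the key column.
#' @export
write_count_table <- function(counts, path, key_name = "key") {
  m <- as.matrix(counts)
  if (any(m < 0)) stopf("refusing to write negative counts")
  df <- data.frame(rownames(counts), as.data.frame(counts),
                   check.names = FALSE)
  names(df)[1] <- key_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
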