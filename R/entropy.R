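# Conformational entropy: per-position letter frequencies over ensembles
# and Shannon entropy (natural log) of frequency rows or predicted class
# distributions.

#' Per-position letter frequency matrix of an ensemble
#'
#' For encodings of the conformations of one protein under one alphabet,
#' `freq[i, j]` is the fraction of conformations showing letter j at
#' position i among the conformations unmasked there; `support[i]` counts
#' those conformations. Rows with zero support are fully masked (`NA`).
#'
#' @param encodings list of [sa_encoding] sharing alphabet and length.
#' @return object of class `letter_matrix` with fields `freq` (n x m),
#'   `support`, `n`, `m`, `letters`, `alphabet_name`.
#' @export
letter_matrix <- function(encodings) {
  if (inherits(encodings, "sa_encoding")) encodings <- list(encodings)
  stopifnot(length(encodings) >= 1)
  a0 <- encodings[[1]]
  same <- vapply(encodings, function(e) {
    identical(e$alphabet_name, a0$alphabet_name) &&
      identical(e$alphabet_letters, a0$alphabet_letters) && e$n == a0$n
  }, TRUE)
  if (!all(same)) {
    saflex_error("saflex_incompatible_encoding",
                 "encodings must share one alphabet and length")
  }
  n <- a0$n
  m <- a0$m
  L <- vapply(encodings, function(e) e$letters, character(n))
  L <- matrix(L, nrow = n)
  counts <- matrix(0L, n, m, dimnames = list(NULL, a0$alphabet_letters))
  for (j in seq_len(m)) counts[, j] <- rowSums(L == a0$alphabet_letters[j])
  support <- rowSums(counts)
  freq <- counts / ifelse(support > 0, support, 1)
  freq[support == 0, ] <- NA_real_
  structure(
    list(freq = freq, support = as.integer(support), n = n, m = m,
         letters = a0$alphabet_letters, alphabet_name = a0$alphabet_name),
    class = "letter_matrix"
  )
}

#' @export
print.letter_matrix <- function(x, ...) {
  cat(sprintf("<letter_matrix> %d positions x %d letters (%s), support %d-%d\n",
              x$n, x$m, x$alphabet_name, min(x$support), max(x$support)))
  invisible(x)
}

# Shannon entropy (nats) of probability rows with the 0*log(0) := 0
# convention.
row_entropy <- function(P) {
  Plog <- P * log(P)
  Plog[!is.na(P) & P == 0] <- 0
  -rowSums(Plog)
}

#' Per-residue entropy profile container
#'
#' @param values numeric entropies in nats (`NA` where masked).
#' @param mask logical, `TRUE` where the position is masked.
#' @return object of class `entropy_profile`.
#' @export
entropy_profile <- function(values, mask = NULL) {
  if (is.null(mask)) mask <- is.na(values)
  stopifnot(length(mask) == length(values))
  values[mask] <- NA_real_
  structure(list(values = values, mask = mask), class = "entropy_profile")
}

#' @export
print.entropy_profile <- function(x, ...) {
  cat(sprintf("<entropy_profile> %d residues (%d masked), mean %.4f nats\n",
              length(x$values), sum(x$mask),
              mean(x$values, na.rm = TRUE)))
  invisible(x)
}

#' @export
as.data.frame.entropy_profile <- function(x, ...) {
  data.frame(residue = seq_along(x$values), entropy = x$values, mask = x$mask)
}

#' Conformational entropy of an ensemble letter matrix
#'
#' Per-position Shannon entropy `H(i) = -sum_j a_ij * ln(a_ij)` of the
#' across-conformation letter frequencies, in nats; `0 * ln 0` is taken as
#' 0 and masked rows stay masked. H ranges from 0 (one letter in every
#' conformation) to `ln m` (uniform over the alphabet).
#'
#' @param mat a [letter_matrix].
#' @return [entropy_profile].
#' @export
conformational_entropy <- function(mat) {
  stopifnot(inherits(mat, "letter_matrix"))
  entropy_profile(row_entropy(mat$freq), mask = mat$support == 0)
}

#' Entropy of predicted class distributions
#'
#' Applies `H = -sum_j Y_j * ln(Y_j)` to each residue's predicted
#' local-structure class distribution. High entropy indicates a residue
#' predicted to be compatible with several local conformations (relative
#' disorder); low entropy indicates a confident single-class prediction.
#'
#' @param d n x m matrix of per-residue class probabilities; each row must
#'   sum to 1 within `1e-6`. Rows that are entirely `NA` are masked.
#' @return [entropy_profile].
#' @export
prediction_entropy <- function(d) {
  d <- as.matrix(d)
  masked <- rowSums(is.na(d)) == ncol(d)
  check <- !masked
  if (any(check)) {
    bad <- abs(rowSums(d[check, , drop = FALSE]) - 1) > 1e-6 |
      apply(d[check, , drop = FALSE] < 0, 1, any)
    if (any(bad)) {
      saflex_error("saflex_invalid_distribution",
                   sprintf("%d rows are not probability distributions", sum(bad)))
    }
  }
  vals <- rep(NA_real_, nrow(d))
  vals[check] <- row_entropy(d[check, , drop = FALSE])
  entropy_profile(vals, mask = masked)
}

#' Export an entropy profile with letter frequencies as TSV
#'
#' Columns: residue index, one frequency column per letter, entropy (nats),
#' support, mask flag.
#'
#' @param mat a [letter_matrix].
#' @param h matching [entropy_profile]; computed if missing.
#' @param path output file.
#' @return the exported data frame, invisibly.
#' @export
write_entropy_tsv <- function(mat, h = conformational_entropy(mat), path) {
  df <- data.frame(residue = seq_len(mat$n))
  freq <- mat$freq
  colnames(freq) <- paste0("freq_", mat$letters)
  df <- cbind(df, as.data.frame(freq))
  df$entropy <- h$values
  df$support <- mat$support
  df$mask <- h$mask
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
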