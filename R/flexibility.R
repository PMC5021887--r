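# Flexibility analysis: entropy/B-factor correlation, flexible-residue
# labeling and threshold classification, confusion-matrix metrics, ROC
# evaluation, and RMSD-uniform decoy selection.

FLEX_LEVELS <- c("flexible", "rigid", "masked")

as_flex_labels <- function(x) {
  x <- as.character(x)
  bad <- !(x %in% FLEX_LEVELS)
  if (any(bad)) {
    saflex_error("saflex_bad_labels",
                 sprintf("unknown labels: %s", paste(unique(x[bad]), collapse = ", ")))
  }
  x
}

#' Correlation between entropy and B-factors
#'
#' Pearson correlation between per-residue conformational entropy and
#' B-factors over the jointly unmasked positions.
#'
#' @param h an [entropy_profile] (or numeric vector).
#' @param b numeric per-residue B-factors (`NA` treated as masked).
#' @return correlation coefficient in `[-1, 1]`.
#' @export
bfactor_correlation <- function(h, b) {
  hv <- if (inherits(h, "entropy_profile")) h$values else as.numeric(h)
  if (length(hv) != length(b)) {
    saflex_error("saflex_length_mismatch", "entropy and B-factor lengths differ")
  }
  keep <- !is.na(hv) & !is.na(b)
  if (sum(keep) < 3) {
    saflex_error("saflex_insufficient_data",
                 "need >= 3 jointly unmasked positions for correlation")
  }
  if (var(hv[keep]) == 0 || var(b[keep]) == 0) {
    saflex_error("saflex_undefined_correlation",
                 "zero variance in entropy or B-factor vector")
  }
  cor(hv[keep], b[keep])
}

#' Label flexible residues from an ensemble of encodings
#'
#' A residue is flexible when at least two distinct non-mask letters occur
#' at its position across the conformations, rigid when exactly one occurs,
#' and masked when none does.
#'
#' @param encodings list of >= 2 [sa_encoding] sharing alphabet and length.
#' @return character vector over \{"flexible", "rigid", "masked"\}.
#' @export
label_flexible_from_ensemble <- function(encodings) {
  if (inherits(encodings, "sa_encoding") || length(encodings) < 2) {
    saflex_error("saflex_insufficient_conformations",
                 "need >= 2 conformations to label flexibility")
  }
  mat <- letter_matrix(encodings)
  k <- rowSums(!is.na(mat$freq) & mat$freq > 0)
  ifelse(mat$support == 0, "masked", ifelse(k >= 2, "flexible", "rigid"))
}

#' Pooled mean-entropy threshold
#'
#' The flexibility threshold T is the mean entropy over all unmasked
#' residues of all supplied profiles pooled together (residue-weighted, not
#' protein-weighted).
#'
#' @param profiles an [entropy_profile] or list of them.
#' @return threshold in nats.
#' @export
mean_entropy_threshold <- function(profiles) {
  if (inherits(profiles, "entropy_profile")) profiles <- list(profiles)
  vals <- unlist(lapply(profiles, function(p) p$values[!p$mask]))
  if (length(vals) == 0) {
    saflex_error("saflex_insufficient_data", "no unmasked residues")
  }
  mean(vals)
}

#' Classify residues as flexible by an entropy threshold
#'
#' Residues with entropy strictly larger than `T` are flexible; residues at
#' or below `T` are rigid; masked positions stay masked.
#'
#' @param h an [entropy_profile].
#' @param T threshold in nats (finite scalar).
#' @return character labels over \{"flexible", "rigid", "masked"\}.
#' @export
classify_by_threshold <- function(h, T) {
  stopifnot(is.finite(T))
  hv <- if (inherits(h, "entropy_profile")) h$values else as.numeric(h)
  ifelse(is.na(hv), "masked", ifelse(hv > T, "flexible", "rigid"))
}

#' Confusion counts for flexible/rigid classification
#'
#' Counts over positions unmasked in both vectors, with flexible as the
#' positive class.
#'
#' @param pred,truth label vectors over \{"flexible", "rigid", "masked"\}.
#' @return list with integer `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(pred, truth) {
  pred <- as_flex_labels(pred)
  truth <- as_flex_labels(truth)
  if (length(pred) != length(truth)) {
    saflex_error("saflex_length_mismatch", "label vectors differ in length")
  }
  keep <- pred != "masked" & truth != "masked"
  p <- pred[keep] == "flexible"
  t <- truth[keep] == "flexible"
  list(TP = sum(p & t), FP = sum(p & !t), TN = sum(!p & !t), FN = sum(!p & t))
}

#' Sensitivity, specificity and precision from confusion counts
#'
#' `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)`,
#' `precision = TP/(TP+FP)`. A metric whose denominator is zero is
#' returned as `NA` (undefined) rather than failing.
#'
#' @param counts list with `TP`, `FP`, `TN`, `FN` (as from [confusion()]).
#' @return named numeric vector `sensitivity`, `specificity`, `precision`.
#' @export
flex_metrics <- function(counts) {
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  c(sensitivity = safe_div(counts$TP, counts$TP + counts$FN),
    specificity = safe_div(counts$TN, counts$TN + counts$FP),
    precision = safe_div(counts$TP, counts$TP + counts$FP))
}

#' ROC curve and normalized area for entropy-based flexibility scores
#'
#' Sweeps the classification threshold over the unique score values (equal
#' scores grouped into one sweep step), tracing true-positive rate against
#' false-positive rate from (0, 0) to (1, 1), and reports the normalized
#' (trapezoidal) area under the curve. With tie grouping this area equals
#' the Mann-Whitney statistic: the probability that a random flexible
#' residue scores above a random rigid one, counting ties as 1/2. A score
#' of 1 means perfect separation; 0 means complete inversion.
#'
#' @param scores numeric per-residue scores (higher = more flexible).
#' @param truth labels over \{"flexible", "rigid", "masked"\}; masked
#'   positions and `NA` scores are excluded.
#' @return list with `points` (data frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_score <- function(scores, truth) {
  truth <- as_flex_labels(truth)
  if (length(scores) != length(truth)) {
    saflex_error("saflex_length_mismatch", "scores and truth differ in length")
  }
  keep <- !is.na(scores) & truth != "masked"
  s <- scores[keep]
  y <- truth[keep] == "flexible"
  P <- sum(y)
  N <- sum(!y)
  if (P == 0 || N == 0) {
    saflex_error("saflex_undefined_roc",
                 "need both flexible and rigid residues for a ROC curve")
  }
  o <- order(s, decreasing = TRUE)
  s <- s[o]
  y <- y[o]
  grp_last <- cumsum(rle(s)$lengths) # last index of each tied score group
  tp <- cumsum(y)[grp_last]
  fp <- cumsum(!y)[grp_last]
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr,
                           threshold = c(Inf, s[grp_last])),
       auc = auc)
}

#' Select decoys approximately uniform over RMSD bins
#'
#' Each ensemble member is binned by its CA RMSD to the native structure
#' (default bin edges 0, 3, 4, 5, 6, Inf angstrom), then at most `per_bin`
#' members are drawn from each bin without replacement (seeded), so the
#' retained decoys are approximately uniformly distributed across RMSD
#' classes. Selection is deterministic given `seed`; the output preserves
#' the original member order.
#'
#' @param e an [ensemble] of decoys.
#' @param native a [backbone_structure].
#' @param bin_edges ascending bin edges in angstrom.
#' @param per_bin maximum members retained per bin.
#' @param seed integer seed.
#' @return list with `ensemble` (the selected [ensemble]), `rmsd` (per
#'   selected member) and `bin` (bin index per selected member).
#' @export
select_uniform_decoys <- function(e, native, bin_edges = c(0, 3, 4, 5, 6, Inf),
                                  per_bin = 300, seed = 1) {
  stopifnot(inherits(e, "sa_ensemble"), !is.unsorted(bin_edges))
  rmsds <- vapply(e$members, function(m) kabsch_rmsd(m, native), 0)
  bins <- findInterval(rmsds, bin_edges, rightmost.closed = FALSE)
  sel <- with_seed(seed, {
    unlist(lapply(sort(unique(bins)), function(b) {
      idx <- which(bins == b)
      if (length(idx) <= per_bin) idx else sort(sample(idx, per_bin))
    }))
  })
  sel <- sort(sel)
  list(ensemble = ensemble(e$members[sel], e$source_labels[sel]),
       rmsd = rmsds[sel], bin = bins[sel])
}

#' Write a flexibility evaluation report
#'
#' Emits matching TSV (per-residue table) and JSON (summary: counts,
#' metrics, threshold, ROC points and score) files.
#'
#' @param h an [entropy_profile] of the evaluated scores.
#' @param pred predicted labels; `truth` optional reference labels.
#' @param threshold the entropy threshold used (nats).
#' @param prefix output path prefix (writes `<prefix>.tsv`, `<prefix>.json`).
#' @param truth optional truth labels; enables metrics and ROC.
#' @param extra named list merged into the JSON summary (e.g. seed).
#' @return the JSON summary list, invisibly.
#' @export
write_flex_report <- function(h, pred, threshold, prefix, truth = NULL,
                              extra = list()) {
  df <- data.frame(residue = seq_along(pred), entropy = h$values,
                   predicted = pred)
  summary <- list(threshold_T = threshold,
                  n_residues = length(pred),
                  n_flexible = sum(pred == "flexible"),
                  n_rigid = sum(pred == "rigid"),
                  n_masked = sum(pred == "masked"))
  if (!is.null(truth)) {
    df$truth <- truth
    cm <- confusion(pred, truth)
    roc <- roc_score(h$values, truth)
    summary <- c(summary, list(counts = cm,
                               metrics = as.list(flex_metrics(cm)),
                               roc_score = roc$auc,
                               roc_points = roc$points))
  }
  summary <- c(summary, extra)
  utils::write.table(df, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(summary, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns", na = "null")
  invisible(summary)
}
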