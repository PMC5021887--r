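# Dual-layer local-structure predictor: PSSM ingestion, sliding-window
# featurization, stacked multinomial classification (first layer on profile
# windows, second layer on windows of first-layer class distributions), and
# Q-score evaluation.

logistic <- function(x) 1 / (1 + exp(-x))

PSSM_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
             "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Sequence profile container
#'
#' Per-residue evolutionary profile: the 20 log-odds scores of a PSSM row
#' squashed to `(0, 1)` by the logistic function `x -> 1/(1+exp(-x))`, the
#' standard featurization for profile-based local-structure prediction.
#'
#' @param features n x 20 matrix of squashed scores in `[0, 1]`, columns in
#'   PSI-BLAST amino-acid order (ARNDCQEGHILKMFPSTWYV).
#' @param sequence one-letter amino-acid vector (length n).
#' @param logodds optional raw n x 20 log-odds matrix.
#' @return object of class `sequence_profile`.
#' @export
sequence_profile <- function(features, sequence = NULL, logodds = NULL) {
  features <- as.matrix(features)
  if (ncol(features) != 20) {
    saflex_error("saflex_bad_profile", "sequence profile must have 20 columns")
  }
  if (is.null(sequence)) sequence <- rep("X", nrow(features))
  stopifnot(length(sequence) == nrow(features))
  colnames(features) <- PSSM_AA
  structure(list(features = features, sequence = sequence, logodds = logodds,
                 n = nrow(features)),
            class = "sequence_profile")
}

#' @export
print.sequence_profile <- function(x, ...) {
  cat(sprintf("<sequence_profile> %d residues x 20 columns\n", x$n))
  invisible(x)
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the log-odds block of a PSSM written with `-out_ascii_pssm`
#' (header lines, then one row per residue: index, amino acid, 20 log-odds
#' columns) and squashes the log-odds through the logistic function.
#'
#' @param path PSSM file.
#' @return [sequence_profile].
#' @export
read_pssm <- function(path) {
  if (!file.exists(path)) {
    saflex_error("saflex_io", sprintf("cannot read PSSM file '%s'", path))
  }
  lines <- readLines(path)
  is_row <- grepl("^\\s*\\d+\\s+[A-Z]\\s+-?\\d", lines)
  if (!any(is_row)) {
    saflex_error("saflex_parse", sprintf("no PSSM rows found in '%s'", path))
  }
  rows <- which(is_row)
  seq1 <- character(length(rows))
  lo <- matrix(NA_real_, length(rows), 20)
  for (r in seq_along(rows)) {
    parts <- strsplit(trimws(lines[rows[r]]), "\\s+")[[1]]
    if (length(parts) < 22) {
      saflex_error("saflex_parse",
                   sprintf("malformed PSSM row at line %d of '%s'", rows[r], path))
    }
    vals <- suppressWarnings(as.numeric(parts[3:22]))
    if (anyNA(vals)) {
      saflex_error("saflex_parse",
                   sprintf("non-numeric PSSM entry at line %d of '%s'", rows[r], path))
    }
    seq1[r] <- parts[2]
    lo[r, ] <- vals
  }
  sequence_profile(logistic(lo), sequence = seq1, logodds = lo)
}

#' Write a sequence profile as a PSI-BLAST-style ASCII PSSM
#'
#' Emits the standard layout (header, per-residue rows of 20 rounded
#' log-odds). Log-odds are rounded to integers as PSI-BLAST prints them, so
#' profiles with integer log-odds round-trip exactly.
#'
#' @param p a [sequence_profile] with a `logodds` matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(p, path) {
  stopifnot(inherits(p, "sequence_profile"))
  lo <- p$logodds
  if (is.null(lo)) {
    saflex_error("saflex_bad_profile", "profile carries no log-odds matrix")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed",
               paste0("            ", paste(sprintf("%3s", PSSM_AA), collapse = " "))),
             con)
  for (i in seq_len(p$n)) {
    writeLines(sprintf("%5d %s  %s", i, p$sequence[i],
                       paste(sprintf("%3d", round(lo[i, ])), collapse = " ")),
               con)
  }
  writeLines("", con)
  invisible(path)
}

#' Sliding-window profile features
#'
#' Concatenates the profile rows `i - (W-1)/2 ... i + (W-1)/2`;
#' out-of-range rows are zero-padded.
#'
#' @param p a [sequence_profile].
#' @param i residue position (1-based); omit for all positions.
#' @param W odd window width.
#' @return for scalar `i` a length `W*20` vector, otherwise an n x (W*20)
#'   matrix.
#' @export
window_features <- function(p, i = NULL, W = 15) {
  stopifnot(W %% 2 == 1)
  half <- (W - 1L) %/% 2L
  X <- rbind(matrix(0, half, 20), p$features, matrix(0, half, 20))
  all_rows <- function(pos) {
    idx <- outer(pos - 1L, seq_len(W), "+") # rows in padded matrix
    out <- matrix(0, length(pos), W * 20)
    for (w in seq_len(W)) {
      out[, ((w - 1) * 20 + 1):(w * 20)] <- X[idx[, w], , drop = FALSE]
    }
    out
  }
  if (is.null(i)) {
    all_rows(seq_len(p$n))
  } else {
    drop(all_rows(i))
  }
}

# Window features over an arbitrary feature matrix (used for layer 2 on
# first-layer distributions).
window_matrix <- function(M, W) {
  stopifnot(W %% 2 == 1)
  half <- (W - 1L) %/% 2L
  k <- ncol(M)
  X <- rbind(matrix(0, half, k), M, matrix(0, half, k))
  n <- nrow(M)
  out <- matrix(0, n, W * k)
  for (w in seq_len(W)) {
    out[, ((w - 1) * k + 1):(w * k)] <- X[(seq_len(n) + w - 1L), , drop = FALSE]
  }
  out
}

# Fit one probabilistic multiclass layer: L2-regularized multinomial
# logistic regression (glmnet, single fixed lambda -> deterministic).
fit_layer <- function(X, y, letters_all, lambda) {
  glmnet::glmnet(X, factor(y, levels = letters_all), family = "multinomial",
                 lambda = lambda, standardize = FALSE)
}

# Predict class probabilities, aligning columns to the full letter set.
predict_layer <- function(fit, X, letters_all) {
  pr <- predict(fit, newx = X, type = "response")[, , 1, drop = FALSE]
  pr <- matrix(pr, nrow = nrow(X), dimnames = list(NULL, dimnames(pr)[[2]]))
  out <- matrix(0, nrow(X), length(letters_all),
                dimnames = list(NULL, letters_all))
  out[, colnames(pr)] <- pr
  out / rowSums(out)
}

#' Train the dual-layer local-structure predictor
#'
#' Layer 1 is a probabilistic multiclass classifier (L2-regularized
#' multinomial logistic regression) mapping a `W1`-residue window of
#' squashed PSSM features to a distribution over the alphabet letters.
#' Layer 2 refines it by classifying a `W2`-residue window of neighboring
#' layer-1 class distributions, exploiting the strong correlation between
#' neighboring local structures. Layer 2 is trained on cross-fitted layer-1
#' outputs (protein-level folds) so its inputs on the training set have
#' held-out quality and the stacking is not optimistically biased. Masked
#' positions are excluded from both training targets.
#'
#' @param profiles list of [sequence_profile].
#' @param encodings matched list of [sa_encoding] (training letters).
#' @param W1,W2 odd window widths for the two layers.
#' @param lambda ridge penalty for both layers.
#' @param n_folds protein-level folds for cross-fitted stacking.
#' @param seed integer seed (fold assignment; fitting is deterministic).
#' @return object of class `dual_layer_model`.
#' @export
train_dual_layer <- function(profiles, encodings, W1 = 15, W2 = 9,
                             lambda = 0.01, n_folds = 3, seed = 1) {
  stopifnot(length(profiles) == length(encodings), length(profiles) >= 1)
  np <- length(profiles)
  for (i in seq_len(np)) {
    stopifnot(profiles[[i]]$n == encodings[[i]]$n)
  }
  letters_all <- encodings[[1]]$alphabet_letters
  y_all <- lapply(encodings, function(e) e$letters)
  present <- unique(unlist(y_all))
  present <- present[present != SA_MASK]
  if (length(present) < 2) {
    saflex_error("saflex_degenerate_training",
                 "training corpus contains fewer than 2 letter classes")
  }
  X1 <- lapply(profiles, window_features, W = W1)
  unmasked <- lapply(y_all, function(y) y != SA_MASK)
  Xtrain <- do.call(rbind, lapply(seq_len(np), function(i) {
    X1[[i]][unmasked[[i]], , drop = FALSE]
  }))
  ytrain <- unlist(lapply(seq_len(np), function(i) y_all[[i]][unmasked[[i]]]))
  layer1 <- fit_layer(Xtrain, ytrain, letters_all, lambda)

  # cross-fitted layer-1 distributions, fold split at protein level
  folds <- with_seed(seed, sample(rep_len(seq_len(min(n_folds, np)), np)))
  P1 <- vector("list", np)
  for (f in sort(unique(folds))) {
    tr <- which(folds != f)
    if (length(tr) == 0) tr <- which(folds == f) # single-protein corpus
    Xf <- do.call(rbind, lapply(tr, function(i) {
      X1[[i]][unmasked[[i]], , drop = FALSE]
    }))
    yf <- unlist(lapply(tr, function(i) y_all[[i]][unmasked[[i]]]))
    fitf <- if (length(unique(yf)) >= 2) {
      fit_layer(Xf, yf, letters_all, lambda)
    } else layer1
    for (i in which(folds == f)) {
      P1[[i]] <- predict_layer(fitf, X1[[i]], letters_all)
    }
  }
  X2 <- do.call(rbind, lapply(seq_len(np), function(i) {
    window_matrix(P1[[i]], W2)[unmasked[[i]], , drop = FALSE]
  }))
  layer2 <- fit_layer(X2, ytrain, letters_all, lambda)

  structure(
    list(layer1 = layer1, layer2 = layer2, letters = letters_all,
         alphabet_name = encodings[[1]]$alphabet_name,
         W1 = as.integer(W1), W2 = as.integer(W2), lambda = lambda,
         n_folds = n_folds, seed = seed),
    class = "dual_layer_model"
  )
}

#' @export
print.dual_layer_model <- function(x, ...) {
  cat(sprintf("<dual_layer_model> %s (%d letters), windows W1=%d W2=%d\n",
              x$alphabet_name, length(x$letters), x$W1, x$W2))
  invisible(x)
}

#' Predict per-residue local-structure class distributions
#'
#' Runs the trained dual-layer model on a sequence profile and returns one
#' probability distribution over the alphabet letters per residue (rows sum
#' to 1). `layer = "first"` returns the unrefined layer-1 output.
#'
#' @param model a [train_dual_layer()] model.
#' @param p a [sequence_profile].
#' @param layer `"dual"` (default) or `"first"`.
#' @return n x m probability matrix with letter column names.
#' @export
predict_distribution <- function(model, p, layer = c("dual", "first")) {
  layer <- match.arg(layer)
  stopifnot(inherits(model, "dual_layer_model"), inherits(p, "sequence_profile"))
  P1 <- predict_layer(model$layer1, window_features(p, W = model$W1),
                      model$letters)
  if (layer == "first") return(P1)
  predict_layer(model$layer2, window_matrix(P1, model$W2), model$letters)
}

#' Q-score of a class-distribution prediction
#'
#' Fraction of unmasked residues whose maximum-probability predicted letter
#' (ties to the lowest letter index) equals the true letter. For the
#' 3-class secondary-structure alphabet this is the usual Q3.
#'
#' @param pred n x m probability matrix with letter column names.
#' @param truth [sa_encoding] of the true letters.
#' @return fraction in `[0, 1]`.
#' @export
q_score <- function(pred, truth) {
  stopifnot(nrow(pred) == truth$n)
  keep <- truth$letters != SA_MASK
  if (!any(keep)) {
    saflex_error("saflex_insufficient_data", "no unmasked residues to score")
  }
  called <- colnames(pred)[apply(pred[keep, , drop = FALSE], 1, which.max)]
  mean(called == truth$letters[keep])
}

#' Save / load a trained dual-layer model
#'
#' Serializes the model together with a format version tag to a single
#' archive file (RDS).
#'
#' @param model a `dual_layer_model`.
#' @param path file path.
#' @return `path` invisibly (`save_model`); the model (`load_model`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "dual_layer_model"))
  saveRDS(list(format = "saflex_dual_layer", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "saflex_dual_layer")) {
    saflex_error("saflex_io", sprintf("'%s' is not a saved saflex model", path))
  }
  obj$model
}
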