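# Structural alphabets: containers, the bundled Protein Blocks table,
# dihedral computation, dihedral-RMSD (RMSDA) assignment, a nearest-center
# Ramachandran-class encoder, and the trainable Cartesian fragment alphabet.

#' Structural alphabet container
#'
#' @param name alphabet name (e.g. `"Sec3"`, `"Sec8"`, `"PB"`,
#'   `"FragmentSA"`).
#' @param letters ordered distinct letter symbols; must not contain the
#'   reserved mask symbol `"-"`.
#' @param kind one of `"dihedral-prototype"`, `"fragment-prototype"`,
#'   `"rule-based"`.
#' @param prototypes prototype matrix: for dihedral-prototype alphabets an
#'   m x 8 matrix of angles in degrees; for fragment-prototype alphabets an
#'   m x (3L) matrix of centered CA coordinates; for rule-based alphabets a
#'   center matrix or `NULL`.
#' @param fragment_length odd fragment length (PB: 5).
#' @return object of class `sa_alphabet`.
#' @export
sa_alphabet <- function(name, letters, kind, prototypes = NULL,
                        fragment_length = 1L) {
  letters <- as.character(letters)
  if (anyDuplicated(letters)) {
    saflex_error("saflex_bad_alphabet", "alphabet letters must be unique")
  }
  if (SA_MASK %in% letters) {
    saflex_error("saflex_bad_alphabet",
                 sprintf("mask symbol '%s' is reserved", SA_MASK))
  }
  stopifnot(kind %in% c("dihedral-prototype", "fragment-prototype", "rule-based"))
  structure(
    list(name = name, letters = letters, m = length(letters), kind = kind,
         prototypes = prototypes, fragment_length = as.integer(fragment_length)),
    class = "sa_alphabet"
  )
}

#' @export
print.sa_alphabet <- function(x, ...) {
  cat(sprintf("<sa_alphabet> %s: %d letters, %s, fragment length %d\n",
              x$name, x$m, x$kind, x$fragment_length))
  invisible(x)
}

#' The Protein Blocks alphabet
#'
#' Loads the bundled 16-prototype Protein Blocks table: letters a-p, each a
#' 5-residue fragment described by 8 consecutive backbone dihedral angles
#' (psi(i-2), phi(i-1), psi(i-1), phi(i), psi(i), phi(i+1), psi(i+1),
#' phi(i+2)).
#'
#' @return `sa_alphabet` of kind `"dihedral-prototype"` with 16 letters.
#' @export
pb_alphabet <- function() {
  path <- system.file("extdata", "pb_prototypes.txt", package = "saflex",
                      mustWork = TRUE)
  tab <- read.table(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  proto <- as.matrix(tab[, -1])
  dimnames(proto) <- list(tab[[1]], c("psi_m2", "phi_m1", "psi_m1", "phi_0",
                                      "psi_0", "phi_p1", "psi_p1", "phi_p2"))
  stopifnot(nrow(proto) == 16, ncol(proto) == 8,
            all(proto > -180), all(proto <= 180))
  sa_alphabet("PB", tab[[1]], "dihedral-prototype", prototypes = proto,
              fragment_length = 5L)
}

#' Secondary-structure alphabets (3- or 8-class)
#'
#' Rule-based alphabets assigned by the hydrogen-bond pattern assigner
#' [assign_secondary_structure()]. The 8-class letters follow DSSP
#' conventions (H, G, I, E, B, T, S, C); the 3-class alphabet collapses
#' \{H,G,I\} to H and \{E,B\} to E, everything else to C.
#'
#' @param classes 3 or 8.
#' @return `sa_alphabet` of kind `"rule-based"`.
#' @export
sec_alphabet <- function(classes = 3) {
  classes <- as.integer(classes)
  if (classes == 3L) {
    sa_alphabet("Sec3", c("H", "E", "C"), "rule-based")
  } else if (classes == 8L) {
    sa_alphabet("Sec8", c("H", "G", "I", "E", "B", "T", "S", "C"), "rule-based")
  } else {
    saflex_error("saflex_bad_alphabet", "classes must be 3 or 8")
  }
}

#' Nearest-center Ramachandran-class alphabet
#'
#' A per-residue rule-based alphabet that assigns each residue to the
#' nearest (phi, psi) class center under the wrapped Euclidean angle
#' distance. The default three centers are the canonical alpha-helical,
#' extended and left-handed basins. Because assignment depends only on the
#' residue's own dihedrals it is the exact inverse of the dihedral-class
#' synthetic generator, which makes generating letter distributions
#' recoverable position by position.
#'
#' @param centers m x 2 matrix of (phi, psi) centers in degrees, rownames
#'   used as letters. Default: H (-57, -47), E (-119, 113), L (60, 45).
#' @return `sa_alphabet` of kind `"rule-based"`.
#' @export
rama_alphabet <- function(centers = NULL) {
  if (is.null(centers)) {
    centers <- rbind(H = c(-57, -47), E = c(-119, 113), L = c(60, 45))
  }
  stopifnot(is.matrix(centers), ncol(centers) == 2, !is.null(rownames(centers)))
  sa_alphabet(sprintf("Rama%d", nrow(centers)), rownames(centers),
              "rule-based", prototypes = centers, fragment_length = 1L)
}

#' Structural-alphabet encoding container
#'
#' One letter (or the mask symbol `"-"`) per residue under a given
#' alphabet.
#'
#' @param letters character vector of symbols.
#' @param alphabet the [sa_alphabet] used.
#' @return object of class `sa_encoding` with fields `letters`,
#'   `alphabet_name`, `alphabet_letters`, `m`, `n`.
#' @export
sa_encoding <- function(letters, alphabet) {
  bad <- !(letters %in% c(alphabet$letters, SA_MASK))
  if (any(bad)) {
    saflex_error("saflex_bad_encoding",
                 sprintf("symbols not in alphabet '%s': %s", alphabet$name,
                         paste(unique(letters[bad]), collapse = ", ")))
  }
  structure(
    list(letters = letters, alphabet_name = alphabet$name,
         alphabet_letters = alphabet$letters, m = alphabet$m,
         n = length(letters)),
    class = "sa_encoding"
  )
}

#' @export
print.sa_encoding <- function(x, ...) {
  cat(sprintf("<sa_encoding> %s (%d letters): %s\n", x$alphabet_name, x$m,
              paste(x$letters, collapse = "")))
  invisible(x)
}

#' Backbone dihedral angles
#'
#' Computes per-residue (phi, psi): phi(i) from C(i-1)-N(i)-CA(i)-C(i) and
#' psi(i) from N(i)-CA(i)-C(i)-N(i+1). phi of the first residue, psi of the
#' last, and any angle touching an invalid residue are `NA`.
#'
#' @param s a [backbone_structure].
#' @return n x 2 matrix with columns `phi`, `psi`, degrees in `(-180, 180]`.
#' @export
compute_dihedrals <- function(s) {
  stopifnot(inherits(s, "backbone_structure"))
  n <- s$n
  phi <- psi <- rep(NA_real_, n)
  if (n >= 2) {
    i <- 2:n
    ok <- s$valid[i] & s$valid[i - 1]
    if (any(ok)) {
      phi[i[ok]] <- torsion_angle(s$C[i[ok] - 1, , drop = FALSE],
                                  s$N[i[ok], , drop = FALSE],
                                  s$CA[i[ok], , drop = FALSE],
                                  s$C[i[ok], , drop = FALSE])
    }
    j <- 1:(n - 1)
    ok <- s$valid[j] & s$valid[j + 1]
    if (any(ok)) {
      psi[j[ok]] <- torsion_angle(s$N[j[ok], , drop = FALSE],
                                  s$CA[j[ok], , drop = FALSE],
                                  s$C[j[ok], , drop = FALSE],
                                  s$N[j[ok] + 1, , drop = FALSE])
    }
  }
  cbind(phi = phi, psi = psi)
}

#' Dihedral root-mean-square deviation (RMSDA)
#'
#' RMSDA between two vectors of angles in degrees with periodic wrapping:
#' `sqrt(mean(d^2))` where `d = min(|delta|, 360 - |delta|)` per component.
#'
#' @param frag,proto numeric vectors of equal length, degrees; no NA.
#' @return RMSDA in degrees, in `[0, 180]`.
#' @export
rmsda <- function(frag, proto) {
  if (length(frag) != length(proto)) {
    saflex_error("saflex_length_mismatch", "angle vectors differ in length")
  }
  if (anyNA(frag) || anyNA(proto)) {
    saflex_error("saflex_not_assignable", "masked angle in RMSDA input")
  }
  d <- abs(frag - proto) %% 360
  d <- pmin(d, 360 - d)
  sqrt(mean(d^2))
}

# Vectorized RMSDA of rows of A (k x 8) against rows of P (m x 8) -> k x m.
rmsda_grid <- function(A, P) {
  k <- nrow(A); m <- nrow(P)
  out <- matrix(NA_real_, k, m)
  for (j in seq_len(m)) {
    d <- abs(sweep(A, 2, P[j, ], "-")) %% 360
    d <- pmin(d, 360 - d)
    out[, j] <- sqrt(rowMeans(d^2))
  }
  out
}

#' Assign a Protein Blocks letter to one 8-angle fragment vector
#'
#' Returns the letter of the prototype with minimal [rmsda()]; ties break
#' to the lowest prototype index.
#'
#' @param angles numeric vector of 8 dihedrals (degrees), no NA.
#' @param alphabet a dihedral-prototype [sa_alphabet]; default [pb_alphabet()].
#' @return single letter.
#' @export
pb_assign <- function(angles, alphabet = pb_alphabet()) {
  stopifnot(alphabet$kind == "dihedral-prototype")
  d <- rmsda_grid(matrix(angles, nrow = 1), alphabet$prototypes)
  alphabet$letters[which.min(d[1, ])]
}

# Build the n x 8 window-angle matrix used by PB assignment; rows with any
# NA (termini, invalid neighbours) are left as NA.
pb_window_angles <- function(dih) {
  n <- nrow(dih)
  A <- matrix(NA_real_, n, 8)
  if (n >= 5) {
    for (i in 3:(n - 2)) {
      A[i, ] <- c(dih[i - 2, "psi"], dih[i - 1, "phi"], dih[i - 1, "psi"],
                  dih[i, "phi"], dih[i, "psi"], dih[i + 1, "phi"],
                  dih[i + 1, "psi"], dih[i + 2, "phi"])
    }
  }
  A
}

#' Encode a structure with the Protein Blocks alphabet
#'
#' For each residue with a complete 5-residue window the 8-angle vector
#' (psi(i-2) ... phi(i+2)) is assigned to the minimum-RMSDA prototype. The
#' first two and last two residues, and any window touching an invalid
#' residue, are masked.
#'
#' @param s a [backbone_structure].
#' @param alphabet a dihedral-prototype [sa_alphabet]; default [pb_alphabet()].
#' @return [sa_encoding].
#' @export
encode_pb <- function(s, alphabet = pb_alphabet()) {
  stopifnot(alphabet$kind == "dihedral-prototype")
  A <- pb_window_angles(compute_dihedrals(s))
  letters_out <- rep(SA_MASK, s$n)
  ok <- rowSums(is.na(A)) == 0
  if (any(ok)) {
    d <- rmsda_grid(A[ok, , drop = FALSE], alphabet$prototypes)
    letters_out[ok] <- alphabet$letters[apply(d, 1, which.min)]
  }
  sa_encoding(letters_out, alphabet)
}

#' Encode a structure by nearest Ramachandran class center
#'
#' Per-residue assignment to the nearest (phi, psi) center of a
#' [rama_alphabet()] under wrapped Euclidean distance. Residues with masked
#' phi or psi (chain termini, invalid neighbours) are masked.
#'
#' @param s a [backbone_structure].
#' @param alphabet a [rama_alphabet()].
#' @return [sa_encoding].
#' @export
encode_rama <- function(s, alphabet = rama_alphabet()) {
  stopifnot(alphabet$kind == "rule-based", !is.null(alphabet$prototypes))
  dih <- compute_dihedrals(s)
  letters_out <- rep(SA_MASK, s$n)
  ok <- rowSums(is.na(dih)) == 0
  if (any(ok)) {
    d2 <- sapply(seq_len(nrow(alphabet$prototypes)), function(k) {
      dphi <- abs(dih[ok, "phi"] - alphabet$prototypes[k, 1]) %% 360
      dpsi <- abs(dih[ok, "psi"] - alphabet$prototypes[k, 2]) %% 360
      pmin(dphi, 360 - dphi)^2 + pmin(dpsi, 360 - dpsi)^2
    })
    d2 <- matrix(d2, nrow = sum(ok))
    letters_out[ok] <- alphabet$letters[apply(d2, 1, which.min)]
  }
  sa_encoding(letters_out, alphabet)
}

# fragment alphabet ---------------------------------------------------------

# Extract centered CA fragments of length L from a structure. Returns a
# matrix nfrag x 3L (layout x1..xL, y1..yL, z1..zL) plus center positions.
ca_fragments <- function(s, L) {
  half <- (L - 1L) %/% 2L
  n <- s$n
  centers <- integer(0)
  if (n >= L) {
    cand <- (half + 1):(n - half)
    ok <- vapply(cand, function(i) all(s$valid[(i - half):(i + half)]), TRUE)
    centers <- cand[ok]
  }
  if (length(centers) == 0) {
    return(list(mat = matrix(numeric(0), 0, 3 * L), centers = centers))
  }
  mat <- t(vapply(centers, function(i) {
    X <- s$CA[(i - half):(i + half), , drop = FALSE]
    X <- sweep(X, 2, colMeans(X))
    c(X[, 1], X[, 2], X[, 3])
  }, numeric(3 * L)))
  list(mat = mat, centers = centers)
}

frag_to_xyz <- function(row, L) matrix(row, nrow = L)

#' Train a Cartesian fragment alphabet
#'
#' Clusters centered CA fragments of length `L` pooled from the input
#' structures into `m` prototypes by Lloyd-style iteration under the
#' superposed (Kabsch) RMSD distance: fragments are assigned to the nearest
#' prototype, and each prototype is recomputed as the centroid of its
#' members after rotating every member onto the current prototype. This is
#' the same construction family as published Cartesian fragment alphabets
#' (28 prototypes of 7 residues); prototypes here are trained from data,
#' not copied from any published library.
#'
#' @param structures list of [backbone_structure] objects.
#' @param m number of prototypes (default 28).
#' @param L odd fragment length (default 7).
#' @param seed integer seed; training is deterministic given `seed`.
#' @param max_iter maximum Lloyd iterations.
#' @return `sa_alphabet` of kind `"fragment-prototype"` with `m` letters,
#'   letters drawn from `a..z, A..`.
#' @export
train_fragment_alphabet <- function(structures, m = 28, L = 7, seed = 1,
                                    max_iter = 30) {
  stopifnot(L %% 2 == 1, m >= 1)
  if (inherits(structures, "backbone_structure")) structures <- list(structures)
  if (inherits(structures, "sa_ensemble")) structures <- structures$members
  F <- do.call(rbind, lapply(structures, function(s) ca_fragments(s, L)$mat))
  nf <- nrow(F)
  if (is.null(nf) || nf < m) {
    saflex_error("saflex_insufficient_data",
                 sprintf("%d fragments available, need >= %d", if (is.null(nf)) 0 else nf, m))
  }
  protos <- with_seed(seed, F[sample.int(nf, m), , drop = FALSE])
  assign_old <- rep(0L, nf)
  update_proto <- function(members_rows, ref) {
    # rotate each member onto ref, average, recenter
    acc <- matrix(0, L, 3)
    refX <- frag_to_xyz(ref, L)
    for (r in members_rows) {
      X <- frag_to_xyz(F[r, ], L)
      acc <- acc + X %*% kabsch_rotation(X, refX)
    }
    acc <- acc / length(members_rows)
    acc <- sweep(acc, 2, colMeans(acc))
    c(acc[, 1], acc[, 2], acc[, 3])
  }
  for (iter in seq_len(max_iter)) {
    D <- frag_rmsd_grid(F, protos, L)
    assign_new <- max.col(-D, ties.method = "first")
    # refill empty clusters with the worst-fit fragments (deterministic)
    empty <- setdiff(seq_len(m), unique(assign_new))
    if (length(empty) > 0) {
      mind <- D[cbind(seq_len(nf), assign_new)]
      worst <- order(mind, decreasing = TRUE)
      take <- head(worst, length(empty))
      assign_new[take] <- empty[seq_along(take)]
    }
    shift <- 0
    for (k in seq_len(m)) {
      rows <- which(assign_new == k)
      if (length(rows) > 0) {
        new_p <- update_proto(rows, protos[k, ])
        shift <- max(shift, max(abs(new_p - protos[k, ])))
        protos[k, ] <- new_p
      }
    }
    # stop once memberships are stable and prototypes are at their
    # generalized (superposed) centroids
    if (identical(assign_new, assign_old) && shift < 1e-7) break
    assign_old <- assign_new
  }
  syms <- c(letters, LETTERS)[seq_len(m)]
  rownames(protos) <- syms
  sa_alphabet("FragmentSA", syms, "fragment-prototype", prototypes = protos,
              fragment_length = L)
}

#' Encode a structure with a Cartesian fragment alphabet
#'
#' Each residue with a complete centered L-residue window of valid
#' positions is assigned the prototype with minimal superposed CA RMSD
#' (ties to the lowest prototype index); `(L-1)/2` terminal residues on
#' each side are masked.
#'
#' @param s a [backbone_structure].
#' @param alphabet a fragment-prototype [sa_alphabet].
#' @return [sa_encoding].
#' @export
encode_fragments <- function(s, alphabet) {
  stopifnot(alphabet$kind == "fragment-prototype")
  L <- alphabet$fragment_length
  fr <- ca_fragments(s, L)
  letters_out <- rep(SA_MASK, s$n)
  if (length(fr$centers) > 0) {
    D <- frag_rmsd_grid(fr$mat, alphabet$prototypes, L)
    letters_out[fr$centers] <- alphabet$letters[max.col(-D, ties.method = "first")]
  }
  sa_encoding(letters_out, alphabet)
}

#' Encode a structure under any structural alphabet
#'
#' Dispatches on the alphabet: dihedral-prototype alphabets use
#' [encode_pb()], fragment-prototype alphabets use [encode_fragments()],
#' the Sec3/Sec8 rule-based alphabets use [assign_secondary_structure()],
#' and Ramachandran-center alphabets use [encode_rama()].
#'
#' @param s a [backbone_structure].
#' @param alphabet an [sa_alphabet].
#' @return [sa_encoding].
#' @export
sa_encode <- function(s, alphabet) {
  switch(alphabet$kind,
    "dihedral-prototype" = encode_pb(s, alphabet),
    "fragment-prototype" = encode_fragments(s, alphabet),
    "rule-based" = {
      if (alphabet$name %in% c("Sec3", "Sec8")) {
        assign_secondary_structure(s, classes = if (alphabet$name == "Sec3") 3 else 8)
      } else {
        encode_rama(s, alphabet)
      }
    },
    saflex_error("saflex_bad_alphabet", "unknown alphabet kind")
  )
}

# SA-string FASTA -----------------------------------------------------------

#' Write structural-alphabet strings as FASTA
#'
#' Headers carry the record name and the alphabet name; the mask symbol
#' `"-"` is written as-is.
#'
#' @param encodings list of [sa_encoding] (or a single one).
#' @param path output file.
#' @param names record names.
#' @return `path`, invisibly.
#' @export
write_sa_fasta <- function(encodings, path, names = NULL) {
  if (inherits(encodings, "sa_encoding")) encodings <- list(encodings)
  if (is.null(names)) names <- sprintf("encoding_%d", seq_along(encodings))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(encodings)) {
    e <- encodings[[i]]
    writeLines(c(sprintf(">%s alphabet=%s", names[i], e$alphabet_name),
                 paste(e$letters, collapse = "")), con)
  }
  invisible(path)
}

#' Read structural-alphabet strings from FASTA
#'
#' @param path FASTA file written by [write_sa_fasta()] (or compatible).
#' @param alphabet the [sa_alphabet] the strings are encoded under.
#' @return named list of [sa_encoding].
#' @export
read_sa_fasta <- function(path, alphabet) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) saflex_error("saflex_io", "no FASTA records found")
  out <- list()
  for (i in seq_along(hdr)) {
    to <- if (i < length(hdr)) hdr[i + 1] - 1 else length(lines)
    seqstr <- paste(lines[(hdr[i] + 1):to], collapse = "")
    nm <- sub("\\s.*$", "", sub("^>", "", lines[hdr[i]]))
    out[[nm]] <- sa_encoding(strsplit(seqstr, "")[[1]], alphabet)
  }
  out
}
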