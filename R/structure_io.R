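# Coordinate input/output: PDB reading (via bio3d), backbone extraction with
# validity masking, decoy-directory pooling, and PDB export of synthetic
# structures.

#' Backbone structure container
#'
#' Holds per-residue backbone geometry for one conformation: N/CA/C/O
#' coordinates, one-letter sequence, B-factors (from the CA atom) and a
#' validity mask. A residue is valid when all four backbone atoms are
#' present with finite coordinates and it is not preceded by a chain break
#' (CA-CA distance to the previous valid residue >= 4.5 angstrom marks the
#' downstream residue invalid). Masked positions propagate as mask through
#' all downstream per-residue outputs.
#'
#' @param N,CA,C,O n x 3 coordinate matrices (angstrom). May contain NA at
#'   invalid positions.
#' @param sequence character vector of one-letter amino-acid codes.
#' @param bfactor numeric vector of per-residue B-factors (angstrom^2);
#'   defaults to zero.
#' @param resno integer author residue numbers; defaults to `1:n`.
#' @param chain single chain identifier.
#' @return object of class `backbone_structure` with fields `n`, `N`, `CA`,
#'   `C`, `O`, `sequence`, `bfactor`, `resno`, `chain`, `valid`.
#' @export
backbone_structure <- function(N, CA, C, O, sequence = NULL, bfactor = NULL,
                               resno = NULL, chain = "A") {
  n <- nrow(CA)
  if (is.null(n) || n < 1) {
    saflex_error("saflex_empty_structure", "structure must contain >= 1 residue")
  }
  stopifnot(nrow(N) == n, nrow(C) == n, nrow(O) == n)
  if (is.null(sequence)) sequence <- rep("A", n)
  if (is.null(bfactor)) bfactor <- rep(0, n)
  if (is.null(resno)) resno <- seq_len(n)
  stopifnot(length(sequence) == n, length(bfactor) == n, length(resno) == n)
  atoms_ok <- rowSums(is.finite(N)) == 3 & rowSums(is.finite(CA)) == 3 &
    rowSums(is.finite(C)) == 3 & rowSums(is.finite(O)) == 3
  valid <- atoms_ok
  if (n > 1) {
    d <- sqrt(rowSums((CA[-1, , drop = FALSE] - CA[-n, , drop = FALSE])^2))
    brk <- which(valid[-n] & valid[-1] & (!is.finite(d) | d >= 4.5))
    valid[brk + 1] <- FALSE # mask the residue downstream of the break
  }
  structure(
    list(n = n, N = N, CA = CA, C = C, O = O, sequence = sequence,
         bfactor = as.numeric(bfactor), resno = as.integer(resno),
         chain = chain, valid = valid),
    class = "backbone_structure"
  )
}

#' @export
print.backbone_structure <- function(x, ...) {
  cat(sprintf("<backbone_structure> %d residues (chain %s), %d valid\n",
              x$n, x$chain, sum(x$valid)))
  invisible(x)
}

#' @export
as.data.frame.backbone_structure <- function(x, ...) {
  data.frame(resno = x$resno, chain = x$chain, aa = x$sequence,
             bfactor = x$bfactor, valid = x$valid)
}

#' Conformational ensemble container
#'
#' A list of [backbone_structure] members sharing one sequence and length,
#' e.g. the decoy set or morph frames of a single protein.
#'
#' @param members list of `backbone_structure` objects.
#' @param source_labels character labels, one per member.
#' @return object of class `sa_ensemble`.
#' @export
ensemble <- function(members, source_labels = NULL) {
  if (length(members) < 1) {
    saflex_error("saflex_empty_ensemble", "ensemble must contain >= 1 member")
  }
  seqs <- vapply(members, function(m) paste(m$sequence, collapse = ""), "")
  ns <- vapply(members, function(m) m$n, 0L)
  if (length(unique(ns)) != 1 || length(unique(seqs)) != 1) {
    saflex_error("saflex_mixed_ensemble",
                 "all ensemble members must share one sequence and length")
  }
  if (is.null(source_labels)) {
    source_labels <- sprintf("member_%d", seq_along(members))
  }
  structure(list(members = members, source_labels = source_labels),
            class = "sa_ensemble")
}

#' @export
print.sa_ensemble <- function(x, ...) {
  cat(sprintf("<sa_ensemble> %d conformations of %d residues\n",
              length(x$members), x$members[[1]]$n))
  invisible(x)
}

#' @export
length.sa_ensemble <- function(x) length(x$members)

# Three-letter -> one-letter residue code (bio3d); unknowns become X.
aa_one <- function(resid) {
  out <- suppressWarnings(bio3d::aa321(resid))
  out[is.na(out) | !out %in% LETTERS] <- "X"
  out
}

#' Read a PDB file into an ensemble
#'
#' Parses a PDB coordinate file (fixed-column, via \pkg{bio3d}) and returns
#' one [backbone_structure] per MODEL (a single implicit model yields one
#' member). Only one chain is used: the first chain encountered unless
#' `chain` is given. Alternate locations are resolved to the highest
#' occupancy, then first-seen. The per-residue B-factor is taken from the CA
#' atom. Residues missing any of N/CA/C/O are kept but flagged invalid.
#'
#' @param path path to a PDB file.
#' @param chain optional chain identifier.
#' @return [ensemble] object.
#' @export
read_pdb <- function(path, chain = NULL) {
  if (!file.exists(path)) {
    saflex_error("saflex_io", sprintf("cannot read PDB file '%s'", path))
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) {
      saflex_error("saflex_io", sprintf("failed to parse '%s': %s",
                                        path, conditionMessage(e)))
    }
  )
  atom <- pdb$atom
  atom <- atom[atom$type == "ATOM", , drop = FALSE]
  if (nrow(atom) == 0) {
    saflex_error("saflex_empty_structure",
                 sprintf("no parsable ATOM records in '%s'", path))
  }
  atom$chain[is.na(atom$chain)] <- " "
  if (is.null(chain)) chain <- atom$chain[1]
  atom$row <- seq_len(nrow(atom))
  atom <- atom[atom$chain == chain, , drop = FALSE]
  if (nrow(atom) == 0) {
    saflex_error("saflex_empty_structure",
                 sprintf("chain '%s' not found in '%s'", chain, path))
  }
  atom$insert[is.na(atom$insert)] <- ""
  reskey <- paste(atom$resno, atom$insert, sep = "_")
  residues <- unique(reskey) # file order within the chain
  nres <- length(residues)
  # altloc: keep highest occupancy then first occurrence per (residue, atom)
  occ <- atom$o
  occ[is.na(occ)] <- 1
  ord <- order(match(reskey, residues), atom$elety, -occ, atom$row)
  atom <- atom[ord, , drop = FALSE]
  keep <- !duplicated(paste(reskey[ord], atom$elety, sep = "|"))
  atom <- atom[keep, , drop = FALSE]
  reskey <- paste(atom$resno, atom$insert, sep = "_")

  nmodels <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1
  xyz_of <- function(model, rows) {
    v <- if (is.matrix(pdb$xyz)) pdb$xyz[model, ] else as.numeric(pdb$xyz)
    idx <- rep((rows - 1) * 3, each = 3) + 1:3
    matrix(v[idx], ncol = 3, byrow = TRUE)
  }
  ridx <- match(reskey, residues)
  seq1 <- rep("X", nres)
  resno <- rep(NA_integer_, nres)
  first_per_res <- !duplicated(ridx)
  seq1[ridx[first_per_res]] <- aa_one(atom$resid[first_per_res])
  resno[ridx[first_per_res]] <- atom$resno[first_per_res]

  members <- vector("list", nmodels)
  for (mod in seq_len(nmodels)) {
    mk <- function(elety) {
      M <- matrix(NA_real_, nres, 3)
      sel <- atom$elety == elety
      if (any(sel)) M[ridx[sel], ] <- xyz_of(mod, atom$row[sel])
      M
    }
    N <- mk("N"); CA <- mk("CA"); C <- mk("C"); O <- mk("O")
    bf <- rep(NA_real_, nres)
    sel <- atom$elety == "CA"
    bf[ridx[sel]] <- atom$b[sel]
    bf[is.na(bf)] <- 0
    members[[mod]] <- backbone_structure(N, CA, C, O, sequence = seq1,
                                         bfactor = bf, resno = resno,
                                         chain = chain)
  }
  ensemble(members, source_labels = sprintf("%s#%d", basename(path),
                                            seq_len(nmodels)))
}

#' Read a directory of decoy PDB files as one ensemble
#'
#' Pools every `*.pdb` file in `dir` (first model, first chain each) into a
#' single [ensemble]. Files whose sequence or length differs from the first
#' file are skipped with a warning.
#'
#' @param dir directory containing PDB files.
#' @param chain optional chain identifier passed to [read_pdb()].
#' @return [ensemble] object.
#' @export
read_decoy_dir <- function(dir, chain = NULL) {
  files <- sort(list.files(dir, pattern = "\\.pdb$", full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0) {
    saflex_error("saflex_empty_ensemble",
                 sprintf("no PDB files found in '%s'", dir))
  }
  members <- list()
  labels <- character()
  ref_seq <- NULL
  for (f in files) {
    m <- tryCatch(read_pdb(f, chain = chain)$members[[1]], error = function(e) NULL)
    if (is.null(m)) {
      warning(sprintf("skipping unreadable decoy '%s'", basename(f)))
      next
    }
    sq <- paste(m$sequence, collapse = "")
    if (is.null(ref_seq)) ref_seq <- sq
    if (!identical(sq, ref_seq)) {
      warning(sprintf("skipping '%s': sequence mismatch with first decoy",
                      basename(f)))
      next
    }
    members[[length(members) + 1]] <- m
    labels <- c(labels, basename(f))
  }
  if (length(members) == 0) {
    saflex_error("saflex_empty_ensemble",
                 sprintf("no consistent decoy members in '%s'", dir))
  }
  ensemble(members, source_labels = labels)
}

#' Write structures to a PDB file
#'
#' Writes a [backbone_structure] or [ensemble] (as MODEL blocks) with
#' backbone atoms N, CA, C, O. All four atoms of a residue carry its
#' B-factor, so the CA convention round-trips. Invalid positions with
#' missing coordinates are dropped atom-wise.
#'
#' @param x a `backbone_structure` or `sa_ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  members <- if (inherits(x, "sa_ensemble")) x$members else list(x)
  s0 <- members[[1]]
  elety <- rep(c("N", "CA", "C", "O"), s0$n)
  resno <- rep(s0$resno, each = 4)
  resid <- rep(bio3d::aa123(s0$sequence), each = 4)
  b <- rep(s0$bfactor, each = 4)
  xyz <- do.call(rbind, lapply(members, function(s) {
    # interleave atoms residue-wise: N, CA, C, O per residue
    coords <- matrix(NA_real_, 4 * s$n, 3)
    coords[seq(1, 4 * s$n, by = 4), ] <- s$N
    coords[seq(2, 4 * s$n, by = 4), ] <- s$CA
    coords[seq(3, 4 * s$n, by = 4), ] <- s$C
    coords[seq(4, 4 * s$n, by = 4), ] <- s$O
    as.numeric(t(coords))
  }))
  ok <- is.finite(colSums(matrix(xyz[1, ], nrow = 3)))
  for (r in seq_len(nrow(xyz))) {
    ok <- ok & is.finite(colSums(matrix(xyz[r, ], nrow = 3)))
  }
  sel <- rep(ok, each = 3)
  xyz <- xyz[, sel, drop = FALSE]
  if (nrow(xyz) == 1) xyz <- as.numeric(xyz)
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno[ok],
                   resid = resid[ok], elety = elety[ok],
                   chain = rep(s0$chain, sum(ok)), b = b[ok])
  invisible(path)
}
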