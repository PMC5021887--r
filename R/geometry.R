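# Backbone geometry: torsion angles, internal-coordinate chain building
# (NeRF), and Kabsch least-squares superposition.

DEG <- 180 / pi

#' Wrap angles in degrees to the interval (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector with every value in `(-180, 180]`.
#' @keywords internal
wrap180 <- function(x) {
  y <- ((x + 180) %% 360) - 180
  y[!is.na(y) & y == -180] <- 180
  y
}

# Row-wise cross product of n x 3 matrices.
row_cross <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

row_dot <- function(a, b) rowSums(a * b)

row_unit <- function(a) a / sqrt(rowSums(a * a))

#' Torsion angle defined by four points
#'
#' Computes the signed dihedral angle p1-p2-p3-p4 (IUPAC sign convention)
#' for each row of the input matrices.
#'
#' @param p1,p2,p3,p4 n x 3 matrices (or length-3 vectors) of coordinates.
#' @return numeric vector of angles in degrees, wrapped to `(-180, 180]`.
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  as_m <- function(p) if (is.matrix(p)) p else matrix(p, nrow = 1)
  p1 <- as_m(p1); p2 <- as_m(p2); p3 <- as_m(p3); p4 <- as_m(p4)
  b0 <- p1 - p2
  b1 <- row_unit(p3 - p2)
  b2 <- p4 - p3
  v <- b0 - row_dot(b0, b1) * b1
  w <- b2 - row_dot(b2, b1) * b1
  wrap180(atan2(row_dot(row_cross(b1, v), w), row_dot(v, w)) * DEG)
}

# Place atom D given positions A, B, C, the C-D bond length, the B-C-D bond
# angle and the A-B-C-D torsion (degrees). Standard natural-extension
# reference frame construction.
place_atom <- function(A, B, C, bond, angle, torsion) {
  th <- angle / DEG
  ta <- torsion / DEG
  bc <- C - B
  bc <- bc / sqrt(sum(bc * bc))
  ab <- B - A
  n <- c(
    ab[2] * bc[3] - ab[3] * bc[2],
    ab[3] * bc[1] - ab[1] * bc[3],
    ab[1] * bc[2] - ab[2] * bc[1]
  )
  n <- n / sqrt(sum(n * n))
  m <- c(
    n[2] * bc[3] - n[3] * bc[2],
    n[3] * bc[1] - n[1] * bc[3],
    n[1] * bc[2] - n[2] * bc[1]
  )
  d <- c(-bond * cos(th), bond * sin(th) * cos(ta), bond * sin(th) * sin(ta))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# Canonical backbone internal coordinates (Engh-Huber-like averages).
BB_GEOM <- list(
  n_ca = 1.46, ca_c = 1.52, c_n = 1.33, c_o = 1.23,
  ang_n_ca_c = 111.0, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.5, omega = 180
)

#' Build backbone coordinates from phi/psi dihedrals
#'
#' Constructs N, CA, C, O coordinates residue by residue from supplied
#' backbone dihedrals using standard bond lengths and angles (N-CA 1.46,
#' CA-C 1.52, C-N 1.33 angstrom; omega fixed at 180 degrees). `phi[1]` is
#' ignored (no preceding carbonyl); `psi[n]` is used only to place the
#' terminal carbonyl oxygen.
#'
#' @param phi,psi numeric vectors of equal length n, degrees.
#' @return list with n x 3 matrices `N`, `CA`, `C`, `O`.
#' @export
build_backbone <- function(phi, psi) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 1)
  g <- BB_GEOM
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$n_ca, 0, 0)
  thNCA <- g$ang_n_ca_c / DEG
  C[1, ] <- CA[1, ] + g$ca_c * c(-cos(thNCA), sin(thNCA), 0)
  if (n > 1) {
    for (i in 2:n) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           g$c_n, g$ang_ca_c_n, psi[i - 1])
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            g$n_ca, g$ang_c_n_ca, g$omega)
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                           g$ca_c, g$ang_n_ca_c, phi[i])
    }
  }
  for (i in seq_len(n)) {
    # carbonyl O is anti to the next amide N, i.e. torsion N-CA-C-O = psi+180
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         g$c_o, g$ang_ca_c_o, wrap180(psi[i] + 180))
  }
  list(N = N, CA = CA, C = C, O = O)
}

# Kabsch superposition ------------------------------------------------------

# Minimal least-squares RMSD between two n x 3 coordinate matrices after
# optimal rigid-body (proper rotation + translation) superposition.
kabsch_rmsd_xyz <- function(X, Y) {
  n <- nrow(X)
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  M <- crossprod(Yc, Xc)
  s <- svd(M)
  sig <- s$d
  if (det(M) < 0) sig[3] <- -sig[3]
  msd <- (sum(Xc^2) + sum(Yc^2) - 2 * sum(sig)) / n
  sqrt(max(msd, 0))
}

# Optimal proper rotation matrix mapping centered X onto centered Y.
kabsch_rotation <- function(X, Y) {
  s <- svd(crossprod(X, Y))
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

#' CA RMSD after optimal superposition
#'
#' Least-squares root-mean-square deviation over the CA atoms of positions
#' valid in both structures, after optimal rigid-body superposition
#' (Kabsch algorithm). Symmetric and invariant to proper rigid transforms
#' of either argument.
#'
#' @param a,b [backbone_structure] objects of equal length.
#' @return RMSD in angstrom (non-negative scalar).
#' @export
kabsch_rmsd <- function(a, b) {
  stopifnot(inherits(a, "backbone_structure"), inherits(b, "backbone_structure"))
  if (a$n != b$n) {
    saflex_error("saflex_length_mismatch", "structures have different lengths")
  }
  keep <- a$valid & b$valid
  if (sum(keep) < 3) {
    saflex_error("saflex_insufficient_data",
                 "fewer than 3 jointly valid positions for superposition")
  }
  kabsch_rmsd_xyz(a$CA[keep, , drop = FALSE], b$CA[keep, , drop = FALSE])
}

# Vectorized fragment-to-prototype RMSD.
#
# W: nf x 3L matrix of centered fragments (row layout x1..xL,y1..yL,z1..zL);
# P: m x 3L matrix of centered prototypes. Returns nf x m matrix of
# superposed RMSDs. Uses the closed-form symmetric 3x3 eigensolve on the
# cross-covariance Gram matrix so the whole grid is computed with nine
# matrix products instead of per-pair SVDs.
frag_rmsd_grid <- function(W, P, L) {
  nf <- nrow(W); m <- nrow(P)
  idx <- function(a) ((a - 1) * L + 1):(a * L)
  Wc <- lapply(1:3, function(a) W[, idx(a), drop = FALSE])
  Pc <- lapply(1:3, function(a) P[, idx(a), drop = FALSE])
  # M[a,b] entry for pair (i,k): sum_l P_k[l,a] * W_i[l,b]
  M <- vector("list", 9)
  dim(M) <- c(3, 3)
  for (a in 1:3) for (b in 1:3) {
    M[[a, b]] <- tcrossprod(Wc[[b]], Pc[[a]]) # nf x m
  }
  detM <- M[[1, 1]] * (M[[2, 2]] * M[[3, 3]] - M[[2, 3]] * M[[3, 2]]) -
    M[[1, 2]] * (M[[2, 1]] * M[[3, 3]] - M[[2, 3]] * M[[3, 1]]) +
    M[[1, 3]] * (M[[2, 1]] * M[[3, 2]] - M[[2, 2]] * M[[3, 1]])
  # K = M^T M, symmetric; six unique entries
  K11 <- M[[1, 1]]^2 + M[[2, 1]]^2 + M[[3, 1]]^2
  K22 <- M[[1, 2]]^2 + M[[2, 2]]^2 + M[[3, 2]]^2
  K33 <- M[[1, 3]]^2 + M[[2, 3]]^2 + M[[3, 3]]^2
  K12 <- M[[1, 1]] * M[[1, 2]] + M[[2, 1]] * M[[2, 2]] + M[[3, 1]] * M[[3, 2]]
  K13 <- M[[1, 1]] * M[[1, 3]] + M[[2, 1]] * M[[2, 3]] + M[[3, 1]] * M[[3, 3]]
  K23 <- M[[1, 2]] * M[[1, 3]] + M[[2, 2]] * M[[2, 3]] + M[[3, 2]] * M[[3, 3]]
  q <- (K11 + K22 + K33) / 3
  p2 <- (K11 - q)^2 + (K22 - q)^2 + (K33 - q)^2 + 2 * (K12^2 + K13^2 + K23^2)
  p <- sqrt(pmax(p2 / 6, 0))
  # detB = det((K - qI)/p); guard p ~ 0 (triple eigenvalue)
  safe_p <- ifelse(p < 1e-12, 1, p)
  B11 <- (K11 - q) / safe_p; B22 <- (K22 - q) / safe_p; B33 <- (K33 - q) / safe_p
  B12 <- K12 / safe_p; B13 <- K13 / safe_p; B23 <- K23 / safe_p
  detB <- B11 * (B22 * B33 - B23^2) - B12 * (B12 * B33 - B23 * B13) +
    B13 * (B12 * B23 - B22 * B13)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  s1 <- sqrt(pmax(e1, 0)); s2 <- sqrt(pmax(e2, 0)); s3 <- sqrt(pmax(e3, 0))
  sigsum <- s1 + s2 + ifelse(detM < 0, -s3, s3)
  w2 <- rowSums(W^2) # nf
  p2n <- rowSums(P^2) # m
  msd <- (outer(w2, p2n, "+") - 2 * sigsum) / L
  sqrt(pmax(msd, 0))
}
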