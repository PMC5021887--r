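# Shared fixture builders: everything is generated in code at test time.

# Ideal helix backbone_structure of length n.
helix_structure <- function(n = 12) {
  bb <- build_backbone(rep(-57, n), rep(-47, n))
  backbone_structure(bb$N, bb$CA, bb$C, bb$O)
}

# Apply a proper rigid transform (rotation about an arbitrary axis plus
# translation) to a backbone_structure.
rigid_transform <- function(s, angle_deg = 37, axis = c(1, 2, 3),
                            shift = c(5, -4, 11)) {
  axis <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- rbind(c(0, -axis[3], axis[2]),
             c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  tr <- function(M) M %*% t(R) + matrix(shift, nrow(M), 3, byrow = TRUE)
  backbone_structure(tr(s$N), tr(s$CA), tr(s$C), tr(s$O),
                     sequence = s$sequence, bfactor = s$bfactor,
                     resno = s$resno, chain = s$chain)
}

# sa_encoding from a plain letter string under a given alphabet.
enc_str <- function(x, alphabet) {
  sa_encoding(strsplit(x, "")[[1]], alphabet)
}

# Mann-Whitney pairwise ROC oracle: P(score_pos > score_neg) + 0.5 ties.
auc_pairwise <- function(scores, labels) {
  sp <- scores[labels == "flexible"]
  sn <- scores[labels == "rigid"]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Explicit summation form of the entropy/B-factor correlation.
cc_oracle <- function(h, b) {
  num <- sum((h - mean(h)) * (b - mean(b)))
  num / sqrt(sum((h - mean(h))^2) * sum((b - mean(b))^2))
}

# Random probability rows (Dirichlet-ish via normalized exponentials).
random_prob_rows <- function(n, m) {
  x <- matrix(rexp(n * m), n, m)
  x / rowSums(x)
}

# A PB window-angle vector realized as a 5-residue backbone; the center
# residue of encode_pb() sees exactly `angles`.
structure_from_pb_window <- function(angles) {
  stopifnot(length(angles) == 8)
  bb <- build_backbone(phi = c(-120, angles[2], angles[4], angles[6], angles[8]),
                       psi = c(angles[1], angles[3], angles[5], angles[7], 120))
  backbone_structure(bb$N, bb$CA, bb$C, bb$O)
}
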