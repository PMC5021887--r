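# Hydrogen-bond-based secondary-structure assignment (simplified
# Kabsch-Sander scheme) and ingestion of precomputed DSSP files.

# Place amide hydrogens geometrically: H = N + 1.01 A along the direction
# opposite the bisector of (C_prev - N) and (CA - N). Residue 1 gets no H.
place_amide_h <- function(s) {
  H <- matrix(NA_real_, s$n, 3)
  if (s$n >= 2) {
    i <- 2:s$n
    ok <- s$valid[i] & s$valid[i - 1]
    v1 <- row_unit(s$C[i - 1, , drop = FALSE] - s$N[i, , drop = FALSE])
    v2 <- row_unit(s$CA[i, , drop = FALSE] - s$N[i, , drop = FALSE])
    dir <- -row_unit(v1 + v2)
    H[i[ok], ] <- s$N[i[ok], , drop = FALSE] + 1.01 * dir[ok, , drop = FALSE]
  }
  H
}

#' Backbone hydrogen-bond energy matrix
#'
#' Kabsch-Sander electrostatic model: for acceptor carbonyl C=O of residue
#' j and donor amide N-H of residue i,
#' `E = 27.888 * (1/r(ON) + 1/r(CH) - 1/r(OH) - 1/r(CN))` kcal/mol, with a
#' bond recorded when `E < -0.5`. Pairs with `|i - j| < 3` (no assignment
#' pattern uses closer pairs), invalid residues, or a missing donor
#' hydrogen are excluded.
#'
#' @param s a [backbone_structure].
#' @return list with `energy` (n x n matrix, `energy[j, i]` = energy of the
#'   CO(j) <- HN(i) interaction) and `hbond` (logical n x n, `hbond[j, i]`).
#' @export
hbond_energies <- function(s) {
  n <- s$n
  H <- place_amide_h(s)
  E <- matrix(NA_real_, n, n)
  donors <- which(s$valid & rowSums(is.finite(H)) == 3)
  acceptors <- which(s$valid)
  for (i in donors) {
    js <- acceptors[abs(acceptors - i) >= 3]
    if (length(js) == 0) next
    rON <- sqrt(rowSums((s$O[js, , drop = FALSE] -
                           matrix(s$N[i, ], length(js), 3, byrow = TRUE))^2))
    rCH <- sqrt(rowSums((s$C[js, , drop = FALSE] -
                           matrix(H[i, ], length(js), 3, byrow = TRUE))^2))
    rOH <- sqrt(rowSums((s$O[js, , drop = FALSE] -
                           matrix(H[i, ], length(js), 3, byrow = TRUE))^2))
    rCN <- sqrt(rowSums((s$C[js, , drop = FALSE] -
                           matrix(s$N[i, ], length(js), 3, byrow = TRUE))^2))
    E[js, i] <- 27.888 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
  }
  list(energy = E, hbond = !is.na(E) & E < -0.5)
}

#' Assign secondary structure from backbone geometry
#'
#' Simplified Kabsch-Sander assignment: amide hydrogens are placed
#' geometrically, hydrogen bonds are detected with the electrostatic energy
#' model of [hbond_energies()], n-turns at i -> i+3/4/5 yield G/H/I helices
#' (two consecutive turns required), bridge patterns yield E (ladders) or B
#' (isolated bridges), remaining turn residues T, bends S (CA angle over
#' 70 degrees), else C. Priority H > E > G > I > B > T > S > C. With
#' `classes = 3`, \{H,G,I\} collapse to H, \{E,B\} to E, the rest to C.
#' Invalid residues are masked.
#'
#' @param s a [backbone_structure].
#' @param classes 3 or 8.
#' @return [sa_encoding] under [sec_alphabet()].
#' @export
assign_secondary_structure <- function(s, classes = 3) {
  n <- s$n
  hb <- hbond_energies(s)$hbond
  turn <- function(k) {
    t <- rep(FALSE, n)
    if (n > k) {
      i <- 1:(n - k)
      t[i] <- hb[cbind(i, i + k)]
    }
    t
  }
  t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)
  # two consecutive n-turns (at st-1 and st) start a helix at st
  mark_helix <- function(t, k) {
    h <- rep(FALSE, n)
    starts <- which(t)
    starts <- starts[starts >= 2]
    starts <- starts[t[starts - 1]]
    for (st in starts) h[st:min(st + k - 1, n)] <- TRUE
    h
  }
  isH <- mark_helix(t4, 4)
  isG <- mark_helix(t3, 3)
  isI <- mark_helix(t5, 5)

  # bridges (Kabsch-Sander patterns), |i - j| > 2
  bridge <- rep(FALSE, n)
  if (n >= 5) for (i in 2:(n - 1)) {
    for (j in 2:(n - 1)) {
      if (abs(i - j) <= 2) next
      par <- (hb[i - 1, j] && hb[j, i + 1]) || (hb[j - 1, i] && hb[i, j + 1])
      anti <- (hb[i, j] && hb[j, i]) ||
        (i >= 2 && j + 1 <= n && j >= 2 && i + 1 <= n &&
           hb[i - 1, j + 1] && hb[j - 1, i + 1])
      if (par || anti) {
        bridge[i] <- TRUE
        bridge[j] <- TRUE
      }
    }
  }
  ladder <- bridge & (c(FALSE, bridge[-n]) | c(bridge[-1], FALSE))

  # turn residues: positions bracketed by an n-turn
  isT <- rep(FALSE, n)
  for (k in 3:5) {
    t <- list(t3, t4, t5)[[k - 2]]
    for (st in which(t)) {
      span <- (st + 1):(st + k - 1)
      span <- span[span <= n]
      isT[span] <- TRUE
    }
  }

  # bend: CA virtual-bond angle at i between (CA_i - CA_{i-2}) and
  # (CA_{i+2} - CA_i) greater than 70 degrees
  isS <- rep(FALSE, n)
  if (n >= 5) {
    for (i in 3:(n - 2)) {
      if (!all(s$valid[(i - 2):(i + 2)])) next
      u <- s$CA[i, ] - s$CA[i - 2, ]
      v <- s$CA[i + 2, ] - s$CA[i, ]
      ang <- acos(pmin(pmax(sum(u * v) / sqrt(sum(u^2) * sum(v^2)), -1), 1)) * DEG
      isS[i] <- ang > 70
    }
  }

  ss <- rep("C", n)
  ss[isS] <- "S"
  ss[isT] <- "T"
  ss[bridge & !ladder] <- "B"
  ss[isI] <- "I"
  ss[isG] <- "G"
  ss[ladder] <- "E"
  ss[isH] <- "H"
  ss[!s$valid] <- SA_MASK

  if (classes == 3) {
    ss[ss %in% c("G", "I")] <- "H"
    ss[ss == "B"] <- "E"
    ss[ss %in% c("T", "S")] <- "C"
    sa_encoding(ss, sec_alphabet(3))
  } else {
    sa_encoding(ss, sec_alphabet(8))
  }
}

#' Collapse an 8-class secondary-structure encoding to 3 classes
#'
#' \{H,G,I\} -> H, \{E,B\} -> E, everything else -> C; mask preserved.
#'
#' @param enc an [sa_encoding] under the Sec8 alphabet.
#' @return [sa_encoding] under the Sec3 alphabet.
#' @export
collapse_sec8 <- function(enc) {
  stopifnot(enc$alphabet_name == "Sec8")
  x <- enc$letters
  out <- ifelse(x %in% c("H", "G", "I"), "H",
                ifelse(x %in% c("E", "B"), "E",
                       ifelse(x == SA_MASK, SA_MASK, "C")))
  sa_encoding(out, sec_alphabet(3))
}

#' Read a classic DSSP output file
#'
#' Parses the fixed-column residue block of a precomputed DSSP file and
#' returns the 8-class encoding (blank summary symbol -> C, chain-break
#' records -> mask). Accepting DSSP files directly allows overriding the
#' package's built-in assigner with reference assignments.
#'
#' @param path DSSP output file.
#' @param classes 3 or 8.
#' @return [sa_encoding].
#' @export
read_dssp <- function(path, classes = 8) {
  if (!file.exists(path)) {
    saflex_error("saflex_io", sprintf("cannot read DSSP file '%s'", path))
  }
  lines <- readLines(path)
  start <- grep("^  #  RESIDUE", lines)
  if (length(start) == 0) {
    saflex_error("saflex_io", sprintf("'%s' is not a DSSP file", path))
  }
  body <- lines[(start[1] + 1):length(lines)]
  body <- body[nchar(body) >= 17]
  aa <- substring(body, 14, 14)
  ss <- substring(body, 17, 17)
  ss[aa == "!"] <- SA_MASK
  ss[ss == " "] <- "C"
  ss[!(ss %in% c("H", "G", "I", "E", "B", "T", "S", "C", SA_MASK))] <- "C"
  enc <- sa_encoding(ss, sec_alphabet(8))
  if (classes == 3) collapse_sec8(enc) else enc
}
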