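# Synthetic fixtures with exact ground truth: ideal and perturbed
# backbones, decoy ensembles with known per-position letter distributions,
# B-factor profiles tied to true entropy, and sequence profiles carrying a
# learnable local-structure signal.

# Local-conformation classes used by the generator: canonical dihedral
# basins plus a "subtle" variant inside each basin. Subtle variants change
# the backbone geometry without leaving the coarse Ramachandran class, so
# only finer alphabets can see those conformational changes.
SYN_CLASSES <- rbind(
  H = c(-57, -47), E = c(-119, 113), L = c(60, 45),
  Ha = c(-70, -30), Ea = c(-140, 135), La = c(75, 25)
)

syn_base_class <- function(ss) c(H = "H", E = "E", C = "L")[ss]

syn_alt_class <- function(base, subtle) {
  ifelse(subtle, paste0(base, "a"), c(H = "E", E = "H", L = "H")[base])
}

# Coarse (3-class) letter of a generator class under rama_alphabet().
syn_coarse_letter <- function(cls) sub("a$", "", cls)

#' Build an ideal backbone from a secondary-structure pattern
#'
#' Residues are built from canonical dihedrals: H (helix) phi = -57,
#' psi = -47; E (strand) phi = -119, psi = 113; C (coil) phi ~ U(-90, -60),
#' psi ~ U(100, 160), sampled with `seed`. Standard bond lengths and angles
#' are used throughout (see [build_backbone()]).
#'
#' @param ss_pattern string (or character vector) over \{H, E, C\}.
#' @param seed integer seed for the coil dihedrals.
#' @return [backbone_structure].
#' @export
make_ideal_backbone <- function(ss_pattern, seed = 1) {
  ss <- if (length(ss_pattern) == 1) strsplit(ss_pattern, "")[[1]] else ss_pattern
  n <- length(ss)
  if (n == 0) saflex_error("saflex_empty_structure", "empty pattern")
  if (!all(ss %in% c("H", "E", "C"))) {
    saflex_error("saflex_bad_pattern", "pattern must be over {H, E, C}")
  }
  phi <- psi <- numeric(n)
  phi[ss == "H"] <- -57; psi[ss == "H"] <- -47
  phi[ss == "E"] <- -119; psi[ss == "E"] <- 113
  ncoil <- sum(ss == "C")
  if (ncoil > 0) {
    coil <- with_seed(seed, cbind(runif(ncoil, -90, -60), runif(ncoil, 100, 160)))
    phi[ss == "C"] <- coil[, 1]
    psi[ss == "C"] <- coil[, 2]
  }
  bb <- build_backbone(phi, psi)
  backbone_structure(bb$N, bb$CA, bb$C, bb$O)
}

#' Generator specification for synthetic decoy ensembles
#'
#' @param ss_pattern string over \{H, E, C\}: the base local conformation
#'   per residue (C maps to a fixed left-handed coil basin so the
#'   generating letter distribution is exact).
#' @param variability per-residue probability in `[0, 1]` that a member
#'   swaps the residue to its alternative conformation class.
#' @param subtle logical per residue (recycled): if `TRUE` the alternative
#'   class is the within-basin variant of the base class (invisible to
#'   coarse alphabets); if `FALSE` it is a different basin.
#' @param n_members number of ensemble members.
#' @param bfactor_noise_sd Gaussian noise SD for [make_synthetic_bfactors()].
#' @param seed integer seed driving all randomness of the ensemble.
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(ss_pattern, variability, subtle = FALSE,
                           n_members = 100, bfactor_noise_sd = 0, seed = 1) {
  ss <- if (length(ss_pattern) == 1) strsplit(ss_pattern, "")[[1]] else ss_pattern
  n <- length(ss)
  stopifnot(n >= 1, all(ss %in% c("H", "E", "C")))
  variability <- rep_len(variability, n)
  subtle <- rep_len(subtle, n)
  stopifnot(all(variability >= 0 & variability <= 1))
  structure(list(ss = ss, n_residues = n, variability = variability,
                 subtle = subtle, n_members = as.integer(n_members),
                 bfactor_noise_sd = bfactor_noise_sd, seed = as.integer(seed)),
            class = "generator_spec")
}

#' Generate a decoy ensemble with known ground truth
#'
#' Each member is built residue by residue: position i keeps its base
#' conformation class with probability `1 - variability[i]` and otherwise
#' swaps to its alternative class, independently across positions and
#' members. Because the perturbation acts in local-conformation (dihedral
#' class) space, the exact generating per-position letter distribution is
#' known, making entropy recovery testable. Deterministic given
#' `spec$seed`.
#'
#' @param spec a [generator_spec()].
#' @return list with:
#'   * `ensemble`: the generated [ensemble];
#'   * `truth`: data frame with per-residue `base`, `alt` class,
#'     `p_alt` (= variability), `true_entropy` (nats, binary entropy of the
#'     base/alt mixture) and `flexible` (`TRUE` iff variability > 0);
#'   * `class_distribution`: n x 6 matrix of generating probabilities over
#'     the generator classes;
#'   * `coarse_distribution`: n x 3 matrix of the same probabilities
#'     collapsed onto the coarse \{H, E, L\} letters of [rama_alphabet()].
#' @export
make_decoy_ensemble <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- spec$n_residues
  base <- unname(syn_base_class(spec$ss))
  alt <- unname(syn_alt_class(base, spec$subtle))
  members <- with_seed(spec$seed, {
    lapply(seq_len(spec$n_members), function(k) {
      swap <- runif(n) < spec$variability
      cls <- ifelse(swap, alt, base)
      ang <- SYN_CLASSES[cls, , drop = FALSE]
      bb <- build_backbone(ang[, 1], ang[, 2])
      backbone_structure(bb$N, bb$CA, bb$C, bb$O)
    })
  })
  p <- spec$variability
  ent <- ifelse(p %in% c(0, 1), 0, -(p * log(p) + (1 - p) * log(1 - p)))
  cd <- matrix(0, n, nrow(SYN_CLASSES),
               dimnames = list(NULL, rownames(SYN_CLASSES)))
  cd[cbind(seq_len(n), match(base, rownames(SYN_CLASSES)))] <- 1 - p
  cd[cbind(seq_len(n), match(alt, rownames(SYN_CLASSES)))] <-
    cd[cbind(seq_len(n), match(alt, rownames(SYN_CLASSES)))] + p
  coarse <- sapply(c("H", "E", "L"), function(l) {
    rowSums(cd[, syn_coarse_letter(colnames(cd)) == l, drop = FALSE])
  })
  list(
    ensemble = ensemble(members),
    truth = data.frame(base = base, alt = alt, p_alt = p, true_entropy = ent,
                       flexible = p > 0),
    class_distribution = cd,
    coarse_distribution = matrix(coarse, nrow = n,
                                 dimnames = list(NULL, c("H", "E", "L")))
  )
}

#' Synthetic B-factors tied to true entropy
#'
#' `B_i = a * H_i + b + eps_i` with Gaussian noise `eps_i ~ N(0, noise_sd)`.
#' With `a > 0` and no noise the entropy-B-factor correlation is exactly 1.
#'
#' @param true_entropy per-residue entropies (nats).
#' @param noise_sd Gaussian noise standard deviation (angstrom^2).
#' @param seed integer seed.
#' @param a,b affine coefficients (defaults a = 20 A^2/nat, b = 10 A^2,
#'   typical crystallographic magnitudes).
#' @return numeric B-factor vector.
#' @export
make_synthetic_bfactors <- function(true_entropy, noise_sd = 0, seed = 1,
                                    a = 20, b = 10) {
  stopifnot(noise_sd >= 0)
  with_seed(seed, a * true_entropy + b + rnorm(length(true_entropy), 0, noise_sd))
}

#' Generate letter strings with neighbor correlation
#'
#' First-order Markov chains over the alphabet letters with a fixed
#' self-transition probability, emulating the strong correlation between
#' neighboring local structures that the second predictor layer exploits.
#'
#' @param n_chains number of proteins.
#' @param len residues per protein.
#' @param alphabet an [sa_alphabet].
#' @param stay self-transition probability.
#' @param seed integer seed.
#' @return list of [sa_encoding].
#' @export
make_markov_encodings <- function(n_chains, len, alphabet, stay = 0.85,
                                  seed = 1) {
  m <- alphabet$m
  with_seed(seed, {
    lapply(seq_len(n_chains), function(k) {
      x <- integer(len)
      x[1] <- sample.int(m, 1)
      for (i in seq_len(len - 1)) {
        x[i + 1] <- if (runif(1) < stay) x[i] else sample.int(m, 1)
      }
      sa_encoding(alphabet$letters[x], alphabet)
    })
  })
}

#' Synthetic sequence profiles carrying a local-structure signal
#'
#' Each residue's 20-component log-odds vector is Gaussian noise plus a
#' letter-specific offset pattern scaled by `signal_strength`, so the
#' letters are recoverable from profile windows; the per-letter patterns
#' are drawn once from the seed. Masked positions receive noise only.
#'
#' @param encodings list of [sa_encoding] providing the true letters.
#' @param signal_strength non-negative scale of the letter-dependent
#'   offset; 0 leaves pure noise (nothing learnable).
#' @param noise_sd SD of the additive Gaussian noise.
#' @param seed integer seed.
#' @return list of [sequence_profile].
#' @export
make_synthetic_profiles <- function(encodings, signal_strength = 1,
                                    noise_sd = 1, seed = 1) {
  stopifnot(signal_strength >= 0)
  if (inherits(encodings, "sa_encoding")) encodings <- list(encodings)
  letters_all <- encodings[[1]]$alphabet_letters
  with_seed(seed, {
    pattern <- matrix(rnorm(length(letters_all) * 20), length(letters_all), 20,
                      dimnames = list(letters_all, NULL))
    lapply(encodings, function(e) {
      lo <- matrix(rnorm(e$n * 20, 0, noise_sd), e$n, 20)
      hit <- e$letters != SA_MASK
      lo[hit, ] <- lo[hit, , drop = FALSE] +
        signal_strength * pattern[e$letters[hit], , drop = FALSE]
      sequence_profile(logistic(lo),
                       sequence = sample(PSSM_AA, e$n, replace = TRUE),
                       logodds = lo)
    })
  })
}
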