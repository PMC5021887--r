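# Synthetic generators: ideal backbones, decoy ensembles with known letter
# distributions, matched B-factors and learnable sequence profiles.

test_that("ideal backbones have the requested length and geometry", {
  s <- make_ideal_backbone("HHHHHHHHHH")
  expect_equal(s$n, 10)
  d <- compute_dihedrals(s)
  expect_true(all(abs(d[2:9, "phi"] + 57) < 1e-4))
  expect_true(all(abs(d[2:9, "psi"] + 47) < 1e-4))
  # i -> i+4 carbonyl-amide distances in the H-bonding range
  on <- sqrt(rowSums((s$O[1:6, ] - s$N[5:10, ])^2))
  expect_true(all(on > 2.5 & on < 3.5))
  expect_error(make_ideal_backbone(""), class = "saflex_empty_structure")
  expect_error(make_ideal_backbone("HXZ"), class = "saflex_bad_pattern")
  # coil is seeded
  c1 <- make_ideal_backbone("CCCCCC", seed = 5)
  c2 <- make_ideal_backbone("CCCCCC", seed = 5)
  expect_identical(c1$CA, c2$CA)
})

test_that("zero-variability ensembles are identical and all-rigid", {
  spec <- generator_spec("HHEEHHCC", variability = 0, n_members = 6, seed = 3)
  gen <- make_decoy_ensemble(spec)
  expect_length(gen$ensemble, 6)
  for (m in gen$ensemble$members[-1]) {
    expect_equal(m$CA, gen$ensemble$members[[1]]$CA)
  }
  expect_true(all(!gen$truth$flexible))
  expect_true(all(gen$truth$true_entropy == 0))
  encs <- lapply(gen$ensemble$members, encode_rama)
  expect_true(all(label_flexible_from_ensemble(encs) != "flexible"))
})

test_that("generating distributions and entropies are exact", {
  spec <- generator_spec(strrep("H", 10), variability = c(rep(0, 5), rep(0.5, 5)),
                         n_members = 4, seed = 1)
  gen <- make_decoy_ensemble(spec)
  expect_equal(gen$truth$true_entropy[6], log(2))
  expect_equal(gen$truth$true_entropy[1], 0)
  expect_equal(unname(gen$class_distribution[6, c("H", "E")]), c(0.5, 0.5))
  expect_equal(rowSums(gen$class_distribution), rep(1, 10))
  expect_equal(rowSums(gen$coarse_distribution), rep(1, 10))
  # subtle alternates stay in the same coarse class
  spec_s <- generator_spec(strrep("H", 4), variability = 0.5, subtle = TRUE,
                           n_members = 2, seed = 1)
  gen_s <- make_decoy_ensemble(spec_s)
  expect_equal(unname(gen_s$coarse_distribution[, "H"]), rep(1, 4))
  expect_equal(gen_s$truth$alt, rep("Ha", 4))
})

test_that("empirical letter frequencies concentrate on the generating law", {
  spec <- generator_spec(strrep("HEC", 8), variability = 0.3,
                         n_members = 2000, seed = 11)
  gen <- make_decoy_ensemble(spec)
  encs <- lapply(gen$ensemble$members, encode_rama)
  mat <- letter_matrix(encs)
  emp <- mat$freq[2:23, ]
  expected <- gen$coarse_distribution[2:23, colnames(emp)]
  expect_lt(max(abs(emp - expected)), 0.05)
})

test_that("ensembles are deterministic given the spec seed", {
  spec <- generator_spec("HHEECC", variability = 0.4, n_members = 5, seed = 12)
  g1 <- make_decoy_ensemble(spec)
  g2 <- make_decoy_ensemble(spec)
  expect_equal(g1$ensemble$members[[3]]$CA, g2$ensemble$members[[3]]$CA)
})

test_that("synthetic B-factors are affine in entropy with seeded noise", {
  h <- seq(0, log(3), length.out = 25)
  b0 <- make_synthetic_bfactors(h, noise_sd = 0)
  expect_equal(bfactor_correlation(entropy_profile(h), b0), 1)
  bneg <- make_synthetic_bfactors(h, noise_sd = 0, a = -20)
  expect_equal(bfactor_correlation(entropy_profile(h), bneg), -1)
  expect_identical(make_synthetic_bfactors(h, 2, seed = 7),
                   make_synthetic_bfactors(h, 2, seed = 7))
})

test_that("entropy/B-factor correlation decays monotonically with noise", {
  h <- seq(0, log(2), length.out = 40)
  mean_cor <- vapply(c(0.5, 4, 20), function(sd) {
    mean(vapply(1:20, function(seed) {
      b <- make_synthetic_bfactors(h, noise_sd = sd, seed = seed)
      bfactor_correlation(entropy_profile(h), b)
    }, 0))
  }, 0)
  expect_true(all(diff(mean_cor) < 0))
})

test_that("markov encodings and profiles are seeded and signal-bearing", {
  ab <- rama_alphabet()
  e1 <- make_markov_encodings(3, 50, ab, seed = 9)
  e2 <- make_markov_encodings(3, 50, ab, seed = 9)
  expect_identical(lapply(e1, `[[`, "letters"), lapply(e2, `[[`, "letters"))
  p1 <- make_synthetic_profiles(e1, seed = 10)
  p2 <- make_synthetic_profiles(e1, seed = 10)
  expect_identical(p1[[2]]$features, p2[[2]]$features)
  expect_true(all(p1[[1]]$features > 0 & p1[[1]]$features < 1))
})

test_that("zero signal strength leaves letters unlearnable", {
  ab <- rama_alphabet()
  encs <- make_markov_encodings(10, 60, ab, stay = 0.8, seed = 13)
  profs <- make_synthetic_profiles(encs, signal_strength = 0, seed = 14)
  tr <- 1:7; te <- 8:10
  model <- train_dual_layer(profs[tr], encs[tr], seed = 13)
  q <- mean(vapply(te, function(i) {
    q_score(predict_distribution(model, profs[[i]]), encs[[i]])
  }, 0))
  counts <- table(factor(unlist(lapply(encs[tr], `[[`, "letters")),
                         levels = ab$letters))
  base <- mean(vapply(te, function(i) {
    mean(encs[[i]]$letters == names(which.max(counts)))
  }, 0))
  expect_lt(abs(q - base), 0.12)
})

test_that("strong signal on a simple alphabet is almost perfectly learnable", {
  ab <- sa_alphabet("Toy2", c("H", "E"), "rule-based")
  set.seed(15)
  encs <- lapply(1:8, function(i) {
    sa_encoding(sample(c("H", "E"), 60, TRUE), ab)
  })
  profs <- make_synthetic_profiles(encs, signal_strength = 3, noise_sd = 0.5,
                                   seed = 16)
  model <- train_dual_layer(profs[1:6], encs[1:6], seed = 15)
  q <- mean(vapply(7:8, function(i) {
    q_score(predict_distribution(model, profs[[i]]), encs[[i]])
  }, 0))
  expect_gt(q, 0.9)
})
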