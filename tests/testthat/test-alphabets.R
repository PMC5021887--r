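# Alphabet containers, RMSDA assignment, PB encoding, Ramachandran classes
# and the trainable Cartesian fragment alphabet.

test_that("rmsda matches closed forms including periodic wrap", {
  v <- c(10, -170, 45, 0, 90, -90, 135, 180)
  expect_equal(rmsda(v, v), 0)
  w <- v; w[3] <- v[3] + 180
  expect_equal(rmsda(v, w), sqrt(180^2 / 8))
  u <- v; u[1] <- 179; t <- v; t[1] <- -179
  expect_equal(rmsda(u, t), sqrt(2^2 / 8))
  expect_error(rmsda(v, c(v, 1)), class = "saflex_length_mismatch")
  expect_error(rmsda(replace(v, 2, NA), v), class = "saflex_not_assignable")
})

test_that("bundled alphabets have the canonical letter counts", {
  expect_equal(sec_alphabet(3)$m, 3)
  expect_equal(sec_alphabet(8)$m, 8)
  pb <- pb_alphabet()
  expect_equal(pb$m, 16)
  expect_equal(dim(pb$prototypes), c(16, 8))
  expect_true(all(pb$prototypes > -180 & pb$prototypes <= 180))
  expect_equal(rama_alphabet()$m, 3)
  expect_false("-" %in% pb$letters)
})

test_that("pb_assign matches an exhaustive RMSDA scan on random fragments", {
  pb <- pb_alphabet()
  for (j in 1:16) {
    expect_equal(pb_assign(pb$prototypes[j, ], pb), pb$letters[j])
  }
  set.seed(21)
  for (r in 1:100) {
    ang <- runif(8, -180, 180)
    d <- vapply(1:16, function(j) rmsda(ang, pb$prototypes[j, ]), 0)
    expect_equal(pb_assign(ang, pb), pb$letters[which.min(d)])
  }
})

test_that("encode_pb masks termini and assigns the helical prototype to a helix", {
  pb <- pb_alphabet()
  s <- helix_structure(12)
  enc <- encode_pb(s, pb)
  expect_equal(enc$letters[c(1, 2, 11, 12)], rep("-", 4))
  interior <- enc$letters[3:10]
  # brute-force oracle over the bundled table for the repeated helix window
  helix_window <- c(-47, -57, -47, -57, -47, -57, -47, -57)
  d <- vapply(1:16, function(j) rmsda(helix_window, pb$prototypes[j, ]), 0)
  expect_true(all(interior == pb$letters[which.min(d)]))

  short <- helix_structure(5)
  enc5 <- encode_pb(short, pb)
  expect_equal(sum(enc5$letters != "-"), 1)
  expect_equal(which(enc5$letters != "-"), 3L)
  expect_true(all(encode_pb(helix_structure(4), pb)$letters == "-"))
})

test_that("a backbone realizing a prototype window is assigned that prototype", {
  pb <- pb_alphabet()
  for (j in c(1, 6, 13, 16)) {
    s <- structure_from_pb_window(pb$prototypes[j, ])
    enc <- encode_pb(s, pb)
    expect_equal(enc$letters[3], pb$letters[j])
    w <- saflex:::pb_window_angles(compute_dihedrals(s))[3, ]
    expect_lt(rmsda(w, pb$prototypes[j, ]), 1e-3)
  }
})

test_that("PB encoding is invariant under rigid transforms and re-encoding", {
  s <- make_ideal_backbone("CHHHHHECCEEH", seed = 6)
  e1 <- encode_pb(s)
  e2 <- encode_pb(rigid_transform(s))
  expect_identical(e1$letters, e2$letters)
  expect_identical(e1$letters, encode_pb(s)$letters)
})

test_that("encode_rama recovers generating dihedral classes per residue", {
  s <- make_ideal_backbone("HHEEHH", seed = 1)
  enc <- encode_rama(s)
  expect_equal(enc$letters, c("-", "H", "E", "E", "H", "-"))
})

test_that("fragment alphabet training honours m, L, determinism and centroids", {
  strs <- lapply(1:6, function(i) {
    make_ideal_backbone(paste(rep(c("H", "E", "C"), length.out = 25),
                              collapse = ""), seed = i)
  })
  a1 <- train_fragment_alphabet(strs, m = 5, L = 7, seed = 3)
  a2 <- train_fragment_alphabet(strs, m = 5, L = 7, seed = 3)
  expect_equal(a1$m, 5)
  expect_equal(a1$fragment_length, 7L)
  expect_identical(a1$prototypes, a2$prototypes)

  # m = 1: prototype is the generalized centroid of superposed fragments
  a0 <- train_fragment_alphabet(strs[1], m = 1, L = 5, seed = 1,
                                max_iter = 500) # run to the fixed point
  fr <- saflex:::ca_fragments(strs[[1]], 5)$mat
  proto <- matrix(a0$prototypes[1, ], 5)
  aligned <- lapply(seq_len(nrow(fr)), function(i) {
    X <- matrix(fr[i, ], 5)
    X %*% saflex:::kabsch_rotation(X, proto)
  })
  centroid <- Reduce(`+`, aligned) / length(aligned)
  centroid <- sweep(centroid, 2, colMeans(centroid))
  expect_lt(max(abs(centroid - proto)), 1e-4)

  expect_error(train_fragment_alphabet(strs[1], m = 100, L = 7),
               class = "saflex_insufficient_data")
})

test_that("fragment encoding is an argmin over superposed prototype RMSD", {
  strs <- lapply(1:5, function(i) {
    make_ideal_backbone(paste(sample(c("H", "E", "C"), 30, TRUE), collapse = ""),
                        seed = i)
  })
  set.seed(5)
  a <- train_fragment_alphabet(strs, m = 8, L = 7, seed = 2)
  s <- strs[[1]]
  enc <- encode_fragments(s, a)
  expect_equal(enc$letters[c(1:3, 28:30)], rep("-", 6))
  fr <- saflex:::ca_fragments(s, 7)
  for (k in seq_along(fr$centers)) {
    d <- vapply(seq_len(a$m), function(j) {
      saflex:::kabsch_rmsd_xyz(matrix(fr$mat[k, ], 7),
                               matrix(a$prototypes[j, ], 7))
    }, 0)
    expect_equal(enc$letters[fr$centers[k]], a$letters[which.min(d)])
  }
  # rigid-motion invariance and exact prototype recovery
  enc_rot <- encode_fragments(rigid_transform(s, 63, c(2, -1, 1)), a)
  expect_identical(enc$letters, enc_rot$letters)
  expect_equal(length(encode_fragments(make_ideal_backbone("HHHHHHH"), a)$letters[
    encode_fragments(make_ideal_backbone("HHHHHHH"), a)$letters != "-"]), 1L)
})

test_that("default fragment alphabet trains 28 prototypes of length 7", {
  strs <- lapply(1:8, function(i) {
    make_ideal_backbone(paste(sample(c("H", "E", "C"), 35, TRUE), collapse = ""),
                        seed = 10 + i)
  })
  set.seed(1)
  a <- train_fragment_alphabet(strs, seed = 4)
  expect_equal(a$m, 28)
  expect_equal(length(unique(a$letters)), 28)
  expect_equal(a$fragment_length, 7L)
})

test_that("encodings only contain alphabet letters or mask", {
  s <- make_ideal_backbone("CCHHHHHHEECC", seed = 8)
  for (ab in list(pb_alphabet(), sec_alphabet(3), sec_alphabet(8),
                  rama_alphabet())) {
    enc <- sa_encode(s, ab)
    expect_true(all(enc$letters %in% c(ab$letters, "-")))
    expect_equal(enc$n, s$n)
  }
  expect_error(sa_encoding(c("H", "Z"), sec_alphabet(3)),
               class = "saflex_bad_encoding")
})

test_that("SA strings round-trip through FASTA", {
  pb <- pb_alphabet()
  encs <- list(enc_str("--mmmmkl--", pb), enc_str("--ddddddd-", pb))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_sa_fasta(encs, f, names = c("one", "two"))
  back <- read_sa_fasta(f, pb)
  expect_equal(names(back), c("one", "two"))
  expect_identical(back$one$letters, encs[[1]]$letters)
  expect_identical(back$two$letters, encs[[2]]$letters)
})
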