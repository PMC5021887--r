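# Entropy/B-factor correlation, flexibility labeling, thresholding,
# confusion metrics, ROC and RMSD-uniform decoy selection.

test_that("bfactor_correlation matches the explicit summation formula", {
  h <- entropy_profile(c(0.2, 0.5, 0.9, 0.1, 0.7))
  expect_equal(bfactor_correlation(h, h$values), 1)
  expect_equal(bfactor_correlation(h, -h$values + 3), -1)
  set.seed(8)
  for (r in 1:20) {
    hv <- runif(30)
    b <- runif(30, 5, 60)
    expect_equal(bfactor_correlation(entropy_profile(hv), b),
                 cc_oracle(hv, b), tolerance = 1e-12)
  }
})

test_that("bfactor_correlation enforces its preconditions", {
  h <- entropy_profile(c(0.1, 0.2, NA, 0.4), mask = c(FALSE, FALSE, TRUE, FALSE))
  expect_error(bfactor_correlation(h, c(1, 2, 3)),
               class = "saflex_length_mismatch")
  expect_error(bfactor_correlation(entropy_profile(c(1, 2)), c(1, 2)),
               class = "saflex_insufficient_data")
  expect_error(bfactor_correlation(entropy_profile(rep(0.5, 5)), 1:5),
               class = "saflex_undefined_correlation")
  # masked positions are excluded pairwise
  expect_equal(bfactor_correlation(h, c(1, 2, 99, 4)),
               cc_oracle(c(0.1, 0.2, 0.4), c(1, 2, 4)))
})

test_that("flexible labels need a letter change across conformations", {
  ab <- sec_alphabet(3)
  encs <- list(enc_str("HHEC-", ab), enc_str("HHEH-", ab), enc_str("HCEH-", ab))
  lab <- label_flexible_from_ensemble(encs)
  expect_equal(lab, c("rigid", "flexible", "rigid", "flexible", "masked"))
  expect_error(label_flexible_from_ensemble(list(encs[[1]])),
               class = "saflex_insufficient_conformations")
  # {m,m,k}-style single change is flexible; mask does not count as a letter
  pb <- pb_alphabet()
  encs2 <- list(enc_str("mm", pb), enc_str("mm", pb), enc_str("km", pb))
  expect_equal(label_flexible_from_ensemble(encs2), c("flexible", "rigid"))
  encs3 <- list(enc_str("-m", pb), enc_str("mm", pb))
  expect_equal(label_flexible_from_ensemble(encs3), c("rigid", "rigid"))
})

test_that("mean_entropy_threshold pools residues, not proteins", {
  p1 <- entropy_profile(c(0, 0))
  p2 <- entropy_profile(c(1, 1, 1, 1))
  expect_equal(mean_entropy_threshold(list(p1, p2)), 4 / 6)
  expect_equal(mean_entropy_threshold(p2), 1)
  set.seed(4)
  ps <- lapply(1:3, function(i) {
    v <- runif(10)
    v[sample(10, 2)] <- NA
    entropy_profile(v)
  })
  pooled <- unlist(lapply(ps, function(p) p$values))
  expect_equal(mean_entropy_threshold(ps), mean(pooled, na.rm = TRUE))
  expect_error(mean_entropy_threshold(entropy_profile(c(NA_real_))),
               class = "saflex_insufficient_data")
})

test_that("threshold classification is strict and mask-preserving", {
  h <- entropy_profile(c(0.2, 0.9, 0.5, NA))
  expect_equal(classify_by_threshold(h, 0.5),
               c("rigid", "flexible", "rigid", "masked")) # boundary -> rigid
  expect_equal(classify_by_threshold(h, 2),
               c("rigid", "rigid", "rigid", "masked"))
})

test_that("confusion counts and metrics follow their exact definitions", {
  pred <- rep(c("flexible", "rigid"), c(10, 20))
  cm <- confusion(pred, pred)
  expect_equal(cm, list(TP = 10L, FP = 0L, TN = 20L, FN = 0L))
  truth <- rep("rigid", 7)
  cm2 <- confusion(rep("flexible", 7), truth)
  expect_equal(cm2$FP, 7L)
  expect_equal(cm2$TP + cm2$TN + cm2$FN, 0L)
  # random pair against a direct per-position tally
  set.seed(77)
  p <- sample(c("flexible", "rigid", "masked"), 200, TRUE)
  t <- sample(c("flexible", "rigid", "masked"), 200, TRUE)
  cm3 <- confusion(p, t)
  keep <- p != "masked" & t != "masked"
  expect_equal(cm3$TP, sum(p == "flexible" & t == "flexible" & keep))
  expect_equal(cm3$FN, sum(p == "rigid" & t == "flexible" & keep))
  expect_equal(cm3$TP + cm3$FP + cm3$TN + cm3$FN, sum(keep))

  expect_equal(unname(flex_metrics(list(TP = 5, FN = 5, TN = 0, FP = 0))[1]), 0.5)
  expect_equal(unname(flex_metrics(list(TP = 0, FN = 0, TN = 0, FP = 10))[2]), 0)
  expect_equal(unname(flex_metrics(list(TP = 30, FP = 90, TN = 0, FN = 0))[3]), 0.25)
  expect_true(is.na(flex_metrics(list(TP = 0, FP = 0, TN = 3, FN = 0))["precision"]))
})

test_that("ROC equals the Mann-Whitney pairwise statistic, including ties", {
  set.seed(10)
  for (r in 1:20) {
    n <- 200
    scores <- sample(seq(0, 1, by = 0.05), n, TRUE) # heavy ties
    truth <- sample(c("flexible", "rigid"), n, TRUE)
    if (length(unique(truth)) < 2) next
    roc <- roc_score(scores, truth)
    expect_equal(roc$auc, auc_pairwise(scores, truth), tolerance = 1e-12)
  }
})

test_that("ROC endpoints, monotonicity and degenerate cases behave", {
  truth <- rep(c("flexible", "rigid"), c(5, 10))
  perfect <- roc_score(c(rep(2, 5), rep(1, 10)), truth)
  expect_equal(perfect$auc, 1)
  inverted <- roc_score(c(rep(1, 5), rep(2, 10)), truth)
  expect_equal(inverted$auc, 0)
  pts <- perfect$points
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  expect_error(roc_score(1:5, rep("rigid", 5)), class = "saflex_undefined_roc")
})

test_that("ROC is invariant under strictly monotone score transforms", {
  set.seed(12)
  scores <- runif(120)
  truth <- sample(c("flexible", "rigid"), 120, TRUE)
  base <- roc_score(scores, truth)$auc
  expect_equal(roc_score(exp(3 * scores), truth)$auc, base, tolerance = 1e-12)
  expect_equal(roc_score(rank(scores), truth)$auc, base, tolerance = 1e-12)
})

test_that("ROC agrees with pROC as an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(19)
  scores <- round(runif(150), 2)
  truth <- sample(c("flexible", "rigid"), 150, TRUE)
  mine <- roc_score(scores, truth)$auc
  ref <- suppressMessages(as.numeric(pROC::auc(
    pROC::roc(response = truth == "flexible", predictor = scores,
              direction = "<", quiet = TRUE))))
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("uniform decoy selection caps bins deterministically", {
  native <- make_ideal_backbone(strrep("H", 20))
  spec <- generator_spec(strrep("H", 20), variability = 0.25,
                         n_members = 40, seed = 2)
  ens <- make_decoy_ensemble(spec)$ensemble
  sel1 <- select_uniform_decoys(ens, native, per_bin = 5, seed = 9)
  sel2 <- select_uniform_decoys(ens, native, per_bin = 5, seed = 9)
  expect_identical(sel1$ensemble$source_labels, sel2$ensemble$source_labels)
  expect_true(all(table(sel1$bin) <= 5))
  expect_equal(sel1$bin, findInterval(sel1$rmsd, c(0, 3, 4, 5, 6, Inf)))
  # per_bin above every bin count returns the whole ensemble
  all_sel <- select_uniform_decoys(ens, native, per_bin = 1000, seed = 1)
  expect_equal(length(all_sel$ensemble), length(ens))
})
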