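test_that("feature preparation standardises by train and rotates by PCA", {
  set.seed(101)
  # full-rank orthonormal-ish features: the transform is a rotation, so
  # pairwise distances survive
  tr <- matrix(rnorm(40 * 10), 40, 10)
  te <- matrix(rnorm(12 * 10), 12, 10)
  out <- prepare_features(tr, te, n_components = 10)
  std <- scale(tr)
  d_before <- dist(std)
  d_after <- dist(out$train)
  expect_equal(as.vector(d_after), as.vector(d_before), tolerance = 1e-10)
  # deterministic sign: recomputation is identical
  out2 <- prepare_features(tr, te, n_components = 10)
  expect_identical(out, out2)
  # rank-deficient request errors
  lowrank <- tr[, 1:5] %*% matrix(rnorm(5 * 20), 5, 20)
  expect_error(prepare_features(lowrank, lowrank[1:2, ], 10),
               "insufficient rank")
  expect_error(prepare_features(tr, te, 40), "insufficient rank")
  # explained variance matches the eigendecomposition oracle
  sv_scores <- prepare_features(tr, te, 3)$train
  ev <- eigen(cov(std), symmetric = TRUE)$values[1:3] * (nrow(tr) - 1)
  expect_equal(colSums(sv_scores^2), ev, tolerance = 1e-8)
})

test_that("encoding predictions match the normal-equations oracle", {
  set.seed(102)
  n_tr <- 30; n_te <- 8; p <- 4; V <- 20
  Xtr <- matrix(rnorm(n_tr * p), n_tr, p)
  Xte <- matrix(rnorm(n_te * p), n_te, p)
  Ytr <- matrix(rnorm(n_tr * V), n_tr, V)
  te_betas <- array(rnorm(n_te * 3 * V), c(n_te, 3, V))
  enc <- fit_encode_predict(Xtr, Ytr, Xte, te_betas)
  X1 <- cbind(1, Xtr)
  B <- solve(t(X1) %*% X1, t(X1) %*% Ytr)
  pred <- cbind(1, Xte) %*% B
  expect_equal(enc$pred, pred, tolerance = 1e-8, ignore_attr = TRUE)
  # per-repetition correlation averaging oracle
  for (v in c(1, 7, 20)) {
    want <- mean(sapply(1:3, function(r) cor(pred[, v], te_betas[, r, v])))
    expect_equal(enc$raw[v], want, tolerance = 1e-10)
  }
})

test_that("noiseless linear ground truth is recovered with correlation 1", {
  truth <- synth_truth(n_train = 40, n_test = 12, grid = c(4, 4, 4), k = 5,
                       noise_sd = 0, trial_noise_sd = 0, reliable_frac = 0.5,
                       seed = 103)
  trb <- simulate_beta_tensor(truth, "train", 3, seed = 104)
  teb <- simulate_beta_tensor(truth, "test", 10, seed = 105)
  feats <- prepare_features(
    cbind(truth$latent1[1:40, ], truth$latent3[1:40, ]),
    cbind(truth$latent1[41:52, ], truth$latent3[41:52, ]), 10)
  enc <- fit_encode_predict(feats$train,
                            summarize_betas(trb, zscore = FALSE),
                            feats$test,
                            summarize_betas(teb, zscore = FALSE,
                                            average_reps = FALSE),
                            voxel_mask = truth$reliable_voxel_mask)
  expect_true(all(enc$raw[truth$reliable_voxel_mask] > 1 - 1e-6))
  expect_true(all(is.na(enc$raw[!truth$reliable_voxel_mask])))
})

test_that("features unrelated to the brain give near-zero mean correlation", {
  set.seed(106)
  V <- 500
  Xtr <- matrix(rnorm(50 * 5), 50, 5)
  Xte <- matrix(rnorm(20 * 5), 20, 5)
  Ytr <- matrix(rnorm(50 * V), 50, V)
  te_betas <- array(rnorm(20 * 10 * V), c(20, 10, V))
  enc <- fit_encode_predict(Xtr, Ytr, Xte, te_betas)
  expect_lt(abs(mean(enc$raw)), 0.05)
})

test_that("prediction accuracy rises monotonically with SNR", {
  cors <- vapply(c(4, 1.5, 0.5), function(ns) {
    truth <- synth_truth(n_train = 40, n_test = 12, grid = c(4, 4, 4), k = 5,
                         noise_sd = ns, trial_noise_sd = ns / 2,
                         reliable_frac = 0.5, seed = 107)
    trb <- simulate_beta_tensor(truth, "train", 3, seed = 108)
    teb <- simulate_beta_tensor(truth, "test", 10, seed = 109)
    feats <- prepare_features(
      cbind(truth$latent1[1:40, ], truth$latent3[1:40, ]),
      cbind(truth$latent1[41:52, ], truth$latent3[41:52, ]), 10)
    enc <- fit_encode_predict(feats$train, summarize_betas(trb),
                              feats$test,
                              summarize_betas(teb, average_reps = FALSE),
                              voxel_mask = truth$reliable_voxel_mask)
    mean(enc$raw, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
})

test_that("repetition-wise and repetition-mean evaluation differ only with noise", {
  # noiseless: correlating against each repetition equals correlating
  # against the repetition mean
  truth <- synth_truth(n_train = 20, n_test = 8, grid = c(3, 3, 3), k = 3,
                       noise_sd = 0, trial_noise_sd = 0, reliable_frac = 0.8,
                       seed = 110)
  trb <- simulate_beta_tensor(truth, "train", 3, seed = 111)
  teb <- simulate_beta_tensor(truth, "test", 10, seed = 112)
  feats <- prepare_features(
    cbind(truth$latent1[1:20, ], truth$latent3[1:20, ]),
    cbind(truth$latent1[21:28, ], truth$latent3[21:28, ]), 6)
  per_rep <- summarize_betas(teb, zscore = FALSE, average_reps = FALSE)
  enc <- fit_encode_predict(feats$train, summarize_betas(trb, zscore = FALSE),
                            feats$test, per_rep)
  rel <- truth$reliable_voxel_mask
  rep_mean <- apply(per_rep, c(1, 3), mean)
  mean_cor <- eventfmri:::colwise_cor(enc$pred, rep_mean)
  expect_equal(enc$raw[rel], mean_cor[rel], tolerance = 1e-8)
  # with noise, per-repetition averaging is strictly attenuated relative
  # to correlation against the mean
  set.seed(113)
  noisy <- per_rep + array(rnorm(length(per_rep), sd = 2), dim(per_rep))
  enc_n <- fit_encode_predict(feats$train,
                              summarize_betas(trb, zscore = FALSE),
                              feats$test, noisy)
  mean_cor_n <- eventfmri:::colwise_cor(enc_n$pred, apply(noisy, c(1, 3), mean))
  expect_true(mean(enc_n$raw[rel]) < mean(mean_cor_n[rel]))
})

test_that("noise normalisation divides by the pre-correction split-half rho", {
  rel <- structure(list(rho = c(0.6, 0.3, -0.1, 0.5), sb = NULL),
                   class = "reliability_map")
  res <- structure(list(raw = c(0.3, 0.3, 0.2, 0.5)),
                   class = "encoding_result")
  out <- noise_normalize(res, rel)
  expect_equal(out$normalized[1], 0.5)
  expect_equal(out$normalized[2], 1)
  expect_true(is.na(out$normalized[3]))
  expect_equal(out$normalized[4], 1)
  expect_identical(attr(out$normalized, "n_excluded"), 1L)
})

test_that("shuffled-feature results average voxelwise", {
  r1 <- structure(list(raw = c(0.2, 0.4), voxel_mask = c(TRUE, TRUE),
                       normalized = c(0.4, 0.8)), class = "encoding_result")
  r2 <- structure(list(raw = c(0.4, 0.0), voxel_mask = c(TRUE, TRUE),
                       normalized = c(0.8, 0.0)), class = "encoding_result")
  avg <- average_encoding_results(list(r1, r2))
  expect_equal(avg$raw, c(0.3, 0.2))
  expect_equal(avg$normalized, c(0.6, 0.4))
})

test_that("feature-set contrasts respect the correction scheme", {
  set.seed(114)
  V <- 60
  rois <- list(a = c(rep(TRUE, 20), rep(FALSE, 40)),
               b = c(rep(FALSE, 20), rep(TRUE, 20), rep(FALSE, 20)),
               c = c(rep(FALSE, 40), rep(TRUE, 20)))
  A <- matrix(rnorm(10 * V, sd = 0.05), 10, V)
  B <- A
  same <- contrast_feature_sets(A, B, rois)
  expect_true(all(same$mean_diff == 0))
  expect_false(any(same$significant))
  # +0.2 difference in ROI a across 10 subjects, sd 0.05
  A2 <- A; A2[, rois$a] <- A2[, rois$a] + 0.2
  shifted <- contrast_feature_sets(A2, B, rois, correction = "bonferroni",
                                   m = 22)
  expect_true(shifted$significant[shifted$roi == "a"])
  expect_false(any(shifted$significant[shifted$roi != "a"]))
  fdr <- contrast_feature_sets(A2, B, rois, correction = "fdr", m = 88)
  expect_true(fdr$significant[fdr$roi == "a"])
})
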