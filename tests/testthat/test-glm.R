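make_series <- function(mat, tr_s) {
  attr(mat, "tr_s") <- tr_s
  class(mat) <- c("volume_series", class(mat))
  mat
}

test_that("cubic resampling is exact on polynomials and accurate on sines", {
  n <- 60
  times <- (seq_len(n) - 1) * 1.75
  const <- make_series(matrix(3.7, n, 2), 1.75)
  rc <- resample_timeseries(const)
  expect_true(all(abs(rc - 3.7) < 1e-12))
  expect_identical(nrow(rc), as.integer(floor(times[n]) + 1))
  ramp <- make_series(cbind(2 + 0.5 * times, -1 + times), 1.75)
  rr <- resample_timeseries(ramp)
  tnew <- seq_len(nrow(rr)) - 1
  expect_equal(rr[, 1], 2 + 0.5 * tnew, tolerance = 1e-10)
  expect_equal(rr[, 2], -1 + tnew, tolerance = 1e-10)
  sine <- make_series(cbind(sin(2 * pi * times / 32)), 1.75)
  rs <- resample_timeseries(sine)
  inner <- 5:(nrow(rs) - 5)  # away from the boundary extrapolation region
  expect_lt(max(abs(rs[inner, 1] - sin(2 * pi * (inner - 1) / 32))), 1e-3)
  expect_error(resample_timeseries(make_series(matrix(0, 3, 1), 1.75)),
               "too few")
  expect_error(resample_timeseries(make_series(matrix(0, 30, 1), 1)),
               "exceed")
})

test_that("FIR design places one indicator per trial-delay inside the run", {
  ev <- data.frame(onset = 4, duration = 4, condition = "test0001",
                   repetition = 1L)
  X <- build_fir_design(ev, n_volumes = 20L)
  expect_identical(dim(unclass(X)), c(20L, 9L))
  for (d in 1:9) {
    expect_identical(sum(X[, d]), 1)
    expect_identical(which(X[, d] == 1), 4L + d + 1L)
  }
  # delays past the run end are truncated and flagged, not dropped
  late <- data.frame(onset = c(4, 16), duration = 4,
                     condition = c("a", "b"), repetition = 1L)
  Xl <- build_fir_design(late, n_volumes = 20L)
  expect_identical(ncol(unclass(Xl)), 18L)
  tr <- attr(Xl, "truncated")
  expect_identical(sum(tr), 6L)  # onsets 16 + delays 4..9 exceed volume 20
  expect_error(build_fir_design(data.frame(onset = 4.3, duration = 4,
                                           condition = "a", repetition = 1L),
                                20L), "misaligned")
})

test_that("neighbouring trials at 4 s spacing alias FIR columns", {
  # delays of trials 4 s apart land on shared volumes: the 18 columns span
  # only the 13 distinct volumes onset+1 .. onset+13, so the rank is 13
  # and trial-wise least squares is rejected as unidentifiable
  ev <- data.frame(onset = c(4, 8), duration = 4, condition = c("a", "b"),
                   repetition = 1L)
  X <- build_fir_design(ev, n_volumes = 24L)
  expect_identical(qr(unclass(X))$rank, 13L)
  y <- make_series(matrix(rnorm(24), 24, 1), 1)
  expect_error(fit_fir_glm(y, X, ar1 = FALSE), "rank-deficient")
})

test_that("the high-pass projection removes the cosine set and is idempotent", {
  n <- 300
  basis <- dct_highpass_basis(n, 1, 128)
  expect_gt(ncol(basis), 0)
  y <- matrix(rnorm(n * 3), n, 3)
  f1 <- eventfmri:::highpass_project(y, basis)
  f2 <- eventfmri:::highpass_project(f1, basis)
  expect_equal(f1, f2, tolerance = 1e-10)
  expect_lt(max(abs(crossprod(basis, f1))), 1e-8)
  drift <- basis %*% matrix(rnorm(ncol(basis) * 2), ncol(basis), 2)
  expect_lt(max(abs(eventfmri:::highpass_project(drift, basis))), 1e-8)
})

test_that("noiseless GLM recovery is exact and drift-only data gives zero betas", {
  truth <- synth_truth(n_train = 8, n_test = 4, grid = c(3, 3, 3), k = 3,
                       noise_sd = 0, trial_noise_sd = 0, drift_sd = 0,
                       epoch_lag_s = 2, seed = 31)
  sched <- build_session_schedule(8, 4, 1, 2, 2, seed = 32, trial_s = 12)
  runs <- generate_dataset(sched, truth, seed = 33, tr_s = 1, hrf_trunc_s = 7)
  bt <- fit_beta_tensor(runs, run_types = c("train", "test"), ar1 = FALSE)
  h1 <- hrf_double_gamma(1:9, trunc_s = 7)
  h3 <- hrf_double_gamma(1:9 - 2, trunc_s = 7)
  ids <- dimnames(bt)[[1]]
  amp1 <- eventfmri:::truth_amplitudes(truth, ids, 1L)
  amp3 <- eventfmri:::truth_amplitudes(truth, ids, 3L)
  worst <- 0
  for (d in 1:9) for (r in seq_len(dim(bt)[2])) {
    got <- bt[, r, d, ]
    ok <- !is.na(got[, 1])
    worst <- max(worst, max(abs(got[ok, ] - (amp1 * h1[d] + amp3 * h3[d])[ok, ])))
  }
  expect_lt(worst, 1e-6)
  # drift below the cutoff and no stimulus-locked signal: betas vanish
  # (the noiseless stimulus component is deterministic, so the run-wise
  # difference of a drifting and a drift-free dataset is pure drift)
  pure_sig <- generate_dataset(sched, truth, seed = 36, tr_s = 1,
                               hrf_trunc_s = 7, noise_sd = 0, drift_sd = 0,
                               trial_noise_sd = 0)
  with_drift <- generate_dataset(sched, truth, seed = 37, tr_s = 1,
                                 hrf_trunc_s = 7, noise_sd = 0, drift_sd = 2,
                                 trial_noise_sd = 0)
  drift_only <- lapply(seq_along(pure_sig), function(i) {
    y <- unclass(with_drift[[i]]) - unclass(pure_sig[[i]])
    for (a in c("tr_s", "run_type", "run", "session", "grid", "events"))
      attr(y, a) <- attr(pure_sig[[i]], a)
    class(y) <- c("volume_series", class(y))
    y
  })
  bt0 <- fit_beta_tensor(drift_only, run_types = c("train", "test"),
                         ar1 = FALSE)
  expect_lt(max(abs(bt0), na.rm = TRUE), 1e-6)
})

test_that("the FIR beta estimator is unbiased under white noise", {
  ev <- data.frame(onset = seq(4, by = 12, length.out = 6), duration = 12,
                   condition = paste0("c", 1:6), repetition = 1L)
  n_vol <- 100L
  X <- build_fir_design(ev, n_vol)
  set.seed(44)
  betas <- replicate(150, {
    y <- make_series(matrix(rnorm(n_vol * 4), n_vol, 4), 1)
    fit_fir_glm(y, X, ar1 = FALSE)[1, ]
  })
  m <- mean(betas)
  se <- stats::sd(betas) / sqrt(length(betas))
  expect_lt(abs(m), 2 * se + 1e-8)
})

test_that("beta summaries average the peak window and guard degenerate variance", {
  bt <- array(0, c(4, 2, 9, 3), dimnames = list(paste0("s", 1:4), NULL,
                                                1:9, NULL))
  bt[] <- seq_len(length(bt))
  class(bt) <- c("beta_tensor", "array")
  attr(bt, "delays") <- 1:9
  raw <- summarize_betas(bt, zscore = FALSE, average_reps = TRUE)
  # brute-force mean over delays 5..9 and both repetitions
  brute <- apply(bt[, , 5:9, , drop = FALSE], c(1, 4), mean)
  expect_equal(unclass(raw), brute, ignore_attr = TRUE)
  # all-equal betas: z-score maps to 0 instead of dividing by zero
  flat <- bt; flat[] <- 7
  z <- summarize_betas(flat, zscore = TRUE)
  expect_true(all(z == 0))
  expect_error(summarize_betas(bt, delay_window = c(10, 12)), "out of range")
  # z-scored independent noise averaged over 10 reps has SD near 1/sqrt(10)
  noisy <- array(rnorm(200 * 10 * 9 * 2), c(200, 10, 9, 2))
  class(noisy) <- c("beta_tensor", "array")
  attr(noisy, "delays") <- 1:9
  zz <- summarize_betas(noisy, delay_window = c(5, 5), average_reps = TRUE)
  expect_equal(sd(zz[, 1]), 1 / sqrt(10), tolerance = 0.15)
})

test_that("beta summaries commute with stimulus relabeling", {
  set.seed(51)
  bt <- array(rnorm(6 * 3 * 9 * 4), c(6, 3, 9, 4),
              dimnames = list(paste0("s", 1:6), NULL, 1:9, NULL))
  class(bt) <- c("beta_tensor", "array"); attr(bt, "delays") <- 1:9
  perm <- sample(6)
  btp <- bt[perm, , , , drop = FALSE]
  class(btp) <- c("beta_tensor", "array"); attr(btp, "delays") <- 1:9
  expect_equal(unclass(summarize_betas(btp)),
               unclass(summarize_betas(bt))[perm, ], ignore_attr = TRUE)
})

test_that("the localizer GLM recovers category selectivity and calibrates", {
  tr <- 1.75
  n_vol <- 268L
  onsets <- seq(18, by = 18, length.out = 20)
  cats <- rep(c("faces", "bodies", "scenes", "objects", "scrambled"), 4)
  ev <- data.frame(onset = onsets, duration = 18, condition = cats)
  times <- (seq_len(n_vol) - 1) * tr
  face_sig <- rowSums(sapply(onsets[cats == "faces"], function(o)
    eventfmri:::hrf_block_response(times, o, 18)))
  set.seed(61)
  y <- cbind(face_sig * 2 + rnorm(n_vol, sd = 0.5),
             matrix(rnorm(n_vol * 1000, sd = 1), n_vol, 1000))
  y <- make_series(y, tr)
  cons <- list(faces_gt_objects = c(faces = 1, objects = -1),
               scenes_gt_objects = c(scenes = 1, objects = -1),
               all_gt_baseline = c(objects = 0.5, scrambled = 0.5))
  tmaps <- fit_localizer_glm(y, ev, cons)
  expect_gt(tmaps[1, "faces_gt_objects"], 10)
  expect_lt(abs(tmaps[1, "scenes_gt_objects"]), 3)
  # null voxels: ~5% exceed the two-sided 0.05 t threshold
  df <- attr(tmaps, "df")
  crit <- qt(0.975, df)
  frac <- mean(abs(tmaps[-1, "faces_gt_objects"]) > crit)
  expect_lt(abs(frac - 0.05), 0.02)
  # contrast sign flip negates t exactly
  neg <- fit_localizer_glm(y, ev, list(o_gt_f = c(faces = -1, objects = 1)))
  expect_equal(neg[, 1], -tmaps[, "faces_gt_objects"], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(fit_localizer_glm(y, ev, list(bad = c(houses = 1))),
               "unknown contrast")
})
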