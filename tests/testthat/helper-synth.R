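# shared fixture builders: everything is generated in code at test time

# per-TR summarised betas [stimulus, TR, voxel] from a beta tensor
make_per_tr <- function(bt, zscore = TRUE) {
  d <- dim(bt)
  out <- array(0, c(d[1], d[3], d[4]))
  for (k in seq_len(d[3]))
    out[, k, ] <- summarize_betas(bt, delay_window = c(k, k), zscore = zscore)
  out
}

# one subject's unique-variance curves under a shared-stimulus truth
varpart_curves <- function(truth, seed_train, seed_test, radius = 2) {
  n_tr <- truth$n_train
  n_te <- truth$n_test
  tr_bt <- simulate_beta_tensor(truth, "train", 3, seed = seed_train)
  te_bt <- simulate_beta_tensor(truth, "test", 10, seed = seed_test)
  tr_per <- make_per_tr(tr_bt)
  te_per <- make_per_tr(te_bt)
  f1 <- prepare_features(truth$latent1[seq_len(n_tr), , drop = FALSE],
                         truth$latent1[n_tr + seq_len(n_te), , drop = FALSE],
                         truth$k)
  f3 <- prepare_features(truth$latent3[seq_len(n_tr), , drop = FALSE],
                         truth$latent3[n_tr + seq_len(n_te), , drop = FALSE],
                         truth$k)
  syn <- epoch_encode(list(f1$train, f3$train), list(f1$test, f3$test), tr_per)
  unique_variance(te_per, syn[[1]], syn[[2]], grid = truth$grid,
                  searchlight_radius = radius)
}

# subject-by-voxel pooled (train + test) amplitude summaries for one truth
pooled_betas_subject <- function(truth, seed) {
  trb <- simulate_beta_tensor(truth, "train", 3, seed = seed)
  teb <- simulate_beta_tensor(truth, "test", 10, seed = seed + 1000L)
  rbind(summarize_betas(trb), summarize_betas(teb))
}
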