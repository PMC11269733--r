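# Voxelwise encoding: train-set standardisation, PCA compression to 100
# components, per-voxel OLS from features to betas, repetition-wise
# evaluation on the testing set, noise normalisation by the split-half
# correlation, and ROI contrasts between feature sets.

#' Standardise and PCA-compress a train/test feature pair
#'
#' Centres and scales both matrices by the training-set mean and standard
#' deviation, fits a PCA on the training set, and projects both sets onto
#' the top `n_components` components. Component signs are fixed by making
#' the largest-magnitude loading of each component positive, so the
#' transform is deterministic.
#'
#' @param train,test Stimuli-by-features matrices sharing a feature space.
#' @param n_components Number of components to keep (default 100).
#' @return List with compressed `train` and `test` score matrices, the
#'   `rotation`, and the standardisation statistics.
#' @export
prepare_features <- function(train, test, n_components = 100L) {
  train <- as.matrix(train); test <- as.matrix(test)
  if (ncol(train) != ncol(test)) stop("train and test feature dimensions differ")
  if (n_components > min(nrow(train) - 1L, ncol(train)))
    stop("insufficient rank: n_components exceeds min(n_train - 1, n_features)")
  mu <- colMeans(train)
  sdv <- apply(train, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  std <- function(m) sweep(sweep(m, 2L, mu, "-"), 2L, sdv, "/")
  tr <- std(train)
  sv <- svd(tr, nu = 0, nv = n_components)
  if (sum(sv$d > sv$d[1] * 1e-10) < n_components)
    stop("insufficient rank: feature matrix rank below n_components")
  rot <- sv$v
  flip <- apply(rot, 2L, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(rot, 2L, flip, "*")
  list(train = tr %*% rot, test = std(test) %*% rot, rotation = rot,
       center = mu, scale = sdv)
}

#' Fit a voxelwise linear encoding model and evaluate on repetitions
#'
#' Fits per-voxel ordinary least squares (with intercept) from training
#' features to repetition-averaged training betas, predicts the testing
#' stimuli, Pearson-correlates the prediction with each of the held-out
#' repetitions separately, and averages the per-repetition correlations.
#'
#' @param train_feats Training stimuli x components.
#' @param train_betas Training stimuli x voxels (repetition-averaged,
#'   z-scored, delay-averaged).
#' @param test_feats Testing stimuli x components.
#' @param test_betas Array `[test stimulus, repetition, voxel]`.
#' @param voxel_mask Optional logical mask restricting evaluation to
#'   (reliability-selected) voxels; others return NA.
#' @return An `encoding_result` list: `raw` (per-voxel mean correlation),
#'   `per_rep` (repetition x voxel), `pred` (test predictions),
#'   `normalized` (NULL until [noise_normalize()]).
#' @export
fit_encode_predict <- function(train_feats, train_betas, test_feats,
                               test_betas, voxel_mask = NULL) {
  stopifnot(nrow(train_feats) == nrow(train_betas),
            length(dim(test_betas)) == 3L,
            ncol(train_betas) == dim(test_betas)[3])
  n_vox <- ncol(train_betas)
  if (is.null(voxel_mask)) voxel_mask <- rep(TRUE, n_vox)
  X <- cbind(1, train_feats)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("singular fit: compressed features are rank deficient")
  B <- qr.coef(qx, train_betas[, voxel_mask, drop = FALSE])
  pred <- cbind(1, test_feats) %*% B
  n_rep <- dim(test_betas)[2]
  per_rep <- matrix(NA_real_, n_rep, n_vox)
  for (r in seq_len(n_rep)) {
    obs <- matrix(test_betas[, r, voxel_mask], dim(test_betas)[1])
    per_rep[r, voxel_mask] <- colwise_cor(pred, obs)
  }
  raw <- colMeans(per_rep)
  pred_full <- matrix(NA_real_, nrow(test_feats), n_vox)
  pred_full[, voxel_mask] <- pred
  structure(list(raw = raw, per_rep = per_rep, pred = pred_full,
                 voxel_mask = voxel_mask, normalized = NULL),
            class = "encoding_result")
}

#' Noise-normalise encoding correlations
#'
#' Divides each voxel's mean prediction correlation by its mean split-half
#' correlation (the Pearson value before Spearman-Brown correction),
#' expressing performance as a fraction of the explainable signal. Voxels
#' with non-positive split-half correlation are excluded (NA) and counted
#' in attribute `n_excluded`. Values above 1 are reported unclipped.
#'
#' @param result An `encoding_result`.
#' @param reliability A `reliability_map` with the `rho` field.
#' @return The `encoding_result` with `normalized` filled in.
#' @export
noise_normalize <- function(result, reliability) {
  rho <- reliability$rho
  if (length(rho) != length(result$raw))
    stop("reliability map and encoding result cover different voxels")
  ok <- is.finite(rho) & rho > 0
  norm <- rep(NA_real_, length(rho))
  norm[ok] <- result$raw[ok] / rho[ok]
  result$normalized <- norm
  attr(result$normalized, "n_excluded") <- sum(!ok & is.finite(result$raw))
  result
}

#' Average encoding results over shuffled feature sets
#'
#' Feature shuffling upstream produces one feature matrix per random
#' order; their encoding results are combined by averaging the per-voxel
#' correlations, giving the mean shuffled performance that the unshuffled
#' result is contrasted against.
#'
#' @param results List of `encoding_result` objects on the same voxels.
#' @return An `encoding_result` with averaged `raw` (and `normalized` when
#'   present in all inputs).
#' @export
average_encoding_results <- function(results) {
  stopifnot(length(results) >= 1L)
  raw <- rowMeans(sapply(results, function(r) r$raw))
  norm <- if (all(vapply(results, function(r) !is.null(r$normalized),
                         logical(1))))
    rowMeans(sapply(results, function(r) r$normalized)) else NULL
  structure(list(raw = raw, per_rep = NULL, pred = NULL,
                 voxel_mask = results[[1]]$voxel_mask, normalized = norm),
            class = "encoding_result")
}

#' Contrast two feature sets' encoding performance across ROIs
#'
#' Per subject and ROI, averages the (noise-normalised) correlations of
#' each feature set over in-ROI voxels and takes the difference A - B;
#' a one-sample two-sided t-test across subjects is then corrected either
#' by Bonferroni over the ROI count or by Benjamini-Hochberg FDR over `m`
#' comparisons (e.g. 88 = 22 ROIs x 4 network blocks when the caller pools
#' blocks).
#'
#' @param resultsA,resultsB Subject-by-voxel matrices of per-voxel
#'   correlations for the two feature sets.
#' @param rois Named list of logical voxel masks.
#' @param correction `"bonferroni"` or `"fdr"`.
#' @param m Number of comparisons for the correction (default: number of
#'   ROIs).
#' @param alpha Significance level (default 0.05).
#' @return Data frame: `roi`, `mean_diff`, `t`, `p`, `significant`.
#' @export
contrast_feature_sets <- function(resultsA, resultsB, rois,
                                  correction = c("bonferroni", "fdr"),
                                  m = NULL, alpha = 0.05) {
  correction <- match.arg(correction)
  stopifnot(identical(dim(resultsA), dim(resultsB)))
  if (is.null(m)) m <- length(rois)
  rows <- lapply(names(rois), function(nm) {
    mask <- rois[[nm]]
    diffs <- vapply(seq_len(nrow(resultsA)), function(s)
      mean(resultsA[s, mask], na.rm = TRUE) -
        mean(resultsB[s, mask], na.rm = TRUE), numeric(1))
    tt <- group_ttest(diffs, mu0 = 0, sides = "two")
    data.frame(roi = nm, mean_diff = mean(diffs), t = tt$statistic, p = tt$p)
  })
  out <- do.call(rbind, rows)
  out$significant <- if (correction == "bonferroni") out$p < alpha / m
  else stats::p.adjust(out$p, method = "BH", n = max(m, nrow(out))) < alpha
  out
}
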