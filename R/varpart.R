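# Variance partitioning of within-video temporal epochs: per-TR encoding
# from first- and third-second features, unique adjusted-R2 of each epoch
# predictor, and peak-TR difference statistics.

#' Adjusted R-squared
#'
#' `1 - (1 - R2) * (n - 1) / (n - p - 1)`; e.g. R2 = 0.5 at n = 102
#' observations and p = 2 predictors gives 0.4899.
#'
#' @param r2 Coefficient of determination.
#' @param n Number of observations.
#' @param p Number of predictors (excluding the intercept).
#' @return Adjusted R-squared (may be negative).
#' @export
adjusted_r2 <- function(r2, n, p) {
  if (n <= p + 1) stop("n must exceed p + 1 for adjusted R-squared")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

# R2 of OLS with intercept, y ~ X
r2_ols <- function(y, X) {
  Xd <- cbind(1, X)
  fit <- qr.coef(qr(Xd), y)
  res <- y - Xd %*% fit
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(NA_real_)
  1 - sum(res^2) / tss
}

#' Per-TR epoch encoding producing synthetic test responses
#'
#' For each TR and epoch independently, fits a linear regression (with
#' intercept) from that epoch's training features to the
#' repetition-averaged training betas at that TR, then predicts the
#' testing stimuli, yielding one synthetic test-response instance per
#' epoch of shape `[test stimulus, TR, voxel]`.
#'
#' @param train_feats List of two stimuli-by-component matrices (epoch 1
#'   and epoch 3 training features).
#' @param test_feats List of two matching testing feature matrices.
#' @param train_betas Array `[train stimulus, TR, voxel]` of
#'   repetition-averaged betas on the full delay grid.
#' @return List of two `[test stimulus, TR, voxel]` arrays.
#' @export
epoch_encode <- function(train_feats, test_feats, train_betas) {
  stopifnot(length(train_feats) == 2L, length(test_feats) == 2L,
            length(dim(train_betas)) == 3L)
  n_tr <- dim(train_betas)[2]
  n_vox <- dim(train_betas)[3]
  lapply(1:2, function(e) {
    Xtr <- cbind(1, train_feats[[e]])
    Xte <- cbind(1, test_feats[[e]])
    if (ncol(Xtr) != ncol(Xte)) stop("TR grid / feature mismatch across splits")
    out <- array(NA_real_, dim = c(nrow(Xte), n_tr, n_vox))
    for (t in seq_len(n_tr)) {
      B <- qr.coef(qr(Xtr), matrix(train_betas[, t, ], dim(train_betas)[1]))
      B[is.na(B)] <- 0  # collinear feature columns drop out of the fit
      out[, t, ] <- Xte %*% B
    }
    out
  })
}

#' Unique variance of two epoch predictors via adjusted R-squared
#'
#' At each TR and searchlight centre, stacks the in-sphere voxel values
#' across videos as observations and computes
#' `unique(A) = adjR2(bio ~ A + B) - adjR2(bio ~ B)` (and symmetrically
#' for B), where A and B are the two synthetic test-response instances and
#' bio is the repetition-averaged biological test response.
#'
#' @param bio Array `[video, TR, voxel]`, test betas averaged over
#'   repetitions.
#' @param synthA,synthB Arrays of the same shape from [epoch_encode()].
#' @param grid Integer length-3 voxel grid.
#' @param searchlight_radius Radius in voxels (default 4).
#' @return A `unique_variance_curves` list: `uniqueA`, `uniqueB`
#'   (TR x voxel matrices).
#' @export
unique_variance <- function(bio, synthA, synthB, grid,
                            searchlight_radius = 4) {
  stopifnot(identical(dim(bio), dim(synthA)),
            identical(dim(bio), dim(synthB)))
  n_tr <- dim(bio)[2]
  n_vox <- dim(bio)[3]
  if (prod(grid) != n_vox) stop("grid does not match voxel count")
  offs <- searchlight_offsets(searchlight_radius)
  coords <- arrayInd(seq_len(n_vox), grid)
  sphere_idx <- lapply(seq_len(n_vox), function(v) {
    pts <- sweep(offs, 2L, as.integer(coords[v, ]), `+`)
    ok <- pts[, 1] >= 1 & pts[, 1] <= grid[1] &
      pts[, 2] >= 1 & pts[, 2] <= grid[2] &
      pts[, 3] >= 1 & pts[, 3] <= grid[3]
    pts[ok, 1] + (pts[ok, 2] - 1L) * grid[1] +
      (pts[ok, 3] - 1L) * grid[1] * grid[2]
  })
  uniqueA <- uniqueB <- matrix(NA_real_, n_tr, n_vox)
  for (t in seq_len(n_tr)) {
    bio_t <- matrix(bio[, t, ], dim(bio)[1])
    a_t <- matrix(synthA[, t, ], dim(bio)[1])
    b_t <- matrix(synthB[, t, ], dim(bio)[1])
    for (v in seq_len(n_vox)) {
      idx <- sphere_idx[[v]]
      y <- as.vector(bio_t[, idx])
      n <- length(y)
      if (n <= 3L) stop("n <= p + 1: too few observations in searchlight")
      xa <- as.vector(a_t[, idx])
      xb <- as.vector(b_t[, idx])
      full <- adjusted_r2(r2_ols(y, cbind(xa, xb)), n, 2L)
      uniqueA[t, v] <- full - adjusted_r2(r2_ols(y, xb), n, 1L)
      uniqueB[t, v] <- full - adjusted_r2(r2_ols(y, xa), n, 1L)
    }
  }
  structure(list(uniqueA = uniqueA, uniqueB = uniqueB, grid = grid),
            class = "unique_variance_curves")
}

#' Peak-TR differences between epoch predictors
#'
#' Per subject and voxel, the peak TR of each epoch's unique-variance
#' curve is its argmax over TRs (ties resolved to the earliest TR) and the
#' difference is `peak(B) - peak(A)` (third minus first epoch). The
#' whole-brain test counts, per voxel, the subjects whose difference falls
#' in `[1, 3]` and applies an exact binomial test against `p0` with BH-FDR
#' across voxels. The ROI summary reports, per ROI, a two-sided one-sample
#' t-test of the mean in-ROI peak difference and one-sided per-TR tests of
#' positive unique variance for both epochs with FDR over the 2 x TR
#' comparisons.
#'
#' @param curves List (one per subject) of `unique_variance_curves`.
#' @param rois Optional named list of logical voxel masks.
#' @param p0 Null probability that an independent peak pair lands in
#'   `[1, 3]`; default `21/81`, the fraction of ordered TR-peak pairs on a
#'   9-TR grid with difference in `[1, 3]` under a uniform null.
#' @param q FDR level for the voxelwise binomial test (default 0.05).
#' @return List with `peak_diff` (subject x voxel), `voxel`
#'   (data frame: `k`, `p`, `significant`, `pct_subjects`) and `roi`
#'   (data frame or NULL).
#' @export
peak_tr_analysis <- function(curves, rois = NULL, p0 = 21 / 81, q = 0.05) {
  n_sub <- length(curves)
  if (n_sub < 2L) stop("need at least 2 subjects")
  n_vox <- ncol(curves[[1]]$uniqueA)
  peakA <- t(vapply(curves, function(cu) apply(cu$uniqueA, 2L, which.max),
                    integer(n_vox)))
  peakB <- t(vapply(curves, function(cu) apply(cu$uniqueB, 2L, which.max),
                    integer(n_vox)))
  diff <- peakB - peakA
  k <- colSums(diff >= 1 & diff <= 3)
  pvals <- vapply(k, function(kk)
    binomial_fraction_test(kk, n_sub, p0, side = "greater")$p, numeric(1))
  sig <- bh_fdr(pvals, q = q)
  voxel <- data.frame(k = k, p = pvals, significant = as.logical(sig),
                      pct_subjects = 100 * k / n_sub)
  roi <- NULL
  if (!is.null(rois)) {
    n_tr <- nrow(curves[[1]]$uniqueA)
    rows <- lapply(names(rois), function(nm) {
      mask <- rois[[nm]]
      md <- rowMeans(diff[, mask, drop = FALSE])
      tt <- group_ttest(md, 0, sides = "two")
      # per-TR one-sided tests that unique variance exceeds 0, both epochs
      ptr <- unlist(lapply(list("A", "B"), function(ep) {
        vapply(seq_len(n_tr), function(t) {
          vals <- vapply(curves, function(cu)
            mean(cu[[paste0("unique", ep)]][t, mask]), numeric(1))
          group_ttest(vals, 0, sides = "one")$p
        }, numeric(1))
      }))
      data.frame(roi = nm, mean_peak_diff = mean(md), t = tt$statistic,
                 p = tt$p,
                 n_tr_significant = sum(bh_fdr(ptr, q = q)))
    })
    roi <- do.call(rbind, rows)
  }
  list(peak_diff = diff, voxel = voxel, roi = roi)
}
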