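# Univariate split-half reliability. A voxel is reliable when the mean
# Spearman-Brown corrected correlation over all 5/5 repetition splits of
# the 10-repetition testing set beats a stimulus-label permutation null.

# all unordered complementary half-splits of `R` repetitions (126 for R=10):
# columns of `a` index one half, the complement forms the other
half_splits <- function(R) {
  if (R %% 2L != 0L) stop("repetition count must be even for half splits")
  cc <- utils::combn(R, R %/% 2L)
  cc[, cc[1L, ] == 1L, drop = FALSE]
}

# per-split 5-rep averages of an S x R x V tensor, as two lists of S x V
# matrices (one per unordered split)
split_averages <- function(betas) {
  d <- dim(betas)
  reps <- lapply(seq_len(d[2]), function(r) matrix(betas[, r, ], d[1], d[3]))
  splits <- half_splits(d[2])
  A <- B <- vector("list", ncol(splits))
  for (j in seq_len(ncol(splits))) {
    ia <- splits[, j]
    ib <- setdiff(seq_len(d[2]), ia)
    A[[j]] <- Reduce(`+`, reps[ia]) / length(ia)
    B[[j]] <- Reduce(`+`, reps[ib]) / length(ib)
  }
  list(A = A, B = B)
}

split_mean_stats <- function(halves, perm = NULL) {
  n_split <- length(halves$A)
  V <- ncol(halves$A[[1]])
  rho_sum <- sb_sum <- numeric(V)
  for (j in seq_len(n_split)) {
    A <- halves$A[[j]]
    if (!is.null(perm)) A <- A[perm, , drop = FALSE]
    rho <- colwise_cor(A, halves$B[[j]])
    rho_sum <- rho_sum + rho
    sb_sum <- sb_sum + spearman_brown(rho)
  }
  list(rho = rho_sum / n_split, sb = sb_sum / n_split)
}

#' Split-half reliability with Spearman-Brown correction
#'
#' For each of the 126 unordered complementary 5/5 partitions of the 10
#' testing-set repetitions, averages each half across its 5 repetitions,
#' Pearson-correlates the two averages across stimuli per voxel, applies
#' the Spearman-Brown correction `2 * rho / (1 + rho)`, and averages over
#' partitions. Negative split correlations pass through uncorrected (the
#' corrected value can be negative).
#'
#' @param test_betas Array `[stimulus, repetition, voxel]` of delay-averaged,
#'   z-scored betas (see [summarize_betas()] with `average_reps = FALSE`).
#' @return A `reliability_map` list: `sb` (mean corrected reliability),
#'   `rho` (mean split correlation before correction), `n_splits`.
#' @export
split_half_reliability <- function(test_betas) {
  d <- dim(test_betas)
  if (is.null(d) || length(d) != 3L)
    stop("test_betas must be [stimulus, repetition, voxel]")
  if (d[1] < 3L) stop("need at least 3 stimuli to correlate across")
  halves <- split_averages(test_betas)
  obs <- split_mean_stats(halves)
  structure(list(sb = obs$sb, rho = obs$rho, n_splits = length(halves$A),
                 p = NULL, reliable = NULL, grid = attr(test_betas, "grid")),
            class = "reliability_map")
}

#' Permutation null for the split-half reliability criterion
#'
#' Repeats the split-half computation `n_perm` times with the stimulus
#' indices of one split freshly permuted each iteration (the same
#' permutation is applied across all 126 partitions within an iteration),
#' and converts the observed mean reliability to an add-one permutation
#' p-value: `p = (#{null >= observed} + 1) / (n_perm + 1)`.
#'
#' @param test_betas Array `[stimulus, repetition, voxel]` as in
#'   [split_half_reliability()].
#' @param n_perm Number of permutations (default 100).
#' @param seed Integer seed.
#' @return A `reliability_map` with `sb`, `rho`, `p` and `null_sb`
#'   (the `n_perm` x voxel null matrix).
#' @export
permutation_null <- function(test_betas, n_perm = 100L, seed) {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  map <- split_half_reliability(test_betas)
  halves <- split_averages(test_betas)
  S <- dim(test_betas)[1]
  null_sb <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(i)
      split_mean_stats(halves, perm = sample.int(S))$sb,
      numeric(length(map$sb))))
  })
  exceed <- colSums(sweep(null_sb, 2L, map$sb, `>=`))
  map$p <- (exceed + 1) / (n_perm + 1)
  map$null_sb <- null_sb
  map
}

#' Select reliable voxels
#'
#' Thresholds the permutation p-values of a reliability map at `alpha`;
#' optionally reports counts per region of interest.
#'
#' @param map A `reliability_map` with a `p` field (see
#'   [permutation_null()]).
#' @param alpha Significance level (default 0.05).
#' @param roi_masks Optional named list of logical voxel masks; per-ROI
#'   reliable-voxel counts are attached as attribute `roi_counts`.
#' @return Logical voxel mask.
#' @export
select_reliable_voxels <- function(map, alpha = 0.05, roi_masks = NULL) {
  if (is.null(map$p)) stop("reliability map has no permutation p-values")
  # add-one permutation p-values reach exactly 1, so alpha >= 1 disables
  # the criterion rather than excluding those voxels on a strict inequality
  mask <- if (alpha >= 1) rep(TRUE, length(map$p)) else map$p < alpha
  if (!is.null(roi_masks))
    attr(mask, "roi_counts") <- vapply(roi_masks, function(m) sum(mask & m),
                                       integer(1))
  mask
}
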