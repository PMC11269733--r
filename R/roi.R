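# ROI definition from localizer contrasts: per-subject FWE thresholding,
# group probabilistic maps, top-1000 voxel selection, and assignment of
# overlapping voxels by probability with patch-growth tie-breaking.

# Bonferroni FWE t threshold (one-sided, positive tail) over in-mask voxels
fwe_t_threshold <- function(df, n_voxels, alpha = 0.05) {
  stats::qt(1 - alpha / n_voxels, df)
}

#' Group probabilistic map from per-subject t-maps
#'
#' Binarises each subject's contrast t-map at the Bonferroni FWE threshold
#' (one-sided over in-mask voxels), sums across subjects and divides by
#' the subject count, giving per-voxel values on the `1/n_subjects` grid
#' (0, 0.1, ..., 1.0 for 10 subjects).
#'
#' @param tmaps Voxels-by-subjects matrix of t-statistics (or list of
#'   per-subject vectors).
#' @param df Residual degrees of freedom of the t-maps.
#' @param fwe_alpha Family-wise error level (default 0.05).
#' @param mask Optional logical in-mask vector; out-of-mask voxels get 0.
#' @return Numeric per-voxel probability vector.
#' @export
build_probabilistic_map <- function(tmaps, df, fwe_alpha = 0.05, mask = NULL) {
  if (is.list(tmaps)) tmaps <- do.call(cbind, tmaps)
  if (ncol(tmaps) < 2L) stop("need at least 2 subjects")
  if (is.null(mask)) mask <- rep(TRUE, nrow(tmaps))
  if (length(mask) != nrow(tmaps)) stop("shape mismatch between mask and t-maps")
  thr <- fwe_t_threshold(df, sum(mask), fwe_alpha)
  hits <- (tmaps > thr) & mask
  rowMeans(hits)
}

#' Define a subject ROI from a t-map and a group probabilistic map
#'
#' Restricts the subject's FWE-surviving voxels to the support of the group
#' probabilistic map (and an optional anatomical mask) and keeps the
#' `top_k` voxels with the largest t-values. An empty result is returned
#' as an empty mask with a warning, not an error (some subjects lack
#' responses in some regions).
#'
#' @param subject_tmap Per-voxel t-statistics for this subject.
#' @param probmap Group probabilistic map from [build_probabilistic_map()].
#' @param df Residual degrees of freedom of the t-map.
#' @param anatomical_mask Optional logical voxel mask.
#' @param top_k Maximum ROI size (default 1000).
#' @param fwe_alpha Family-wise error level (default 0.05).
#' @return Logical voxel mask.
#' @export
define_roi <- function(subject_tmap, probmap, df, anatomical_mask = NULL,
                       top_k = 1000L, fwe_alpha = 0.05) {
  if (length(subject_tmap) != length(probmap))
    stop("shape mismatch between t-map and probabilistic map")
  if (is.null(anatomical_mask)) anatomical_mask <- rep(TRUE, length(probmap))
  thr <- fwe_t_threshold(df, sum(anatomical_mask), fwe_alpha)
  cand <- which(subject_tmap > thr & probmap > 0 & anatomical_mask)
  if (!length(cand)) {
    warning("empty ROI: no voxels survive thresholding within the map support")
    return(rep(FALSE, length(probmap)))
  }
  if (length(cand) > top_k)
    cand <- cand[order(subject_tmap[cand], decreasing = TRUE)[seq_len(top_k)]]
  mask <- rep(FALSE, length(probmap))
  mask[cand] <- TRUE
  mask
}

# mean of `values` over the cube of half-width `r` voxels centred at
# coordinate `cc` on `grid`, clipped at volume boundaries
patch_mean <- function(values, grid, cc, r) {
  xs <- max(1L, cc[1] - r):min(grid[1], cc[1] + r)
  ys <- max(1L, cc[2] - r):min(grid[2], cc[2] + r)
  zs <- max(1L, cc[3] - r):min(grid[3], cc[3] + r)
  idx <- as.vector(outer(outer(xs, (ys - 1L) * grid[1], `+`),
                         (zs - 1L) * grid[1] * grid[2], `+`))
  mean(values[idx])
}

#' Assign overlapping voxels to a unique ROI
#'
#' Every voxel claimed by more than one ROI is assigned to the ROI whose
#' group probabilistic map is larger at that voxel. Ties are broken by
#' comparing mean probability within a cube grown by one voxel per
#' dimension per iteration until the tie breaks; if the patch spans the
#' whole grid and the tie persists, the voxel goes to the first ROI with a
#' warning. The returned masks are disjoint and cover the original union.
#'
#' @param rois Named list of logical voxel masks.
#' @param probmaps List of probabilistic maps, same order as `rois`.
#' @param grid Integer length-3 voxel grid dimensions.
#' @return Named list of disjoint logical masks.
#' @export
resolve_overlaps <- function(rois, probmaps, grid) {
  stopifnot(length(rois) == length(probmaps))
  n_vox <- length(rois[[1]])
  if (prod(grid) != n_vox) stop("grid does not match mask length")
  claim <- Reduce(`+`, lapply(rois, as.integer))
  overlap <- which(claim > 1L)
  out <- rois
  max_r <- max(grid)
  for (v in overlap) {
    owners <- which(vapply(rois, function(m) m[v], logical(1)))
    probs <- vapply(owners, function(i) probmaps[[i]][v], numeric(1))
    best <- owners[probs == max(probs)]
    if (length(best) > 1L) {
      cc <- as.integer(arrayInd(v, grid))
      for (r in seq_len(max_r)) {
        pm <- vapply(best, function(i) patch_mean(probmaps[[i]], grid, cc, r),
                     numeric(1))
        if (max(pm) > min(pm) + 1e-12) {
          best <- best[pm == max(pm)]
          if (length(best) == 1L) break
        }
        if (r == max_r && length(best) > 1L) {
          warning("unresolvable tie at voxel ", v,
                  ": assigning to the first ROI")
          best <- best[1L]
        }
      }
    }
    for (i in owners) out[[i]][v] <- (i == best[1L])
  }
  out
}

#' Nearest-neighbour mask regridding
#'
#' Resamples a voxel mask (or label volume) defined on `from_grid` onto
#' `to_grid` by nearest-neighbour interpolation of grid coordinates, as
#' used to bring atlas parcellations to a functional voxel resolution.
#'
#' @param values Vector of length `prod(from_grid)`.
#' @param from_grid,to_grid Integer length-3 grid dimensions.
#' @return Vector of length `prod(to_grid)`.
#' @export
regrid_nearest <- function(values, from_grid, to_grid) {
  if (length(values) != prod(from_grid)) stop("values do not match from_grid")
  coords <- arrayInd(seq_len(prod(to_grid)), to_grid)
  src <- sapply(1:3, function(a) {
    pmin(from_grid[a], pmax(1L, as.integer(round(
      (coords[, a] - 0.5) * from_grid[a] / to_grid[a] + 0.5))))
  })
  idx <- src[, 1] + (src[, 2] - 1L) * from_grid[1] +
    (src[, 3] - 1L) * from_grid[1] * from_grid[2]
  values[idx]
}
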