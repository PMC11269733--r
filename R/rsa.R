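# Representational similarity analysis: searchlight RDMs over voxel
# patterns, metadata RDMs from annotation embeddings, Spearman RSA maps,
# subject-to-group noise ceilings, and ROI-level model comparison.

#' Integer lattice offsets of a spherical searchlight
#'
#' All integer offsets with squared norm at most `radius^2`; 257 voxels at
#' the canonical radius of 4.
#'
#' @param radius_vox Searchlight radius in voxels.
#' @return Matrix of offsets (rows) by x/y/z.
#' @export
searchlight_offsets <- function(radius_vox = 4) {
  if (radius_vox < 1) stop("searchlight radius must be at least 1 voxel")
  r <- floor(radius_vox)
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  as.matrix(g[g$x^2 + g$y^2 + g$z^2 <= radius_vox^2, , drop = FALSE])
}

# 1 - Pearson dissimilarity between rows of a stimulus-by-feature matrix
one_minus_pearson_rdm <- function(patterns) {
  1 - stats::cor(t(patterns))
}

# pairwise cosine distance between rows
cosine_distance_rdm <- function(vectors) {
  nrm <- sqrt(rowSums(vectors^2))
  sim <- (vectors %*% t(vectors)) / outer(nrm, nrm)
  d <- 1 - sim
  diag(d) <- 0
  d
}

#' Searchlight RDMs over a voxel grid
#'
#' Centres a spherical searchlight of `radius_vox` voxels on every voxel,
#' stacks the in-sphere voxel patterns (stimuli x sphere voxels, spheres
#' truncated at volume edges), and computes the 1 - Pearson dissimilarity
#' between all stimulus pairs. Centres whose patterns are degenerate
#' (any constant stimulus pattern) yield missing-value RDMs, which
#' downstream group maps exclude.
#'
#' @param summaries Stimulus-by-voxel matrix of z-scored, delay-averaged,
#'   repetition-averaged betas (see [summarize_betas()]); must carry a
#'   `grid` attribute or `grid` must be given.
#' @param radius_vox Searchlight radius in voxels (default 4).
#' @param grid Integer length-3 voxel grid dimensions.
#' @return A `searchlight_rdms` object: matrix of lower-triangle RDM
#'   entries (stimulus pairs x voxels) with attributes `conditions`,
#'   `metric`, `grid`, `radius_vox`.
#' @export
searchlight_rdms <- function(summaries, radius_vox = 4, grid = NULL) {
  if (is.null(grid)) grid <- attr(summaries, "grid")
  if (is.null(grid)) stop("voxel grid dimensions are required")
  if (prod(grid) != ncol(summaries)) stop("grid does not match voxel count")
  if (any(2 * radius_vox + 1 > grid))
    stop("searchlight radius exceeds the voxel grid")
  offs <- searchlight_offsets(radius_vox)
  S <- nrow(summaries)
  n_pair <- S * (S - 1) / 2
  coords <- arrayInd(seq_len(prod(grid)), grid)
  out <- matrix(NA_real_, n_pair, prod(grid))
  for (v in seq_len(prod(grid))) {
    pts <- sweep(offs, 2L, as.integer(coords[v, ]), `+`)
    ok <- pts[, 1] >= 1 & pts[, 1] <= grid[1] &
      pts[, 2] >= 1 & pts[, 2] <= grid[2] &
      pts[, 3] >= 1 & pts[, 3] <= grid[3]
    idx <- pts[ok, 1] + (pts[ok, 2] - 1L) * grid[1] +
      (pts[ok, 3] - 1L) * grid[1] * grid[2]
    pat <- summaries[, idx, drop = FALSE]
    sds <- apply(pat, 1L, stats::sd)
    if (any(!is.finite(sds) | sds == 0)) next
    out[, v] <- lower_tri_vec(one_minus_pearson_rdm(pat))
  }
  structure(out, conditions = rownames(summaries),
            metric = "one_minus_pearson", grid = grid,
            radius_vox = radius_vox,
            class = c("searchlight_rdms", "matrix", "array"))
}

# exhaustive best triple of annotation vectors: the 3 of 5 with maximal
# mean pairwise cosine similarity, averaged into one vector
consensus_embedding <- function(ann) {
  n <- nrow(ann)
  if (n < 3L) stop("fewer than 3 annotations for a video")
  nrm <- sqrt(rowSums(ann^2))
  sim <- (ann %*% t(ann)) / outer(nrm, nrm)
  triples <- utils::combn(n, 3L)
  score <- apply(triples, 2L, function(tr)
    mean(sim[tr, tr][lower.tri(sim[tr, tr])]))
  best <- triples[, which.max(score)]
  colMeans(ann[best, , drop = FALSE])
}

#' Metadata RDM from annotation embeddings
#'
#' Per video, selects the 3 most mutually similar of its 5 annotation
#' embeddings (the triple with maximal mean pairwise cosine similarity,
#' searched exhaustively), averages them into a consensus vector, and
#' computes pairwise cosine distances between videos. The combined
#' `"object_scene_action"` category concatenates the three per-video
#' consensus vectors before the distance computation.
#'
#' @param embeddings An `embedding_set` from
#'   [generate_metadata_embeddings()], or a list of `[video, annotation,
#'   dim]` arrays keyed by category.
#' @param category One of `"object"`, `"scene"`, `"action"`, `"sentence"`,
#'   `"object_scene_action"`.
#' @return An n-videos square `rdm` matrix (cosine distance, zero
#'   diagonal) with attribute `metric`.
#' @export
metadata_rdm <- function(embeddings,
                         category = c("object", "scene", "action", "sentence",
                                      "object_scene_association",
                                      "object_scene_action")) {
  category <- match.arg(category)
  if (category == "object_scene_association") category <- "object_scene_action"
  emb <- if (inherits(embeddings, "embedding_set")) embeddings$embeddings
  else embeddings
  cats <- if (category == "object_scene_action")
    c("object", "scene", "action") else category
  vecs <- lapply(cats, function(cat) {
    a <- emb[[cat]]
    if (is.null(a)) stop("embedding set lacks category ", cat)
    t(vapply(seq_len(dim(a)[1]),
             function(v) consensus_embedding(matrix(a[v, , ], dim(a)[2])),
             numeric(dim(a)[3])))
  })
  vec <- do.call(cbind, vecs)
  structure(cosine_distance_rdm(vec), metric = "cosine_distance",
            class = c("rdm", "matrix", "array"))
}

# Spearman correlation between one vector and each column of a matrix
spearman_cols <- function(x, m) {
  rx <- rank(x)
  rm_ <- apply(m, 2L, rank)
  colwise_cor(matrix(rx, length(rx), ncol(m)), rm_)
}

#' Correlate a model RDM with searchlight RDMs
#'
#' Spearman-correlates the lower-triangle entries of the model RDM with
#' each voxel's searchlight RDM (diagonal excluded). Voxels with missing
#' RDMs return NA; a constant model RDM (no rank variation) is an error.
#'
#' @param neural_rdms A `searchlight_rdms` object.
#' @param model_rdm Square model RDM with matching condition count.
#' @return Per-voxel Spearman correlations.
#' @export
rsa_map <- function(neural_rdms, model_rdm) {
  mv <- lower_tri_vec(as.matrix(model_rdm))
  if (length(mv) != nrow(neural_rdms))
    stop("condition mismatch between model RDM and searchlight RDMs")
  if (stats::sd(mv) == 0)
    stop("degenerate model RDM: all dissimilarities equal")
  ok <- !apply(neural_rdms, 2L, anyNA)
  out <- rep(NA_real_, ncol(neural_rdms))
  if (any(ok)) out[ok] <- spearman_cols(mv, neural_rdms[, ok, drop = FALSE])
  out
}

#' Upper and lower searchlight noise ceilings
#'
#' Per voxel, the upper ceiling is the mean over subjects of the Spearman
#' correlation between each subject's RDM and the all-subject average RDM;
#' the lower ceiling is the mean over subjects of the correlation between
#' the left-out subject's RDM and the average of the remaining subjects.
#'
#' @param subject_rdms List (length >= 3) of `searchlight_rdms`, one per
#'   subject, on the same grid and condition set.
#' @return List with per-voxel `upper` and `lower` vectors.
#' @export
noise_ceilings <- function(subject_rdms) {
  n_sub <- length(subject_rdms)
  if (n_sub < 3L) stop("need at least 3 subjects for noise ceilings")
  dims <- vapply(subject_rdms, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("subject RDM sets differ in shape")
  total <- Reduce(`+`, lapply(subject_rdms, unclass))
  upper_acc <- lower_acc <- matrix(0, 1, dims[2, 1])
  n_ok <- rep(0L, dims[2, 1])
  upper <- lower <- matrix(NA_real_, n_sub, dims[2, 1])
  for (s in seq_len(n_sub)) {
    own <- unclass(subject_rdms[[s]])
    grand <- total / n_sub
    loo <- (total - own) / (n_sub - 1)
    ok <- !apply(own, 2L, anyNA) & !apply(grand, 2L, anyNA)
    if (any(ok)) {
      ranks_own <- apply(own[, ok, drop = FALSE], 2L, rank)
      upper[s, ok] <- colwise_cor(ranks_own,
                                  apply(grand[, ok, drop = FALSE], 2L, rank))
      lower[s, ok] <- colwise_cor(ranks_own,
                                  apply(loo[, ok, drop = FALSE], 2L, rank))
    }
  }
  list(upper = colMeans(upper), lower = colMeans(lower),
       per_subject_upper = upper, per_subject_lower = lower)
}

#' ROI-level comparison of model RSA performance
#'
#' For each ROI, a one-way ANOVA compares the mean noise-normalised
#' correlations of the candidate models across subjects, with Bonferroni
#' correction over ROIs; where the corrected ANOVA is significant, Tukey
#' HSD flags the pairwise model differences at FWER `alpha`.
#'
#' @param corrs Array `[subject, roi, model]` of noise-normalised
#'   correlations (dimnames used for labels when present).
#' @param alpha Significance level (default 0.05).
#' @return List of per-ROI results: `anova_p`, `significant` (after
#'   Bonferroni over ROIs), and `tukey` (pairwise table or NULL).
#' @export
roi_model_comparison <- function(corrs, alpha = 0.05) {
  stopifnot(length(dim(corrs)) == 3L)
  n_roi <- dim(corrs)[2]
  roi_names <- dimnames(corrs)[[2]]
  if (is.null(roi_names)) roi_names <- paste0("roi", seq_len(n_roi))
  model_names <- dimnames(corrs)[[3]]
  if (is.null(model_names)) model_names <- paste0("model", seq_len(dim(corrs)[3]))
  out <- list()
  for (r in seq_len(n_roi)) {
    vals <- matrix(corrs[, r, ], dim(corrs)[1], dim(corrs)[3],
                   dimnames = list(NULL, model_names))
    res <- anova_tukey(vals, alpha = alpha)
    sig <- is.finite(res$p) && res$p < alpha / n_roi
    out[[roi_names[r]]] <- list(anova_p = res$p, significant = sig,
                                tukey = if (sig) res$pairwise else NULL)
  }
  out
}
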