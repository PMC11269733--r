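# Memorability: linear decay model over recognition lag, and correlation
# of per-video memorability scores with voxelwise response amplitude.

#' Predict memorability at an arbitrary lag
#'
#' Linear decay from the score at the reference lag:
#' `m_t = m_T + alpha * (t - T)` with `T = 80` intervening videos, clipped
#' to `[0, 1]`. Positive decay rates are preserved by default;
#' `clip_decay = TRUE` caps them at 0 before extrapolating.
#'
#' @param score Memorability score(s) at the reference lag, in `[0, 1]`.
#' @param decay Decay rate(s) per lag unit (typically negative).
#' @param t Target lag (number of intervening videos), `t >= 0`.
#' @param T_ref Reference lag (default 80).
#' @param clip_decay Cap positive decay rates at 0.
#' @return Predicted memorability in `[0, 1]`.
#' @export
#' @examples
#' memorability_at_lag(0.8, -0.001, 180) # 0.7
memorability_at_lag <- function(score, decay, t, T_ref = 80,
                                clip_decay = FALSE) {
  stopifnot(all(t >= 0), all(score >= 0 & score <= 1))
  if (clip_decay) decay <- pmin(decay, 0)
  pmin(1, pmax(0, score + decay * (t - T_ref)))
}

#' Correlate memorability scores with voxel response amplitude
#'
#' Per subject and voxel, Spearman-correlates the per-video memorability
#' scores with the per-video response amplitudes (betas z-scored across
#' stimuli, averaged over the peak delays and over repetitions, training
#' and testing sets pooled). Group inference is one-sided toward positive
#' correlation (the a-priori direction: memorable stimuli evoke larger
#' responses): a voxelwise one-sample t-test with BH-FDR at `q`, and an
#' ROI-level t-test on the mean in-ROI correlation with Bonferroni
#' correction over the ROI count.
#'
#' @param scores Per-video memorability scores.
#' @param betas_by_subject List (one per subject) of stimulus-by-voxel
#'   amplitude matrices, rows aligned with `scores`.
#' @param rois Optional named list of logical voxel masks.
#' @param q FDR level for the voxelwise map (default 0.05).
#' @param alpha ROI significance level before Bonferroni (default 0.05).
#' @return List: `corr` (subject x voxel Spearman correlations), `voxel`
#'   (data frame `t`, `p`, `significant`), `roi` (data frame or NULL).
#' @export
memorability_correlation <- function(scores, betas_by_subject, rois = NULL,
                                     q = 0.05, alpha = 0.05) {
  for (b in betas_by_subject)
    if (nrow(b) != length(scores))
      stop("length mismatch between scores and per-video betas")
  corr <- t(vapply(betas_by_subject, function(b)
    spearman_cols(scores, b), numeric(ncol(betas_by_subject[[1]]))))
  stats_ <- apply(corr, 2L, function(v) {
    tt <- group_ttest(v, 0, sides = "one")
    c(tt$statistic, tt$p)
  })
  sig <- bh_fdr(stats_[2, ], q = q)
  voxel <- data.frame(t = stats_[1, ], p = stats_[2, ],
                      significant = as.logical(sig))
  roi <- NULL
  if (!is.null(rois)) {
    rows <- lapply(names(rois), function(nm) {
      vals <- rowMeans(corr[, rois[[nm]], drop = FALSE])
      tt <- group_ttest(vals, 0, sides = "one")
      data.frame(roi = nm, mean_corr = mean(vals), t = tt$statistic,
                 p = tt$p, significant = tt$p < alpha / length(rois))
    })
    roi <- do.call(rbind, rows)
  }
  list(corr = corr, voxel = voxel, roi = roi)
}
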