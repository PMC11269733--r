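# FIR and canonical-HRF general linear modeling. The FIR model estimates a
# free response value per (trial, delay 1..9 s) with no shape assumption;
# the localizer GLM convolves category boxcars with the canonical
# double-gamma response.

#' Resample a volume series to a finer regular TR by cubic interpolation
#'
#' Interpolates each voxel's time series from the acquisition grid onto a
#' regular grid at `target_tr_s` aligned to run start, so that trial onsets
#' (multiples of the trial length) fall on sampled volumes. The output
#' covers `0, 1, ..., floor(duration)` seconds where duration is the time
#' of the last acquired sample.
#'
#' @param series A time-by-voxel `volume_series` (attribute `tr_s`).
#' @param target_tr_s Output TR, seconds (default 1).
#' @return A `volume_series` at the new TR with attributes carried over.
#' @export
resample_timeseries <- function(series, target_tr_s = 1) {
  tr <- attr(series, "tr_s")
  if (is.null(tr)) stop("series lacks a tr_s attribute")
  if (tr <= target_tr_s) stop("input TR must exceed the target TR")
  n <- nrow(series)
  if (n < 4L) stop("too few timepoints for cubic interpolation (need >= 4)")
  times <- (seq_len(n) - 1) * tr
  new_times <- seq(0, floor(times[n]), by = target_tr_s)
  out <- apply(series, 2L, function(y)
    stats::spline(times, y, xout = new_times, method = "fmm")$y)
  for (a in c("run_type", "run", "session", "grid", "events"))
    attr(out, a) <- attr(series, a)
  attr(out, "tr_s") <- target_tr_s
  class(out) <- c("volume_series", class(out))
  out
}

#' Discrete-cosine high-pass basis
#'
#' Cosine regressors with frequencies up to `1/cutoff_s` Hz (excluding the
#' constant), spanning the slow drift that the GLM projects out.
#'
#' @param n Number of timepoints.
#' @param tr_s Sampling interval, seconds.
#' @param cutoff_s Period cutoff, seconds (default 128).
#' @return An `n` x K matrix (K may be 0).
#' @export
dct_highpass_basis <- function(n, tr_s, cutoff_s = 128) {
  K <- floor(2 * n * tr_s / cutoff_s)
  t0 <- seq_len(n) - 1
  if (K < 1L) return(matrix(0, n, 0))
  sapply(seq_len(K), function(k) cos(pi * k * (2 * t0 + 1) / (2 * n)))
}

#' Build a trial-wise FIR design matrix
#'
#' One indicator column per (stimulus trial, delay) pair: the column for
#' delay d carries a single 1 at the volume `onset + d` seconds after run
#' start. Null trials are excluded. Delays extending past the run end are
#' truncated (all-zero columns are flagged in the `truncated` attribute,
#' not dropped). Onsets must align to the sampling grid.
#'
#' Note that columns of trials whose onsets differ by less than the delay
#' span land on shared volumes and are then exactly collinear; such designs
#' are rejected by [fit_fir_glm()]. Identifiable trial-wise estimation
#' requires adequate trial separation (or sparse schedules).
#'
#' @param events Event data frame (`onset`, `condition` with NA for nulls,
#'   `repetition`), or a `run_schedule`.
#' @param n_volumes Number of volumes in the (resampled) run.
#' @param delays Delay grid, seconds post-onset (default `1:9`).
#' @param tr_s Sampling TR of the modeled series (default 1).
#' @return An `fir_design`: matrix `n_volumes` x (trials x delays) with a
#'   `labels` attribute (`condition`, `repetition`, `delay` per column).
#' @export
build_fir_design <- function(events, n_volumes, delays = 1:9, tr_s = 1) {
  if (inherits(events, "run_schedule")) events <- events$events
  stim <- events[!is.na(events$condition), , drop = FALSE]
  if (nrow(stim) == 0L) stop("no stimulus trials in events")
  frac <- stim$onset / tr_s
  if (any(abs(frac - round(frac)) > 1e-6))
    stop("misaligned onset: onsets must be integer multiples of the TR")
  n_col <- nrow(stim) * length(delays)
  X <- matrix(0, n_volumes, n_col)
  labels <- data.frame(condition = rep(stim$condition, each = length(delays)),
                       repetition = rep(stim$repetition, each = length(delays)),
                       delay = rep(delays, times = nrow(stim)))
  truncated <- logical(n_col)
  col <- 0L
  for (i in seq_len(nrow(stim))) {
    for (d in delays) {
      col <- col + 1L
      row <- round(stim$onset[i] / tr_s) + round(d / tr_s) + 1L
      if (row <= n_volumes) X[row, col] <- 1 else truncated[col] <- TRUE
    }
  }
  structure(X, labels = labels, truncated = truncated, tr_s = tr_s,
            class = c("fir_design", "matrix", "array"))
}

# residual-forming projection removing an intercept plus the DCT drift set
highpass_project <- function(m, basis) {
  C <- cbind(1, basis)
  m - C %*% qr.coef(qr(C), m)
}

#' Fit a trial-wise FIR GLM with high-pass filtering and AR(1) prewhitening
#'
#' Projects a discrete-cosine high-pass set (period cutoff `highpass_cutoff_s`)
#' out of both data and design, then estimates the FIR betas by least
#' squares. With `ar1 = TRUE` a single AR(1) coefficient is pooled across
#' voxels from the OLS residuals, data and design are prewhitened, and the
#' model is refit. Rank-deficient filtered designs are an error: trial-wise
#' FIR betas are not identifiable when trial delays alias onto shared
#' volumes.
#'
#' @param series Time-by-voxel matrix (resampled to the design's TR).
#' @param design An `fir_design` from [build_fir_design()].
#' @param highpass_cutoff_s High-pass period cutoff, seconds (128).
#' @param ar1 Prewhiten with a pooled AR(1) coefficient.
#' @return A `beta_slice`: coefficient matrix (design columns x voxels)
#'   with the design `labels` attached, plus `ar1_phi`.
#' @export
fit_fir_glm <- function(series, design, highpass_cutoff_s = 128, ar1 = TRUE) {
  series <- unclass(series)
  n <- nrow(series)
  stopifnot(nrow(design) == n)
  basis <- dct_highpass_basis(n, attr(design, "tr_s"), highpass_cutoff_s)
  keep <- !attr(design, "truncated")
  Xf <- highpass_project(unclass(design)[, keep, drop = FALSE], basis)
  yf <- highpass_project(series, basis)
  qx <- qr(Xf)
  if (qx$rank < ncol(Xf))
    stop("rank-deficient design after filtering: trial-wise FIR betas are ",
         "not identifiable (", ncol(Xf) - qx$rank, " aliased column(s))")
  beta <- qr.coef(qx, yf)
  phi <- NA_real_
  if (ar1) {
    res <- yf - Xf %*% beta
    num <- sum(res[-1, , drop = FALSE] * res[-n, , drop = FALSE])
    den <- sum(res[-n, , drop = FALSE]^2)
    phi <- if (den > 0) num / den else 0
    if (!is.finite(phi) || abs(phi) >= 1)
      stop("AR(1) estimate did not converge (|phi| >= 1)")
    W <- function(m) {
      out <- m
      out[1, ] <- m[1, ] * sqrt(1 - phi^2)
      out[-1, ] <- m[-1, , drop = FALSE] - phi * m[-nrow(m), , drop = FALSE]
      out
    }
    qx <- qr(W(Xf))
    if (qx$rank < ncol(Xf)) stop("rank-deficient design after prewhitening")
    beta <- qr.coef(qx, W(yf))
  }
  full <- matrix(NA_real_, ncol(design), ncol(series))
  full[keep, ] <- beta
  structure(full, labels = attr(design, "labels"),
            truncated = attr(design, "truncated"), ar1_phi = phi,
            class = c("beta_slice", "matrix", "array"))
}

#' Estimate a full beta tensor from a set of runs
#'
#' Convenience wrapper running, per run: temporal resampling to 1 s (when
#' the series TR exceeds 1), FIR design construction, and
#' [fit_fir_glm()]; the per-run trial-wise estimates are then assembled
#' into a `[stimulus, repetition, delay, voxel]` array keyed by the
#' condition and repetition labels from the schedule.
#'
#' @param series_list List of `volume_series` (with `events` attributes).
#' @param run_types Which run types to include (default `"test"`).
#' @param delays Delay grid, seconds (default `1:9`).
#' @param highpass_cutoff_s,ar1 Passed to [fit_fir_glm()].
#' @return A `beta_tensor` array.
#' @export
fit_beta_tensor <- function(series_list, run_types = "test", delays = 1:9,
                            highpass_cutoff_s = 128, ar1 = TRUE) {
  series_list <- Filter(function(s) attr(s, "run_type") %in% run_types,
                        series_list)
  if (!length(series_list)) stop("no runs of the requested type")
  slices <- lapply(series_list, function(s) {
    if (attr(s, "tr_s") > 1) s <- resample_timeseries(s, 1)
    design <- build_fir_design(attr(s, "events"), nrow(s), delays, 1)
    fit_fir_glm(s, design, highpass_cutoff_s, ar1)
  })
  labels <- do.call(rbind, lapply(slices, function(b) attr(b, "labels")))
  ids <- sort(unique(labels$condition))
  n_rep <- max(labels$repetition)
  n_vox <- ncol(slices[[1]])
  betas <- array(NA_real_, dim = c(length(ids), n_rep, length(delays), n_vox),
                 dimnames = list(ids, NULL, delays, NULL))
  for (b in slices) {
    lab <- attr(b, "labels")
    for (j in seq_len(nrow(lab))) {
      betas[match(lab$condition[j], ids), lab$repetition[j],
            match(lab$delay[j], delays), ] <- b[j, ]
    }
  }
  structure(betas, class = c("beta_tensor", "array"), delays = delays,
            grid = attr(series_list[[1]], "grid"))
}

#' Summarise a beta tensor over the response peak
#'
#' Z-scores betas across stimuli (per voxel, per repetition, per delay),
#' averages over the delay window (canonically TRs 5-9, the peak of a
#' typical BOLD response), and optionally averages over repetitions.
#' Zero-variance voxels z-score to 0 rather than dividing by zero.
#'
#' @param betas A `beta_tensor` `[stimulus, repetition, delay, voxel]`.
#' @param delay_window Length-2 inclusive delay range in the tensor's
#'   delay units (default `c(5, 9)`).
#' @param zscore Z-score across stimuli before averaging.
#' @param average_reps Average over repetitions.
#' @return Stimulus-by-voxel matrix (if `average_reps`) or
#'   `[stimulus, repetition, voxel]` array, with stimulus ids as rownames.
#' @export
summarize_betas <- function(betas, delay_window = c(5, 9), zscore = TRUE,
                            average_reps = TRUE) {
  delays <- attr(betas, "delays")
  if (is.null(delays)) delays <- as.numeric(dimnames(betas)[[3]])
  sel <- which(delays >= delay_window[1] & delays <= delay_window[2])
  if (!length(sel)) stop("delay window out of range for this tensor")
  d <- dim(betas)
  out <- array(0, dim = c(d[1], d[2], d[4]))
  for (r in seq_len(d[2])) {
    acc <- matrix(0, d[1], d[4])
    for (k in sel) {
      slab <- betas[, r, k, , drop = TRUE]
      slab <- matrix(slab, d[1], d[4])
      if (zscore) slab <- zscore_cols(slab)
      acc <- acc + slab
    }
    out[, r, ] <- acc / length(sel)
  }
  dimnames(out) <- list(dimnames(betas)[[1]], NULL, NULL)
  if (average_reps) {
    m <- apply(out, c(1, 3), mean)
    rownames(m) <- dimnames(betas)[[1]]
    attr(m, "grid") <- attr(betas, "grid")
    return(m)
  }
  attr(out, "grid") <- attr(betas, "grid")
  out
}

#' Canonical-HRF block GLM for functional localizer runs
#'
#' Builds one boxcar regressor per stimulus category, convolves each with
#' the canonical double-gamma response, adds an intercept, fits by least
#' squares, and returns per-voxel t-statistics for the requested category
#' contrasts (the baseline is the unmodeled fixation).
#'
#' @param series Time-by-voxel matrix with a `tr_s` attribute.
#' @param block_events Data frame `onset`, `duration`, `condition`
#'   (category labels; NA rows are baseline), or a `run_schedule`.
#' @param contrasts Named list of named numeric vectors over categories,
#'   e.g. `list(faces_gt_objects = c(faces = 1, objects = -1))`.
#' @return Matrix voxels x contrasts of t-statistics, with the residual
#'   degrees of freedom in attribute `df`.
#' @export
fit_localizer_glm <- function(series, block_events, contrasts) {
  if (inherits(block_events, "run_schedule")) block_events <- block_events$events
  tr <- attr(series, "tr_s")
  if (is.null(tr)) stop("series lacks a tr_s attribute")
  n <- nrow(series)
  times <- (seq_len(n) - 1) * tr
  ev <- block_events[!is.na(block_events$condition), , drop = FALSE]
  cats <- sort(unique(ev$condition))
  X <- sapply(cats, function(cat) {
    on <- ev[ev$condition == cat, , drop = FALSE]
    reg <- numeric(n)
    for (i in seq_len(nrow(on))) {
      # convolve the boxcar with the HRF in continuous time, sampled at TR
      reg <- reg + hrf_block_response(times, on$onset[i], on$duration[i])
    }
    reg
  })
  colnames(X) <- cats
  Xd <- cbind(intercept = 1, X)
  qx <- qr(Xd)
  beta <- qr.coef(qx, unclass(series))
  res <- unclass(series) - Xd %*% beta
  df <- n - qx$rank
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qx))
  out <- sapply(names(contrasts), function(nm) {
    cv <- contrasts[[nm]]
    if (!all(names(cv) %in% cats))
      stop("unknown contrast: ", nm, " references absent categories")
    cc <- numeric(ncol(Xd))
    cc[match(names(cv), colnames(Xd))] <- cv
    (drop(cc %*% beta)) / sqrt(sigma2 * drop(t(cc) %*% XtXinv %*% cc))
  })
  attr(out, "df") <- df
  out
}

# HRF response to a boxcar of given onset/duration, evaluated at `times`;
# the boxcar is integrated at 0.1 s resolution
hrf_block_response <- function(times, onset, duration) {
  grid <- seq(0, duration, by = 0.1)
  vals <- vapply(times, function(t)
    sum(hrf_double_gamma(t - onset - grid)) * 0.1, numeric(1))
  vals
}
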