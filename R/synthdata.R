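# Synthetic BOLD generator. Every pipeline stage in the package is
# exercised against data from this module, whose ground truth (latent
# features, voxel weights, epoch lag, memorability slopes, reliable-voxel
# mask) is returned alongside the data so recovery can be measured.

#' Canonical double-gamma hemodynamic response function
#'
#' Positive gamma peaking at `peak_s`, minus an undershoot gamma peaking at
#' `undershoot_s` scaled by `1/ratio`; normalised to a maximum of 1.
#' `trunc_s` zeroes the response beyond a cutoff, which confines the
#' response to the 9-s FIR estimation window in noiseless recovery tests.
#'
#' @param t Time(s) since event onset, seconds (vectorised).
#' @param peak_s Time-to-peak of the positive lobe, seconds.
#' @param undershoot_s Time-to-peak of the undershoot lobe, seconds.
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @param trunc_s Support cutoff, seconds (`Inf` for the full response).
#' @return HRF values at `t`.
#' @export
hrf_double_gamma <- function(t, peak_s = 5, undershoot_s = 15, ratio = 6,
                             trunc_s = Inf) {
  shape1 <- peak_s + 1
  shape2 <- undershoot_s + 1
  h <- function(x) stats::dgamma(x, shape = shape1, rate = 1) -
    stats::dgamma(x, shape = shape2, rate = 1) / ratio
  peak_val <- h(peak_s)
  out <- ifelse(t > 0 & t <= trunc_s, h(pmax(t, 0)) / peak_val, 0)
  out
}

#' Ground truth for the synthetic generator
#'
#' Draws the latent quantities that define a synthetic dataset: per-video
#' latent feature vectors for the first- and third-second epochs, a shared
#' k x voxels weight map supported on a `reliable_frac` subset of voxels,
#' per-video memorability scores and decay rates, and the noise model
#' parameters. Training and testing videos share the voxel weights, so
#' encoding models fit on the training set generalise by construction.
#'
#' @param n_train,n_test Video counts in the training and testing sets.
#' @param grid Integer length-3 voxel grid, e.g. `c(8, 8, 8)`.
#' @param k Latent feature dimensionality.
#' @param signal_sd Scale of latent features (response-amplitude units).
#' @param noise_sd Innovation SD of the AR(1) measurement noise; also the
#'   per-delay beta noise in [simulate_beta_tensor()]. The default (3,
#'   with `trial_noise_sd` 1.5) is calibrated so reliable voxels show a
#'   mean Spearman-Brown split-half reliability near 0.45, the middle of
#'   the 0.3-0.6 range typical of single-voxel responses to brief events.
#' @param trial_noise_sd SD of trial-level amplitude jitter shared across
#'   delays within one presentation.
#' @param ar1_phi AR(1) coefficient of the measurement noise, |phi| < 1.
#' @param baseline_amp Mean evoked response amplitude at reliable voxels,
#'   added to each epoch's stimulus-specific amplitude: visual stimulation
#'   evokes a positive response on every trial, on top of which the
#'   stimulus-specific pattern varies. Without it, a multiplicative
#'   memorability modulation would leave response magnitude uncorrelated
#'   with memorability across videos.
#' @param epoch_lag_s Onset lag of third-epoch content, seconds.
#' @param memorability_effect Per-voxel slope scaling response amplitude by
#'   `(1 + effect * score)`; scalar is applied at reliable voxels only.
#' @param reliable_frac Fraction of voxels carrying stimulus signal.
#' @param drift_sd SD of the low-frequency cosine drift amplitudes.
#' @param mem_mean,mem_sd,decay_mean,decay_sd Memorability distribution.
#' @param seed Integer seed.
#' @return A `ground_truth` list.
#' @export
synth_truth <- function(n_train = 60, n_test = 12, grid = c(8, 8, 8), k = 10,
                        signal_sd = 1, noise_sd = 3, trial_noise_sd = 1.5,
                        ar1_phi = 0.4, baseline_amp = 1, epoch_lag_s = 2,
                        memorability_effect = 0, reliable_frac = 0.3,
                        drift_sd = 1,
                        mem_mean = 0.8422, mem_sd = 0.0888,
                        decay_mean = -0.0014, decay_sd = 0.0011, seed) {
  stopifnot(abs(ar1_phi) < 1, noise_sd >= 0, length(grid) == 3)
  n_vox <- prod(grid)
  with_seed(seed, {
    n_videos <- n_train + n_test
    latent1 <- matrix(stats::rnorm(n_videos * k, sd = signal_sd), n_videos, k)
    latent3 <- matrix(stats::rnorm(n_videos * k, sd = signal_sd), n_videos, k)
    reliable <- rep(FALSE, n_vox)
    reliable[sample(n_vox, max(1L, round(reliable_frac * n_vox)))] <- TRUE
    weights <- matrix(0, k, n_vox)
    weights[, reliable] <- stats::rnorm(k * sum(reliable), sd = 1 / sqrt(k))
    mem <- generate_memorability(n_videos, mean = mem_mean, sd = mem_sd,
                                 decay_mean = decay_mean, decay_sd = decay_sd,
                                 seed = sample.int(2^31 - 1L, 1L))
    slope <- rep(0, n_vox)
    slope[reliable] <- memorability_effect
    width <- max(4L, nchar(as.character(max(n_train, n_test))))
    structure(list(
      n_train = n_train, n_test = n_test, grid = grid, k = k,
      train_ids = sprintf("train%0*d", width, seq_len(n_train)),
      test_ids = sprintf("test%0*d", width, seq_len(n_test)),
      latent1 = latent1, latent3 = latent3,
      voxel_weights = weights, reliable_voxel_mask = reliable,
      signal_sd = signal_sd, noise_sd = noise_sd,
      trial_noise_sd = trial_noise_sd, ar1_phi = ar1_phi,
      baseline_amp = baseline_amp,
      epoch_lag_s = epoch_lag_s, memorability_effect = slope,
      drift_sd = drift_sd, memorability = mem), class = "ground_truth")
  })
}

# amplitude of video `ids` at every voxel for one epoch; memorability scales
# the response multiplicatively
truth_amplitudes <- function(truth, ids, epoch = 1L) {
  all_ids <- c(truth$train_ids, truth$test_ids)
  idx <- match(ids, all_ids)
  if (anyNA(idx)) stop("unknown video id(s) in schedule")
  latent <- if (epoch == 1L) truth$latent1 else truth$latent3
  amp <- latent[idx, , drop = FALSE] %*% truth$voxel_weights
  base <- truth$baseline_amp * as.numeric(truth$reliable_voxel_mask)
  amp <- sweep(amp, 2L, base, `+`)
  scale <- 1 + outer(truth$memorability$memorability[idx], truth$memorability_effect)
  amp * scale
}

#' Generate synthetic BOLD volume series for a schedule
#'
#' For every run in `schedules`, samples a voxels-by-time BOLD series at the
#' acquisition TR. Each stimulus trial adds a double-gamma response whose
#' amplitude at voxel v is the epoch-1 latent projected through the voxel
#' weights at the trial onset, plus the epoch-3 latent at onset +
#' `epoch_lag_s`, both scaled by `(1 + memorability_effect_v * score)`.
#' Additive noise is AR(1) with innovation SD `noise_sd`, plus a
#' low-frequency cosine drift (3 components below 1/128 Hz) that the GLM
#' high-pass removes by construction. Trial-level amplitude jitter
#' (`trial_noise_sd`) makes repeated presentations of a video differ.
#'
#' @param schedules A `session_schedule_list` from [build_session_schedule()].
#' @param truth A `ground_truth` from [synth_truth()].
#' @param seed Integer seed (required).
#' @param tr_s Sampling TR; defaults to each run's acquisition TR.
#' @param hrf_trunc_s HRF support cutoff passed to [hrf_double_gamma()].
#' @param noise_sd,drift_sd,trial_noise_sd Optional overrides of the truth.
#' @return List of `volume_series` objects: time-by-voxel matrices with
#'   attributes `tr_s`, `run_type`, `run`, `session`, `grid`, `events`.
#' @export
generate_dataset <- function(schedules, truth, seed, tr_s = NULL,
                             hrf_trunc_s = Inf, noise_sd = NULL,
                             drift_sd = NULL, trial_noise_sd = NULL) {
  if (missing(seed)) stop("seed is required: all randomness must be seeded")
  noise_sd <- if (is.null(noise_sd)) truth$noise_sd else noise_sd
  drift_sd <- if (is.null(drift_sd)) truth$drift_sd else drift_sd
  trial_noise_sd <- if (is.null(trial_noise_sd)) truth$trial_noise_sd else trial_noise_sd
  n_vox <- prod(truth$grid)
  with_seed(seed, {
    out <- list()
    for (sess in schedules) {
      for (r in seq_along(sess$runs)) {
        run <- sess$runs[[r]]
        tr <- if (is.null(tr_s)) run$tr_s else tr_s
        n_t <- compute_run_volumes(nrow(run$events), run$trial_s,
                                   run$lead_in_s, run$lead_out_s, tr)
        times <- (seq_len(n_t) - 1) * tr
        y <- matrix(0, n_t, n_vox)
        ev <- run$events
        stim <- which(!is.na(ev$condition))
        if (length(stim)) {
          amp1 <- truth_amplitudes(truth, ev$condition[stim], 1L)
          amp3 <- truth_amplitudes(truth, ev$condition[stim], 3L)
          for (i in seq_along(stim)) {
            onset <- ev$onset[stim[i]]
            jit <- stats::rnorm(n_vox, sd = trial_noise_sd)
            h1 <- hrf_double_gamma(times - onset, trunc_s = hrf_trunc_s)
            h3 <- hrf_double_gamma(times - onset - truth$epoch_lag_s,
                                   trunc_s = hrf_trunc_s)
            nz <- which(h1 != 0 | h3 != 0)
            if (length(nz))
              y[nz, ] <- y[nz, ] + outer(h1[nz], amp1[i, ] + jit) +
                outer(h3[nz], amp3[i, ] + jit)
          }
        }
        if (noise_sd > 0) {
          innov <- matrix(stats::rnorm(n_t * n_vox, sd = noise_sd), n_t, n_vox)
          y <- y + apply(innov, 2L, function(e)
            as.numeric(stats::filter(e, truth$ar1_phi, method = "recursive")))
        }
        if (drift_sd > 0) {
          # slow cosines on the DCT phase convention, frequencies below the
          # 1/128 Hz cutoff, so the GLM high-pass spans them by construction
          i0 <- seq_len(n_t) - 1
          for (kk in 1:3) {
            if (kk / (2 * n_t * tr) < 1 / 128)
              y <- y + outer(cos(pi * kk * (2 * i0 + 1) / (2 * n_t)),
                             stats::rnorm(n_vox, sd = drift_sd))
          }
        }
        attr(y, "tr_s") <- tr
        attr(y, "run_type") <- run$run_type
        attr(y, "run") <- r
        attr(y, "session") <- sess$session_index
        attr(y, "grid") <- truth$grid
        attr(y, "events") <- ev
        class(y) <- c("volume_series", class(y))
        out[[length(out) + 1L]] <- y
      }
    }
    out
  })
}

#' Simulate an FIR beta tensor directly from the generative model
#'
#' Draws trial-wise FIR amplitude estimates (stimulus x repetition x delay
#' x voxel) without passing through time-series simulation and GLM fitting:
#' the noiseless value at delay d is `amp1 * h(d) + amp3 * h(d - lag)`,
#' to which trial-level amplitude jitter (shared across delays) and
#' independent per-delay noise are added. This is the standing input for
#' the downstream reliability, encoding, RSA, variance-partitioning and
#' memorability stages, whose recovery tests need betas at scales where
#' full GLM estimation would be slow.
#'
#' @param truth A `ground_truth` from [synth_truth()].
#' @param set `"train"` or `"test"`.
#' @param n_reps Repetition count (canonically 3 for train, 10 for test).
#' @param seed Integer seed.
#' @param delays Delay grid in seconds post-onset.
#' @return A `beta_tensor`: 4-d array `[stimulus, repetition, delay, voxel]`
#'   with `dimnames` carrying stimulus ids.
#' @export
simulate_beta_tensor <- function(truth, set = c("test", "train"),
                                 n_reps = NULL, seed, delays = 1:9) {
  set <- match.arg(set)
  ids <- if (set == "train") truth$train_ids else truth$test_ids
  if (is.null(n_reps)) n_reps <- if (set == "train") 3L else 10L
  n_vox <- prod(truth$grid)
  amp1 <- truth_amplitudes(truth, ids, 1L)
  amp3 <- truth_amplitudes(truth, ids, 3L)
  h1 <- hrf_double_gamma(delays)
  h3 <- hrf_double_gamma(delays - truth$epoch_lag_s)
  with_seed(seed, {
    betas <- array(0, dim = c(length(ids), n_reps, length(delays), n_vox),
                   dimnames = list(ids, NULL, delays, NULL))
    for (d in seq_along(delays)) {
      sig <- amp1 * h1[d] + amp3 * h3[d]
      for (r in seq_len(n_reps)) betas[, r, d, ] <- sig
    }
    if (truth$trial_noise_sd > 0) {
      jit <- array(stats::rnorm(length(ids) * n_reps * n_vox,
                                sd = truth$trial_noise_sd),
                   dim = c(length(ids), n_reps, n_vox))
      prof <- h1 + h3
      for (d in seq_along(delays))
        betas[, , d, ] <- betas[, , d, ] + jit * prof[d]
    }
    if (truth$noise_sd > 0)
      betas <- betas + array(stats::rnorm(length(betas), sd = truth$noise_sd),
                             dim = dim(betas))
    structure(betas, class = c("beta_tensor", "array"), delays = delays,
              grid = truth$grid)
  })
}

#' Generate annotation embeddings with controllable structure
#'
#' Emulates five independent human annotations per video and metadata
#' category: each annotation is the video's true latent embedding plus
#' isotropic annotator noise. Word-level categories (object, scene, action)
#' use `dims["word"]`-dimensional latents and the sentence category uses
#' `dims["sentence"]` dimensions. `cross_cat_rho` mixes a shared per-video
#' latent into every category so that metadata dissimilarity structure can
#' be made correlated across categories.
#'
#' @param n_videos Number of videos.
#' @param dims Named vector `c(word = 300, sentence = 384)`.
#' @param annotator_noise_sd Annotator noise SD, embedding units.
#' @param cross_cat_rho Latent cross-category correlation in `[0, 1)`.
#' @param n_annotations Annotations per video per category.
#' @param seed Integer seed.
#' @return An `embedding_set`: per category (`object`, `scene`, `action`,
#'   `sentence`) an array `[video, annotation, dim]`, plus the true latents.
#' @export
generate_metadata_embeddings <- function(n_videos,
                                         dims = c(word = 300, sentence = 384),
                                         annotator_noise_sd = 0.1,
                                         cross_cat_rho = 0,
                                         n_annotations = 5L, seed) {
  if (!all(c("word", "sentence") %in% names(dims)))
    stop("dimension mismatch: dims must name 'word' and 'sentence'")
  stopifnot(cross_cat_rho >= 0, cross_cat_rho < 1)
  cats <- c(object = "word", scene = "word", action = "word",
            sentence = "sentence")
  with_seed(seed, {
    dmax <- max(dims)
    shared <- matrix(stats::rnorm(n_videos * dmax), n_videos, dmax)
    latents <- list()
    emb <- list()
    for (cat in names(cats)) {
      d <- dims[[cats[[cat]]]]
      own <- matrix(stats::rnorm(n_videos * d), n_videos, d)
      lat <- sqrt(cross_cat_rho) * shared[, seq_len(d), drop = FALSE] +
        sqrt(1 - cross_cat_rho) * own
      latents[[cat]] <- lat
      a <- array(NA_real_, dim = c(n_videos, n_annotations, d))
      for (j in seq_len(n_annotations))
        a[, j, ] <- lat + matrix(stats::rnorm(n_videos * d,
                                              sd = annotator_noise_sd),
                                 n_videos, d)
      emb[[cat]] <- a
    }
    structure(list(embeddings = emb, latents = latents,
                   n_annotations = n_annotations),
              class = "embedding_set")
  })
}

#' Generate memorability scores and decay rates
#'
#' Scores are normal draws clipped to `[0, 1]`; decay rates are normal
#' draws whose positive values are preserved (clipping to zero is an
#' analysis-time option, see [memorability_at_lag()]).
#'
#' @param n_videos Number of videos.
#' @param mean,sd Score distribution (defaults match the observed stimulus
#'   set statistics: 0.8422 +/- 0.0888 at reference lag 80).
#' @param decay_mean,decay_sd Decay-rate distribution (defaults -0.0014
#'   +/- 0.0011 per lag unit).
#' @param seed Integer seed.
#' @return Data frame with `video`, `memorability`, `decay`.
#' @export
generate_memorability <- function(n_videos, mean = 0.8422, sd = 0.0888,
                                  decay_mean = -0.0014, decay_sd = 0.0011,
                                  seed) {
  if (mean <= 0 || mean >= 1) stop("mean memorability must lie in (0, 1)")
  stopifnot(sd >= 0, decay_sd >= 0)
  with_seed(seed, {
    scores <- pmin(1, pmax(0, stats::rnorm(n_videos, mean, sd)))
    decay <- stats::rnorm(n_videos, decay_mean, decay_sd)
    data.frame(video = seq_len(n_videos), memorability = scores,
               decay = decay)
  })
}
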