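# Canonical run geometry: every trial (stimulus or null) is 4 s long
# (3 s video + 1 s intertrial, or 4 s gray screen for nulls).

#' Number of acquisition volumes in a run
#'
#' Computes the number of volumes needed to cover a run consisting of a
#' fixation lead-in, `n_trials` equal-length trials, and a fixation
#' lead-out, at acquisition repetition time `tr_s`. The total duration is
#' divided by the TR and rounded up; for the canonical parameter sets the
#' division is exact (e.g. 113 trials of 4 s with 4 s lead-in and 13 s
#' lead-out at TR 1.75 s gives exactly 268 volumes).
#'
#' @param n_trials Number of trials in the run.
#' @param trial_s Trial duration in seconds.
#' @param lead_in_s Fixation duration before the first trial, seconds.
#' @param lead_out_s Fixation duration after the last trial, seconds.
#' @param tr_s Acquisition repetition time, seconds.
#' @return Integer volume count.
#' @export
#' @examples
#' compute_run_volumes(113, 4, 4, 13, 1.75)   # 268
#' compute_run_volumes(100, 4, 4, 12.5, 1.75) # 238
compute_run_volumes <- function(n_trials, trial_s, lead_in_s, lead_out_s, tr_s) {
  if (trial_s <= 0 || tr_s <= 0 || lead_in_s < 0 || lead_out_s < 0)
    stop("non-positive duration: trial_s and tr_s must be > 0, leads >= 0")
  total_s <- lead_in_s + n_trials * trial_s + lead_out_s
  as.integer(ceiling(total_s / tr_s - 1e-9))
}

run_schedule <- function(run_type, events, lead_in_s, lead_out_s, tr_s, trial_s = 4) {
  n_volumes <- compute_run_volumes(nrow(events), trial_s, lead_in_s, lead_out_s, tr_s)
  structure(list(run_type = run_type, events = events,
                 lead_in_s = lead_in_s, lead_out_s = lead_out_s,
                 tr_s = tr_s, trial_s = trial_s, n_volumes = n_volumes),
            class = "run_schedule")
}

# shuffle a multiset (character vector) so that no two equal elements are
# adjacent; rejection-sampled with bounded retries
shuffle_no_adjacent <- function(ids, max_attempts = 10000L) {
  if (length(ids) < 2L) return(sample(ids, length(ids)))
  for (i in seq_len(max_attempts)) {
    s <- sample(ids, length(ids))
    if (!any(s[-1L] == s[-length(s)])) return(s)
  }
  stop("constraint violation: could not order trials without consecutive ",
       "repetition after ", max_attempts, " attempts")
}

# default runs-per-session: fewest runs with at most 85 stimulus trials each
# that divide the per-session presentation count evenly
auto_runs_per_session <- function(pres_per_session, max_stim_per_run = 85L) {
  r <- max(1L, as.integer(ceiling(pres_per_session / max_stim_per_run)))
  while (pres_per_session %% r != 0L) r <- r + 1L
  r
}

#' Build a balanced multi-session trial schedule
#'
#' Schedules `n_train_videos` training videos for `train_reps` presentations
#' and `n_test_videos` testing videos for `test_reps` presentations across
#' `n_sessions` scanning sessions. Each session holds
#' `test_runs_per_session` testing runs and `train_runs_per_session`
#' training runs in randomized order with no two testing runs adjacent.
#' Null (fixation) trials are interleaved at 25% of each run's trials
#' (`round(n_stim / 3)` nulls per run), and no video is presented on two
#' consecutive stimulus trials. Training videos are never repeated within a
#' session; testing videos may be.
#'
#' The canonical configuration (1000 training videos x 3 reps, 102 testing
#' videos x 10 reps, 4 sessions) yields 85 + 28 = 113 trials per testing
#' run, 75 + 25 = 100 trials per training run, 255 testing presentations
#' per session and 4020 stimulus trials per participant.
#'
#' @param n_train_videos,n_test_videos Video counts in each stimulus set.
#' @param train_reps,test_reps Presentations per video.
#' @param n_sessions Number of sessions.
#' @param seed Integer seed; schedules are a pure function of the arguments.
#' @param train_runs_per_session,test_runs_per_session Runs per session;
#'   `NULL` selects the fewest runs of at most 85 stimulus trials that tile
#'   the per-session presentation count (10 and 3 for the canonical set).
#' @param trial_s,lead_in_s,tr_s Run timing, seconds.
#' @param test_lead_out_s,train_lead_out_s Final fixation, seconds.
#' @param max_attempts Bounded retries for the adjacency constraints.
#' @return List of `session_schedule` objects (fields `runs`,
#'   `session_index`), classed `session_schedule_list`.
#' @export
build_session_schedule <- function(n_train_videos, n_test_videos,
                                   train_reps, test_reps, n_sessions, seed,
                                   train_runs_per_session = NULL,
                                   test_runs_per_session = NULL,
                                   trial_s = 4, lead_in_s = 4,
                                   test_lead_out_s = 13, train_lead_out_s = 12.5,
                                   tr_s = 1.75, max_attempts = 10000L) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  stopifnot(n_train_videos >= 1, n_test_videos >= 1,
            train_reps >= 1, test_reps >= 1, n_sessions >= 1)
  total_train <- n_train_videos * train_reps
  total_test <- n_test_videos * test_reps
  if (total_train %% n_sessions != 0L)
    stop("infeasible configuration: training presentations do not tile into sessions")
  if (total_test %% n_sessions != 0L)
    stop("infeasible configuration: testing presentations do not tile into sessions")
  train_per_session <- total_train %/% n_sessions
  test_per_session <- total_test %/% n_sessions
  if (train_reps > n_sessions)
    stop("infeasible configuration: train_reps > n_sessions would repeat a ",
         "training video within a session")
  if (n_train_videos %% n_sessions != 0L && train_reps < n_sessions)
    stop("infeasible configuration: n_train_videos must divide evenly into sessions")
  if (is.null(train_runs_per_session))
    train_runs_per_session <- auto_runs_per_session(train_per_session)
  if (is.null(test_runs_per_session))
    test_runs_per_session <- auto_runs_per_session(test_per_session)
  if (train_per_session %% train_runs_per_session != 0L)
    stop("infeasible configuration: training presentations do not tile into runs")
  if (test_per_session %% test_runs_per_session != 0L)
    stop("infeasible configuration: testing presentations do not tile into runs")
  train_stim_per_run <- train_per_session %/% train_runs_per_session
  test_stim_per_run <- test_per_session %/% test_runs_per_session

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  width <- max(4L, nchar(as.character(max(n_train_videos, n_test_videos))))
  train_ids <- sprintf("train%0*d", width, seq_len(n_train_videos))
  test_ids <- sprintf("test%0*d", width, seq_len(n_test_videos))

  # training videos: each video occupies train_reps consecutive sessions
  # (cyclically) from a balanced random offset, so no session repeats a video
  if (train_reps == n_sessions) {
    offsets <- rep(0L, n_train_videos)
  } else {
    offsets <- sample(rep(seq_len(n_sessions) - 1L, length.out = n_train_videos))
  }
  train_sessions <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) train_sessions[[s]] <- character(0)
  for (v in seq_len(n_train_videos)) {
    ss <- (offsets[v] + seq_len(train_reps) - 1L) %% n_sessions + 1L
    for (s in ss) train_sessions[[s]] <- c(train_sessions[[s]], train_ids[v])
  }
  if (any(lengths(train_sessions) != train_per_session))
    stop("infeasible configuration: unbalanced training session assignment")

  # testing videos: floor(reps/sessions) everywhere plus remainder sessions
  # assigned greedily against per-session quotas
  base <- test_reps %/% n_sessions
  rem <- test_reps %% n_sessions
  test_counts <- matrix(base, nrow = n_test_videos, ncol = n_sessions)
  if (rem > 0L) {
    quota <- test_per_session - base * n_test_videos
    if (quota * n_sessions != rem * n_test_videos)
      stop("infeasible configuration: testing remainder does not balance")
    remaining <- rep(quota, n_sessions)
    for (v in sample(seq_len(n_test_videos))) {
      pick <- order(remaining + stats::runif(n_sessions, 0, 0.5),
                    decreasing = TRUE)[seq_len(rem)]
      test_counts[v, pick] <- test_counts[v, pick] + 1L
      remaining[pick] <- remaining[pick] - 1L
    }
    if (any(remaining != 0L))
      stop("constraint violation: testing presentations could not be balanced")
  }

  sessions <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    # run-type order with no two test runs back-to-back
    types <- c(rep("test", test_runs_per_session), rep("train", train_runs_per_session))
    ok <- FALSE
    for (i in seq_len(max_attempts)) {
      ord <- sample(types)
      tpos <- which(ord == "test")
      if (length(tpos) < 2L || all(diff(tpos) > 1L)) { ok <- TRUE; break }
    }
    if (!ok)
      stop("constraint violation: could not order runs without adjacent test runs")

    train_seq <- shuffle_no_adjacent(train_sessions[[s]], max_attempts)
    test_seq <- shuffle_no_adjacent(rep(test_ids, times = test_counts[, s]), max_attempts)
    ti <- 0L; ei <- 0L
    runs <- vector("list", length(ord))
    for (r in seq_along(ord)) {
      if (ord[r] == "test") {
        stim <- test_seq[ei + seq_len(test_stim_per_run)]; ei <- ei + test_stim_per_run
        lead_out <- test_lead_out_s
      } else {
        stim <- train_seq[ti + seq_len(train_stim_per_run)]; ti <- ti + train_stim_per_run
        lead_out <- train_lead_out_s
      }
      n_null <- as.integer(round(length(stim) / 3))
      cond <- rep(NA_character_, length(stim) + n_null)
      cond[sort(sample(seq_along(cond), length(stim)))] <- stim
      events <- data.frame(
        onset = lead_in_s + (seq_along(cond) - 1) * trial_s,
        duration = trial_s,
        condition = cond,
        repetition = NA_integer_,
        stringsAsFactors = FALSE)
      runs[[r]] <- run_schedule(ord[r], events, lead_in_s, lead_out, tr_s, trial_s)
    }
    sessions[[s]] <- structure(list(runs = runs, session_index = s),
                               class = "session_schedule")
  }

  # chronological repetition index per video
  seen <- new.env(parent = emptyenv())
  for (s in seq_len(n_sessions)) {
    for (r in seq_along(sessions[[s]]$runs)) {
      ev <- sessions[[s]]$runs[[r]]$events
      for (k in seq_len(nrow(ev))) {
        id <- ev$condition[k]
        if (!is.na(id)) {
          n <- if (is.null(seen[[id]])) 1L else seen[[id]] + 1L
          seen[[id]] <- n
          ev$repetition[k] <- n
        }
      }
      sessions[[s]]$runs[[r]]$events <- ev
    }
  }

  reps <- unlist(as.list(seen))
  if (any(reps[grep("^train", names(reps))] != train_reps) ||
      any(reps[grep("^test", names(reps))] != test_reps))
    stop("internal scheduling error: presentation counts off target")
  structure(sessions, class = "session_schedule_list")
}

#' Count stimulus presentations in a schedule
#'
#' Tallies non-null (stimulus) presentations by video set at the requested
#' scope. For the canonical schedule this reproduces 4020 stimulus trials
#' per participant, 40,200 across 10 subjects, 3000/1020 training/testing
#' presentations, and 255 testing presentations per session.
#'
#' @param schedules Result of [build_session_schedule()].
#' @param scope One of `"per_session"`, `"per_participant"`, `"total"`.
#' @param n_subjects Subject count (used for `scope = "total"`).
#' @return Data frame of counts with columns `train`, `test` and `total`
#'   (one row per session for `"per_session"`, one row otherwise).
#' @export
count_trials <- function(schedules, scope = c("per_participant", "per_session", "total"),
                         n_subjects = 1L) {
  scope <- match.arg(scope)
  if (length(schedules) == 0L) stop("empty schedule")
  per_session <- do.call(rbind, lapply(schedules, function(sess) {
    conds <- unlist(lapply(sess$runs, function(r) r$events$condition))
    conds <- conds[!is.na(conds)]
    data.frame(session = sess$session_index,
               train = sum(grepl("^train", conds)),
               test = sum(grepl("^test", conds)))
  }))
  per_session$total <- per_session$train + per_session$test
  if (scope == "per_session") return(per_session)
  out <- data.frame(train = sum(per_session$train), test = sum(per_session$test))
  out$total <- out$train + out$test
  if (scope == "total")
    out[] <- lapply(out, function(x) as.integer(x * n_subjects))
  out
}

#' Write BIDS-style events tables for a schedule
#'
#' Writes one tab-separated events file per run with columns
#' `onset duration condition repetition run session`; onsets carry three
#' decimals and null trials use the condition label `n/a`.
#'
#' @param schedules Result of [build_session_schedule()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_events_tsv <- function(schedules, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (sess in schedules) {
    for (r in seq_along(sess$runs)) {
      ev <- sess$runs[[r]]$events
      out <- data.frame(onset = sprintf("%.3f", ev$onset),
                        duration = sprintf("%.3f", ev$duration),
                        condition = ifelse(is.na(ev$condition), "n/a", ev$condition),
                        repetition = ifelse(is.na(ev$condition), "n/a",
                                            as.character(ev$repetition)),
                        run = r, session = sess$session_index)
      path <- file.path(dir, sprintf("ses-%02d_run-%02d_events.tsv",
                                     sess$session_index, r))
      utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, path)
    }
  }
  invisible(paths)
}

#' Read an events table written by [write_events_tsv()]
#' @param path Path to a tab-separated events file.
#' @return Data frame with `onset`, `duration`, `condition` (NA for nulls),
#'   `repetition`, `run`, `session`.
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "n/a")
  ev$repetition <- suppressWarnings(as.integer(ev$repetition))
  ev
}
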