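#' Configuration for a synthetic microendoscopy session
#'
#' Describes one simulated recording session: independent Poisson background
#' event trains on every cell, optional planted pairwise synchrony (a shared
#' Poisson process copied to both members with small jitter), optional planted
#' ordered event sequences, optional direction-tuned task responses, and a
#' behavioral trial table. The defaults emulate sparse deconvolved calcium
#' event trains on a 10 Hz frame grid.
#'
#' @param n_cells number of cells.
#' @param duration_s recording duration in seconds (events live in
#'   `[0, duration_s)`).
#' @param base_rate_hz background event rate per cell, events/s; a scalar or a
#'   vector of length `n_cells`.
#' @param frame_rate_hz fluorescence sampling rate, frames/s.
#' @param synchrony optional list of planted common-input pairs; each element
#'   is a list with `cells` (two cell indices or ids), `shared_rate_hz`, and
#'   `jitter_s` (each shared event is copied to both members with independent
#'   uniform jitter on `[0, jitter_s]`; default 0.2 s, one coactivation bin).
#' @param motifs optional list of planted ordered sequences; each element has
#'   `cells` (ordered, distinct), `step_lags_s` (one lag per consecutive step,
#'   each in (0.05, 2] s after jitter), `n_plants`, and optional `lag_jitter_s`
#'   (uniform on `[-lag_jitter_s, lag_jitter_s]` per step, default 0).
#' @param tuning optional list of direction-tuned task responses; each element
#'   has `cell`, `direction` (a task direction, or `"all"` for an untuned but
#'   task-responsive cell), `gain` (multiplicative rate gain inside the
#'   response window; default 10, i.e. a rest-to-burst transition of the
#'   event rate), and `window_s` (response window after target
#'   onset, default 1 s).
#' @param task `NULL` for a spontaneous-only session, else `"one_target"`
#'   (directions left/center/right) or `"two_target"` (left/right, with a
#'   movement-onset event after a 1-s hold).
#' @param n_trials number of trials when `task` is set.
#' @param task_start_s time at which the trial block starts.
#' @param amplitude_meanlog,amplitude_sdlog log-normal event-amplitude
#'   parameters (positive, right-skewed like deconvolved amplitudes).
#' @param kernel_tau_s,noise_sd single-exponential calcium kernel decay and
#'   additive Gaussian trace noise used when rendering traces.
#' @param seed integer seed; the whole session is a deterministic function of
#'   the configuration including this seed.
#'
#' @return A validated list of class `ca_sim_config`.
#' @seealso [simulate_session()]
#' @export
sim_config <- function(n_cells,
                       duration_s,
                       base_rate_hz = 0.2,
                       frame_rate_hz = 10,
                       synchrony = NULL,
                       motifs = NULL,
                       tuning = NULL,
                       task = NULL,
                       n_trials = 0L,
                       task_start_s = 0,
                       amplitude_meanlog = 0,
                       amplitude_sdlog = 0.5,
                       kernel_tau_s = 0.5,
                       noise_sd = 0.1,
                       seed = 1L) {
  stopifnot(n_cells >= 1, duration_s > 0, frame_rate_hz > 0, kernel_tau_s > 0,
            noise_sd >= 0, amplitude_sdlog >= 0)
  if (length(base_rate_hz) == 1) base_rate_hz <- rep(base_rate_hz, n_cells)
  if (length(base_rate_hz) != n_cells || any(base_rate_hz < 0)) {
    stop("`base_rate_hz` must be a scalar or length-n_cells vector of rates >= 0",
         call. = FALSE)
  }
  ids <- cell_ids(n_cells)
  resolve_cell <- function(x) {
    if (is.numeric(x)) {
      if (any(x < 1 | x > n_cells)) stop("cell index out of range", call. = FALSE)
      ids[x]
    } else {
      if (!all(x %in% ids)) stop("unknown cell id: ", paste(setdiff(x, ids), collapse = ", "),
                                 call. = FALSE)
      x
    }
  }
  synchrony <- lapply(synchrony %||% list(), function(s) {
    s$cells <- resolve_cell(s$cells)
    if (length(s$cells) != 2 || anyDuplicated(s$cells)) {
      stop("a synchrony entry needs two distinct cells", call. = FALSE)
    }
    s$jitter_s <- s$jitter_s %||% 0.2
    stopifnot(s$shared_rate_hz >= 0, s$jitter_s >= 0)
    s
  })
  motifs <- lapply(motifs %||% list(), function(m) {
    m$cells <- resolve_cell(m$cells)
    if (length(m$cells) < 2 || anyDuplicated(m$cells)) {
      stop("a motif needs >= 2 distinct ordered cells", call. = FALSE)
    }
    m$lag_jitter_s <- m$lag_jitter_s %||% 0
    if (length(m$step_lags_s) != length(m$cells) - 1) {
      stop("motif needs one step lag per consecutive cell pair", call. = FALSE)
    }
    lo <- m$step_lags_s - m$lag_jitter_s
    hi <- m$step_lags_s + m$lag_jitter_s
    if (any(lo <= 0.05) || any(hi > 2)) {
      stop("motif step lags must lie in (0.05, 2] s after jitter", call. = FALSE)
    }
    stopifnot(m$n_plants >= 1)
    m
  })
  if (!is.null(task)) task <- match.arg(task, c("one_target", "two_target"))
  tuning <- lapply(tuning %||% list(), function(tu) {
    tu$cell <- resolve_cell(tu$cell)
    tu$gain <- tu$gain %||% 10
    tu$window_s <- tu$window_s %||% 1
    stopifnot(tu$gain >= 0, tu$window_s > 0)
    dirs <- c(task_directions(task %||% "one_target"), "all")
    if (!tu$direction %in% dirs) {
      stop("tuning direction must be one of: ", paste(dirs, collapse = ", "),
           call. = FALSE)
    }
    tu
  })
  if (length(tuning) && is.null(task)) {
    stop("`tuning` requires a task", call. = FALSE)
  }
  structure(
    list(n_cells = as.integer(n_cells), duration_s = duration_s,
         base_rate_hz = base_rate_hz, frame_rate_hz = frame_rate_hz,
         synchrony = synchrony, motifs = motifs, tuning = tuning,
         task = task, n_trials = as.integer(n_trials),
         task_start_s = task_start_s,
         amplitude_meanlog = amplitude_meanlog,
         amplitude_sdlog = amplitude_sdlog,
         kernel_tau_s = kernel_tau_s, noise_sd = noise_sd,
         seed = as.integer(seed), cell_ids = ids),
    class = "ca_sim_config"
  )
}

task_directions <- function(task) {
  switch(task,
         one_target = c("left", "center", "right"),
         two_target = c("left", "right"),
         stop("unknown task: ", task, call. = FALSE))
}

#' Simulate a behavioral trial table
#'
#' Trials follow the center-out touchscreen reaching structure: each trial is
#' preceded by a random inter-trial interval drawn uniformly from 2-3 s, the
#' rewarded target appears in a uniformly random direction (three directions
#' for the one-target task, two for the two-target task), and two-target
#' trials add a movement-onset time after a 1-s hold at the center target.
#' Timestamps are strictly increasing.
#'
#' @param task `"one_target"` or `"two_target"`.
#' @param n_trials number of trials (>= 1).
#' @param seed optional integer seed (local to this call).
#' @param t_start session time at which the first inter-trial interval begins.
#' @param p_success probability a trial is successful (default 1).
#' @return A tibble with columns `trial_id`, `iti_start_s`, `target_onset_s`,
#'   `direction`, `movement_onset_s` (NA for one-target), `success`.
#' @export
simulate_trial_table <- function(task, n_trials, seed = NULL, t_start = 0,
                                 p_success = 1) {
  task <- match.arg(task, c("one_target", "two_target"))
  stopifnot(n_trials >= 1, p_success >= 0, p_success <= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  dirs <- task_directions(task)
  iti <- runif(n_trials, 2, 3)
  direction <- sample(dirs, n_trials, replace = TRUE)
  hold_release <- if (task == "two_target") 1 + runif(n_trials, 0.1, 0.4) else rep(NA_real_, n_trials)
  # time from alignment event to end of trial (reach + reward consumption)
  post <- 2
  target_onset <- numeric(n_trials)
  movement_onset <- rep(NA_real_, n_trials)
  iti_start <- numeric(n_trials)
  cur <- t_start
  for (i in seq_len(n_trials)) {
    iti_start[i] <- cur
    target_onset[i] <- cur + iti[i]
    last <- target_onset[i]
    if (task == "two_target") {
      movement_onset[i] <- target_onset[i] + hold_release[i]
      last <- movement_onset[i]
    }
    cur <- last + post
  }
  tibble::tibble(
    trial_id = seq_len(n_trials),
    iti_start_s = iti_start,
    target_onset_s = target_onset,
    direction = direction,
    movement_onset_s = movement_onset,
    success = runif(n_trials) <= p_success
  )
}

#' Generate a full synthetic session
#'
#' Draws background events as independent homogeneous Poisson processes,
#' superimposes planted synchrony pairs (shared Poisson events copied to both
#' members with independent uniform jitter), planted ordered sequences (start
#' times drawn with rejection so occurrences of a motif never overlap within a
#' cell), and direction-tuned task responses (extra Poisson events at rate
#' `base_rate * (gain - 1)` inside the response window of matching successful
#' trials). Event amplitudes are i.i.d. log-normal. Fluorescence traces are
#' rendered from the events with [events_to_traces()], and centroids are
#' placed uniformly in a 400 x 400 micrometer field of view. The result is a
#' deterministic function of the configuration.
#'
#' @param config a [sim_config()].
#' @return An object of class `ca_session`: a list with tibbles `events`
#'   (`cell_id`, `time_s`, `amplitude`), `traces` (wide: `time_s` plus one
#'   column per cell), `centroids` (`cell_id`, `x`, `y`, `unit`), `trials`,
#'   plus `segment`, `frame_rate_hz` and a `ground_truth` list describing all
#'   planted structure.
#' @examples
#' s <- simulate_session(sim_config(n_cells = 5, duration_s = 60, seed = 1))
#' dplyr::count(s$events, cell_id)
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "ca_sim_config"))
  withr::local_seed(config$seed)
  dur <- config$duration_s
  ids <- config$cell_ids

  trials <- NULL
  if (!is.null(config$task) && config$n_trials > 0) {
    trials <- simulate_trial_table(config$task, config$n_trials,
                                   t_start = config$task_start_s)
    if (max(trials$target_onset_s) + 3 > dur) {
      stop("trial table does not fit in `duration_s`; reduce `n_trials` ",
           "or lengthen the session", call. = FALSE)
    }
  }

  ev_time <- list()
  ev_cell <- list()
  push <- function(cell, times) {
    if (length(times)) {
      ev_time[[length(ev_time) + 1]] <<- times
      ev_cell[[length(ev_cell) + 1]] <<- rep(cell, length(times))
    }
  }

  # independent homogeneous Poisson background
  for (i in seq_along(ids)) {
    n <- rpois(1, config$base_rate_hz[i] * dur)
    push(ids[i], sort(runif(n, 0, dur)))
  }

  # planted common-input pairs
  gt_sync <- purrr::map(config$synchrony, function(s) {
    n <- rpois(1, s$shared_rate_hz * dur)
    base <- sort(runif(n, 0, max(dur - s$jitter_s, 0)))
    for (cell in s$cells) push(cell, base + runif(n, 0, s$jitter_s))
    list(cells = s$cells, shared_rate_hz = s$shared_rate_hz,
         jitter_s = s$jitter_s, n_shared = n, shared_times = base)
  })

  # planted ordered sequences, rejection-sampled so occurrences of one motif
  # never overlap within a cell (keeps ground-truth counts unambiguous)
  gt_motifs <- purrr::map(config$motifs, function(m) {
    span_max <- sum(m$step_lags_s + m$lag_jitter_s)
    if (span_max >= dur) stop("motif span exceeds session duration", call. = FALSE)
    occ <- matrix(NA_real_, nrow = m$n_plants, ncol = length(m$cells))
    intervals <- matrix(numeric(0), ncol = 2)
    tries <- 0L
    planted <- 0L
    while (planted < m$n_plants) {
      tries <- tries + 1L
      if (tries > 200L * m$n_plants) {
        stop("could not place motif occurrences without overlap; ",
             "reduce `n_plants` or lengthen the session", call. = FALSE)
      }
      start <- runif(1, 0, dur - span_max)
      lags <- m$step_lags_s
      if (m$lag_jitter_s > 0) {
        lags <- lags + runif(length(lags), -m$lag_jitter_s, m$lag_jitter_s)
      }
      times <- start + cumsum(c(0, lags))
      if (nrow(intervals) &&
          any(times[1] <= intervals[, 2] & times[length(times)] >= intervals[, 1])) {
        next
      }
      planted <- planted + 1L
      occ[planted, ] <- times
      intervals <- rbind(intervals, c(times[1], times[length(times)]))
    }
    for (j in seq_along(m$cells)) push(m$cells[j], occ[, j])
    list(cells = m$cells, step_lags_s = m$step_lags_s,
         n_plants = m$n_plants, occurrence_times = occ[order(occ[, 1]), , drop = FALSE])
  })

  # direction-tuned task responses
  gt_tuning <- purrr::map(config$tuning, function(tu) {
    stopifnot(!is.null(trials))
    sel <- trials$success & (tu$direction == "all" | trials$direction == tu$direction)
    onsets <- trials$target_onset_s[sel]
    extra_rate <- config$base_rate_hz[match(tu$cell, ids)] * (tu$gain - 1)
    times <- unlist(lapply(onsets, function(t0) {
      n <- rpois(1, extra_rate * tu$window_s)
      t0 + runif(n, 0, tu$window_s)
    }))
    times <- times[times < dur]
    push(tu$cell, times)
    list(cell = tu$cell, direction = tu$direction, gain = tu$gain,
         window_s = tu$window_s, n_extra = length(times))
  })

  events <- tibble::tibble(
    cell_id = unlist(ev_cell) %||% character(),
    time_s = unlist(ev_time) %||% numeric()
  )
  events <- dplyr::arrange(events, .data$cell_id, .data$time_s)
  events$amplitude <- rlnorm(nrow(events), config$amplitude_meanlog,
                             config$amplitude_sdlog)

  centroids <- tibble::tibble(
    cell_id = ids,
    x = runif(length(ids), 0, 400),
    y = runif(length(ids), 0, 400),
    unit = "um"
  )

  traces <- events_to_traces(events, duration_s = dur,
                             kernel_tau_s = config$kernel_tau_s,
                             noise_sd = config$noise_sd,
                             frame_rate_hz = config$frame_rate_hz,
                             cells = ids,
                             seed = derive_seed(config$seed, 7L))

  structure(
    list(events = events, traces = traces, centroids = centroids,
         trials = trials, segment = c(0, dur),
         frame_rate_hz = config$frame_rate_hz,
         ground_truth = list(synchrony = gt_sync, motifs = gt_motifs,
                             tuning = gt_tuning),
         config = config),
    class = "ca_session"
  )
}

#' @export
print.ca_session <- function(x, ...) {
  cat("<ca_session> ", length(unique(x$centroids$cell_id)), " cells, ",
      nrow(x$events), " events, segment [", x$segment[1], ", ", x$segment[2],
      ") s", if (!is.null(x$trials)) paste0(", ", nrow(x$trials), " trials"),
      "\n", sep = "")
  invisible(x)
}

#' Render fluorescence traces from an event train
#'
#' Each event contributes `amplitude * exp(-(t - t_event) / tau)` for
#' `t >= t_event`, sampled on the frame grid, emulating a GCaMP6f-like
#' single-exponential transient; independent Gaussian noise is added to every
#' frame.
#'
#' @param events events tibble (`cell_id`, `time_s`, `amplitude`).
#' @param duration_s trace duration; frames = `ceiling(duration_s * frame_rate_hz)`.
#' @param kernel_tau_s exponential decay constant, s.
#' @param noise_sd additive Gaussian noise sd, a.u. (0 for noiseless).
#' @param frame_rate_hz sampling rate, frames/s.
#' @param cells cell ids to render (columns of the output); defaults to the
#'   cells present in `events`.
#' @param seed optional integer seed for the noise (local to this call).
#' @return A wide tibble: `time_s` plus one column per cell.
#' @export
events_to_traces <- function(events, duration_s, kernel_tau_s = 0.5,
                             noise_sd = 0.1, frame_rate_hz = 10,
                             cells = NULL, seed = NULL) {
  assert_events(events)
  stopifnot(kernel_tau_s > 0, frame_rate_hz > 0, duration_s > 0, noise_sd >= 0)
  if (nrow(events) && (min(events$time_s) < 0 || max(events$time_s) >= duration_s)) {
    stop("event times must lie in [0, duration_s)", call. = FALSE)
  }
  cells <- cells %||% sort(unique(events$cell_id))
  n_frames <- as.integer(ceiling(duration_s * frame_rate_hz - 1e-9))
  tg <- (seq_len(n_frames) - 1) / frame_rate_hz
  mat <- matrix(0, nrow = n_frames, ncol = length(cells),
                dimnames = list(NULL, cells))
  for (j in seq_along(cells)) {
    ev <- events[events$cell_id == cells[j], ]
    for (k in seq_len(nrow(ev))) {
      i0 <- as.integer(ceiling(ev$time_s[k] * frame_rate_hz - 1e-9)) + 1L
      if (i0 > n_frames) next
      # transient is numerically zero beyond ~30 decay constants
      i1 <- min(n_frames, i0 + as.integer(ceiling(30 * kernel_tau_s * frame_rate_hz)))
      idx <- i0:i1
      mat[idx, j] <- mat[idx, j] +
        ev$amplitude[k] * exp(-(tg[idx] - ev$time_s[k]) / kernel_tau_s)
    }
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) withr::local_seed(seed)
    mat <- mat + rnorm(length(mat), 0, noise_sd)
  }
  out <- tibble::as_tibble(as.data.frame(mat))
  dplyr::bind_cols(tibble::tibble(time_s = tg), out)
}
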