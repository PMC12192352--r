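#' Configuration for trial-aligned epoch extraction
#'
#' Defaults follow the standard peri-event convention for this analysis: a
#' 3-s epoch starting 1 s before the alignment event, Z-scored per trial
#' against the first second of the inter-trial interval preceding the trial;
#' modulation contrasts the event window (0 to +1 s) against the pre-window
#' (-1 to 0 s).
#'
#' @param align_event `"target_onset"` (common to both tasks) or
#'   `"movement_onset"` (two-target task only).
#' @param epoch_s epoch bounds around the alignment event, seconds, half-open.
#' @param baseline_s length of the baseline taken from the start of the
#'   preceding inter-trial interval, seconds.
#' @param event_window_s,pre_window_s half-open windows (relative to the
#'   alignment event) whose mean Z-scores are contrasted.
#' @param alpha significance level for FDR-corrected modulation calls.
#' @param min_trials minimum successful trials per condition; conditions below
#'   this are excluded from testing and reported.
#' @return A validated list of class `ca_alignment_config`.
#' @export
alignment_config <- function(align_event = c("target_onset", "movement_onset"),
                             epoch_s = c(-1, 2), baseline_s = 1,
                             event_window_s = c(0, 1), pre_window_s = c(-1, 0),
                             alpha = 0.05, min_trials = 5L) {
  align_event <- match.arg(align_event)
  stopifnot(length(epoch_s) == 2, epoch_s[2] > epoch_s[1], baseline_s > 0,
            alpha > 0, alpha < 1, min_trials >= 2)
  for (w in list(event_window_s, pre_window_s)) {
    if (w[1] < epoch_s[1] || w[2] > epoch_s[2] || w[2] <= w[1]) {
      stop("analysis windows must be non-empty and lie within the epoch",
           call. = FALSE)
    }
  }
  structure(list(align_event = align_event, epoch_s = epoch_s,
                 baseline_s = baseline_s, event_window_s = event_window_s,
                 pre_window_s = pre_window_s, alpha = alpha,
                 min_trials = as.integer(min_trials)),
            class = "ca_alignment_config")
}

#' Extract trial-aligned, baseline-Z-scored epochs
#'
#' For every cell and successful trial, cuts the epoch around the alignment
#' event from the trace and Z-scores it against that trial's own baseline
#' (mean and sd of the first `baseline_s` seconds of the preceding
#' inter-trial interval, per cell). Event times map to the 10 Hz frame grid by
#' nearest-frame rounding. Trials whose epoch or baseline fall outside the
#' recording are dropped with a warning; cell-by-trial combinations with zero
#' baseline sd are dropped and counted (see `attr(, "n_dropped_flat")`).
#'
#' @param traces wide trace tibble (`time_s` plus one column per cell).
#' @param trials trial table; only successful trials are used.
#' @param config an [alignment_config()].
#' @return A long tibble of class `ca_epochs` with columns `trial_id`,
#'   `direction`, `cell_id`, `frame_offset` (integer frames relative to the
#'   alignment event), `time_rel_s` and `z`. Attributes: `config`,
#'   `frame_rate_hz`, `n_dropped_trials`, `n_dropped_flat`.
#' @export
extract_epochs <- function(traces, trials, config = alignment_config()) {
  stopifnot(inherits(config, "ca_alignment_config"))
  trials <- dplyr::filter(trials, .data$success)
  if (nrow(trials) == 0) stop("no successful trials to align", call. = FALSE)
  ev_time <- trials[[paste0(config$align_event, "_s")]]
  if (all(is.na(ev_time))) {
    stop("alignment event `", config$align_event, "` is missing for all trials",
         call. = FALSE)
  }
  keep <- !is.na(ev_time)
  trials <- trials[keep, ]
  ev_time <- ev_time[keep]

  fr <- trace_frame_rate(traces)
  t0 <- traces$time_s[1]
  cells <- trace_cell_columns(traces)
  mat <- as.matrix(traces[, cells, drop = FALSE])
  n_frames <- nrow(mat)

  offsets <- seq(round(config$epoch_s[1] * fr), round(config$epoch_s[2] * fr) - 1)
  n_base <- round(config$baseline_s * fr)

  f0 <- round((ev_time - t0) * fr) + 1
  b0 <- round((trials$iti_start_s - t0) * fr) + 1
  in_range <- f0 + offsets[1] >= 1 & f0 + offsets[length(offsets)] <= n_frames &
    b0 >= 1 & b0 + n_base - 1 <= n_frames
  n_dropped_trials <- sum(!in_range)
  if (n_dropped_trials > 0) {
    warning(n_dropped_trials, " trial(s) dropped: epoch or baseline outside the recording")
  }
  trials <- trials[in_range, ]
  f0 <- f0[in_range]
  b0 <- b0[in_range]
  if (nrow(trials) == 0) stop("no trials left after range checks", call. = FALSE)

  n_dropped_flat <- 0L
  pieces <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    base <- mat[b0[i]:(b0[i] + n_base - 1), , drop = FALSE]
    mu <- colMeans(base)
    sdv <- apply(base, 2, sd)
    ok <- sdv > 0
    n_dropped_flat <- n_dropped_flat + sum(!ok)
    if (!any(ok)) next
    ep <- mat[f0[i] + offsets, ok, drop = FALSE]
    z <- sweep(sweep(ep, 2, mu[ok]), 2, sdv[ok], "/")
    pieces[[i]] <- tibble::tibble(
      trial_id = trials$trial_id[i],
      direction = trials$direction[i],
      cell_id = rep(cells[ok], each = length(offsets)),
      frame_offset = rep(offsets, sum(ok)),
      z = as.vector(z)
    )
  }
  out <- dplyr::bind_rows(pieces)
  out$time_rel_s <- out$frame_offset / fr
  out <- out[, c("trial_id", "direction", "cell_id", "frame_offset",
                 "time_rel_s", "z")]
  structure(out, class = c("ca_epochs", class(out)),
            config = config, frame_rate_hz = fr,
            n_dropped_trials = n_dropped_trials,
            n_dropped_flat = n_dropped_flat)
}

window_offsets <- function(window_s, fr) {
  seq(round(window_s[1] * fr), round(window_s[2] * fr) - 1)
}

#' Test peri-event modulation of every cell in every condition
#'
#' For each cell and target direction, a two-sided Wilcoxon signed-rank test
#' across trials contrasts the per-trial mean Z in the event window with the
#' per-trial mean Z in the pre-window. Raw p-values are FDR-corrected with
#' [bh_fdr()] across all cell-by-condition tests of the session (the
#' "chamber-level" family, e.g. 129 cells x 3 conditions = 387 tests).
#' Conditions with fewer than `min_trials` trials are excluded and reported in
#' `attr(, "excluded_conditions")`.
#'
#' @param epochs a `ca_epochs` from [extract_epochs()].
#' @param config alignment config; defaults to the one stored in `epochs`.
#' @return A tibble of class `ca_modulation`, one row per tested cell x
#'   condition: `cell_id`, `direction`, `n_trials`, `mean_pre_z`,
#'   `mean_event_z`, `delta_z` (event minus pre, trial-averaged), `magnitude`
#'   (`|delta_z|`), `sign`, `statistic`, `p_value`, `p_adjusted`.
#' @export
modulation_test <- function(epochs, config = attr(epochs, "config")) {
  fr <- attr(epochs, "frame_rate_hz")
  ev_off <- window_offsets(config$event_window_s, fr)
  pre_off <- window_offsets(config$pre_window_s, fr)

  win_mean <- function(off, label) {
    epochs |>
      dplyr::filter(.data$frame_offset %in% off) |>
      dplyr::group_by(.data$cell_id, .data$direction, .data$trial_id) |>
      dplyr::summarise("{label}" := mean(.data$z), .groups = "drop")
  }
  per_trial <- dplyr::inner_join(win_mean(ev_off, "event"),
                                 win_mean(pre_off, "pre"),
                                 by = c("cell_id", "direction", "trial_id")) |>
    dplyr::filter(is.finite(.data$event), is.finite(.data$pre))

  counts <- per_trial |>
    dplyr::count(.data$cell_id, .data$direction, name = "n_trials")
  excluded <- dplyr::filter(counts, .data$n_trials < config$min_trials)

  res <- per_trial |>
    dplyr::inner_join(dplyr::filter(counts, .data$n_trials >= config$min_trials),
                      by = c("cell_id", "direction")) |>
    dplyr::group_by(.data$cell_id, .data$direction) |>
    dplyr::summarise(
      n_trials = dplyr::first(.data$n_trials),
      mean_pre_z = mean(.data$pre),
      mean_event_z = mean(.data$event),
      statistic = wilcox_guarded(.data$event, .data$pre, paired = TRUE)$statistic,
      p_value = wilcox_guarded(.data$event, .data$pre, paired = TRUE)$p.value,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      delta_z = .data$mean_event_z - .data$mean_pre_z,
      magnitude = abs(.data$delta_z),
      sign = sign(.data$delta_z),
      p_adjusted = bh_fdr(.data$p_value)
    ) |>
    dplyr::select("cell_id", "direction", "n_trials", "mean_pre_z",
                  "mean_event_z", "delta_z", "magnitude", "sign",
                  "statistic", "p_value", "p_adjusted")
  structure(res, class = c("ca_modulation", class(res)),
            alpha = config$alpha, excluded_conditions = excluded)
}

#' Classify cells by their pattern of significant conditions
#'
#' A cell with no condition significant at the FDR-corrected threshold is
#' `not_modulated`; exactly one significant condition makes it
#' `direction_related` (the significant direction is reported); two or more
#' make it `non_direction_related`.
#'
#' @param modulation a `ca_modulation` from [modulation_test()].
#' @param alpha significance level on the adjusted p-values; defaults to the
#'   level stored in `modulation`.
#' @return A tibble, one row per cell: `cell_id`, `n_significant`, `category`
#'   (factor), `preferred_direction` (`NA` unless `direction_related`).
#' @export
classify_cells <- function(modulation, alpha = attr(modulation, "alpha") %||% 0.05) {
  modulation |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      n_significant = sum(.data$p_adjusted < alpha),
      preferred_direction = if (sum(.data$p_adjusted < alpha) == 1)
        .data$direction[.data$p_adjusted < alpha] else NA_character_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      category = factor(
        dplyr::case_when(
          .data$n_significant == 0 ~ "not_modulated",
          .data$n_significant == 1 ~ "direction_related",
          TRUE ~ "non_direction_related"
        ),
        levels = c("not_modulated", "direction_related", "non_direction_related")
      )
    ) |>
    dplyr::select("cell_id", "n_significant", "category", "preferred_direction")
}

#' Compare modulation magnitudes across response signs and conditions
#'
#' Among significantly modulated cell-by-condition responses, contrasts the
#' absolute Z-score change `|delta_z|` of increasing vs decreasing responses
#' with a Mann-Whitney rank-sum test, and across target directions with a
#' Kruskal-Wallis test. A comparison whose groups are missing or singleton is
#' skipped and reported as such.
#'
#' @param modulation a `ca_modulation`.
#' @param alpha threshold on adjusted p-values selecting the modulated set.
#' @return A tibble, one row per comparison: `comparison`, `test`,
#'   `statistic`, `p_value`, `n`, `skipped`, `note`.
#' @export
magnitude_comparisons <- function(modulation,
                                  alpha = attr(modulation, "alpha") %||% 0.05) {
  sig <- dplyr::filter(modulation, .data$p_adjusted < alpha)

  inc <- sig$magnitude[sig$sign > 0]
  dec <- sig$magnitude[sig$sign < 0]
  row1 <- if (length(inc) >= 2 && length(dec) >= 2) {
    ht <- wilcox_guarded(inc, dec)
    tibble::tibble(comparison = "increase_vs_decrease", test = "wilcoxon_rank_sum",
                   statistic = ht$statistic, p_value = ht$p.value,
                   n = length(inc) + length(dec), skipped = FALSE, note = NA_character_)
  } else {
    tibble::tibble(comparison = "increase_vs_decrease", test = "wilcoxon_rank_sum",
                   statistic = NA_real_, p_value = NA_real_,
                   n = length(inc) + length(dec), skipped = TRUE,
                   note = "fewer than 2 responses of each sign")
  }

  n_dirs <- length(unique(sig$direction))
  row2 <- if (n_dirs >= 2 && all(table(sig$direction) >= 2)) {
    ht <- kruskal.test(sig$magnitude, factor(sig$direction))
    tibble::tibble(comparison = "across_conditions", test = "kruskal_wallis",
                   statistic = unname(ht$statistic), p_value = ht$p.value,
                   n = nrow(sig), skipped = FALSE, note = NA_character_)
  } else {
    tibble::tibble(comparison = "across_conditions", test = "kruskal_wallis",
                   statistic = NA_real_, p_value = NA_real_, n = nrow(sig),
                   skipped = TRUE, note = "fewer than 2 conditions with >= 2 responses")
  }
  dplyr::bind_rows(row1, row2)
}
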