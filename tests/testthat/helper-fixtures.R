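# small in-code fixtures shared across test files

make_events <- function(cell_id, time_s, amplitude = NULL) {
  tibble::tibble(
    cell_id = cell_id,
    time_s = time_s,
    amplitude = amplitude %||% rep(1, length(time_s))
  ) |> dplyr::arrange(cell_id, time_s)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

cell_ids_for <- function(n) sprintf("cell_%03d", seq_len(n))

# binary matrix -> ca_binned wrapper (for feeding hand-built matrices into
# the coactivation operations)
as_binned <- function(mat, bin_width_s = 0.2, smoothed = TRUE) {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("cell_%03d", seq_len(nrow(mat)))
  storage.mode(mat) <- "integer"
  structure(list(mat = mat, bin_width_s = bin_width_s,
                 segment = c(0, ncol(mat) * bin_width_s),
                 smoothed = smoothed, lookahead_bins = 4L),
            class = "ca_binned")
}

# a tiny task session used by alignment tests: planted cells respond by
# construction through the tuning entries
tuned_task_config <- function(n_null = 10, n_tuned = 3, n_untuned = 2,
                              n_trials = 90, seed = 1, gain = 10,
                              base_rate = 0.2) {
  n_cells <- n_null + n_tuned + n_untuned
  dirs <- c("left", "center", "right")
  tuning <- c(
    lapply(seq_len(n_tuned), function(i)
      list(cell = n_null + i, direction = dirs[(i - 1) %% 3 + 1], gain = gain)),
    lapply(seq_len(n_untuned), function(i)
      list(cell = n_null + n_tuned + i, direction = "all", gain = gain))
  )
  sim_config(n_cells = n_cells, duration_s = n_trials * 5.5 + 30,
             base_rate_hz = base_rate, task = "one_target",
             n_trials = n_trials, tuning = tuning, seed = seed)
}
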