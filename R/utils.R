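`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a module-level seed from a global seed
#'
#' Deterministic linear-congruential mixing so each pipeline stage gets its
#' own reproducible stream without seed collisions. Result is always a valid
#' 32-bit integer seed.
#'
#' @param seed integer global seed.
#' @param k integer stream index (>= 0).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 48271 + as.numeric(k) * 3167 + 1) %% 2147483647)
}

# numerical guard for half-open binning on a double grid: events landing a few
# ulp below a bin edge due to division round-off are pulled up to the edge
.bin_index <- function(t, origin, width) {
  as.integer(floor((t - origin) / width + 1e-9)) + 1L
}

assert_segment <- function(segment) {
  if (!is.numeric(segment) || length(segment) != 2 || !all(is.finite(segment)) ||
      segment[2] <= segment[1]) {
    stop("`segment` must be numeric c(start, end) with end > start", call. = FALSE)
  }
  invisible(segment)
}

assert_events <- function(events) {
  need <- c("cell_id", "time_s", "amplitude")
  miss <- setdiff(need, names(events))
  if (length(miss)) {
    stop("events table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(events$time_s))) stop("event times must be finite", call. = FALSE)
  if (any(events$amplitude <= 0)) stop("event amplitudes must be > 0", call. = FALSE)
  invisible(events)
}

events_in_segment <- function(events, segment) {
  dplyr::filter(events, .data$time_s >= segment[1], .data$time_s < segment[2])
}

# cell id factory shared by simulator and tests
cell_ids <- function(n) sprintf("cell_%03d", seq_len(n))

trace_cell_columns <- function(traces) setdiff(names(traces), "time_s")

trace_frame_rate <- function(traces) {
  dt <- diff(traces$time_s)
  if (length(dt) == 0) stop("traces must have at least two frames", call. = FALSE)
  1 / stats::median(dt)
}
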