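#' Write a session to a directory of CSV files
#'
#' Serializes the four session artifacts in fixed schemas: `events.csv`
#' (`cell_id,time_s,amplitude`, long format, one row per event),
#' `traces.csv` (`time_s` then one column per cell), `centroids.csv`
#' (`cell_id,x,y,unit`), and `trials.csv`
#' (`trial_id,iti_start_s,target_onset_s,direction,movement_onset_s,success`;
#' header-only when the session has no trials). A small `session.json` records
#' segment bounds, frame rate and, for simulated sessions, the seed. Event
#' times survive a round trip at better than microsecond precision.
#'
#' @param session a `ca_session` (from [simulate_session()] or
#'   [read_session()]).
#' @param dir output directory (created if needed).
#' @return Invisibly, a named character vector of the written file paths.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "ca_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- c(events = file.path(dir, "events.csv"),
         traces = file.path(dir, "traces.csv"),
         centroids = file.path(dir, "centroids.csv"),
         trials = file.path(dir, "trials.csv"),
         meta = file.path(dir, "session.json"))
  readr::write_csv(session$events, p[["events"]])
  readr::write_csv(session$traces, p[["traces"]])
  readr::write_csv(session$centroids, p[["centroids"]])
  trials <- session$trials
  if (is.null(trials)) {
    trials <- tibble::tibble(trial_id = integer(), iti_start_s = numeric(),
                             target_onset_s = numeric(), direction = character(),
                             movement_onset_s = numeric(), success = logical())
  }
  readr::write_csv(trials, p[["trials"]])
  meta <- list(segment = session$segment, frame_rate_hz = session$frame_rate_hz)
  if (!is.null(session$config)) meta$seed <- session$config$seed
  jsonlite::write_json(meta, p[["meta"]], auto_unbox = TRUE, digits = NA)
  invisible(p)
}

read_csv_quiet <- function(path, col_types) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # schema violations are reported by the explicit checks below, not by
  # readr's parser chatter
  suppressWarnings(readr::read_csv(path, col_types = col_types, progress = FALSE))
}

schema_fail <- function(file, row, rule) {
  stop(sprintf("%s: row %d violates rule \"%s\"", basename(file), row, rule),
       call. = FALSE)
}

#' Read and validate a session from CSV files
#'
#' The inverse of [write_session()]. All type invariants are enforced at read
#' time; a violation produces an error naming the file, the offending row and
#' the rule. Cells appearing in the events table but missing from the
#' centroids table are an error listing the offenders. The trials file may be
#' absent or header-only (spontaneous-only sessions). Segment bounds and frame
#' rate come from `session.json` when present, otherwise they are derived from
#' the trace time grid.
#'
#' @param dir directory containing the session CSVs, or `NULL` if the four
#'   paths are given explicitly.
#' @param events_path,traces_path,centroids_path,trials_path explicit file
#'   paths overriding `dir`.
#' @return A validated `ca_session`.
#' @export
read_session <- function(dir = NULL, events_path = NULL, traces_path = NULL,
                         centroids_path = NULL, trials_path = NULL) {
  if (!is.null(dir)) {
    events_path <- events_path %||% file.path(dir, "events.csv")
    traces_path <- traces_path %||% file.path(dir, "traces.csv")
    centroids_path <- centroids_path %||% file.path(dir, "centroids.csv")
    trials_path <- trials_path %||% file.path(dir, "trials.csv")
  }

  events <- read_csv_quiet(events_path, readr::cols(
    cell_id = readr::col_character(), time_s = readr::col_double(),
    amplitude = readr::col_double()))
  need <- c("cell_id", "time_s", "amplitude")
  if (length(miss <- setdiff(need, names(events)))) {
    stop(basename(events_path), ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(events)) {
    bad <- which(!is.finite(events$time_s))
    if (length(bad)) schema_fail(events_path, bad[1], "time_s finite")
    bad <- which(!is.finite(events$amplitude) | events$amplitude <= 0)
    if (length(bad)) schema_fail(events_path, bad[1], "amplitude > 0")
    unsorted <- events |>
      dplyr::mutate(.row = dplyr::row_number()) |>
      dplyr::group_by(.data$cell_id) |>
      dplyr::filter(.data$time_s < dplyr::lag(.data$time_s, default = -Inf)) |>
      dplyr::ungroup()
    if (nrow(unsorted)) {
      schema_fail(events_path, unsorted$.row[1], "time_s sorted within cell")
    }
  }

  traces <- read_csv_quiet(traces_path, readr::cols(.default = readr::col_double()))
  if (!"time_s" %in% names(traces)) {
    stop(basename(traces_path), ": missing column time_s", call. = FALSE)
  }
  if (nrow(traces) < 2) stop(basename(traces_path), ": needs >= 2 frames", call. = FALSE)
  if (anyNA(traces)) {
    schema_fail(traces_path, which(!stats::complete.cases(traces))[1], "values finite")
  }

  centroids <- read_csv_quiet(centroids_path, readr::cols(
    cell_id = readr::col_character(), x = readr::col_double(),
    y = readr::col_double(), unit = readr::col_character()))
  if (length(miss <- setdiff(c("cell_id", "x", "y"), names(centroids)))) {
    stop(basename(centroids_path), ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(centroids$x) | !is.finite(centroids$y))
  if (length(bad)) schema_fail(centroids_path, bad[1], "coordinates finite")
  if (anyDuplicated(centroids$cell_id)) {
    schema_fail(centroids_path, anyDuplicated(centroids$cell_id), "one centroid per cell")
  }
  orphans <- setdiff(unique(events$cell_id), centroids$cell_id)
  if (length(orphans)) {
    stop("cells present in events but missing from centroids: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }

  trials <- NULL
  if (!is.null(trials_path) && file.exists(trials_path)) {
    trials <- read_csv_quiet(trials_path, readr::cols(
      trial_id = readr::col_integer(), iti_start_s = readr::col_double(),
      target_onset_s = readr::col_double(), direction = readr::col_character(),
      movement_onset_s = readr::col_double(), success = readr::col_logical()))
    if (nrow(trials) == 0) {
      trials <- NULL
    } else {
      if (any(diff(trials$target_onset_s) <= 0)) {
        schema_fail(trials_path, which(diff(trials$target_onset_s) <= 0)[1] + 1L,
                    "target_onset_s strictly increasing")
      }
      bad <- which(trials$iti_start_s >= trials$target_onset_s)
      if (length(bad)) schema_fail(trials_path, bad[1], "iti_start_s < target_onset_s")
      bad <- which(!trials$direction %in% c("left", "center", "right"))
      if (length(bad)) schema_fail(trials_path, bad[1],
                                   "direction in {left, center, right}")
      bad <- which(!is.na(trials$movement_onset_s) &
                     trials$movement_onset_s < trials$target_onset_s)
      if (length(bad)) schema_fail(trials_path, bad[1],
                                   "movement_onset_s >= target_onset_s")
    }
  }

  meta_path <- if (!is.null(dir)) file.path(dir, "session.json") else
    file.path(dirname(events_path), "session.json")
  fr <- trace_frame_rate(traces)
  segment <- c(traces$time_s[1], traces$time_s[nrow(traces)] + 1 / fr)
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    segment <- meta$segment %||% segment
    fr <- meta$frame_rate_hz %||% fr
  }
  if (nrow(events) && (min(events$time_s) < segment[1] ||
                       max(events$time_s) >= segment[2])) {
    stop("events fall outside the session segment [",
         segment[1], ", ", segment[2], ")", call. = FALSE)
  }

  structure(
    list(events = events, traces = traces, centroids = centroids,
         trials = trials, segment = segment, frame_rate_hz = fr,
         ground_truth = NULL, config = NULL),
    class = "ca_session"
  )
}
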