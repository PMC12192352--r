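#' Configuration for precisely timed sequence detection
#'
#' A sequence (motif) is an ordered tuple of distinct cells whose events
#' recur in that temporal order, each consecutive step separated by more than
#' `min_intra_gap_s` (to avoid counting near-simultaneous bursts) and by at
#' most `max_step_lag_s`. A motif is significant if it occurs at least
#' `min_repetitions` times within the observation window and more often than
#' the `null_percentile` quantile of its circular-shift permutation null.
#'
#' @param max_step_lag_s maximum per-step lag, s (default 2).
#' @param min_intra_gap_s minimum per-step gap, s, strict (default 0.05).
#' @param min_repetitions minimum occurrence count for significance
#'   (default 4).
#' @param window_s observation window length, s (default 600, i.e. 10 min).
#' @param n_shuffles permutation replicates per motif (default 1000).
#' @param null_percentile null quantile that the observed count must strictly
#'   exceed (default 0.95; the quantile is the order statistic at
#'   `ceiling(null_percentile * n_shuffles)`, no interpolation).
#' @param min_order,max_order motif lengths considered (defaults 2 and 5; the
#'   cap bounds the combinatorial search, which is pruned by downward
#'   closure: only motifs reaching `min_repetitions` are extended).
#' @return A validated list of class `ca_sequence_config`.
#' @export
sequence_config <- function(max_step_lag_s = 2, min_intra_gap_s = 0.05,
                            min_repetitions = 4L, window_s = 600,
                            n_shuffles = 1000L, null_percentile = 0.95,
                            min_order = 2L, max_order = 5L) {
  stopifnot(min_intra_gap_s > 0, min_intra_gap_s < max_step_lag_s,
            min_repetitions >= 2, window_s > 0, n_shuffles >= 100,
            null_percentile > 0, null_percentile < 1,
            min_order >= 2, max_order >= min_order)
  structure(list(max_step_lag_s = max_step_lag_s,
                 min_intra_gap_s = min_intra_gap_s,
                 min_repetitions = as.integer(min_repetitions),
                 window_s = window_s, n_shuffles = as.integer(n_shuffles),
                 null_percentile = null_percentile,
                 min_order = as.integer(min_order),
                 max_order = as.integer(max_order)),
            class = "ca_sequence_config")
}

# per-cell sorted event-time lists relative to segment start
event_time_list <- function(events, segment) {
  ev <- events_in_segment(events, segment)
  split(ev$time_s - segment[1], factor(ev$cell_id, levels = sort(unique(ev$cell_id))))
}

#' Enumerate candidate sequences and their occurrence counts
#'
#' Tabulates all ordered cell pairs observed at least once under the step
#' constraints, then grows longer motifs by appending one cell at a time,
#' extending only motifs that reached `min_repetitions` (downward-closure
#' pruning) up to `max_order`. Occurrences are counted greedily: anchors are
#' scanned in time order and each subsequent cell contributes its earliest
#' unused event within `(gap, lag]` of the previous matched event; the
#' events of a completed occurrence are consumed, so occurrences are
#' event-disjoint.
#'
#' @param events events tibble.
#' @param config a [sequence_config()].
#' @param segment half-open analysis window `c(start, end)`; its length must
#'   be at least `config$window_s`, and only the first `window_s` seconds are
#'   analyzed.
#' @return A tibble, one row per candidate motif: `motif_id` (cells pasted
#'   with `->`), `cells` (list column), `order`, `count`.
#' @export
enumerate_sequences <- function(events, config = sequence_config(), segment) {
  stopifnot(inherits(config, "ca_sequence_config"))
  assert_segment(segment)
  if (segment[2] - segment[1] < config$window_s - 1e-9) {
    stop("analysis window (", config$window_s, " s) is longer than the segment",
         call. = FALSE)
  }
  win <- c(segment[1], segment[1] + config$window_s)
  tl <- event_time_list(events, win)
  tl <- tl[lengths(tl) > 0]
  gap <- config$min_intra_gap_s
  lag <- config$max_step_lag_s
  empty <- tibble::tibble(motif_id = character(), cells = list(),
                          order = integer(), count = integer())
  if (length(tl) < 2) return(empty)
  ids <- names(tl)

  pair_idx <- which(matrix(TRUE, length(ids), length(ids)) & !diag(length(ids)),
                    arr.ind = TRUE)
  counts <- pair_counts_cpp(tl, cbind(pair_idx[, 1], pair_idx[, 2]), gap, lag)
  keep <- counts > 0
  motifs <- purrr::map2(pair_idx[keep, 1], pair_idx[keep, 2], ~ids[c(.x, .y)])
  counts <- counts[keep]

  out <- list(tibble::tibble(cells = motifs, order = 2L, count = as.integer(counts)))
  frequent_pairs <- motifs[counts >= config$min_repetitions]
  frequent_next <- split(
    purrr::map_chr(frequent_pairs, 2),
    purrr::map_chr(frequent_pairs, 1)
  )
  frontier <- frequent_pairs
  ord <- 2L
  while (ord < config$max_order && length(frontier)) {
    ord <- ord + 1L
    grown <- purrr::map(frontier, function(cells) {
      ext <- setdiff(frequent_next[[cells[length(cells)]]] %||% character(), cells)
      lapply(ext, function(d) c(cells, d))
    })
    grown <- unlist(grown, recursive = FALSE)
    if (!length(grown)) break
    cnt <- purrr::map_int(grown, function(cells)
      count_motif_cpp(tl[cells], gap, lag))
    keep <- cnt > 0
    if (any(keep)) {
      out[[length(out) + 1]] <- tibble::tibble(
        cells = grown[keep], order = ord, count = as.integer(cnt[keep]))
    }
    frontier <- grown[cnt >= config$min_repetitions]
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(empty)
  res$motif_id <- purrr::map_chr(res$cells, paste, collapse = "->")
  res[, c("motif_id", "cells", "order", "count")]
}

# empirical null quantile: order statistic at ceiling(q * K), no interpolation
null_order_stat <- function(counts, q) {
  sort(counts)[ceiling(q * length(counts))]
}

#' Circular-shift permutation null for sequence counts
#'
#' For each motif and each of `n_shuffles` replicates, every member cell
#' except the motif's first (anchor) is independently circularly shifted by a
#' uniform random offset in `(0, window)` with wrap-around, and the motif is
#' recounted with the same greedy counter. The shift preserves each train's
#' event count and within-train structure while destroying cross-cell
#' temporal coupling.
#'
#' @param events events tibble.
#' @param motifs candidate tibble from [enumerate_sequences()].
#' @param config a [sequence_config()].
#' @param segment analysis window as in [enumerate_sequences()].
#' @param seed integer seed; required.
#' @return `motifs` with list-column `null_counts` (length-`n_shuffles`
#'   integer vectors) and `null_q` (the `null_percentile` order statistic).
#' @export
sequence_null <- function(events, motifs, config = sequence_config(), segment,
                          seed = NULL) {
  if (is.null(seed)) stop("`seed` is required for a reproducible null", call. = FALSE)
  win <- c(segment[1], segment[1] + config$window_s)
  tl <- event_time_list(events, win)
  withr::local_seed(seed)
  K <- config$n_shuffles
  nulls <- vector("list", nrow(motifs))
  for (i in seq_len(nrow(motifs))) {
    cells <- motifs$cells[[i]]
    offs <- matrix(runif(K * (length(cells) - 1), 0, config$window_s),
                   nrow = K)
    nulls[[i]] <- null_counts_cpp(tl[cells], config$min_intra_gap_s,
                                  config$max_step_lag_s, config$window_s, offs)
  }
  motifs$null_counts <- nulls
  motifs$null_q <- purrr::map_dbl(nulls, null_order_stat,
                                  q = config$null_percentile)
  motifs
}

# is `short` an ordered subsequence of `long`?
is_subsequence <- function(short, long) {
  pos <- match(short, long)
  !anyNA(pos) && !is.unsorted(pos, strictly = TRUE)
}

#' Detect significant precisely timed event sequences
#'
#' Runs [enumerate_sequences()] and [sequence_null()] on one observation
#' window and applies the significance rule: a motif is significant when its
#' observed count is at least `min_repetitions` AND strictly exceeds the
#' `null_percentile` order statistic of its permutation null. Significant
#' motifs that are ordered subsequences of a longer significant motif are
#' flagged `subsumed` but retained. Occurrence times are attached and
#' re-validated against the gap/lag constraints.
#'
#' @inheritParams sequence_null
#' @return An object of class `ca_sequences`: list with `motifs` (tibble:
#'   `motif_id`, `cells`, `order`, `count`, `null_q`, `null_counts`,
#'   `significant`, `subsumed`, `occurrences` - a list column of
#'   count-by-order matrices of event times), `config`, `segment`,
#'   `n_cells`, `seed`.
#' @export
detect_sequences <- function(events, config = sequence_config(), segment,
                             seed = NULL, n_cells = NULL) {
  if (is.null(seed)) stop("`seed` is required", call. = FALSE)
  motifs <- enumerate_sequences(events, config, segment)
  n_cells <- n_cells %||% length(unique(events_in_segment(events, segment)$cell_id))
  win <- c(segment[1], segment[1] + config$window_s)
  if (nrow(motifs)) {
    motifs <- sequence_null(events, motifs, config, segment, seed = seed)
    motifs$significant <- motifs$count >= config$min_repetitions &
      motifs$count > motifs$null_q
    tl <- event_time_list(events, win)
    motifs$occurrences <- purrr::map(motifs$cells, function(cells) {
      occ <- motif_occurrences_cpp(tl[cells], config$min_intra_gap_s,
                                   config$max_step_lag_s)
      occ + win[1]
    })
    sig_idx <- which(motifs$significant)
    motifs$subsumed <- FALSE
    for (i in sig_idx) {
      for (j in sig_idx) {
        if (i != j && motifs$order[j] > motifs$order[i] &&
            is_subsequence(motifs$cells[[i]], motifs$cells[[j]])) {
          motifs$subsumed[i] <- TRUE
          break
        }
      }
    }
  } else {
    motifs$null_counts <- list()
    motifs$null_q <- numeric()
    motifs$significant <- logical()
    motifs$subsumed <- logical()
    motifs$occurrences <- list()
  }
  res <- structure(list(motifs = motifs, config = config, segment = segment,
                        window = win, n_cells = n_cells, seed = seed),
                   class = "ca_sequences")
  stopifnot(validate_occurrences(res))
  res
}

#' @export
print.ca_sequences <- function(x, ...) {
  cat("<ca_sequences> ", nrow(x$motifs), " candidate motifs, ",
      sum(x$motifs$significant), " significant (", x$n_cells, " cells, window [",
      x$window[1], ", ", x$window[2], ") s)\n", sep = "")
  invisible(x)
}

#' Check that every reported occurrence respects the step constraints
#'
#' Post-hoc validation run after every detection: all consecutive within-
#' occurrence gaps must lie in `(min_intra_gap_s, max_step_lag_s]`.
#'
#' @param x a `ca_sequences`.
#' @return `TRUE` if all occurrences are valid, otherwise `FALSE`.
#' @export
validate_occurrences <- function(x) {
  cfg <- x$config
  all(purrr::map_lgl(x$motifs$occurrences, function(occ) {
    if (nrow(occ) == 0) return(TRUE)
    gaps <- t(apply(occ, 1, diff))
    all(gaps > cfg$min_intra_gap_s & gaps <= cfg$max_step_lag_s)
  }))
}

#' Summarize a sequence-detection result
#'
#' @param x a `ca_sequences` from [detect_sequences()].
#' @param n_cells total cells in the session (denominator of the normalized
#'   count and the member proportion); defaults to the count stored in `x`.
#' @return A one-row tibble: `n_candidates`, `n_significant`,
#'   `normalized_n` (significant sequences per cell),
#'   `mean_repetitions` and `max_repetitions` over significant motifs, and
#'   `proportion_cells_in_sequences` (distinct member cells / total cells).
#' @export
summarize_sequences <- function(x, n_cells = x$n_cells) {
  if (is.null(n_cells) || n_cells == 0) stop("`n_cells` must be > 0", call. = FALSE)
  sig <- dplyr::filter(x$motifs, .data$significant)
  members <- unique(unlist(sig$cells))
  tibble::tibble(
    n_candidates = nrow(x$motifs),
    n_significant = nrow(sig),
    normalized_n = nrow(sig) / n_cells,
    mean_repetitions = if (nrow(sig)) mean(sig$count) else 0,
    max_repetitions = if (nrow(sig)) max(sig$count) else 0,
    proportion_cells_in_sequences = length(members) / n_cells
  )
}

#' Spatial distribution of sequence-member cells
#'
#' Compares the pairwise centroid distances among cells participating in
#' significant sequences with the distances among all cells, via a
#' two-sample Kolmogorov-Smirnov test. Skipped (with reason) when fewer than
#' two member cells exist.
#'
#' @param x a `ca_sequences`.
#' @param centroids centroid tibble (`cell_id`, `x`, `y`).
#' @return A list: `member_distances`, `all_distances`, `test` (one-row
#'   tibble with `statistic`, `p_value`, `skipped`, `note`).
#' @export
sequence_spatial_distribution <- function(x, centroids) {
  members <- unique(unlist(dplyr::filter(x$motifs, .data$significant)$cells))
  pd <- function(ids) {
    xy <- centroids[match(ids, centroids$cell_id), c("x", "y")]
    if (anyNA(xy$x)) stop("centroids missing for some cells", call. = FALSE)
    as.numeric(stats::dist(as.matrix(xy)))
  }
  all_d <- pd(centroids$cell_id)
  if (length(members) < 2) {
    return(list(member_distances = numeric(), all_distances = all_d,
                test = tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                                      skipped = TRUE,
                                      note = "fewer than 2 sequence-member cells")))
  }
  mem_d <- pd(members)
  ht <- suppressWarnings(ks.test(mem_d, all_d))
  list(member_distances = mem_d, all_distances = all_d,
       test = tibble::tibble(statistic = unname(ht$statistic),
                             p_value = ht$p.value, skipped = FALSE,
                             note = NA_character_))
}

#' Split a segment into consecutive non-overlapping analysis windows
#'
#' Longer recordings are analyzed in consecutive windows of `window_s`
#' (e.g. "spontaneous 1", "spontaneous 2" halves of a 20-min recording); a
#' trailing remainder shorter than the window is dropped.
#'
#' @param segment `c(start, end)`, seconds.
#' @param window_s window length, seconds.
#' @return A list of `c(start, end)` windows (possibly empty).
#' @export
split_windows <- function(segment, window_s) {
  assert_segment(segment)
  n <- floor((segment[2] - segment[1]) / window_s + 1e-9)
  lapply(seq_len(n), function(i)
    c(segment[1] + (i - 1) * window_s, segment[1] + i * window_s))
}
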