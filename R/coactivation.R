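#' Bin event trains into a binary cell-by-bin matrix
#'
#' Bin `t` covers the half-open interval
#' `[start + (t-1) * w, start + t * w)`; a bin is 1 if at least one event
#' falls in it (binary, not counts). The number of bins is
#' `floor(segment duration / bin width)`; a trailing partial bin is
#' discarded, as are events falling in it.
#'
#' @param events events tibble (`cell_id`, `time_s`, `amplitude`).
#' @param bin_width_s bin width, seconds (default 0.2 s, the coactivation
#'   coincidence resolution).
#' @param segment numeric `c(start, end)`, seconds, half-open.
#' @param cells cells to include as rows (silent cells give all-zero rows);
#'   defaults to the cells present in `events`.
#' @return An object of class `ca_binned`: a list with the binary integer
#'   matrix `mat` (rownames = cell ids), `bin_width_s`, `segment`,
#'   `smoothed`, `lookahead_bins`.
#' @export
bin_events <- function(events, bin_width_s = 0.2, segment, cells = NULL) {
  assert_events(events)
  assert_segment(segment)
  stopifnot(bin_width_s > 0)
  n_bins <- as.integer(floor((segment[2] - segment[1]) / bin_width_s + 1e-9))
  if (n_bins < 1) stop("segment shorter than one bin", call. = FALSE)
  cells <- cells %||% sort(unique(events$cell_id))
  mat <- matrix(0L, nrow = length(cells), ncol = n_bins,
                dimnames = list(cells, NULL))
  ev <- events_in_segment(events, segment)
  ev <- ev[ev$cell_id %in% cells, ]
  if (nrow(ev)) {
    idx <- .bin_index(ev$time_s, segment[1], bin_width_s)
    keep <- idx >= 1L & idx <= n_bins
    mat[cbind(match(ev$cell_id[keep], cells), idx[keep])] <- 1L
  }
  structure(list(mat = mat, bin_width_s = bin_width_s, segment = segment,
                 smoothed = FALSE, lookahead_bins = 0L),
            class = "ca_binned")
}

#' @export
print.ca_binned <- function(x, ...) {
  cat("<ca_binned> ", nrow(x$mat), " cells x ", ncol(x$mat), " bins of ",
      x$bin_width_s, " s", if (x$smoothed)
        paste0(" (forward-smoothed, lookahead ", x$lookahead_bins, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Forward-smooth a binned event matrix
#'
#' Sets bin `t` to 1 if an event occurred in the current bin or any of the
#' next `lookahead_bins` bins (default 4, so events within 1 s at 0.2-s bins
#' count as coincident). Bins near the end of the segment use only the bins
#' that exist. The result dominates the input elementwise.
#'
#' @param binned a `ca_binned` from [bin_events()].
#' @param lookahead_bins number of future bins ORed into each bin (>= 0).
#' @return A `ca_binned` with `smoothed = TRUE`.
#' @export
forward_smooth <- function(binned, lookahead_bins = 4L) {
  stopifnot(inherits(binned, "ca_binned"), lookahead_bins >= 0)
  y <- binned$mat
  n <- ncol(y)
  out <- y
  for (j in seq_len(min(lookahead_bins, n - 1))) {
    idx <- seq_len(n - j)
    out[, idx] <- out[, idx, drop = FALSE] | y[, idx + j, drop = FALSE]
  }
  storage.mode(out) <- "integer"
  binned$mat <- out
  binned$smoothed <- TRUE
  binned$lookahead_bins <- as.integer(lookahead_bins)
  binned
}

#' Pairwise Jaccard index of active-bin sets
#'
#' For cells `c` and `c'` with binary rows `y*`, the Jaccard index is the
#' intersection over the union of their active bins:
#' `sum_t y*[c,t] y*[c',t] / (sum_t y*[c,t] + sum_t y*[c',t] - sum_t y*[c,t] y*[c',t])`.
#' Computed exactly with integer matrix products. Pairs where the union is
#' empty (both cells silent) are undefined and returned as `NA`.
#'
#' @param x a `ca_binned` (normally forward-smoothed) or a binary matrix with
#'   cells in rows.
#' @return A symmetric cells-by-cells matrix of Jaccard indices in `[0, 1]`.
#' @export
jaccard_matrix <- function(x) {
  mat <- if (inherits(x, "ca_binned")) x$mat else x
  if (nrow(mat) < 2) stop("need >= 2 cells for pairwise Jaccard", call. = FALSE)
  inter <- tcrossprod(mat)
  rs <- rowSums(mat)
  union <- outer(rs, rs, `+`) - inter
  out <- ifelse(union > 0, inter / union, NA_real_)
  dimnames(out) <- list(rownames(mat), rownames(mat))
  out
}

# circular rotation helper: rotate a row left by `offset` bins, so the series
# starting at index offset+1 wraps to the front (offset 0 is the identity)
rotate_bins <- function(row, offset) {
  n <- length(row)
  offset <- offset %% n
  if (offset == 0) return(row)
  c(row[(offset + 1):n], row[1:offset])
}

#' Z-Jaccard: circular-shift-standardized pairwise coactivation
#'
#' For every unordered cell pair, the observed Jaccard index of the
#' forward-smoothed rows is standardized against a null distribution obtained
#' by circularly rotating the second cell's row by random offsets and
#' recomputing the Jaccard index:
#' `Z = (Jaccard - mean(null)) / sd(null)`.
#' The circular shift preserves each train's autocorrelation (and its number
#' of active bins) while destroying cross-train coupling. `|Z| > 1.96`
#' flags a pair as synchronized at the nominal two-sided 5% level.
#'
#' Offsets are drawn independently per pair, uniformly from `{1, ..., T-1}` -
#' the identity rotation is excluded. All `T` rotated intersection counts are
#' obtained exactly via FFT circular cross-correlation and the sampled
#' offsets are looked up, which is identical to rotating and recounting.
#' Pairs whose null sd is zero (e.g. a cell with no events) are marked
#' invalid and excluded from downstream proportions.
#'
#' @param x a forward-smoothed `ca_binned` (see [forward_smooth()]).
#' @param n_shuffles number of null replicates per pair (>= 100; default
#'   1000).
#' @param seed integer seed; required, every shuffle stream must be
#'   reproducible.
#' @return A tibble of class `ca_pairsync`, one row per unordered pair:
#'   `cell_a`, `cell_b`, `jaccard`, `null_mean`, `null_sd`, `z_jaccard`,
#'   `n_shuffles`, `valid`.
#' @export
z_jaccard <- function(x, n_shuffles = 1000L, seed = NULL) {
  stopifnot(inherits(x, "ca_binned"))
  if (is.null(seed)) stop("`seed` is required for a reproducible null", call. = FALSE)
  if (n_shuffles < 100) stop("`n_shuffles` must be >= 100", call. = FALSE)
  mat <- x$mat
  n_cells <- nrow(mat)
  n_bins <- ncol(mat)
  if (n_cells < 2) stop("need >= 2 cells", call. = FALSE)
  if (n_bins < 2) stop("need >= 2 bins", call. = FALSE)
  withr::local_seed(seed)

  # one FFT per cell, then each pair's full rotation-intersection profile is
  # a single inverse FFT
  ft <- mvfft(t(mat))
  rs <- rowSums(mat)
  pairs <- utils::combn(n_cells, 2)
  out <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    cc <- round(Re(fft(Conj(ft[, i]) * ft[, j], inverse = TRUE)) / n_bins)
    union0 <- unname(rs[i] + rs[j] - cc[1])
    obs <- if (union0 > 0) unname(cc[1]) / union0 else NA_real_
    offs <- sample.int(n_bins - 1L, n_shuffles, replace = TRUE)
    inter_k <- cc[offs + 1L]
    null_j <- inter_k / (rs[i] + rs[j] - inter_k)
    null_j[!is.finite(null_j)] <- NA_real_
    nm <- mean(null_j)
    ns <- sd(null_j)
    valid <- is.finite(obs) && is.finite(nm) && is.finite(ns) && ns > 0
    out[[p]] <- tibble::tibble(
      cell_a = rownames(mat)[i], cell_b = rownames(mat)[j],
      jaccard = obs, null_mean = nm, null_sd = ns,
      z_jaccard = if (valid) (obs - nm) / ns else NA_real_,
      valid = valid
    )
  }
  res <- dplyr::bind_rows(out)
  res$n_shuffles <- as.integer(n_shuffles)
  structure(res, class = c("ca_pairsync", class(res)),
            bin_width_s = x$bin_width_s, lookahead_bins = x$lookahead_bins,
            n_bins = n_bins, seed = seed)
}

#' Proportion of synchronized cell pairs
#'
#' The fraction of valid pairs whose `|Z-Jaccard|` exceeds the threshold
#' (default 1.96, the two-sided 5% normal quantile). Invalid pairs are
#' excluded from the denominator.
#'
#' @param pairs a `ca_pairsync` from [z_jaccard()].
#' @param threshold absolute Z threshold.
#' @return A single proportion in `[0, 1]`.
#' @export
synchronized_proportion <- function(pairs, threshold = 1.96) {
  v <- dplyr::filter(pairs, .data$valid)
  if (nrow(v) == 0) stop("no valid pairs", call. = FALSE)
  mean(abs(v$z_jaccard) > threshold)
}

#' Paired comparison of synchronized-pair proportions across sessions
#'
#' Wilcoxon signed-rank test contrasting per-session synchronized-pair
#' proportions between two conditions recorded in the same sessions (e.g.
#' spontaneous vs reaching task).
#'
#' @param prop_a,prop_b numeric vectors of per-session proportions, matched
#'   by position.
#' @return A one-row tibble: `test`, `statistic`, `p_value`, `n`.
#' @export
compare_sync_proportions <- function(prop_a, prop_b) {
  stopifnot(length(prop_a) == length(prop_b), length(prop_a) >= 1)
  ht <- wilcox_guarded(prop_b, prop_a, paired = TRUE)
  tibble::tibble(test = "wilcoxon_signed_rank", statistic = ht$statistic,
                 p_value = ht$p.value, n = length(prop_a))
}

#' Relate pairwise synchrony to centroid distance
#'
#' Joins each valid pair's Z-Jaccard with the Euclidean distance between the
#' two cells' spatial centroids and fits a loess smoother (locally weighted
#' linear regression, tricube weights, span as a fraction of points) over a
#' distance grid. With fewer than 5 valid pairs, or a degenerate distance
#' range, the smoother is skipped and the raw pair table is still returned.
#'
#' @param pairs a `ca_pairsync`.
#' @param centroids centroid tibble (`cell_id`, `x`, `y`); must cover all
#'   cells in `pairs`.
#' @param span loess span (default 1).
#' @return An object of class `ca_distsync`: list with `pairs` (tibble:
#'   `cell_a`, `cell_b`, `distance`, `z_jaccard`), `curve` (tibble
#'   `distance`, `z_fit`, or `NULL`), `span`, `skipped_reason`.
#' @export
distance_vs_synchrony <- function(pairs, centroids, span = 1) {
  v <- dplyr::filter(pairs, .data$valid)
  missing_cells <- setdiff(unique(c(v$cell_a, v$cell_b)), centroids$cell_id)
  if (length(missing_cells)) {
    stop("centroids missing for: ", paste(missing_cells, collapse = ", "),
         call. = FALSE)
  }
  tab <- v |>
    dplyr::left_join(dplyr::select(centroids, "cell_id", xa = "x", ya = "y"),
                     by = c(cell_a = "cell_id")) |>
    dplyr::left_join(dplyr::select(centroids, "cell_id", xb = "x", yb = "y"),
                     by = c(cell_b = "cell_id")) |>
    dplyr::mutate(distance = sqrt((.data$xa - .data$xb)^2 + (.data$ya - .data$yb)^2)) |>
    dplyr::select("cell_a", "cell_b", "distance", "z_jaccard")

  curve <- NULL
  skipped <- NA_character_
  if (nrow(tab) < 5) {
    skipped <- "fewer than 5 valid pairs"
  } else if (diff(range(tab$distance)) == 0) {
    skipped <- "zero-range distance grid"
  } else {
    fit <- tryCatch(
      loess(z_jaccard ~ distance, data = tab, span = span, degree = 1),
      error = function(e) NULL)
    if (is.null(fit)) {
      skipped <- "loess fit failed"
    } else {
      grid <- seq(min(tab$distance), max(tab$distance), length.out = 100)
      curve <- tibble::tibble(distance = grid,
                              z_fit = as.numeric(predict(fit, newdata = data.frame(distance = grid))))
    }
  }
  structure(list(pairs = tab, curve = curve, span = span,
                 skipped_reason = skipped),
            class = "ca_distsync")
}
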