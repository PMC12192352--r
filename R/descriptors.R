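#' Per-cell calcium-event descriptors
#'
#' For each cell, over a half-open segment `[start, end)`: the event rate
#' (count / segment duration), the coefficient of variation of the
#' inter-event intervals (sample sd / mean of consecutive intervals; 1 for a
#' homogeneous Poisson train), and the mean deconvolved event amplitude.
#' The IEI CV is `NA` below 3 events (fewer than 2 intervals) and the mean
#' amplitude is `NA` for silent cells.
#'
#' @param events events tibble (`cell_id`, `time_s`, `amplitude`).
#' @param segment numeric `c(start, end)`, seconds.
#' @param cells cell ids to report (silent cells get rate 0); defaults to the
#'   cells present in `events`.
#' @param condition,region optional labels copied into the output (e.g.
#'   `"spontaneous"` / `"task"`, `"SMA"` / `"M1"`).
#' @return A tibble with one row per cell: `cell_id`, `n_events`,
#'   `event_rate`, `iei_cv`, `mean_amplitude`, plus any labels.
#' @export
event_descriptors <- function(events, segment, cells = NULL,
                              condition = NULL, region = NULL) {
  assert_events(events)
  assert_segment(segment)
  cells <- cells %||% sort(unique(events$cell_id))
  ev <- events_in_segment(events, segment)
  dur <- segment[2] - segment[1]
  out <- tibble::tibble(cell_id = cells) |>
    dplyr::left_join(
      ev |>
        dplyr::group_by(.data$cell_id) |>
        dplyr::summarise(
          n_events = dplyr::n(),
          iei_cv = if (dplyr::n() >= 3) {
            iei <- diff(sort(.data$time_s))
            sd(iei) / mean(iei)
          } else NA_real_,
          mean_amplitude = mean(.data$amplitude),
          .groups = "drop"
        ),
      by = "cell_id"
    ) |>
    dplyr::mutate(
      n_events = dplyr::coalesce(.data$n_events, 0L),
      event_rate = .data$n_events / dur
    ) |>
    dplyr::select("cell_id", "n_events", "event_rate", "iei_cv", "mean_amplitude")
  if (!is.null(condition)) out$condition <- condition
  if (!is.null(region)) out$region <- region
  out
}

# degenerate-data guard shared by the comparison wrappers: Wilcoxon tests are
# undefined when every (paired difference | pooled value) is identical; the
# package's convention is p = 1 there.
wilcox_guarded <- function(x, y = NULL, paired = FALSE) {
  degenerate <- if (paired) all(x - y == 0) else
    (length(unique(c(x, y))) == 1)
  if (degenerate) {
    return(list(statistic = NA_real_, p.value = 1))
  }
  ht <- suppressWarnings(stats::wilcox.test(x, y, paired = paired))
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Compare a descriptor between two cell groups or conditions
#'
#' Paired mode (`paired = TRUE`) contrasts the same cells across two
#' conditions (e.g. spontaneous vs reaching task) with a two-sided Wilcoxon
#' signed-rank test on per-cell differences; cells with an undefined metric in
#' either table are dropped and counted. Unpaired mode contrasts disjoint cell
#' sets (e.g. M1 vs SMA) with a two-sided Wilcoxon rank-sum (Mann-Whitney)
#' test. Identical inputs give p = 1 by convention. Comparisons with fewer
#' than 5 valid pairs (or per group) are flagged `underpowered` but still
#' report a p-value. Apply [bh_fdr()] across a family of such results for
#' multiple-comparison correction.
#'
#' @param a,b descriptor tables from [event_descriptors()].
#' @param metric one of `"event_rate"`, `"iei_cv"`, `"mean_amplitude"`.
#' @param paired logical; see above.
#' @return A one-row tibble: `metric`, `test`, `statistic`, `p_value`, `n`
#'   (pairs, or `n_a`/`n_b` columns when unpaired), `n_dropped`, `direction`
#'   (sign of the median difference, b relative to a), `underpowered`.
#' @export
compare_descriptors <- function(a, b,
                                metric = c("event_rate", "iei_cv", "mean_amplitude"),
                                paired = TRUE) {
  metric <- match.arg(metric)
  if (paired) {
    if (!setequal(a$cell_id, b$cell_id)) {
      stop("paired comparison requires the same cell set in both tables",
           call. = FALSE)
    }
    d <- dplyr::inner_join(
      dplyr::select(a, "cell_id", va = dplyr::all_of(metric)),
      dplyr::select(b, "cell_id", vb = dplyr::all_of(metric)),
      by = "cell_id"
    )
    ok <- is.finite(d$va) & is.finite(d$vb)
    n_dropped <- sum(!ok)
    d <- d[ok, ]
    if (nrow(d) == 0) stop("no valid pairs for metric ", metric, call. = FALSE)
    ht <- wilcox_guarded(d$vb, d$va, paired = TRUE)
    tibble::tibble(
      metric = metric, test = "wilcoxon_signed_rank",
      statistic = ht$statistic, p_value = ht$p.value,
      n = nrow(d), n_dropped = n_dropped,
      direction = sign(stats::median(d$vb - d$va)),
      underpowered = nrow(d) < 5
    )
  } else {
    if (length(intersect(a$cell_id, b$cell_id))) {
      stop("unpaired comparison requires disjoint cell sets", call. = FALSE)
    }
    va <- a[[metric]][is.finite(a[[metric]])]
    vb <- b[[metric]][is.finite(b[[metric]])]
    if (!length(va) || !length(vb)) {
      stop("empty group for metric ", metric, call. = FALSE)
    }
    ht <- wilcox_guarded(va, vb)
    tibble::tibble(
      metric = metric, test = "wilcoxon_rank_sum",
      statistic = ht$statistic, p_value = ht$p.value,
      n_a = length(va), n_b = length(vb),
      n_dropped = (nrow(a) - length(va)) + (nrow(b) - length(vb)),
      direction = sign(stats::median(vb) - stats::median(va)),
      underpowered = min(length(va), length(vb)) < 5
    )
  }
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment: with p-values sorted ascending,
#' `q_i = min_{j >= i} p_j * m / j`, clipped at 1 and returned in input order,
#' so adjusted values always dominate the raw ones.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.5))
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}
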