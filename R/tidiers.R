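#' Tidy a sequence-detection result
#'
#' @param x a `ca_sequences`.
#' @param ... unused.
#' @return One row per candidate motif with its count, null quantile,
#'   significance and subsumption flags, member cells and occurrence starts.
#' @export
tidy.ca_sequences <- function(x, ...) tidy_sequences(x)

#' @rdname tidy.ca_sequences
#' @return For `glance()`: the one-row [summarize_sequences()] table.
#' @export
glance.ca_sequences <- function(x, ...) summarize_sequences(x)

#' Tidy a pairwise-synchrony result
#'
#' @param x a `ca_pairsync`.
#' @param ... unused.
#' @return The pair table as a plain tibble.
#' @export
tidy.ca_pairsync <- function(x, ...) tibble::as_tibble(unclass_keep_tbl(x))

#' @rdname tidy.ca_pairsync
#' @param threshold synchrony threshold used by `glance()`.
#' @return For `glance()`: one row with `n_pairs`, `n_valid`,
#'   `proportion_synchronized`, `n_shuffles`.
#' @export
glance.ca_pairsync <- function(x, threshold = 1.96, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    n_valid = sum(x$valid),
    proportion_synchronized = synchronized_proportion(x, threshold),
    n_shuffles = x$n_shuffles[1]
  )
}

#' Tidy a modulation-test result
#'
#' @param x a `ca_modulation`.
#' @param ... unused.
#' @return The per-cell-by-condition test table as a plain tibble.
#' @export
tidy.ca_modulation <- function(x, ...) tibble::as_tibble(unclass_keep_tbl(x))

#' @rdname tidy.ca_modulation
#' @return For `glance()`: one row with test counts and the category
#'   breakdown from [classify_cells()].
#' @export
glance.ca_modulation <- function(x, ...) {
  alpha <- attr(x, "alpha") %||% 0.05
  cats <- classify_cells(x, alpha)
  tibble::tibble(
    n_cells = length(unique(x$cell_id)),
    n_tests = nrow(x),
    n_significant = sum(x$p_adjusted < alpha),
    n_not_modulated = sum(cats$category == "not_modulated"),
    n_direction_related = sum(cats$category == "direction_related"),
    n_non_direction_related = sum(cats$category == "non_direction_related")
  )
}

unclass_keep_tbl <- function(x) {
  class(x) <- setdiff(class(x), c("ca_pairsync", "ca_modulation", "ca_epochs"))
  x
}
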