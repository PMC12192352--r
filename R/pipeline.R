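#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates simulate (or load) -> descriptors -> alignment ->
#' coactivation -> sequences, writing one CSV per result plus a JSON run
#' manifest (package version, global seed, derived per-stage seeds, parameter
#' echo, exclusion counts). Every stochastic stage receives its own seed
#' derived deterministically from the global seed, so a config plus seed
#' reproduces a run exactly. On a stage failure the run aborts with the stage
#' name and a `RUN.partial` marker is left in the output directory.
#'
#' The configuration is a nested list (or a YAML file with the same shape):
#' \describe{
#'   \item{simulate}{arguments for [sim_config()], or}
#'   \item{session_dir}{a directory readable by [read_session()]}
#'   \item{segments}{named list of `c(start, end)` pairs; names
#'     `spontaneous` and `task` select the segments used by the comparison
#'     stages. Segments must be non-overlapping and inside the recording.}
#'   \item{descriptors, alignment, coactivation, sequences}{optional
#'     per-stage parameter blocks (see [alignment_config()],
#'     [sequence_config()], [z_jaccard()]).}
#'   \item{seed}{global seed (overridden by the `seed` argument).}
#' }
#'
#' @param config nested list or path to a YAML file.
#' @param out_dir output directory.
#' @param seed optional global seed overriding `config$seed`.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  partial <- file.path(out_dir, "RUN.partial")
  file.create(partial)

  segs <- lapply(config$segments %||% list(), unlist)
  validate_segments(segs)

  manifest <- list(package = "catrains",
                   version = as.character(utils::packageVersion("catrains")),
                   seed = seed, config = config, stages = character(),
                   exclusions = list())
  results <- list()
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages <<- c(manifest$stages, name)
    results[[name]] <<- res
    res
  }
  out_csv <- function(x, name) readr::write_csv(x, file.path(out_dir, name))

  ## stage 1: session --------------------------------------------------------
  session <- stage("simulate", function() {
    if (!is.null(config$session_dir)) return(read_session(config$session_dir))
    sim_args <- config$simulate %||% stop("config needs `simulate` or `session_dir`")
    sim_args$seed <- derive_seed(seed, 1L)
    s <- do.call(sim_config, sim_args)
    simulate_session(s)
  })
  write_session(session, file.path(out_dir, "session"))
  if (!length(segs)) segs <- list(spontaneous = session$segment)
  for (sg in segs) {
    if (sg[1] < session$segment[1] || sg[2] > session$segment[2]) {
      stop("segment [", sg[1], ", ", sg[2], ") outside the recording",
           call. = FALSE)
    }
  }
  all_cells <- session$centroids$cell_id

  ## stage 2: descriptors ----------------------------------------------------
  desc <- stage("descriptors", function() {
    tabs <- purrr::imap(segs, function(sg, nm)
      event_descriptors(session$events, sg, cells = all_cells, condition = nm))
    stats_tab <- NULL
    if (all(c("spontaneous", "task") %in% names(tabs))) {
      stats_tab <- purrr::map(c("event_rate", "iei_cv", "mean_amplitude"),
                              ~compare_descriptors(tabs$spontaneous, tabs$task,
                                                   metric = .x, paired = TRUE)) |>
        dplyr::bind_rows()
      stats_tab$p_adjusted <- bh_fdr(stats_tab$p_value)
    }
    list(tables = tabs, stats = stats_tab)
  })
  out_csv(dplyr::bind_rows(desc$tables), "descriptors.csv")
  if (!is.null(desc$stats)) out_csv(desc$stats, "descriptor_stats.csv")

  ## stage 3: task alignment -------------------------------------------------
  if (!is.null(session$trials)) {
    align <- stage("alignment", function() {
      acfg <- do.call(alignment_config, config$alignment %||% list())
      ep <- extract_epochs(session$traces, session$trials, acfg)
      mod <- modulation_test(ep, acfg)
      list(epochs = ep, modulation = mod,
           categories = classify_cells(mod),
           magnitudes = magnitude_comparisons(mod),
           n_dropped_trials = attr(ep, "n_dropped_trials"),
           n_dropped_flat = attr(ep, "n_dropped_flat"))
    })
    manifest$exclusions$alignment <- list(
      dropped_trials = align$n_dropped_trials,
      dropped_flat_baselines = align$n_dropped_flat)
    out_csv(tibble::as_tibble(align$modulation), "modulation.csv")
    out_csv(align$categories, "categories.csv")
    out_csv(align$magnitudes, "magnitude_stats.csv")
  }

  ## stage 4: coactivation ---------------------------------------------------
  coact <- stage("coactivation", function() {
    cc <- config$coactivation %||% list()
    purrr::imap(segs, function(sg, nm) {
      sm <- bin_events(session$events, cc$bin_width_s %||% 0.2, sg,
                       cells = all_cells) |>
        forward_smooth(cc$lookahead_bins %||% 4L)
      ps <- z_jaccard(sm, n_shuffles = cc$n_shuffles %||% 1000L,
                      seed = derive_seed(seed, 40L + match(nm, names(segs))))
      list(pairs = ps,
           proportion = synchronized_proportion(ps, cc$threshold %||% 1.96),
           dist = distance_vs_synchrony(ps, session$centroids))
    })
  })
  out_csv(purrr::imap(coact, ~dplyr::mutate(tibble::as_tibble(.x$pairs),
                                            segment_label = .y)) |>
            dplyr::bind_rows(), "zjaccard.csv")
  out_csv(tibble::tibble(segment_label = names(coact),
                         proportion_synchronized =
                           purrr::map_dbl(coact, "proportion")),
          "sync_proportions.csv")
  out_csv(purrr::imap(coact, ~dplyr::mutate(.x$dist$pairs, segment_label = .y)) |>
            dplyr::bind_rows(), "distance_z.csv")
  manifest$exclusions$coactivation <- purrr::map(coact, function(x)
    list(invalid_pairs = sum(!x$pairs$valid)))

  ## stage 5: sequences ------------------------------------------------------
  seqres <- stage("sequences", function() {
    scfg <- do.call(sequence_config, config$sequences %||% list())
    wins <- purrr::imap(segs, function(sg, nm) {
      ws <- split_windows(sg, scfg$window_s)
      if (!length(ws)) return(NULL)
      purrr::imap(ws, function(w, i) {
        det <- detect_sequences(session$events, scfg, segment = w,
                                seed = derive_seed(seed, 60L + 10L * match(nm, names(segs)) + i),
                                n_cells = length(all_cells))
        list(label = paste0(nm, "_", i), det = det,
             summary = summarize_sequences(det),
             spatial = sequence_spatial_distribution(det, session$centroids))
      })
    })
    purrr::compact(unlist(wins, recursive = FALSE))
  })
  out_csv(purrr::map(seqres, function(w)
    dplyr::mutate(tidy_sequences(w$det), segment_label = w$label)) |>
      dplyr::bind_rows(), "sequences.csv")
  out_csv(purrr::map(seqres, function(w)
    dplyr::mutate(w$summary, segment_label = w$label)) |>
      dplyr::bind_rows(), "sequence_summary.csv")
  out_csv(purrr::map(seqres, function(w)
    dplyr::mutate(w$spatial$test, segment_label = w$label)) |>
      dplyr::bind_rows(), "sequence_spatial.csv")

  manifest$derived_seeds <- list(simulate = derive_seed(seed, 1L))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  file.remove(partial)
  invisible(list(session = session, descriptors = desc,
                 alignment = results$alignment, coactivation = coact,
                 sequences = seqres, manifest = manifest))
}

validate_segments <- function(segs) {
  for (sg in segs) assert_segment(sg)
  if (length(segs) >= 2) {
    ord <- order(purrr::map_dbl(segs, 1))
    s <- segs[ord]
    for (i in seq_len(length(s) - 1)) {
      if (s[[i + 1]][1] < s[[i]][2]) {
        stop("segments overlap: [", s[[i]][1], ", ", s[[i]][2], ") and [",
             s[[i + 1]][1], ", ", s[[i + 1]][2], ")", call. = FALSE)
      }
    }
  }
  invisible(segs)
}

# flat (CSV-friendly) view of a detection result
tidy_sequences <- function(det) {
  m <- det$motifs
  tibble::tibble(
    motif_id = m$motif_id,
    order = m$order,
    count = m$count,
    null_q = m$null_q,
    significant = m$significant,
    subsumed = m$subsumed,
    member_cells = purrr::map_chr(m$cells, paste, collapse = ";"),
    occurrence_starts = purrr::map_chr(m$occurrences, function(o)
      paste(sprintf("%.6f", o[, 1]), collapse = ";"))
  )
}
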