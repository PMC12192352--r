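# hand-built traces: one cell, flat grid, fully controlled
flat_trial_session <- function(trace_values, n_trials = 6, trial_len = 6,
                               direction = "left") {
  n_frames <- length(trace_values)
  traces <- tibble::tibble(time_s = (seq_len(n_frames) - 1) / 10,
                           cell_001 = trace_values)
  trials <- tibble::tibble(
    trial_id = seq_len(n_trials),
    iti_start_s = (seq_len(n_trials) - 1) * trial_len,
    target_onset_s = (seq_len(n_trials) - 1) * trial_len + 2.5,
    direction = direction,
    movement_onset_s = NA_real_,
    success = TRUE
  )
  list(traces = traces, trials = trials)
}

test_that("Z-scoring uses the per-trial ITI baseline", {
  # baseline frames (first second of the ITI) have mean 2, sd 1 by design;
  # one epoch sample is forced to 5 -> Z = 3
  withr::local_seed(1)
  vals <- rep(c(1, 3), 400)  # mean 2, sd ~1.00 on any 10-frame window
  f <- flat_trial_session(vals, n_trials = 6)
  # overwrite one epoch frame of trial 1: onset 2.5 s -> frame 26; epoch
  # starts at frame 16; set the frame at +0.4 s
  f$traces$cell_001[30] <- 5
  ep <- extract_epochs(f$traces, f$trials, alignment_config())
  base_sd <- sd(vals[1:10])
  z <- ep$z[ep$trial_id == 1 & abs(ep$time_rel_s - 0.4) < 1e-9]
  expect_equal(z, (5 - 2) / base_sd, tolerance = 1e-9)
})

test_that("flat-baseline cell-trials are dropped and counted", {
  vals <- c(rep(1, 10), rnorm(590))  # first trial's baseline is constant
  f <- flat_trial_session(vals, n_trials = 6)
  ep <- extract_epochs(f$traces, f$trials, alignment_config())
  expect_equal(attr(ep, "n_dropped_flat"), 1L)
  expect_false(1 %in% ep$trial_id)
  expect_error(
    extract_epochs(f$traces, dplyr::mutate(f$trials, success = FALSE),
                   alignment_config()),
    "no successful trials")
})

test_that("epochs from a stationary white-noise trace are standardized (t-tailed)", {
  # With a 10-frame baseline, z = (x - mu_hat)/s_hat has variance
  # (1 + 1/10) * 9/7 ~ 1.414 (E[1/s^2] = nu/(nu-2), nu = 9), i.e. a pooled
  # sd near 1.19 -- wider than N(0,1), as expected for an estimated baseline.
  withr::local_seed(42)
  n_trials <- 200
  vals <- rnorm(n_trials * 60 + 100)
  f <- flat_trial_session(vals, n_trials = n_trials)
  ep <- extract_epochs(f$traces, f$trials, alignment_config())
  expect_lt(abs(mean(ep$z)), 0.1)
  expect_gt(sd(ep$z), 1.08)
  expect_lt(sd(ep$z), 1.32)
})

test_that("epoch Z-scores are invariant to adding a constant to the trace", {
  withr::local_seed(3)
  vals <- rnorm(700)
  f <- flat_trial_session(vals, n_trials = 8)
  ep1 <- extract_epochs(f$traces, f$trials, alignment_config())
  f$traces$cell_001 <- f$traces$cell_001 + 100
  ep2 <- extract_epochs(f$traces, f$trials, alignment_config())
  expect_equal(ep1$z, ep2$z, tolerance = 1e-9)
})

test_that("trials whose epochs leave the recording are dropped with a warning", {
  withr::local_seed(4)
  vals <- rnorm(300)
  f <- flat_trial_session(vals, n_trials = 6)
  f$trials$target_onset_s[6] <- 29.5  # epoch would extend past 30 s
  expect_warning(ep <- extract_epochs(f$traces, f$trials, alignment_config()),
                 "dropped")
  expect_equal(attr(ep, "n_dropped_trials"), 1L)
})

test_that("identical pre and event windows give p = 1", {
  withr::local_seed(5)
  vals <- rnorm(700)
  f <- flat_trial_session(vals, n_trials = 8)
  cfg <- alignment_config(event_window_s = c(-1, 0), pre_window_s = c(-1, 0))
  ep <- extract_epochs(f$traces, f$trials, cfg)
  mod <- modulation_test(ep, cfg)
  expect_equal(mod$p_value, 1)
})

test_that("conditions with too few trials are excluded and reported", {
  withr::local_seed(6)
  vals <- rnorm(700)
  f <- flat_trial_session(vals, n_trials = 8)
  f$trials$direction <- c(rep("left", 6), rep("right", 2))
  ep <- extract_epochs(f$traces, f$trials, alignment_config())
  mod <- modulation_test(ep)
  expect_equal(unique(mod$direction), "left")
  excl <- attr(mod, "excluded_conditions")
  expect_equal(excl$direction, "right")
})

test_that("the classification rule maps significance patterns to categories", {
  mk <- function(p_adj) {
    structure(
      tibble::tibble(cell_id = "c1", direction = c("left", "center", "right"),
                     p_adjusted = p_adj),
      alpha = 0.05)
  }
  expect_equal(as.character(classify_cells(mk(c(0.01, 0.5, 0.5)))$category),
               "direction_related")
  expect_equal(classify_cells(mk(c(0.01, 0.5, 0.5)))$preferred_direction, "left")
  expect_equal(as.character(classify_cells(mk(c(0.01, 0.04, 0.5)))$category),
               "non_direction_related")
  expect_equal(as.character(classify_cells(mk(c(0.9, 0.5, 0.6)))$category),
               "not_modulated")
})

test_that("planted tuned cells are recovered end-to-end", {
  cfg <- tuned_task_config(n_null = 8, n_tuned = 3, n_untuned = 2,
                           n_trials = 90, seed = 31)
  s <- simulate_session(cfg)
  ep <- extract_epochs(s$traces, s$trials, alignment_config())
  mod <- modulation_test(ep)
  cats <- classify_cells(mod)
  tuned <- sprintf("cell_%03d", 9:11)
  untuned <- sprintf("cell_%03d", 12:13)
  expect_gte(sum(cats$category[cats$cell_id %in% tuned] == "direction_related"), 2)
  expect_true(all(cats$category[cats$cell_id %in% untuned] == "non_direction_related"))
})

test_that("magnitude comparisons are calibrated and detect shifts", {
  withr::local_seed(9)
  # calibration: both signs drawn from one magnitude distribution
  rej <- vapply(1:500, function(i) {
    m1 <- abs(rnorm(15))
    m2 <- abs(rnorm(15))
    stats::wilcox.test(m1, m2)$p.value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.03)

  # a +2 shift in the decreasing group is detected through the wrapper
  mod <- structure(
    tibble::tibble(
      cell_id = sprintf("c%02d", 1:30),
      direction = rep(c("left", "right", "center"), 10),
      magnitude = c(abs(rnorm(15)), abs(rnorm(15)) + 2),
      sign = rep(c(1, -1), each = 15),
      p_adjusted = 0.01),
    alpha = 0.05)
  res <- magnitude_comparisons(mod)
  expect_lt(res$p_value[res$comparison == "increase_vs_decrease"], 0.01)
  expect_false(res$skipped[res$comparison == "across_conditions"])

  # single-sign input: rank-sum comparison is skipped and recorded
  mod1 <- dplyr::filter(mod, sign == 1)
  attr(mod1, "alpha") <- 0.05
  res1 <- magnitude_comparisons(mod1)
  expect_true(res1$skipped[res1$comparison == "increase_vs_decrease"])
})
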