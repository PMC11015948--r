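# Builds (sdf, bg) for a rate that steps from bg_rate to bg_rate + step_to
# during [onset, offset] of each trial; step_to < 0 simulates suppression.
step_response_fixture <- function(bg_rate = 5, step_to = 50, onset = 45,
                                  offset = 145, trial_ms = 300,
                                  n_trials = 20, seed = 1) {
  set.seed(seed)
  sim <- function(rate_fun) {
    replicate(n_trials, {
      rmax <- max(rate_fun(seq(0, trial_ms - 1)))
      if (rmax == 0) return(numeric(0))
      n <- rpois(1, rmax * trial_ms / 1000)
      t <- sort(runif(n, 0, trial_ms))
      t[runif(n) < rate_fun(t) / rmax]
    }, simplify = FALSE)
  }
  stim_rate <- function(t) {
    pmax(0, bg_rate + ifelse(t >= onset & t < offset, step_to, 0))
  }
  null_rate <- function(t) rep(bg_rate, length(t))
  list(
    sdf = bootstrap_sdf(sim(stim_rate), duration = trial_ms),
    bg = background_stats(sim(null_rate), duration = trial_ms)
  )
}

test_that("a firing-rate step is classified excitatory with short latency", {
  fx <- step_response_fixture(bg_rate = 5, step_to = 45, seed = 101)
  cls <- classify_response(fx$sdf, fx$bg, stim_onset = 45, stim_offset = 145)
  expect_equal(cls$label, "excitatory")
  expect_lt(cls$onset_latency, 30)
})

test_that("suppression to silence is classified inhibitory", {
  fx <- step_response_fixture(bg_rate = 20, step_to = -20, seed = 102)
  cls <- classify_response(fx$sdf, fx$bg, stim_onset = 45, stim_offset = 145)
  expect_equal(cls$label, "inhibitory")
})

test_that("background-only activity is mostly classified none", {
  set.seed(103)
  labels <- vapply(1:40, function(i) {
    fx <- step_response_fixture(bg_rate = runif(1, 5, 30), step_to = 0,
                                seed = 200 + i)
    classify_response(fx$sdf, fx$bg, 45, 145)$label
  }, "")
  expect_lte(mean(labels != "none"), 0.10)
})

test_that("detection probability grows with response size", {
  set.seed(104)
  det <- vapply(c(3, 10, 40), function(step) {
    mean(vapply(1:12, function(i) {
      fx <- step_response_fixture(bg_rate = 8, step_to = step,
                                  seed = 300 + step * 20 + i)
      classify_response(fx$sdf, fx$bg, 45, 145)$label == "excitatory"
    }, TRUE))
  }, 0)
  expect_true(all(diff(det) >= 0))
  expect_gt(det[3], det[1])
})

test_that("classification is a pure function of its inputs", {
  fx <- step_response_fixture(seed = 105)
  a <- classify_response(fx$sdf, fx$bg, 45, 145)
  b <- classify_response(fx$sdf, fx$bg, 45, 145)
  expect_identical(a, b)
})

test_that("the analysis window is validated and configurable", {
  fx <- step_response_fixture(trial_ms = 150, offset = 120, seed = 106)
  expect_error(classify_response(fx$sdf, fx$bg, 45, 120), "exceeds")
  expect_silent(classify_response(fx$sdf, fx$bg, 45, 120,
                                  window = "stimulus"))
})

test_that("population table rows follow the CF / upper-limit sort", {
  classes <- tidyr::expand_grid(
    unit_id = c("a", "b", "c", "d", "e"),
    stimulus_id = c("s1", "s2")
  )
  classes$label <- "none"
  units <- tibble::tibble(
    unit_id = c("a", "b", "c", "d", "e"),
    cf = c(16, 13, 13, NA, 5),
    bw_hi = c(30, 62, 19, 40, 10)
  )
  pt <- build_population_table(classes, units)
  # no-CF unit first, then CF ascending with upper-limit tie-break at 13
  expect_equal(pt$unit_order, c("d", "e", "c", "b", "a"))
})

test_that("responsiveness fractions respect the denominator choice", {
  classes <- tibble::tibble(
    unit_id = rep(c("a", "b", "c"), each = 2),
    stimulus_id = rep(c("s1", "s2"), 3),
    label = c("excitatory", "none", "both", "inhibitory", "none", "none")
  )
  units <- tibble::tibble(unit_id = c("a", "b", "c"), cf = c(10, 20, 30))
  pt <- build_population_table(classes, units)
  sr <- responsiveness_percentages(pt, "sound_responsive")
  al <- responsiveness_percentages(pt, "all")
  expect_equal(sr$n_denominator, c(2L, 2L))
  expect_equal(al$n_denominator, c(3L, 3L))
  expect_equal(sr$fraction[sr$stimulus_id == "s1"], 1)
  # all-units denominator can only lower the fraction
  expect_true(all(al$fraction <= sr$fraction))
  # 'both' counts as responsive
  expect_equal(sr$fraction[sr$stimulus_id == "s2"], 0.5)
})

test_that("selectivity counts vocal responses and validates the set", {
  ids <- vocal_stimulus_ids()
  labels <- setNames(rep("none", 10), ids)
  expect_equal(selectivity(labels), 0L)
  labels["LFH"] <- "excitatory"
  expect_equal(selectivity(labels), 1L)
  labels[] <- "excitatory"
  expect_equal(selectivity(labels), 10L)
  expect_error(selectivity(labels[1:9]), "exactly the 10")
  expect_error(selectivity(c(labels[1:9], BBN = "none")), "exactly the 10")
})
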