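test_that("population sampling respects the CF mixture bounds", {
  pop <- sample_population(1000, seed = 101)
  expect_equal(nrow(pop), 1000L)
  # minority high-CF component: mass at >= 40 kHz stays small
  expect_lte(mean(pop$cf_true >= 40), 0.20)
  # primary mode in the low-frequency octaves
  expect_gt(mean(pop$cf_true >= 8 & pop$cf_true <= 25), 0.4)
  expect_true(all(pop$bg_rate >= 0))
  exc <- pop[pop$polarity == "excitatory", ]
  expect_true(all(exc$bw60_lo <= exc$cf_true & exc$cf_true <= exc$bw60_hi))
  expect_true(all(pop$sex %in% c("F", "M")))
  expect_true(all(pop$subdivision %in% c("CIC", "ECIC", "DCIC", "border")))
  expect_true(all(pop$estrous[pop$sex == "M"] == "n/a"))
})

test_that("population sampling is deterministic and validates inputs", {
  expect_identical(sample_population(50, seed = 7),
                   sample_population(50, seed = 7))
  expect_error(sample_population(0), "positive")
  expect_error(default_population_profile(p_excitatory = 0.9,
                                          p_inhibitory = 0.3,
                                          p_none = -0.2),
               "sum to 1")
})

test_that("drive follows the linear threshold rule", {
  u <- make_unit(cf = 12.7, threshold = 20, gain = 2)
  tone <- stimulus_descriptor(
    "tone_cf", "tone", 100,
    tracks = list(frequency_track(0, 100, 12.7, 12.7))
  )
  expect_equal(drive(u, tone, 20, 50), 0)           # at threshold
  expect_equal(drive(u, tone, 30, 50), 20)          # gain x 10 dB
  # far off-CF tone at modest level: silent
  tone_hi <- stimulus_descriptor(
    "tone_hi", "tone", 100,
    tracks = list(frequency_track(0, 100, 80, 80))
  )
  expect_equal(drive(u, tone_hi, 40, 50), 0)
  # null stimulus never drives
  expect_equal(drive(u, build_table1_library()[["null"]], 60, 10), 0)
})

test_that("a low-tuned unit is never driven by the chevron call", {
  u <- make_unit(cf = 11, threshold = 25, s_lo = 40, s_hi = 55)
  expect_equal(unname(u$bw60_lo), 6.0, tolerance = 0.1)
  expect_equal(unname(u$bw60_hi), 17.1, tolerance = 0.1)
  chev <- build_table1_library()[["chevron"]]
  expect_true(all(drive(u, chev, 60, seq(0, 52.9, by = 0.5)) == 0))
})

test_that("simulated trials follow the Poisson background", {
  u <- make_unit(bg = 10, polarity = "none")
  nul <- build_table1_library()[["null"]]
  set <- simulate_trials(u, nul, 0, n_trials = 100, trial_ms = 200,
                         onset_ms = 45, seed = 5)
  counts <- lengths(set$trials)
  expected <- 10 * 0.2                      # rate x duration
  se <- sqrt(expected / 100)
  expect_lt(abs(mean(counts) - expected), 3 * se)
  # all spikes inside the trial window
  expect_true(all(unlist(set$trials) >= 0 & unlist(set$trials) < 200))
})

test_that("silent and suppressed units produce the expected trains", {
  u0 <- make_unit(bg = 0, polarity = "none")
  nul <- build_table1_library()[["null"]]
  set0 <- simulate_trials(u0, nul, 0, n_trials = 10, trial_ms = 200,
                          seed = 2)
  expect_true(all(lengths(set0$trials) == 0))

  # inhibitory unit with drive >= bg: silenced during the stimulus
  ui <- make_unit(cf = 12.7, threshold = 20, gain = 2, bg = 10,
                  polarity = "inhibitory")
  tone <- stimulus_descriptor(
    "tone_cf", "tone", 100,
    tracks = list(frequency_track(0, 100, 12.7, 12.7))
  )
  set_i <- simulate_trials(ui, tone, 40, n_trials = 50, trial_ms = 200,
                           onset_ms = 50, seed = 3)
  in_stim <- unlist(set_i$trials)
  expect_equal(sum(in_stim >= 51 & in_stim < 150), 0)
})

test_that("refractory period is enforced within trials", {
  u <- make_unit(bg = 150, polarity = "none")   # high rate forces collisions
  nul <- build_table1_library()[["null"]]
  set <- simulate_trials(u, nul, 0, n_trials = 20, trial_ms = 500, seed = 9)
  gaps <- unlist(lapply(set$trials, function(s) diff(s)))
  expect_true(all(gaps >= 1))
})

test_that("mean count at CF is non-decreasing in level", {
  u <- make_unit(cf = 12.7, threshold = 30, gain = 3, bg = 5)
  tone <- stimulus_descriptor(
    "tone_cf", "tone", 100,
    tracks = list(frequency_track(0, 100, 12.7, 12.7))
  )
  means <- vapply(seq(0, 80, 20), function(lv) {
    set <- simulate_trials(u, tone, lv, n_trials = 60, trial_ms = 200,
                           onset_ms = 50, seed = 100 + lv)
    mean(vapply(set$trials, function(s) sum(s >= 50 & s < 150), 0))
  }, 0)
  expect_true(all(diff(means) > -0.3))   # monotone up to Poisson noise
  expect_gt(means[5], means[1] + 2)
})

test_that("experiment tables have the protocol geometry", {
  pop <- make_unit()
  lib <- build_table1_library()
  expt <- simulate_experiment(pop, lib, seed = 21, wav_levels = 60)
  proto <- expt$protocol
  tone_rows <- expt$spikes[grepl("^tone_[0-9.]+$", expt$spikes$stimulus_id), ]
  conds <- unique(tone_rows[, c("stimulus_id", "level_db")])
  expect_equal(nrow(conds), 15L * 9L)    # 15 freqs x levels 0..80
  # every trial index present for an arbitrary condition
  one <- tone_rows[tone_rows$stimulus_id == conds$stimulus_id[1] &
                     tone_rows$level_db == conds$level_db[1], ]
  expect_setequal(unique(one$trial_index), 1:20)
  expect_equal(nrow(expt$ground_truth), 1L)

  # blocked randomization: each block is a permutation of the WAV set + null
  blocks <- expt$blocks
  per_block <- split(blocks$stimulus_id, interaction(blocks$level_db,
                                                     blocks$block))
  expect_true(all(vapply(per_block, function(ids) {
    setequal(ids, c(wav_stimulus_ids(lib), "null")) &&
      anyDuplicated(ids) == 0
  }, TRUE)))
})

test_that("experiment simulation is deterministic given the seed", {
  pop <- sample_population(2, seed = 33)
  a <- simulate_experiment(pop, seed = 44, wav_levels = 60,
                           include_fra = FALSE)
  b <- simulate_experiment(pop, seed = 44, wav_levels = 60,
                           include_fra = FALSE)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$blocks, b$blocks)
})
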