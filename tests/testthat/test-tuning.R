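test_that("makima interpolation reproduces independent reference values", {
  # values frozen from an independent implementation of the modified-Akima
  # scheme evaluated on the same knots
  x <- 1:6
  y <- c(0, 2, 1, 4, 3, 0)
  expect_equal(makima_interp(x, y, c(1.5, 2.5, 3.7, 5.2)),
               c(1.31291806, 1.45716113, 3.27843137, 2.56096970),
               tolerance = 1e-7)

  x2 <- log2(c(4, 5.04, 6.35, 8, 10.08, 12.7, 16, 20.16, 25.4, 32))
  y2 <- c(0, 0, 0.5, 3, 8, 9, 6, 2, 0.5, 0)
  expect_equal(
    makima_interp(x2, y2, log2(c(4.5, 7, 11, 18, 30))),
    c(-0.03422172, 1.21729030, 8.85447292, 3.80373162, 0.05818232),
    tolerance = 1e-7
  )
})

test_that("makima passes through its knots and handles matrices", {
  set.seed(61)
  x <- sort(runif(9, 0, 10))
  Y <- matrix(rnorm(27), nrow = 3)
  out <- makima_interp(x, Y, x)
  expect_equal(out, Y, tolerance = 1e-10)    # interpolation, not smoothing
  # rows of a matrix match one-at-a-time interpolation
  q <- seq(min(x), max(x), length.out = 25)
  out_q <- makima_interp(x, Y, q)
  expect_equal(out_q[2, ], makima_interp(x, Y[2, ], q), tolerance = 1e-12)
  expect_error(makima_interp(x, Y[, 1:5], q), "ncol")
  expect_error(makima_interp(x, Y, max(x) + 1), "range")
})

test_that("FRA construction counts spikes in the tone window", {
  u <- make_unit(cf = 12.7, threshold = 20, gain = 3, bg = 10)
  expt <- simulate_experiment(u, seed = 71, wav_levels = numeric(0))
  proto <- expt$protocol
  sets <- list()
  for (sid in sprintf("tone_%0.2f", proto$tone_freqs)) {
    for (lv in proto$levels) {
      sets[[length(sets) + 1L]] <- collect_trials(
        expt$spikes, u$unit_id, sid, lv, proto$reps,
        proto$tone_trial_ms, proto$tone_onset
      )
    }
  }
  fra <- build_fra(sets, proto)
  expect_equal(dim(fra$mean_counts), c(15L, 9L))
  # count at CF, 60 dB matches rate x duration analytically
  fi <- which(abs(fra$freq_grid - 12.7) < 0.005)
  expected <- (10 + 3 * 40) * 0.1            # (bg + gain x 40 dB) x 100 ms
  se <- sqrt(expected / 20)
  cell <- fra$mean_counts[fi, which(fra$level_grid == 60)]
  expect_lt(abs(cell - expected), 3 * se)
  # missing cells are reported by name
  expect_error(build_fra(sets[-1], proto), "missing FRA cells: 4.00")
})

test_that("CF and threshold are recovered from a clean FRA", {
  fra <- make_synthetic_fra(cf = 12.7, threshold = 20, gain = 3,
                            bg_count = 0.3, seed = 81)
  est <- estimate_cf(fra)
  expect_equal(est$cf, 4 * 2^(5 / 3), tolerance = 1e-6)
  expect_equal(est$threshold, 30)    # tip fires one step above threshold
})

test_that("unresponsive or untuned FRAs yield no CF", {
  proto <- build_default_protocol()
  dims <- c(length(proto$tone_freqs), length(proto$levels), 20L)
  flat <- structure(
    list(freq_grid = proto$tone_freqs, level_grid = proto$levels,
         mean_counts = matrix(0, dims[1], dims[2]),
         counts = array(0, dims), cf = NA_real_, threshold = NA_real_),
    class = "fra_result"
  )
  est <- estimate_cf(flat)
  expect_true(is.na(est$cf))
  expect_true(is.na(est$threshold))
})

test_that("CF ties break toward the higher count then lower frequency", {
  proto <- build_default_protocol()
  nf <- length(proto$tone_freqs)
  nl <- length(proto$levels)
  counts <- array(0, c(nf, nl, 20L))
  # two equally strong tips at 8 and 16 kHz from 40 dB upward
  for (fi in which(abs(proto$tone_freqs - 8) < 0.005 |
                     abs(proto$tone_freqs - 16) < 0.005)) {
    for (li in which(proto$levels >= 40)) counts[fi, li, ] <- 5
  }
  fra <- structure(
    list(freq_grid = proto$tone_freqs, level_grid = proto$levels,
         mean_counts = apply(counts, c(1, 2), mean), counts = counts,
         cf = NA_real_, threshold = NA_real_),
    class = "fra_result"
  )
  est <- estimate_cf(fra)
  expect_equal(est$cf, 8, tolerance = 1e-6)
  expect_equal(est$threshold, 40)
})

test_that("bandwidth bootstrap recovers a rectangular tuning curve", {
  proto <- build_default_protocol()
  nf <- length(proto$tone_freqs)
  nl <- length(proto$levels)
  counts <- array(0, c(nf, nl, 20L))
  in_band <- proto$tone_freqs >= 8 - 1e-6 & proto$tone_freqs <= 32 + 1e-6
  counts[in_band, which(proto$levels == 60), ] <- 10
  fra <- structure(
    list(freq_grid = proto$tone_freqs, level_grid = proto$levels,
         mean_counts = apply(counts, c(1, 2), mean), counts = counts,
         cf = 16, threshold = 30),
    class = "fra_result"
  )
  bw <- bootstrap_bandwidth(fra, level = 60, seed = 91)
  # against a zero background the interpolant turns positive somewhere
  # inside the flanking tone-grid interval, so the limits are recovered to
  # within one 1/3-octave step of the true band edges
  expect_lt(abs(log2(bw$bw_lo / 8)), 1 / 3 + 0.05)
  expect_lt(abs(log2(bw$bw_hi / 32)), 1 / 3 + 0.05)
  expect_true(all(bw$ftc_ci_lo <= bw$ftc_ci_hi))
})

test_that("bandwidth is undefined when counts never separate from background", {
  proto <- build_default_protocol()
  nf <- length(proto$tone_freqs)
  nl <- length(proto$levels)
  set.seed(92)
  counts <- array(rpois(nf * nl * 20L, 1), c(nf, nl, 20L))
  fra <- structure(
    list(freq_grid = proto$tone_freqs, level_grid = proto$levels,
         mean_counts = apply(counts, c(1, 2), mean), counts = counts,
         cf = 16, threshold = 30),
    class = "fra_result"
  )
  bw <- bootstrap_bandwidth(fra, level = 60, seed = 93)
  expect_true(is.na(bw$bw_lo))
  expect_true(is.na(bw$bw_hi))
})

test_that("bandwidth bootstrap is deterministic and validates levels", {
  fra <- make_synthetic_fra(seed = 94)
  a <- bootstrap_bandwidth(fra, level = 60, seed = 7)
  b <- bootstrap_bandwidth(fra, level = 60, seed = 7)
  expect_identical(a, b)
  expect_error(bootstrap_bandwidth(fra, level = 65), "not in FRA grid")
  fra0 <- fra
  fra0$level_grid <- fra$level_grid + 5      # no 0 dB column any more
  expect_error(bootstrap_bandwidth(fra0, level = 65), "no background level")
})

test_that("noiseless peaked tuning keeps CF inside the bandwidth", {
  fra <- make_synthetic_fra(cf = 12.7, threshold = 20, gain = 4,
                            bg_count = 0.2, seed = 95)
  est <- estimate_cf(fra)
  bw <- bootstrap_bandwidth(fra, level = 60, seed = 96)
  expect_lte(bw$bw_lo, est$cf)
  expect_gte(bw$bw_hi, est$cf)
})

test_that("CF bands are octave-wide and centered at 10, 20, 40 kHz", {
  expect_equal(assign_cf_band(c(12.7, 16, 64)), c("10", "20", "other"))
  expect_equal(assign_cf_band(10 / sqrt(2)), "10")        # closed lower edge
  expect_equal(assign_cf_band(10 * sqrt(2)), "20")        # open upper edge
  expect_equal(assign_cf_band(c(5, 40, 56, 57)),
               c("other", "40", "40", "other"))
  expect_true(is.na(assign_cf_band(NA_real_)))
})
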