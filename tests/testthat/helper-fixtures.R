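# Shared fixtures. The heavy synthetic-population run used by the
# recovery/overlap/category acceptance checks is built once per test
# session, lazily, and cached here.

.fixture_env <- new.env(parent = emptyenv())

# One excitatory unit with hand-set tuning, as a one-row tibble.
make_unit <- function(cf = 12.7, threshold = 20, s_lo = 40, s_hi = 60,
                      gain = 3, bg = 8, polarity = "excitatory",
                      unit_id = "u0001") {
  db <- max(0, 60 - threshold)
  tibble::tibble(
    unit_id = unit_id, cf_true = cf, threshold_true = threshold,
    low_tail_slope = s_lo, high_edge_slope = s_hi,
    bw60_lo = max(4, cf * 2^(-db / s_lo)),
    bw60_hi = min(100, cf * 2^(db / s_hi)),
    gain = gain, bg_rate = bg, polarity = polarity,
    sex = "F", estrous = "estrus", subdivision = "CIC",
    anesthesia = "ANEST"
  )
}

# Homogeneous Poisson spike trains (no refractoriness) for SDF tests.
poisson_trials <- function(n_trials, rate, trial_ms, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  replicate(n_trials, {
    n <- rpois(1, rate * trial_ms / 1000)
    sort(runif(n, 0, trial_ms))
  }, simplify = FALSE)
}

# Synthetic FRA with an analytically known response region: counts are
# Poisson around bg_count plus drive for cells inside the V centred at cf.
make_synthetic_fra <- function(cf = 12.7, threshold = 20, s_lo = 40,
                               s_hi = 60, gain = 3, bg_count = 0.5,
                               reps = 20, seed = 1) {
  set.seed(seed)
  proto <- build_default_protocol()
  nf <- length(proto$tone_freqs)
  nl <- length(proto$levels)
  counts <- array(0, c(nf, nl, reps),
                  dimnames = list(sprintf("%0.2f", proto$tone_freqs),
                                  proto$levels, NULL))
  for (fi in seq_len(nf)) {
    f <- proto$tone_freqs[fi]
    oct <- log2(f / cf)
    thr <- threshold + if (oct < 0) -oct * s_lo else oct * s_hi
    for (li in seq_len(nl)) {
      lv <- proto$levels[li]
      lam <- bg_count + if (lv > 0) max(0, gain * (lv - thr)) * 0.1 else 0
      counts[fi, li, ] <- rpois(reps, lam)
    }
  }
  structure(
    list(freq_grid = proto$tone_freqs, level_grid = proto$levels,
         mean_counts = apply(counts, c(1, 2), mean), counts = counts,
         cf = NA_real_, threshold = NA_real_),
    class = "fra_result"
  )
}

# The shared medium-scale population run: 120 units, tone mapping + WAV
# playback at 60 dB, tuning + responses + overlap + categories. Built on
# first use and reused by all recovery and population-pattern checks.
population_fixture <- function() {
  if (is.null(.fixture_env$pipeline)) {
    .fixture_env$pipeline <- run_ic_pipeline(n_units = 120, seed = 42)
  }
  .fixture_env$pipeline
}

usv_ids <- c("chevron_NL", "flat", "chevron", "1-step", "2-step")

one_third_octave_step <- 2^(1 / 3)
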