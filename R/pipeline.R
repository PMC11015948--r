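#' Frequency tuning analysis for every unit of an experiment
#'
#' Builds each unit's FRA from the tone trials, estimates CF and
#' threshold, and (for units with a CF) bootstraps the tuning bandwidth at
#' `config$bw_level`.
#'
#' @param experiment An [simulate_experiment()] result, or a list with the
#'   same `spikes` / `trial_info` / `protocol` fields built from read
#'   tables.
#' @param config A [default_config()].
#' @return Tibble per unit: `unit_id`, `cf`, `threshold`, `cf_band`,
#'   `bw_lo`, `bw_hi`, `bw_level`.
#' @export
analyze_tuning <- function(experiment, config = default_config()) {
  proto <- experiment$protocol
  spikes <- experiment$spikes
  tone_ids <- sprintf("tone_%0.2f", proto$tone_freqs)
  units <- unique(spikes$unit_id)
  res <- vector("list", length(units))
  for (i in seq_along(units)) {
    uid <- units[i]
    usp <- spikes[spikes$unit_id == uid & spikes$stimulus_id %in% tone_ids, ]
    sets <- list()
    for (sid in tone_ids) {
      for (lv in proto$levels) {
        sets[[length(sets) + 1L]] <- collect_trials(
          usp, uid, sid, lv, n_trials = proto$reps,
          trial_ms = proto$tone_trial_ms, onset_ms = proto$tone_onset,
          offset_ms = proto$tone_onset + proto$tone_dur
        )
      }
    }
    fra <- build_fra(sets, proto)
    fra <- estimate_cf(fra, n_se = config$cf_n_se,
                       min_count = config$cf_min_count)
    bw <- list(bw_lo = NA_real_, bw_hi = NA_real_)
    if (!is.na(fra$cf)) {
      bw <- bootstrap_bandwidth(fra, level = config$bw_level,
                                n_boot = config$n_boot_bw,
                                alpha = config$alpha,
                                n_interp = config$n_interp)
    }
    res[[i]] <- tibble::tibble(
      unit_id = uid, cf = fra$cf, threshold = fra$threshold,
      cf_band = assign_cf_band(fra$cf),
      bw_lo = bw$bw_lo, bw_hi = bw$bw_hi, bw_level = config$bw_level
    )
  }
  dplyr::bind_rows(res)
}

#' Response classification for every unit x WAV stimulus
#'
#' For each unit, estimates background statistics from its null trials at
#' `level` and classifies the response to every sounded WAV stimulus via
#' the bootstrap-SDF / background-percentile rule.
#'
#' @inheritParams analyze_tuning
#' @param level Playback peak level to analyze (dB SPL).
#' @param library Stimulus library used for stimulus durations.
#' @return Tidy tibble: `unit_id`, `stimulus_id`, `level`, `label`,
#'   `onset_latency`.
#' @export
analyze_responses <- function(experiment, level = 60,
                              library = build_table1_library(),
                              config = default_config()) {
  proto <- experiment$protocol
  spikes <- experiment$spikes
  wav_ids <- wav_stimulus_ids(library)
  units <- unique(spikes$unit_id)
  res <- vector("list", length(units) * length(wav_ids))
  k <- 0L
  for (uid in units) {
    usp <- spikes[spikes$unit_id == uid & spikes$level_db == level, ]
    null_set <- collect_trials(usp, uid, "null", level,
                               n_trials = proto$reps,
                               trial_ms = proto$wav_trial_ms)
    bg <- background_stats(null_set, n_boot = config$n_boot_sdf,
                           kernel_sd = config$kernel_sd)
    for (sid in wav_ids) {
      stim <- library[[sid]]
      set <- collect_trials(usp, uid, sid, level, n_trials = proto$reps,
                            trial_ms = proto$wav_trial_ms,
                            onset_ms = proto$leading_pad,
                            offset_ms = proto$leading_pad + stim$duration)
      est <- bootstrap_sdf(set, n_boot = config$n_boot_sdf,
                           alpha = config$alpha,
                           kernel_sd = config$kernel_sd)
      cls <- classify_response(est, bg,
                               stim_onset = proto$leading_pad,
                               stim_offset = proto$leading_pad +
                                 stim$duration,
                               min_run_ms = config$min_run_ms,
                               post_window_ms = config$post_window_ms,
                               window = config$window)
      k <- k + 1L
      res[[k]] <- tibble::tibble(unit_id = uid, stimulus_id = sid,
                                 level = level, label = cls$label,
                                 onset_latency = cls$onset_latency)
    }
  }
  dplyr::bind_rows(res)
}

#' Run the full synthetic-population pipeline
#'
#' Convenience wrapper: samples a population, simulates the experiment
#' (tone mapping plus WAV playback at `level`), and runs tuning analysis,
#' response classification, overlap scoring and category summaries.
#'
#' @param n_units Population size.
#' @param seed Master seed for population and spikes.
#' @param level WAV playback level analyzed (dB SPL).
#' @param profile Population profile.
#' @param config Run configuration.
#' @return List with `experiment`, `tuning`, `responses`, `overlap`,
#'   `population_table`, `percentages`, `categories`.
#' @export
run_ic_pipeline <- function(n_units = 50, seed = 1L, level = 60,
                            profile = default_population_profile(),
                            config = default_config()) {
  pop <- sample_population(n_units, profile, seed = seed)
  lib <- build_table1_library()
  expt <- simulate_experiment(pop, lib, seed = seed + 1L,
                              wav_levels = level)
  tuning <- analyze_tuning(expt, config)
  responses <- analyze_responses(expt, level = level, library = lib,
                                 config = config)
  ov <- suppressWarnings(
    overlap_records(tuning, responses, library = lib, level = level)
  )
  pt <- build_population_table(responses, tuning)
  list(
    experiment = expt,
    tuning = tuning,
    responses = responses,
    overlap = ov,
    population_table = pt,
    percentages = responsiveness_percentages(pt),
    categories = category_summary(responses, pop, library = lib,
                                  groupby = "none")
  )
}
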