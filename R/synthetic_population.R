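#' Default population profile for the synthetic IC
#'
#' Parameters of the generative model for synthetic inferior colliculus
#' units. The characteristic-frequency (CF) distribution is a two-component
#' mixture on log2 frequency: a dominant low component with its mode in the
#' 13-16 kHz range and a minor high component near 51 kHz, keeping the mass
#' at or above 40 kHz below ~15%. The high-CF component is weighted more
#' heavily in males than in females, echoing the reported sex difference in
#' CF histograms. Tuning edges fall off linearly in dB per octave away from
#' CF, with independently drawn low- and high-side slopes so that units
#' within a CF group span a wide range of upper tuning limits.
#'
#' @param w_high_f,w_high_m Mixture weight of the high-CF component in
#'   females / males.
#' @param cf_mode_low,cf_sd_low Mode (kHz) and SD (octaves) of the low-CF
#'   component.
#' @param cf_mode_high,cf_sd_high Same for the high-CF component.
#' @param threshold_mean,threshold_sd Tone threshold at CF (dB SPL).
#' @param slope_low_range,slope_high_range Uniform ranges for the low-side
#'   and high-side tuning slopes (dB/octave).
#' @param gain_range Uniform range of rate gain ((spikes/s)/dB above
#'   threshold).
#' @param bg_shape,bg_rate_mean Gamma shape and mean (spikes/s) of the
#'   background-rate distribution.
#' @param p_excitatory,p_inhibitory,p_none Polarity mix (must sum to 1).
#' @param rate_ceiling Saturation of the driven rate (spikes/s).
#' @return Named list of class `population_profile`.
#' @export
default_population_profile <- function(w_high_f = 0.08, w_high_m = 0.18,
                                       cf_mode_low = 14.5, cf_sd_low = 0.55,
                                       cf_mode_high = 51, cf_sd_high = 0.22,
                                       threshold_mean = 30, threshold_sd = 8,
                                       slope_low_range = c(20, 70),
                                       slope_high_range = c(15, 60),
                                       gain_range = c(2, 5),
                                       bg_shape = 3, bg_rate_mean = 15,
                                       p_excitatory = 0.7,
                                       p_inhibitory = 0.1,
                                       p_none = 0.2,
                                       rate_ceiling = 350) {
  p <- c(p_excitatory, p_inhibitory, p_none)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("polarity probabilities must be non-negative and sum to 1")
  }
  w <- c(w_high_f, w_high_m)
  if (any(w < 0) || any(w > 1)) stop("invalid mixture weights")
  structure(
    list(w_high_f = w_high_f, w_high_m = w_high_m,
         cf_mode_low = cf_mode_low, cf_sd_low = cf_sd_low,
         cf_mode_high = cf_mode_high, cf_sd_high = cf_sd_high,
         threshold_mean = threshold_mean, threshold_sd = threshold_sd,
         slope_low_range = slope_low_range,
         slope_high_range = slope_high_range,
         gain_range = gain_range,
         bg_shape = bg_shape, bg_rate_mean = bg_rate_mean,
         p_excitatory = p_excitatory, p_inhibitory = p_inhibitory,
         p_none = p_none, rate_ceiling = rate_ceiling),
    class = "population_profile"
  )
}

#' Sample a synthetic IC unit population
#'
#' Draws ground-truth tuning parameters and grouping labels for `n_units`
#' synthetic units from a [default_population_profile()]. The 60 dB tuning
#' band `(bw60_lo, bw60_hi)` is the analytic width of the threshold surface
#' at 60 dB SPL: `cf * 2^(-(60 - threshold)/slope_low)` to
#' `cf * 2^((60 - threshold)/slope_high)`, clipped to 4-100 kHz.
#'
#' @param n_units Number of units (>= 1).
#' @param profile A [default_population_profile()] (or modified copy).
#' @param seed Optional integer seed; the draw is deterministic given it.
#' @return Tibble with one row per unit: `unit_id`, `cf_true`,
#'   `threshold_true`, `low_tail_slope`, `high_edge_slope`, `bw60_lo`,
#'   `bw60_hi`, `gain`, `bg_rate`, `polarity`, `sex`, `estrous`,
#'   `subdivision`, `anesthesia`.
#' @export
sample_population <- function(n_units,
                              profile = default_population_profile(),
                              seed = NULL) {
  if (!is.numeric(n_units) || length(n_units) != 1L || n_units < 1) {
    stop("n_units must be a positive integer")
  }
  n_units <- as.integer(n_units)
  if (!is.null(seed)) withr::local_seed(seed)
  pr <- profile

  sex <- sample(c("F", "M"), n_units, replace = TRUE)
  w_high <- ifelse(sex == "F", pr$w_high_f, pr$w_high_m)
  comp_high <- runif(n_units) < w_high
  log2cf <- ifelse(
    comp_high,
    rnorm(n_units, log2(pr$cf_mode_high), pr$cf_sd_high),
    rnorm(n_units, log2(pr$cf_mode_low), pr$cf_sd_low)
  )
  cf <- pmin(80, pmax(4.5, 2^log2cf))

  threshold <- pmin(55, pmax(10, rnorm(n_units, pr$threshold_mean,
                                       pr$threshold_sd)))
  s_lo <- runif(n_units, pr$slope_low_range[1], pr$slope_low_range[2])
  s_hi <- runif(n_units, pr$slope_high_range[1], pr$slope_high_range[2])
  gain <- runif(n_units, pr$gain_range[1], pr$gain_range[2])
  bg <- rgamma(n_units, shape = pr$bg_shape,
               scale = pr$bg_rate_mean / pr$bg_shape)
  polarity <- sample(c("excitatory", "inhibitory", "none"), n_units,
                     replace = TRUE,
                     prob = c(pr$p_excitatory, pr$p_inhibitory, pr$p_none))
  estrous <- ifelse(sex == "F",
                    sample(c("estrus", "nonestrus"), n_units,
                           replace = TRUE, prob = c(0.4, 0.6)),
                    "n/a")
  subdivision <- sample(c("CIC", "ECIC", "DCIC", "border"), n_units,
                        replace = TRUE, prob = c(0.55, 0.2, 0.17, 0.08))

  db_above <- pmax(0, 60 - threshold)
  tibble::tibble(
    unit_id = sprintf("u%04d", seq_len(n_units)),
    cf_true = cf,
    threshold_true = threshold,
    low_tail_slope = s_lo,
    high_edge_slope = s_hi,
    bw60_lo = pmax(4, cf * 2^(-db_above / s_lo)),
    bw60_hi = pmin(100, cf * 2^(db_above / s_hi)),
    gain = gain,
    bg_rate = bg,
    polarity = polarity,
    sex = sex,
    estrous = estrous,
    subdivision = subdivision,
    anesthesia = "ANEST"
  )
}

# Pure-tone threshold of a unit at frequency f (kHz): the threshold at CF
# plus a linear penalty in dB per octave of distance from CF.
.unit_threshold_at <- function(unit, f) {
  oct <- log2(f / unit$cf_true)
  unit$threshold_true +
    ifelse(oct < 0, -oct * unit$low_tail_slope, oct * unit$high_edge_slope)
}

#' Instantaneous stimulus drive of a synthetic unit
#'
#' Rate increment (spikes/s) a stimulus exerts on a unit at time `t` from
#' stimulus onset. Each active track contributes
#' `gain * (effective level at the track's instantaneous frequency -
#' tone threshold at that frequency)` when positive, where the effective
#' level is the playback level plus the track's amplitude relative to peak;
#' the maximum over tracks is taken and saturates at the profile's rate
#' ceiling. Broadband (noise) tracks excite at the most favorable frequency
#' inside their band. Polarity is not applied here; the magnitude is signed
#' by the spike simulator.
#'
#' @param unit One-row tibble (or list) of ground-truth unit parameters.
#' @param stimulus A [stimulus_descriptor()].
#' @param level Playback peak level (dB SPL).
#' @param t Time(s) from stimulus onset (ms); vectorized.
#' @param rate_ceiling Saturation (spikes/s).
#' @return Numeric vector of rate increments, same length as `t`.
#' @export
drive <- function(unit, stimulus, level, t, rate_ceiling = 350) {
  inc <- numeric(length(t))
  if (stimulus$kind == "null") return(inc)
  for (tr in stimulus$tracks) {
    active <- t >= tr$t_start & t <= tr$t_end
    if (!any(active)) next
    eff <- level + tr$level_rel_peak
    if (stimulus$kind == "bbn") {
      # all frequencies in the band present at once: the unit hears the
      # frequency with the lowest threshold, i.e. the band point nearest CF
      f_best <- pmin(pmax(unit$cf_true, tr$f_start), tr$f_end)
      thr <- .unit_threshold_at(unit, f_best)
      contrib <- rep(max(0, eff - thr), sum(active))
    } else {
      frac <- (t[active] - tr$t_start) / (tr$t_end - tr$t_start)
      f_t <- tr$f_start + frac * (tr$f_end - tr$f_start)
      thr <- .unit_threshold_at(unit, f_t)
      contrib <- pmax(0, eff - thr)
    }
    inc[active] <- pmax(inc[active], contrib)
  }
  pmin(unit$gain * inc, rate_ceiling)
}

# Enforce an absolute refractory period within each trial of a global
# spike list. `trial` and `time` are parallel vectors sorted by
# (trial, time); spikes closer than `refrac` ms to an accepted predecessor
# are dropped, iterating until no violations remain.
.apply_refractory <- function(trial, time, refrac = 1) {
  repeat {
    if (length(time) < 2L) break
    gap_ok <- c(TRUE, diff(time) >= refrac | diff(trial) != 0)
    if (all(gap_ok)) break
    # drop a violator only when its predecessor survives this pass, so a
    # run t, t+0.5, t+1.2 greedily keeps t and t+1.2
    drop <- !gap_ok & c(TRUE, gap_ok[-length(gap_ok)])
    trial <- trial[!drop]
    time <- time[!drop]
  }
  list(trial = trial, time = time)
}

#' Simulate spike trains for one unit x stimulus x level
#'
#' Inhomogeneous Poisson spikes via thinning against the per-ms rate
#' `r(t) = max(0, bg_rate +/- drive(t))` (sign from the unit's polarity;
#' `none` ignores the drive), with a 1 ms absolute refractory period.
#' The stimulus starts `onset_ms` into each trial.
#'
#' @inheritParams drive
#' @param n_trials Number of trials.
#' @param trial_ms Trial duration (ms).
#' @param onset_ms Stimulus onset within the trial (ms).
#' @param seed Optional seed for deterministic output.
#' @return A `trial_spike_set`: list with `unit_id`, `stimulus_id`, `level`,
#'   `trials` (list of sorted spike-time vectors, ms), `trial_duration`,
#'   `onset`, `offset`.
#' @export
simulate_trials <- function(unit, stimulus, level, n_trials = 20L,
                            trial_ms = 500, onset_ms = 45, seed = NULL,
                            rate_ceiling = 350) {
  if (!is.null(seed)) withr::local_seed(seed)
  grid <- seq(0, trial_ms - 1)
  rate <- rep(unit$bg_rate, length(grid))
  in_stim <- grid >= onset_ms & grid < onset_ms + stimulus$duration
  if (any(in_stim) && unit$polarity != "none") {
    d <- drive(unit, stimulus, level, grid[in_stim] - onset_ms,
               rate_ceiling = rate_ceiling)
    rate[in_stim] <- rate[in_stim] + if (unit$polarity == "inhibitory") -d else d
  }
  rate <- pmax(0, rate)
  rmax <- max(rate)
  trials <- rep(list(numeric(0)), n_trials)
  if (rmax > 0) {
    n_cand <- rpois(n_trials, rmax * trial_ms / 1000)
    trial_ix <- rep.int(seq_len(n_trials), n_cand)
    t_cand <- runif(sum(n_cand), 0, trial_ms)
    keep <- runif(sum(n_cand)) < rate[floor(t_cand) + 1L] / rmax
    trial_ix <- trial_ix[keep]
    t_cand <- t_cand[keep]
    o <- order(trial_ix, t_cand)
    res <- .apply_refractory(trial_ix[o], t_cand[o])
    trials[] <- split(res$time, factor(res$trial, levels = seq_len(n_trials)))
  }
  structure(
    list(unit_id = unit$unit_id, stimulus_id = stimulus$id, level = level,
         trials = trials, trial_duration = trial_ms,
         onset = onset_ms, offset = onset_ms + stimulus$duration),
    class = "trial_spike_set"
  )
}

#' @export
print.trial_spike_set <- function(x, ...) {
  cat(sprintf("<trial_spike_set %s x %s @ %s dB: %d trials, %g ms, %d spikes>\n",
              x$unit_id, x$stimulus_id, format(x$level), length(x$trials),
              x$trial_duration, sum(lengths(x$trials))))
  invisible(x)
}

#' Simulate a full recording experiment
#'
#' For every unit in `population`, simulates (a) the tone-mapping protocol
#' (every tone frequency x level combination, including the 0 dB catch
#' level, `reps` trials each), (b) WAV playback of the 13 sounded stimuli
#' plus the null stimulus at each requested peak level in blocked-randomized
#' order (each block is a random permutation of the WAV set with no
#' repeats), and (c) the spike trains for all of these.
#'
#' @param population Tibble from [sample_population()].
#' @param library Stimulus library from [build_table1_library()].
#' @param protocol Protocol from [build_default_protocol()].
#' @param seed Integer seed; all randomness (block orders and spikes) is
#'   deterministic given it.
#' @param wav_levels Peak levels at which to play the WAV set (defaults to
#'   the protocol's four levels; restrict to save time).
#' @param include_fra If `FALSE`, skip the tone-mapping block.
#' @return List of class `ic_experiment` with elements `spikes` (tibble:
#'   `unit_id`, `stimulus_id`, `level_db`, `trial_index`, `spike_time_ms`;
#'   one all-`NA` spike row marks a spikeless trial), `trial_info` (per
#'   stimulus x level: `n_trials`, `trial_ms`, `onset_ms`, `offset_ms`),
#'   `blocks` (presentation order of the WAV blocks), `ground_truth`
#'   (the population tibble), `protocol`.
#' @export
simulate_experiment <- function(population, library = build_table1_library(),
                                protocol = build_default_protocol(),
                                seed = 1L,
                                wav_levels = protocol$wav_levels,
                                include_fra = TRUE) {
  withr::local_seed(seed)
  wav_ids <- c(wav_stimulus_ids(library), "null")
  n_units <- nrow(population)
  spike_chunks <- list()
  info_rows <- list()
  block_rows <- list()

  add_set <- function(set) {
    k <- length(spike_chunks) + 1L
    n_sp <- lengths(set$trials)
    df <- tibble::tibble(
      unit_id = set$unit_id,
      stimulus_id = set$stimulus_id,
      level_db = set$level,
      trial_index = rep.int(seq_along(set$trials), pmax(1L, n_sp)),
      spike_time_ms = unlist(lapply(set$trials, function(s) {
        if (length(s) == 0L) NA_real_ else s
      }), use.names = FALSE)
    )
    spike_chunks[[k]] <<- df
  }

  # blocked-randomized WAV presentation order (shared across units, as for
  # a simultaneously recorded population)
  for (lv in wav_levels) {
    for (b in seq_len(protocol$reps)) {
      block_rows[[length(block_rows) + 1L]] <- tibble::tibble(
        level_db = lv, block = b, position = seq_along(wav_ids),
        stimulus_id = sample(wav_ids)
      )
    }
  }

  for (i in seq_len(n_units)) {
    unit <- population[i, ]
    if (include_fra) {
      for (f in protocol$tone_freqs) {
        tone <- stimulus_descriptor(
          id = sprintf("tone_%0.2f", f), kind = "tone",
          duration = protocol$tone_dur,
          tracks = list(frequency_track(0, protocol$tone_dur, f, f)),
          band20 = c(f, f), band30 = c(f, f), f_peak = f
        )
        for (lv in protocol$levels) {
          add_set(simulate_trials(
            unit, tone, lv, n_trials = protocol$reps,
            trial_ms = protocol$tone_trial_ms,
            onset_ms = protocol$tone_onset
          ))
        }
      }
    }
    for (sid in wav_ids) {
      stim <- library[[sid]]
      for (lv in wav_levels) {
        add_set(simulate_trials(
          unit, stim, lv, n_trials = protocol$reps,
          trial_ms = protocol$wav_trial_ms,
          onset_ms = protocol$leading_pad
        ))
      }
    }
  }

  if (include_fra) {
    info_rows[[1]] <- tidyr::expand_grid(
      stimulus_id = sprintf("tone_%0.2f", protocol$tone_freqs),
      level_db = protocol$levels
    ) |>
      dplyr::mutate(n_trials = protocol$reps,
                    trial_ms = protocol$tone_trial_ms,
                    onset_ms = protocol$tone_onset,
                    offset_ms = protocol$tone_onset + protocol$tone_dur)
  }
  durs <- vapply(library[wav_ids], `[[`, 0, "duration")
  info_rows[[length(info_rows) + 1L]] <- tidyr::expand_grid(
    stimulus_id = wav_ids, level_db = wav_levels
  ) |>
    dplyr::mutate(n_trials = protocol$reps,
                  trial_ms = protocol$wav_trial_ms,
                  onset_ms = protocol$leading_pad,
                  offset_ms = protocol$leading_pad + durs[.data$stimulus_id])

  structure(
    list(
      spikes = dplyr::bind_rows(spike_chunks),
      trial_info = dplyr::bind_rows(info_rows),
      blocks = dplyr::bind_rows(block_rows),
      ground_truth = population,
      protocol = protocol
    ),
    class = "ic_experiment"
  )
}

#' Rebuild trial spike sets from a tidy spike table
#'
#' Inverse of the flat `spikes` representation: collects the spike rows of
#' one unit x stimulus x level back into a `trial_spike_set`.
#'
#' @param spikes Tidy spike tibble (see [simulate_experiment()]).
#' @param unit_id,stimulus_id,level_db Condition selectors.
#' @param n_trials,trial_ms,onset_ms,offset_ms Trial geometry (take them
#'   from the experiment's `trial_info`).
#' @return A `trial_spike_set`.
#' @export
collect_trials <- function(spikes, unit_id, stimulus_id, level_db,
                           n_trials, trial_ms, onset_ms = NA_real_,
                           offset_ms = NA_real_) {
  rows <- spikes[spikes$unit_id == unit_id &
                   spikes$stimulus_id == stimulus_id &
                   spikes$level_db == level_db, ]
  times <- rows$spike_time_ms[!is.na(rows$spike_time_ms)]
  ix <- rows$trial_index[!is.na(rows$spike_time_ms)]
  trials <- split(times, factor(ix, levels = seq_len(n_trials)))
  trials <- lapply(trials, sort)
  names(trials) <- NULL
  structure(
    list(unit_id = unit_id, stimulus_id = stimulus_id, level = level_db,
         trials = trials, trial_duration = trial_ms,
         onset = onset_ms, offset = offset_ms),
    class = "trial_spike_set"
  )
}
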