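#' Spectrotemporal track of a stimulus component
#'
#' A `frequency_track` is a linear time-frequency segment: the instantaneous
#' frequency sweeps from `f_start` to `f_end` between `t_start` and `t_end`,
#' at an amplitude of `level_rel_peak` dB relative to the stimulus peak.
#' A set of tracks is a stylized sonogram: enough spectrotemporal structure
#' to carry a call's band limits and drive a model neuron, not a full
#' spectrogram.
#'
#' @param t_start,t_end Segment start/end time (ms); `t_start < t_end`.
#' @param f_start,f_end Instantaneous frequency at segment start/end (kHz),
#'   within 4-100 kHz.
#' @param level_rel_peak Amplitude relative to the stimulus peak (dB, <= 0).
#' @return An object of class `frequency_track`.
#' @export
frequency_track <- function(t_start, t_end, f_start, f_end,
                            level_rel_peak = 0) {
  stopifnot(is.numeric(t_start), is.numeric(t_end), t_start < t_end)
  if (f_start < 4 || f_start > 100 || f_end < 4 || f_end > 100) {
    stop("track frequencies must lie within [4, 100] kHz")
  }
  if (level_rel_peak > 0) stop("level_rel_peak must be <= 0 dB")
  structure(
    list(t_start = t_start, t_end = t_end,
         f_start = f_start, f_end = f_end,
         level_rel_peak = level_rel_peak),
    class = "frequency_track"
  )
}

#' One acoustic stimulus
#'
#' Describes a playback stimulus: a vocal syllable, broadband noise burst,
#' tone burst, or the silent null stimulus. Band limits are the frequencies
#' at which the spectrum falls 20 / 30 dB below its peak, as tabulated for
#' the vocal repertoire.
#'
#' @param id Stimulus name.
#' @param kind One of `"vocal"`, `"bbn"`, `"tone"`, `"null"`.
#' @param duration Duration (ms), > 0.
#' @param peak_level Nominal peak playback level (dB SPL); `NA` for null.
#' @param tracks List of [frequency_track()] objects (empty for null).
#' @param band20,band30 Length-2 numeric `(lo, hi)` in kHz: spectral limits
#'   at -20 / -30 dB re peak. `band30` must enclose `band20`; both `NA` for
#'   the null stimulus.
#' @param f_peak Frequency of peak spectral energy (kHz).
#' @param context Free-text behavioral context label.
#' @return An object of class `stimulus_descriptor`.
#' @export
stimulus_descriptor <- function(id, kind, duration, peak_level = NA_real_,
                                tracks = list(), band20 = c(NA_real_, NA_real_),
                                band30 = c(NA_real_, NA_real_),
                                f_peak = NA_real_, context = NA_character_) {
  kind <- match.arg(kind, c("vocal", "bbn", "tone", "null"))
  stopifnot(length(duration) == 1L, duration > 0)
  if (kind == "null" && length(tracks) > 0L) {
    stop("null stimulus must have no tracks")
  }
  if (!anyNA(c(band20, band30))) {
    if (band30[1] > band20[1] || band30[2] < band20[2]) {
      stop("band30 must enclose band20")
    }
  }
  if (!is.na(f_peak) && !anyNA(band30)) {
    if (f_peak < band30[1] || f_peak > band30[2]) {
      stop("f_peak must lie within band30")
    }
  }
  structure(
    list(id = id, kind = kind, duration = duration, peak_level = peak_level,
         tracks = tracks, band20 = band20, band30 = band30,
         f_peak = f_peak, context = context),
    class = "stimulus_descriptor"
  )
}

#' @export
print.stimulus_descriptor <- function(x, ...) {
  b30 <- if (anyNA(x$band30)) "-" else
    sprintf("%g-%g kHz", x$band30[1], x$band30[2])
  cat(sprintf("<stimulus '%s' (%s), %g ms, -30 dB band %s>\n",
              x$id, x$kind, x$duration, b30))
  invisible(x)
}

# Tabulated acoustic features of the 10 vocal syllables:
# id, context, duration (ms), -20 dB band, -30 dB band, f_peak (kHz).
.table1 <- function() {
  tibble::tribble(
    ~id,          ~context,    ~duration, ~b20lo, ~b20hi, ~b30lo, ~b30hi, ~f_peak,
    "chevron_NL", "Mating",        65,      83,     93,     81,     94,     89,
    "flat",       "Mating",        40,      63,     77,     62,     77,     70,
    "chevron",    "Mating",        53,      67,     88,     61,     89,     80,
    "1-step",     "Mating",       120,      37,     90,     36,     92,     72,
    "2-step",     "Mating",       140,      34,     81,     29,     84,     50,
    "noisy",      "Isolation",     90,      18,     66,     17,     69,     27,
    "MFV_tonal",  "Restraint",     40,       8,     37,      6,     38,     29,
    "MFV_harm",   "Restraint",    100,       6,     20,      5,     44,     13,
    "MFV_NL",     "Restraint",     16,       5,     59,      4,     63,     50,
    "LFH",        "Mating",        84,       4,     20,      4,     67,     10
  )
}

# Stylized track geometry per syllable. Each syllable gets main tracks at
# 0 dB spanning its -20 dB band (arch for chevrons, piecewise segments for
# stepped USVs, fundamental + harmonics for harmonic calls) plus -25 dB
# side tracks filling the remainder of the -30 dB band. Geometry is
# invented; it is constrained only to reproduce the tabulated duration,
# band limits and peak frequency.
.vocal_tracks <- function(id, dur, b20, b30) {
  tr <- frequency_track
  main <- switch(
    id,
    "chevron" = ,
    "chevron_NL" = list(tr(0, dur * 0.6, b20[1], b20[2]),
                        tr(dur * 0.6, dur, b20[2], b20[1])),
    "1-step" = list(tr(0, dur * 0.5, b20[1], (b20[1] + b20[2]) / 2),
                    tr(dur * 0.5, dur, (b20[1] + b20[2]) / 2, b20[2])),
    "2-step" = list(tr(0, dur / 3, b20[1], b20[1] + diff(b20) / 3),
                    tr(dur / 3, 2 * dur / 3, b20[1] + diff(b20) / 3,
                       b20[1] + 2 * diff(b20) / 3),
                    tr(2 * dur / 3, dur, b20[1] + 2 * diff(b20) / 3, b20[2])),
    "MFV_tonal" = list(tr(0, dur, b20[1], b20[1] + diff(b20) * 0.45),
                       tr(0, dur, b20[1] + diff(b20) * 0.45, b20[2])),
    "MFV_harm" = list(tr(0, dur, b20[1], b20[2])),
    "LFH" = list(tr(0, dur, b20[1], b20[1] + diff(b20) * 0.4),
                 tr(0, dur, b20[1] + diff(b20) * 0.4, b20[2])),
    # flat, noisy, MFV_NL: single slow sweep across the -20 dB band
    list(tr(0, dur, b20[1], b20[2]))
  )
  side <- list()
  if (b30[1] < b20[1]) {
    side <- c(side, list(tr(0, dur, b30[1], b20[1], level_rel_peak = -25)))
  }
  if (b30[2] > b20[2]) {
    side <- c(side, list(tr(0, dur, b20[2], b30[2], level_rel_peak = -25)))
  }
  c(main, side)
}

#' Build the packaged stimulus library
#'
#' Returns the 14 playback stimuli used throughout the pipeline: the 10
#' vocal syllables of the tabulated mouse repertoire, a 4-80 kHz broadband
#' noise burst (BBN), 70 and 80 kHz tone bursts, and a silent null stimulus
#' used to estimate background firing. Band limits and durations of the
#' vocal syllables equal the tabulated values exactly.
#'
#' @param peak_level Nominal peak level assigned to every sounded stimulus
#'   (dB SPL); playback level is chosen per presentation, so this is a
#'   default label only.
#' @return A named list of [stimulus_descriptor()] objects, class
#'   `stimulus_library`.
#' @examples
#' lib <- build_table1_library()
#' lib[["chevron"]]$band30
#' @export
build_table1_library <- function(peak_level = 60) {
  t1 <- .table1()
  vocal <- lapply(seq_len(nrow(t1)), function(i) {
    r <- t1[i, ]
    stimulus_descriptor(
      id = r$id, kind = "vocal", duration = r$duration,
      peak_level = peak_level,
      tracks = .vocal_tracks(r$id, r$duration,
                             c(r$b20lo, r$b20hi), c(r$b30lo, r$b30hi)),
      band20 = c(r$b20lo, r$b20hi), band30 = c(r$b30lo, r$b30hi),
      f_peak = r$f_peak, context = r$context
    )
  })
  names(vocal) <- t1$id
  extra <- list(
    BBN = stimulus_descriptor(
      "BBN", "bbn", duration = 100, peak_level = peak_level,
      tracks = list(frequency_track(0, 100, 4, 80)),
      band20 = c(4, 80), band30 = c(4, 80), f_peak = 20,
      context = "synthetic"
    ),
    tone_70k = stimulus_descriptor(
      "tone_70k", "tone", duration = 100, peak_level = peak_level,
      tracks = list(frequency_track(0, 100, 70, 70)),
      band20 = c(70, 70), band30 = c(70, 70), f_peak = 70,
      context = "synthetic"
    ),
    tone_80k = stimulus_descriptor(
      "tone_80k", "tone", duration = 100, peak_level = peak_level,
      tracks = list(frequency_track(0, 100, 80, 80)),
      band20 = c(80, 80), band30 = c(80, 80), f_peak = 80,
      context = "synthetic"
    ),
    null = stimulus_descriptor(
      "null", "null", duration = 100, peak_level = NA_real_,
      tracks = list(), context = "no sound"
    )
  )
  structure(c(vocal, extra), class = "stimulus_library")
}

#' Identifiers of the WAV playback set
#'
#' The 13 sounded WAV stimuli (10 vocal syllables, BBN, 70 and 80 kHz tone
#' bursts); the null stimulus is excluded.
#'
#' @param library A [build_table1_library()] result.
#' @return Character vector of stimulus ids.
#' @export
wav_stimulus_ids <- function(library = build_table1_library()) {
  ids <- vapply(library, `[[`, "", "id")
  kinds <- vapply(library, `[[`, "", "kind")
  unname(ids[kinds != "null"])
}

#' Ids of the 10 vocal syllables
#' @inheritParams wav_stimulus_ids
#' @return Character vector of the vocal stimulus ids.
#' @export
vocal_stimulus_ids <- function(library = build_table1_library()) {
  kinds <- vapply(library, `[[`, "", "kind")
  unname(vapply(library[kinds == "vocal"], `[[`, "", "id"))
}

#' Default playback and tone-mapping protocol
#'
#' Tone grid of 15 frequencies in 1/3-octave steps from 4 kHz (i.e.
#' `4 * 2^(k/3)` for k = 0..13, then a final step capped at 90 kHz so the
#' grid spans the full 4-90 kHz testing range), levels 10-80 dB
#' SPL in 10 dB steps plus a 0 dB catch level used as the within-protocol
#' background condition, 20 repetitions per condition, and WAV playback at
#' peak levels of 20, 40, 60 and 70 dB SPL at 2 presentations/s. Each WAV
#' presentation is padded with 45 ms of leading and 30 ms of trailing
#' carrier noise.
#'
#' @return A list of class `ic_protocol` with fields `tone_freqs`,
#'   `tone_labels`, `levels`, `reps`, `wav_levels`, `wav_rate`, `tone_rate`,
#'   `leading_pad`, `trailing_pad`, `tone_dur`, `tone_onset`,
#'   `tone_trial_ms`, `wav_trial_ms`.
#' @export
build_default_protocol <- function() {
  freqs <- c(4 * 2^((0:13) / 3), 90)
  structure(
    list(
      tone_freqs = freqs,
      tone_labels = c(4, 5, 6, 8, 10, 13, 16, 20, 25, 32, 40, 51, 64, 80,
                      90),
      levels = seq(0, 80, by = 10),
      reps = 20L,
      wav_levels = c(20, 40, 60, 70),
      wav_rate = 2,
      tone_rate = 5,
      leading_pad = 45,
      trailing_pad = 30,
      tone_dur = 100,
      tone_onset = 50,
      tone_trial_ms = 200,
      wav_trial_ms = 500
    ),
    class = "ic_protocol"
  )
}
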