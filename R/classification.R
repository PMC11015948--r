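#' Classify a unit's response to one stimulus
#'
#' Compares the stimulus-evoked bootstrap SDF band against the background
#' firing percentiles. A bin shows significant excitation when the lower
#' 95% CI of the SDF exceeds the 95th background percentile, and
#' significant inhibition when the upper CI falls below the 5th percentile.
#' The unit is labeled responsive when either mask contains a run of at
#' least `min_run_ms` consecutive milliseconds inside the analysis window:
#' stimulus onset to `post_window_ms` after offset (`window = "extended"`,
#' the default) or onset to offset only (`window = "stimulus"`).
#'
#' @param sdf An [bootstrap_sdf()] estimate whose time grid covers the
#'   analysis window.
#' @param bg A [background_stats()] object.
#' @param stim_onset,stim_offset Stimulus onset/offset within the trial
#'   (ms).
#' @param min_run_ms Minimum persistence of significance (ms).
#' @param post_window_ms Post-offset extension of the analysis window (ms).
#' @param window `"extended"` or `"stimulus"`.
#' @return Object of class `response_class`: `label` (one of
#'   `"excitatory"`, `"inhibitory"`, `"both"`, `"none"`), `sig_exc`,
#'   `sig_inh` (per-ms logical masks over the SDF grid), `onset_latency`
#'   (ms from stimulus onset to the first qualifying run, `NA` when
#'   unresponsive), and the window bounds used.
#' @export
classify_response <- function(sdf, bg, stim_onset, stim_offset,
                              min_run_ms = 10, post_window_ms = 45,
                              window = c("extended", "stimulus")) {
  window <- match.arg(window)
  win_end <- if (window == "extended") stim_offset + post_window_ms else
    stim_offset
  if (stim_onset < min(sdf$time_grid) || win_end > max(sdf$time_grid) + 1) {
    stop("analysis window [", stim_onset, ", ", win_end,
         "] exceeds SDF support")
  }
  sig_exc <- sdf$ci_lo > bg$bg_p95
  sig_inh <- sdf$ci_hi < bg$bg_p05
  in_win <- sdf$time_grid >= stim_onset & sdf$time_grid < win_end

  first_run <- function(mask) {
    r <- rle(mask & in_win)
    ends <- cumsum(r$lengths)
    hit <- which(r$values & r$lengths >= min_run_ms)
    if (length(hit) == 0L) return(NA_real_)
    sdf$time_grid[ends[hit[1]] - r$lengths[hit[1]] + 1L]
  }
  exc_start <- first_run(sig_exc)
  inh_start <- first_run(sig_inh)
  label <- if (!is.na(exc_start) && !is.na(inh_start)) "both"
    else if (!is.na(exc_start)) "excitatory"
    else if (!is.na(inh_start)) "inhibitory"
    else "none"
  latency <- if (label == "none") NA_real_ else
    min(exc_start, inh_start, na.rm = TRUE) - stim_onset
  structure(
    list(label = label, sig_exc = sig_exc, sig_inh = sig_inh,
         onset_latency = latency, window = c(stim_onset, win_end),
         min_run_ms = min_run_ms),
    class = "response_class"
  )
}

#' @export
print.response_class <- function(x, ...) {
  cat(sprintf("<response_class: %s%s>\n", x$label,
              if (is.na(x$onset_latency)) "" else
                sprintf(", latency %.0f ms", x$onset_latency)))
  invisible(x)
}

#' Order units for population response displays
#'
#' Builds the wide unit x stimulus table of response labels, with rows in
#' the canonical display order: units lacking a CF first (sorted by id),
#' then CF ascending, ties broken by the upper tuning limit, then id.
#'
#' @param classes Tidy tibble with columns `unit_id`, `stimulus_id`,
#'   `label` (one classification per pair).
#' @param units Tibble with `unit_id`, `cf` (NA when undefined), and
#'   optionally `bw_hi` used for the within-CF sort.
#' @return Object of class `population_response_table`: list with `table`
#'   (wide tibble, one row per unit in display order) and `unit_order`.
#' @export
build_population_table <- function(classes, units) {
  stopifnot(all(c("unit_id", "stimulus_id", "label") %in% names(classes)),
            all(c("unit_id", "cf") %in% names(units)))
  if (!"bw_hi" %in% names(units)) units$bw_hi <- NA_real_
  ord <- units[order(!is.na(units$cf),      # no-CF block first
                     units$cf, units$bw_hi, units$unit_id,
                     na.last = TRUE), ]
  wide <- tidyr::pivot_wider(classes[, c("unit_id", "stimulus_id", "label")],
                             names_from = "stimulus_id",
                             values_from = "label")
  wide <- dplyr::left_join(ord[, c("unit_id", "cf", "bw_hi")], wide,
                           by = "unit_id")
  structure(list(table = wide, unit_order = ord$unit_id),
            class = "population_response_table")
}

#' Per-stimulus responsiveness fractions
#'
#' Fraction of units responding (label other than `"none"`) to each
#' stimulus. The denominator is either the sound-responsive subset (units
#' responding to at least one stimulus in the table) or all units.
#'
#' @param pop_table A [build_population_table()] result.
#' @param denominator `"sound_responsive"` or `"all"`.
#' @return Tibble with `stimulus_id`, `n_responsive`, `n_denominator`,
#'   `fraction`.
#' @export
responsiveness_percentages <- function(pop_table,
                                       denominator = c("sound_responsive",
                                                       "all")) {
  denominator <- match.arg(denominator)
  tab <- pop_table$table
  stim_cols <- setdiff(names(tab), c("unit_id", "cf", "bw_hi"))
  if (nrow(tab) == 0L || length(stim_cols) == 0L) {
    stop("empty population table")
  }
  resp_mat <- !is.na(as.matrix(tab[stim_cols])) &
    as.matrix(tab[stim_cols]) != "none"
  denom_units <- if (denominator == "sound_responsive") {
    rowSums(resp_mat) > 0
  } else rep(TRUE, nrow(tab))
  n_resp <- unname(colSums(resp_mat[denom_units, , drop = FALSE]))
  tibble::tibble(
    stimulus_id = stim_cols,
    n_responsive = n_resp,
    n_denominator = sum(denom_units),
    fraction = n_resp / max(1L, sum(denom_units))
  )
}

#' Vocal-stimulus selectivity of one unit
#'
#' Number of the 10 vocal syllables (0-10) the unit responds to.
#'
#' @param labels Named character vector or tibble (`stimulus_id`, `label`)
#'   of the unit's response labels for exactly the 10 vocal stimuli.
#' @param vocal_ids The expected stimulus set.
#' @return Integer in 0..10.
#' @export
selectivity <- function(labels, vocal_ids = vocal_stimulus_ids()) {
  if (is.data.frame(labels)) {
    labels <- setNames(labels$label, labels$stimulus_id)
  }
  if (!setequal(names(labels), vocal_ids) ||
      length(labels) != length(vocal_ids)) {
    stop("selectivity requires labels for exactly the 10 vocal stimuli")
  }
  sum(labels != "none")
}
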