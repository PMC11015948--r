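#' Tuning - call-spectrum overlap
#'
#' Signed difference (kHz) between the upper limit of a unit's frequency
#' tuning at the playback level and the lower -30 dB spectral limit of a
#' call. Positive values measure spectral congruence; negative values the
#' distance between the unit's tuning and the call's spectrum.
#'
#' @param bw_hi Upper tuning limit(s), kHz.
#' @param call_lo30 Call lower spectral limit(s) at -30 dB, kHz.
#' @return `bw_hi - call_lo30` (kHz), vectorized.
#' @export
compute_overlap <- function(bw_hi, call_lo30) {
  bw_hi - call_lo30
}

#' Overlap records for a population
#'
#' Joins per-unit upper tuning limits with per-call spectral limits and
#' response labels into the long table behind the overlap histograms.
#' Units without a defined bandwidth are skipped with a warning.
#'
#' @param tuning Tibble with `unit_id`, `bw_hi`.
#' @param classes Tidy tibble `unit_id`, `stimulus_id`, `label` at one
#'   level.
#' @param library Stimulus library; only vocal stimuli are scored.
#' @param level Playback level the records refer to (annotation only).
#' @return Tibble `unit_id`, `stimulus_id`, `level`, `overlap`,
#'   `responsive`.
#' @export
overlap_records <- function(tuning, classes, library = build_table1_library(),
                            level = 60) {
  vocal <- vocal_stimulus_ids(library)
  lo30 <- vapply(library[vocal], function(s) s$band30[1], 0)
  cls <- classes[classes$stimulus_id %in% vocal, ]
  out <- dplyr::left_join(cls, tuning[, c("unit_id", "bw_hi")],
                          by = "unit_id")
  n_bad <- sum(is.na(out$bw_hi))
  if (n_bad > 0L) {
    warning(n_bad, " record(s) skipped: undefined tuning bandwidth")
    out <- out[!is.na(out$bw_hi), ]
  }
  tibble::tibble(
    unit_id = out$unit_id,
    stimulus_id = out$stimulus_id,
    level = level,
    overlap = unname(compute_overlap(out$bw_hi, lo30[out$stimulus_id])),
    responsive = out$label != "none"
  )
}

#' Histogram of overlap for responsive and nonresponsive units
#'
#' Bins the overlap values of one stimulus into `bin_width`-kHz bins
#' aligned at 0 and counts responsive and nonresponsive units per bin.
#'
#' @param records Overlap records sharing one stimulus and level.
#' @param bin_width Bin width (kHz), default 10.
#' @return Tibble `bin_lo`, `bin_hi`, `n_responsive`, `n_nonresponsive`,
#'   `fraction_responsive`.
#' @export
overlap_response_histogram <- function(records, bin_width = 10) {
  if (nrow(records) == 0L) stop("no overlap records")
  lo <- floor(min(records$overlap) / bin_width) * bin_width
  hi <- ceiling(max(records$overlap) / bin_width) * bin_width
  if (hi == lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  bin <- cut(records$overlap, breaks, right = FALSE,
             include.lowest = TRUE)
  n_resp <- tapply(records$responsive, bin, sum, default = 0L)
  n_tot <- tapply(records$responsive, bin, length, default = 0L)
  tibble::tibble(
    bin_lo = breaks[-length(breaks)],
    bin_hi = breaks[-1],
    n_responsive = as.integer(n_resp),
    n_nonresponsive = as.integer(n_tot - n_resp),
    fraction_responsive = ifelse(n_tot > 0, n_resp / n_tot, NA_real_)
  )
}

#' Spectral category of a vocal stimulus
#'
#' Category 1: spectral content below 20 kHz (-30 dB lower limit at or
#' below 20 kHz; the low-frequency harmonic, mid-frequency and noisy
#' calls). Category 2: stepped USVs with energy above 20 kHz extending
#' above 80 kHz. Category 3: USVs with energy exclusively above 60 kHz.
#'
#' @param stimulus A [stimulus_descriptor()] of kind `"vocal"`.
#' @return Integer category 1, 2 or 3.
#' @export
assign_category <- function(stimulus) {
  if (stimulus$kind != "vocal") {
    stop("categories are defined for vocal stimuli only")
  }
  lo <- stimulus$band30[1]
  if (lo <= 20) 1L else if (lo > 60) 3L else 2L
}

#' Responsiveness by vocal category and unit group
#'
#' Long-format counts and fractions of responsive units per vocal category,
#' optionally split by subdivision or sex. Border-subdivision units are
#' excluded from subdivision groupings. A unit counts as responding to a
#' category when it responds to at least one call in it; `n_responses` (the
#' per-unit count of calls responded to, summed) is exported alongside so
#' the table can feed an external Poisson mixed-model fit.
#'
#' @param classes Tidy tibble `unit_id`, `stimulus_id`, `label`.
#' @param units Tibble with `unit_id` and grouping labels (`subdivision`,
#'   `sex`).
#' @param library Stimulus library.
#' @param groupby `"none"`, `"subdivision"` or `"sex"`.
#' @return Tibble `group`, `category`, `n_units`, `n_responsive`,
#'   `n_responses`, `fraction`.
#' @export
category_summary <- function(classes, units,
                             library = build_table1_library(),
                             groupby = c("none", "subdivision", "sex")) {
  groupby <- match.arg(groupby)
  vocal <- vocal_stimulus_ids(library)
  cat_of <- vapply(library[vocal], assign_category, 0L)
  df <- classes[classes$stimulus_id %in% vocal, ]
  df$category <- unname(cat_of[df$stimulus_id])
  df <- dplyr::left_join(df, units, by = "unit_id")
  if (groupby == "subdivision") {
    if (!"subdivision" %in% names(df)) stop("units lack subdivision labels")
    bad <- setdiff(unique(df$subdivision),
                   c("CIC", "ECIC", "DCIC", "border"))
    if (length(bad)) stop("unknown subdivision label(s): ",
                          paste(bad, collapse = ", "))
    df <- df[df$subdivision != "border", ]
    df$group <- df$subdivision
  } else if (groupby == "sex") {
    if (!"sex" %in% names(df)) stop("units lack sex labels")
    bad <- setdiff(unique(df$sex), c("F", "M"))
    if (length(bad)) stop("unknown sex label(s): ",
                          paste(bad, collapse = ", "))
    df$group <- df$sex
  } else {
    df$group <- "all"
  }
  df |>
    dplyr::group_by(.data$group, .data$category, .data$unit_id) |>
    dplyr::summarise(resp = any(.data$label != "none"),
                     n_calls = sum(.data$label != "none"),
                     .groups = "drop") |>
    dplyr::group_by(.data$group, .data$category) |>
    dplyr::summarise(n_units = dplyr::n(),
                     n_responsive = sum(.data$resp),
                     n_responses = sum(.data$n_calls),
                     fraction = mean(.data$resp),
                     .groups = "drop")
}
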