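#' Write / read a tidy spike table
#'
#' Spike tables are UTF-8 CSV with a header and columns `unit_id`,
#' `stimulus_id`, `level_db`, `trial_index`, `spike_time_ms`. A trial with
#' no spikes is represented by a single row whose `spike_time_ms` is empty
#' (NA), so the trial count round-trips losslessly.
#'
#' @param spikes Tibble in the tidy spike format (e.g.
#'   `simulate_experiment()$spikes`).
#' @param path CSV path.
#' @return `write_spike_table()` returns `path` invisibly;
#'   `read_spike_table()` returns the validated tibble.
#' @export
write_spike_table <- function(spikes, path) {
  need <- c("unit_id", "stimulus_id", "level_db", "trial_index",
            "spike_time_ms")
  stopifnot(all(need %in% names(spikes)))
  write.csv(spikes[need], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_spike_table
#' @param max_time_ms Optional trial duration; spike times at or beyond it
#'   are rejected.
#' @export
read_spike_table <- function(path, max_time_ms = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = "character")
  need <- c("unit_id", "stimulus_id", "level_db", "trial_index",
            "spike_time_ms")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("spike table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  t_raw <- df$spike_time_ms
  df$spike_time_ms <- suppressWarnings(as.numeric(t_raw))
  bad_parse <- which(is.na(df$spike_time_ms) & !is.na(t_raw) &
                       trimws(t_raw) != "")
  if (length(bad_parse)) {
    stop("non-numeric spike time(s) at row(s): ",
         paste(head(bad_parse, 5), collapse = ", "))
  }
  df$level_db <- suppressWarnings(as.numeric(df$level_db))
  df$trial_index <- suppressWarnings(as.integer(df$trial_index))
  bad_num <- which(!is.na(df$spike_time_ms) & df$spike_time_ms < 0)
  if (length(bad_num)) {
    stop("negative spike time(s) at row(s): ",
         paste(head(bad_num, 5), collapse = ", "))
  }
  if (!is.null(max_time_ms)) {
    bad <- which(!is.na(df$spike_time_ms) & df$spike_time_ms >= max_time_ms)
    if (length(bad)) {
      stop("spike time(s) beyond trial duration at row(s): ",
           paste(head(bad, 5), collapse = ", "))
    }
  }
  if (anyNA(df$level_db) || anyNA(df$trial_index)) {
    bad <- which(is.na(df$level_db) | is.na(df$trial_index))
    stop("non-numeric level_db / trial_index at row(s): ",
         paste(head(bad, 5), collapse = ", "))
  }
  tibble::as_tibble(df)
}

#' Default run configuration
#'
#' All tunable analysis constants with their standard values: 1 ms SDF
#' bins, 10 ms Gaussian kernel SD, 1000 SDF and bandwidth bootstrap
#' replicates, 95% CIs, 10 ms persistence within the extended analysis
#' window (onset to 45 ms past offset), 100-point tuning-curve
#' interpolation, CF criterion of background + 2 SE with a 0.5-spike
#' floor, 10 kHz overlap histogram bins, and a false discovery rate of
#' 0.05.
#'
#' @param ... Named overrides of any default.
#' @return Named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    kernel_sd = 10,
    n_boot_sdf = 1000L,
    n_boot_bw = 1000L,
    alpha = 0.05,
    min_run_ms = 10,
    post_window_ms = 45,
    window = "extended",
    cf_n_se = 3,
    cf_min_count = 0.5,
    n_interp = 100L,
    overlap_bin_khz = 10,
    fdr_q = 0.05,
    bw_level = 60,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration
#'
#' Configurations are stored as flat key-value JSON or YAML (chosen by
#' file extension); unknown keys are rejected.
#'
#' @param config A [default_config()] list.
#' @param path File ending in `.json`, `.yaml` or `.yml`.
#' @return `read_config()` returns a `run_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  } else if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else stop("config path must end in .json, .yaml or .yml")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else stop("config path must end in .json, .yaml or .yml")
  do.call(default_config, x)
}

#' Serialize / load a stimulus library
#'
#' JSON schema: an array of stimulus objects, each with `id`, `kind`,
#' `duration`, `peak_level`, `f_peak`, `context`, `band20`, `band30`
#' (2-element arrays or null) and `tracks` (array of objects with
#' `t_start`, `t_end`, `f_start`, `f_end`, `level_rel_peak`).
#'
#' @param library A `stimulus_library`.
#' @param path JSON path.
#' @return `read_stimulus_library()` returns a `stimulus_library`.
#' @export
write_stimulus_library <- function(library, path) {
  as_plain <- function(s) {
    list(id = s$id, kind = s$kind, duration = s$duration,
         peak_level = s$peak_level, f_peak = s$f_peak, context = s$context,
         band20 = s$band20, band30 = s$band30,
         tracks = lapply(s$tracks, unclass))
  }
  jsonlite::write_json(lapply(unname(library), as_plain), path,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_stimulus_library
#' @export
read_stimulus_library <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  stims <- lapply(raw, function(s) {
    num2 <- function(v) {
      if (is.null(v)) return(c(NA_real_, NA_real_))
      out <- vapply(v, function(z) if (is.null(z)) NA_real_ else
        as.numeric(z), 0)
      if (length(out) != 2) c(NA_real_, NA_real_) else out
    }
    stimulus_descriptor(
      id = s$id, kind = s$kind, duration = s$duration,
      peak_level = if (is.null(s$peak_level)) NA_real_ else s$peak_level,
      tracks = lapply(s$tracks, function(tr) {
        frequency_track(tr$t_start, tr$t_end, tr$f_start, tr$f_end,
                        tr$level_rel_peak)
      }),
      band20 = num2(s$band20), band30 = num2(s$band30),
      f_peak = if (is.null(s$f_peak)) NA_real_ else s$f_peak,
      context = if (is.null(s$context)) NA_character_ else s$context
    )
  })
  names(stims) <- vapply(stims, `[[`, "", "id")
  structure(stims, class = "stimulus_library")
}
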