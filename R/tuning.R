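#' Modified Akima (makima) interpolation
#'
#' Shape-preserving piecewise-cubic Hermite interpolation with the
#' modified-Akima derivative weights
#' `w1 = |d[i+1] - d[i]| + |d[i+1] + d[i]|/2` (and symmetrically `w2`),
#' which damp the overshoot of classic Akima near flat regions while still
#' passing exactly through every knot. This is the interpolant used to
#' build 100-point frequency tuning curves from 1/3-octave tone responses.
#'
#' @param x Strictly increasing knot positions.
#' @param y Knot values: a vector, or a matrix with one curve per row (all
#'   sharing `x`), in which case all curves are interpolated at once.
#' @param xout Query positions within `range(x)`.
#' @return Interpolated values: vector, or matrix with `nrow(y)` rows.
#' @export
makima_interp <- function(x, y, xout) {
  n <- length(x)
  stopifnot(n >= 2L, all(diff(x) > 0))
  if (any(xout < x[1] - 1e-9 | xout > x[n] + 1e-9)) {
    stop("xout outside interpolation range")
  }
  Y <- if (is.matrix(y)) y else matrix(y, nrow = 1L)
  stopifnot(ncol(Y) == n)
  h <- diff(x)
  # interval slopes, extended by quadratic extrapolation at both ends
  D <- sweep(Y[, -1L, drop = FALSE] - Y[, -n, drop = FALSE], 2L, h, "/")
  d_l1 <- 2 * D[, 1L] - D[, min(2L, n - 1L)]
  d_l2 <- 2 * d_l1 - D[, 1L]
  d_r1 <- 2 * D[, n - 1L] - D[, max(1L, n - 2L)]
  d_r2 <- 2 * d_r1 - D[, n - 1L]
  Dx <- cbind(d_l2, d_l1, D, d_r1, d_r2)     # slopes indexed i-2 .. i+1
  # derivative at knot i uses slopes (i-2, i-1, i, i+1) in Dx columns
  # (i, i+1, i+2, i+3)
  Tm <- matrix(0, nrow(Y), n)
  for (i in seq_len(n)) {
    dm2 <- Dx[, i]; dm1 <- Dx[, i + 1L]
    dp0 <- Dx[, i + 2L]; dp1 <- Dx[, i + 3L]
    w1 <- abs(dp1 - dp0) + abs(dp1 + dp0) / 2
    w2 <- abs(dm1 - dm2) + abs(dm1 + dm2) / 2
    wsum <- w1 + w2
    t_i <- (w1 * dm1 + w2 * dp0) / ifelse(wsum == 0, 1, wsum)
    Tm[, i] <- ifelse(wsum == 0, 0, t_i)
  }
  # cubic Hermite evaluation
  iv <- pmin(pmax(findInterval(xout, x), 1L), n - 1L)
  s <- (xout - x[iv]) / h[iv]
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  res <- Y[, iv, drop = FALSE] * rep(h00, each = nrow(Y)) +
    Tm[, iv, drop = FALSE] * rep(h10 * h[iv], each = nrow(Y)) +
    Y[, iv + 1L, drop = FALSE] * rep(h01, each = nrow(Y)) +
    Tm[, iv + 1L, drop = FALSE] * rep(h11 * h[iv], each = nrow(Y))
  if (is.matrix(y)) res else drop(res)
}

#' Build a frequency response area from tone trials
#'
#' Mean spike count per tone frequency x level condition, counted within
#' the 100 ms tone window. Raw per-trial counts are retained for the
#' bandwidth bootstrap.
#'
#' @param tone_sets List of `trial_spike_set`s, one per frequency x level
#'   condition (tone stimulus ids of the form `tone_<kHz>`).
#' @param protocol Protocol describing the expected grid.
#' @param count_onset,count_dur Spike-counting window within the trial
#'   (ms); defaults to the protocol's tone onset and duration.
#' @return Object of class `fra_result`: `freq_grid`, `level_grid`,
#'   `mean_counts` (freq x level), `counts` (freq x level x rep array),
#'   `cf`, `threshold` (both `NA` until [estimate_cf()]).
#' @export
build_fra <- function(tone_sets, protocol = build_default_protocol(),
                      count_onset = protocol$tone_onset,
                      count_dur = protocol$tone_dur) {
  freqs <- protocol$tone_freqs
  levels <- protocol$levels
  reps <- protocol$reps
  counts <- array(NA_real_, c(length(freqs), length(levels), reps),
                  dimnames = list(sprintf("%0.2f", freqs), levels, NULL))
  labels <- sprintf("%0.2f", freqs)
  for (set in tone_sets) {
    fi <- which(labels == sub("tone_", "", set$stimulus_id))
    li <- which(levels == set$level)
    if (length(fi) != 1L || length(li) != 1L) next
    counts[fi, li, ] <- vapply(
      set$trials,
      function(s) sum(s >= count_onset & s < count_onset + count_dur),
      0
    )
  }
  missing <- which(is.na(counts[, , 1]), arr.ind = TRUE)
  if (nrow(missing) > 0L) {
    stop("missing FRA cells: ",
         paste(sprintf("%.2f kHz @ %s dB", freqs[missing[, 1]],
                       levels[missing[, 2]]), collapse = ", "))
  }
  structure(
    list(freq_grid = freqs, level_grid = levels,
         mean_counts = apply(counts, c(1, 2), mean),
         counts = counts, cf = NA_real_, threshold = NA_real_),
    class = "fra_result"
  )
}

#' Estimate characteristic frequency and threshold from an FRA
#'
#' Automated stand-in for by-eye selection of the tip of the frequency
#' response area: a cell "elicits firing" when its mean count exceeds the
#' background mean count by at least `n_se` standard errors of that mean
#' and an absolute floor of `min_count` spikes. Background counts come
#' from the 0 dB catch level (all frequencies pooled). Because ~126 cells
#' are screened per unit, a qualifying cell must additionally be supported
#' by a qualifying neighbor (same frequency one level up, or adjacent
#' frequency at the same level) -- the FRA tip is contiguous with the
#' response area, and this suppresses isolated noise cells. The threshold
#' is the lowest sounded level with a supported qualifying cell; the CF is
#' the qualifying frequency there, ties broken by the higher count and
#' then the lower frequency. Units with no qualifying cell at any level
#' have no CF.
#'
#' @param fra An [build_fra()] result (its grid must include a 0 dB level).
#' @param n_se Multiplier on the background SE (default 3).
#' @param min_count Absolute floor (spikes per stimulus, default 0.5).
#' @return The `fra_result` with `cf` and `threshold` filled in (`NA` when
#'   no CF is found).
#' @export
estimate_cf <- function(fra, n_se = 3, min_count = 0.5) {
  li0 <- which(fra$level_grid == 0)
  if (length(li0) != 1L) stop("FRA grid lacks a 0 dB background level")
  bg_counts <- as.vector(fra$counts[, li0, ])
  n_cell <- dim(fra$counts)[3]           # trials behind each cell mean
  crit <- max(mean(bg_counts) + n_se * sd(bg_counts) / sqrt(n_cell),
              min_count)
  M <- fra$mean_counts
  hot <- M > crit
  nf <- nrow(M)
  nl <- ncol(M)
  # a lone hot cell in a 126-cell grid is usually noise; the FRA tip is
  # contiguous with the response area, so require support from the cell one
  # level up at the same frequency or an adjacent frequency at the same level
  supported <- hot
  for (fi in seq_len(nf)) {
    for (li in seq_len(nl)) {
      if (!hot[fi, li]) next
      nb <- c(if (li < nl) hot[fi, li + 1L],
              if (fi > 1L) hot[fi - 1L, li],
              if (fi < nf) hot[fi + 1L, li])
      supported[fi, li] <- any(nb)
    }
  }
  sounded <- which(fra$level_grid > 0)
  for (li in sounded) {                  # lowest level first
    qual <- which(supported[, li])
    if (length(qual) > 0L) {
      best <- qual[order(-M[qual, li], fra$freq_grid[qual])][1]
      fra$cf <- fra$freq_grid[best]
      fra$threshold <- fra$level_grid[li]
      return(fra)
    }
  }
  fra
}

#' Bootstrap frequency tuning bandwidth at one level
#'
#' The tuning-bandwidth procedure: for each of `n_boot` replicates, draw
#' 20 spike counts with replacement at every tested frequency at the
#' requested level, fit a modified-Akima interpolant through the resampled
#' means on a 100-point grid (log2-spaced over the tone grid), and form
#' the bootstrap mean tuning curve and percentile CIs from the replicate
#' curves. The unit's background count is bootstrapped from the 0 dB catch
#' data; the lower (upper) bandwidth limit is the lowest (highest) grid
#' frequency at which the lower CI of the tuning curve exceeds the upper
#' CI of the background mean.
#'
#' @param fra An [build_fra()] result.
#' @param level Level (dB SPL) at which to measure bandwidth (60 or 70).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param alpha CI level is `1 - alpha`.
#' @param n_interp Interpolation grid size (default 100).
#' @param seed Optional seed.
#' @return Object of class `bandwidth_estimate`: `level`, `interp_grid`
#'   (kHz), `ftc_mean`, `ftc_ci_lo`, `ftc_ci_hi` (spikes per stimulus),
#'   `bg_mean`, `bg_ci` (lo, hi), `bw_lo`, `bw_hi` (kHz, `NA` when no grid
#'   point separates from background).
#' @export
bootstrap_bandwidth <- function(fra, level = 60, n_boot = 1000L,
                                alpha = 0.05, n_interp = 100L, seed = NULL) {
  li <- which(fra$level_grid == level)
  if (length(li) != 1L) stop("level ", level, " not in FRA grid")
  li0 <- which(fra$level_grid == 0)
  if (length(li0) != 1L) stop("no background level (0 dB stimulus data)")
  if (!is.null(seed)) withr::local_seed(seed)

  cnt <- fra$counts[, li, ]                     # freq x rep
  nf <- nrow(cnt)
  reps <- ncol(cnt)
  # resampled mean count per frequency, n_boot x nf
  R <- matrix(0, n_boot, nf)
  for (fi in seq_len(nf)) {
    draws <- matrix(sample(cnt[fi, ], n_boot * reps, replace = TRUE),
                    n_boot, reps)
    R[, fi] <- rowMeans(draws)
  }
  lx <- log2(fra$freq_grid)
  grid_l <- seq(lx[1], lx[nf], length.out = n_interp)
  curves <- makima_interp(lx, R, grid_l)        # n_boot x n_interp
  ftc_mean <- colMeans(curves)
  qs <- apply(curves, 2, quantile, probs = c(alpha / 2, 1 - alpha / 2),
              names = FALSE)

  # background mean bootstrapped from the pooled 0 dB counts, with each
  # replicate drawing the same number of counts as one FTC frequency so the
  # two CIs being compared carry matched sampling noise
  bg_counts <- as.vector(fra$counts[, li0, ])
  bg_means <- rowMeans(matrix(sample(bg_counts, n_boot * reps,
                                     replace = TRUE), n_boot, reps))
  bg_ci <- quantile(bg_means, c(alpha / 2, 1 - alpha / 2), names = FALSE)

  above <- which(qs[1, ] > bg_ci[2])
  grid_f <- 2^grid_l
  structure(
    list(level = level, interp_grid = grid_f,
         ftc_mean = ftc_mean, ftc_ci_lo = qs[1, ], ftc_ci_hi = qs[2, ],
         bg_mean = mean(bg_means), bg_ci = bg_ci,
         bw_lo = if (length(above)) grid_f[min(above)] else NA_real_,
         bw_hi = if (length(above)) grid_f[max(above)] else NA_real_,
         n_boot = n_boot),
    class = "bandwidth_estimate"
  )
}

#' @export
print.bandwidth_estimate <- function(x, ...) {
  bw <- if (is.na(x$bw_lo)) "undefined" else
    sprintf("%.1f-%.1f kHz", x$bw_lo, x$bw_hi)
  cat(sprintf("<bandwidth_estimate @ %g dB: %s>\n", x$level, bw))
  invisible(x)
}

#' Assign a CF to an octave-wide frequency band
#'
#' Bands are octave-wide and centered at 10, 20 and 40 kHz (i.e.
#' `[b/sqrt(2), b*sqrt(2))`); CFs outside all three get `"other"`.
#'
#' @param cf Characteristic frequency (kHz); vectorized.
#' @return Character vector: `"10"`, `"20"`, `"40"` or `"other"`.
#' @export
assign_cf_band <- function(cf) {
  out <- rep("other", length(cf))
  for (b in c(10, 20, 40)) {
    out[cf >= b / sqrt(2) & cf < b * sqrt(2)] <- as.character(b)
  }
  out[is.na(cf)] <- NA_character_
  out
}
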