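#' Chi-square comparison of two binned CF distributions
#'
#' Compares two CF histograms over shared bins. The default is the 2 x k
#' homogeneity form of the Pearson chi-square; a goodness-of-fit form
#' (testing `group_b` against the proportions of `group_a`) is also
#' available. Adjacent bins are pooled, starting from the low-frequency
#' end, until every expected count reaches `pool_min`.
#'
#' @param group_a,group_b Integer histogram counts over identical bins.
#' @param pool_min Minimum expected count per cell (default 5).
#' @param form `"homogeneity"` (default) or `"gof"`.
#' @return Object of class `chi_square_result`: `statistic`, `df`,
#'   `p_value`, `pooled_a`, `pooled_b`, `n_bins` (after pooling).
#' @export
chi_square_cf <- function(group_a, group_b, pool_min = 5,
                          form = c("homogeneity", "gof")) {
  form <- match.arg(form)
  if (length(group_a) != length(group_b)) stop("histograms must share bins")
  if (sum(group_a) == 0 || sum(group_b) == 0) {
    stop("a group has no observations")
  }
  a <- as.numeric(group_a)
  b <- as.numeric(group_b)

  expected <- function(a, b) {
    tot <- a + b
    N <- sum(tot)
    rbind(tot * sum(a) / N, tot * sum(b) / N)
  }
  # pool adjacent bins (low end first) until all expected counts >= pool_min
  repeat {
    if (length(a) < 2L) stop("pooling left fewer than 2 bins")
    E <- expected(a, b)
    low <- which(apply(E, 2, min) < pool_min)
    if (length(low) == 0L) break
    i <- low[1]
    j <- if (i == length(a)) i - 1L else i + 1L
    k <- min(i, j)
    a <- c(a[seq_len(k - 1)], a[k] + a[k + 1],
           if (k + 2 <= length(a)) a[(k + 2):length(a)])
    b <- c(b[seq_len(k - 1)], b[k] + b[k + 1],
           if (k + 2 <= length(b)) b[(k + 2):length(b)])
  }

  if (form == "homogeneity") {
    O <- rbind(a, b)
    E <- expected(a, b)
    stat <- sum((O - E)^2 / E)
    df <- length(a) - 1L
  } else {
    p <- a / sum(a)
    if (any(p == 0)) stop("gof form requires non-zero reference bins")
    E <- sum(b) * p
    stat <- sum((b - E)^2 / E)
    df <- length(b) - 1L
  }
  structure(
    list(statistic = stat, df = df,
         p_value = pchisq(stat, df, lower.tail = FALSE),
         pooled_a = a, pooled_b = b, n_bins = length(a), form = form),
    class = "chi_square_result"
  )
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("<chi-square (%s): X2(%d) = %.2f, p = %.3g>\n",
              x$form, x$df, x$statistic, x$p_value))
  invisible(x)
}

#' Kruskal-Wallis test on bandwidth limits
#'
#' Rank-based comparison of two or more independent samples (e.g. upper
#' tuning limits across CF bands or subdivisions), with tie correction and
#' the chi-square approximation for the p-value. Computation is delegated
#' to [stats::kruskal.test()].
#'
#' @param groups List of numeric vectors, each with >= 2 observations.
#' @return List with `H`, `df`, `p_value`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least 2 groups")
  }
  if (any(lengths(groups) < 2L)) {
    stop("each group needs at least 2 observations")
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep.int(seq_along(groups), lengths(groups)))
  kt <- kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, n = length(x))
}

#' Benjamini-Hochberg step-up procedure
#'
#' Orders the m raw p-values from smallest to largest, assigns each the
#' critical value `(i/m) * q`, and rejects hypotheses 1..k where k is the
#' largest rank whose p-value does not exceed its critical value (the
#' step-up rule controlling the false discovery rate at level `q`).
#'
#' @param p_values Raw p-values in \[0, 1\].
#' @param q Target false discovery rate (default 0.05).
#' @return Object of class `bh_result`: `p_sorted`, `critical` (per rank),
#'   `reject` (logical, in the order of the input), `k` (number of
#'   rejections), `q`.
#' @export
benjamini_hochberg <- function(p_values, q = 0.05) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  ord <- order(p_values)
  crit <- seq_len(m) / m * q
  ok <- which(p_values[ord] <= crit)
  k <- if (length(ok)) max(ok) else 0L
  reject <- logical(m)
  if (k > 0L) reject[ord[seq_len(k)]] <- TRUE
  structure(
    list(p_sorted = p_values[ord], critical = crit, reject = reject,
         k = k, q = q),
    class = "bh_result"
  )
}

#' @export
print.bh_result <- function(x, ...) {
  cat(sprintf("<benjamini_hochberg: %d of %d rejected at q = %g>\n",
              x$k, length(x$reject), x$q))
  invisible(x)
}

#' Empirical false discovery rate of the step-up rule
#'
#' Simulation used to calibrate the multiple-testing correction: each
#' replicate draws `m0` null p-values from Uniform(0,1) and `m1`
#' alternative p-values from Beta(`beta_a`, `beta_b`), applies
#' [benjamini_hochberg()] at level `q`, and records the false discovery
#' proportion `false rejections / max(1, rejections)`. The mean over
#' replicates estimates the FDR, which the procedure controls at
#' `q * m0 / (m0 + m1)` under independence.
#'
#' @param n_rep Number of replicates.
#' @param m0,m1 Null and alternative test counts per replicate.
#' @param beta_a,beta_b Beta parameters of the alternative p-values.
#' @param q FDR level.
#' @param seed Optional seed.
#' @return List with `fdr` (mean false discovery proportion), `power`
#'   (mean fraction of alternatives rejected), `n_rep`.
#' @export
simulate_bh_fdr <- function(n_rep = 10000L, m0 = 10L, m1 = 10L,
                            beta_a = 0.1, beta_b = 1, q = 0.05,
                            seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  fdp <- numeric(n_rep)
  pow <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    p <- c(runif(m0), rbeta(m1, beta_a, beta_b))
    res <- benjamini_hochberg(p, q)
    n_false <- sum(res$reject[seq_len(m0)])
    fdp[r] <- n_false / max(1L, res$k)
    pow[r] <- sum(res$reject[m0 + seq_len(m1)]) / m1
  }
  list(fdr = mean(fdp), power = mean(pow), n_rep = n_rep)
}
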