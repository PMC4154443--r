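#' Coefficient of variation
#'
#' `sd / mean`, with the sample-SD (n-1) convention assumed for `sd`
#' throughout the package.
#'
#' @param mean Mean (must be positive).
#' @param sd Standard deviation (non-negative).
#' @return CV, dimensionless.
#' @export
#' @examples
#' cv(11.8, 3.3)  # ~0.28: cell-sampling precision
#' cv(75.6, 3)    # ~0.04: ribbon-sampling precision
cv <- function(mean, sd) {
  if (any(mean <= 0)) abort("`mean` must be positive")
  if (any(sd < 0)) abort("`sd` must be non-negative")
  sd / mean
}

#' Precision fold-ratio of two CVs
#'
#' How many times more precise one sampling process is than another, as the
#' ratio of their CVs; reported both exactly and rounded to the nearest
#' integer fold.
#'
#' @param cv_coarse CV of the less precise process (numerator).
#' @param cv_fine CV of the more precise process (denominator, > 0).
#' @return List with `ratio` and integer `fold`.
#' @export
#' @examples
#' precision_ratio(0.28, 0.04)  # 7-fold
precision_ratio <- function(cv_coarse, cv_fine) {
  if (cv_fine <= 0) abort("`cv_fine` must be positive")
  r <- cv_coarse / cv_fine
  list(ratio = r, fold = as.integer(round(r)))
}

# CV after appending one value `x` to a sample known only by (n, mean, sd),
# sample-SD convention
cv_with_appended <- function(n, mean, sd, x) {
  new_mean <- (n * mean + x) / (n + 1)
  ss <- (n - 1) * sd^2 + n * (mean - new_mean)^2 + (x - new_mean)^2
  new_sd <- sqrt(ss / n)  # (n+1) - 1 degrees of freedom
  new_sd / new_mean
}

#' Outlier size needed to degrade a CV to a target
#'
#' Given a sample summarised by (n, mean, sample SD), finds the smallest
#' integer `k` such that appending one value `mean + k * sd` raises the
#' (n+1)-sample CV (sample-SD convention) to at least `target_cv`. Used for
#' the hypothetical-sixth-cell argument: how aberrant would one additional
#' cell's synapse count have to be for synaptic sampling to look as noisy as
#' cell sampling?
#'
#' @param n Sample size (>= 2).
#' @param mean Sample mean (> 0).
#' @param sd Sample SD (>= 0).
#' @param target_cv Target CV.
#' @param k_max Search limit.
#' @return List with `k`, the CV reached at `k` (`cv_at_k`), the CV at
#'   `k - 1` (`cv_below`, the bracketing certificate), and a `note` when the
#'   target is already met at `k = 0`.
#' @export
#' @examples
#' outlier_sds_to_reach_cv(5, 75.6, 3, 0.28)$k  # 20
outlier_sds_to_reach_cv <- function(n, mean, sd, target_cv, k_max = 10000) {
  if (n < 2) abort("`n` must be at least 2")
  if (sd < 0) abort("`sd` must be non-negative")
  current <- cv(mean, sd)
  if (target_cv <= current) {
    return(list(k = 0L, cv_at_k = current, cv_below = NA_real_,
                note = "target CV does not exceed current CV"))
  }
  prev <- NA_real_
  for (k in 0:k_max) {
    val <- cv_with_appended(n, mean, sd, mean + k * sd)
    if (val >= target_cv) {
      return(list(k = as.integer(k), cv_at_k = val, cv_below = prev,
                  note = NULL))
    }
    prev <- val
  }
  abort(sprintf("target CV not reached within k_max = %d SDs", k_max))
}

#' Pooled-variance two-sample t test from summary statistics
#'
#' Homoscedastic (pooled-variance) Student's t test computed from group
#' means, sample SDs and sizes, two-tailed.
#'
#' @param m1,s1,n1 Mean, sample SD and size of group 1.
#' @param m2,s2,n2 Mean, sample SD and size of group 2.
#' @return One-row tibble: `t`, `df`, `p_value`, `pooled_sd`.
#' @export
#' @examples
#' t_from_summary(267, 95, 525, 238, 95, 172)  # p ~ 5e-4
t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) abort("both groups need n >= 2")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df)
  se <- sp * sqrt(1 / n1 + 1 / n2)
  t <- if (se == 0) 0 else (m1 - m2) / se
  tibble(t = t, df = df, p_value = 2 * pt(-abs(t), df), pooled_sd = sp)
}

#' Two-sample Kolmogorov-Smirnov test with small-sample correction
#'
#' Computes the KS statistic `D` (supremum of the ECDF difference) and the
#' asymptotic Kolmogorov p-value evaluated with Stephens' small-sample
#' correction: `lambda = (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D` with
#' effective size `ne = n * m / (n + m)`, and
#' `p = 2 * sum_k (-1)^(k-1) exp(-2 k^2 lambda^2)`.
#'
#' @param x,y Numeric samples (non-empty).
#' @return List with `D`, `p_value`, `ne` and `lambda`.
#' @export
#' @examples
#' ks_two_sample(rep(0, 200), rep(1, 7))  # D = 1, p ~ 5e-7
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty")
  n <- length(x); m <- length(y)
  pts <- sort(unique(c(x, y)))
  fx <- ecdf(x)(pts)
  fy <- ecdf(y)(pts)
  D <- max(abs(fx - fy))
  ne <- n * m / (n + m)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  # survival function of the Kolmogorov distribution; the alternating series
  # converges fast for large lambda, the theta-function form for small lambda
  if (lambda < 0.3) {
    p <- 1
  } else if (lambda < 1) {
    k <- 1:20
    cdf <- sqrt(2 * pi) / lambda *
      sum(exp(-(2 * k - 1)^2 * pi^2 / (8 * lambda^2)))
    p <- 1 - cdf
  } else {
    k <- 1:100
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  }
  p <- min(max(p, 0), 1)
  list(D = D, p_value = p, ne = ne, lambda = lambda)
}

#' Percent difference relative to a reference mean
#'
#' `100 * (m_ref - m_other) / m_ref`: by how many percent the second mean
#' falls below the reference.
#'
#' @param m_ref Reference mean (> 0).
#' @param m_other Comparison mean.
#' @return Percent difference.
#' @export
#' @examples
#' percent_difference(267, 238)  # ~11%
percent_difference <- function(m_ref, m_other) {
  if (m_ref <= 0) abort("`m_ref` must be positive")
  100 * (m_ref - m_other) / m_ref
}

#' Binned size statistics for junction diameters
#'
#' Histograms a set of per-junction Feret diameters into fixed-width bins
#' (25 nm by default), with summary statistics and the cumulative frequency
#' distribution used to compare homocellular and heterocellular coupling.
#'
#' @param diameters_nm Per-junction diameters, nm (> 0).
#' @param bin_nm Bin width, nm.
#' @param pairing Optional label for the pairing class (e.g. "AII::AII").
#' @return Object of class `gj_size_stats`: a list with `pairing`, `n`,
#'   `mean_nm`, `sd_nm`, `max_nm`, and `histogram` (tibble `bin_lo`,
#'   `bin_hi`, `count`, `cum_freq`).
#' @export
size_histogram <- function(diameters_nm, bin_nm = 25, pairing = NA_character_) {
  if (length(diameters_nm) == 0) abort("no diameters supplied")
  if (any(diameters_nm <= 0)) abort("diameters must be positive")
  idx <- floor(diameters_nm / bin_nm)
  bins <- 0:max(idx)
  count <- tabulate(idx + 1, nbins = length(bins))
  hist <- tibble(
    bin_lo = bins * bin_nm,
    bin_hi = (bins + 1) * bin_nm,
    count = count,
    cum_freq = cumsum(count) / length(diameters_nm)
  )
  structure(
    list(
      pairing = pairing,
      n = length(diameters_nm),
      mean_nm = mean(diameters_nm),
      sd_nm = if (length(diameters_nm) > 1) sd(diameters_nm) else 0,
      max_nm = max(diameters_nm),
      histogram = hist
    ),
    class = "gj_size_stats"
  )
}

#' @export
print.gj_size_stats <- function(x, ...) {
  cat(sprintf("<gj_size_stats> %s: n = %d, %.0f +/- %.0f nm, max %.0f nm\n",
              x$pairing %||% "?", x$n, x$mean_nm, x$sd_nm, x$max_nm))
  invisible(x)
}

#' Sampling-precision report from per-unit counts
#'
#' Summarises a vector of per-unit counts (e.g. rod bipolar partners per
#' AII cell, or ribbons per cell) as n, mean, sample SD and CV.
#'
#' @param counts Numeric vector of per-unit counts.
#' @param unit Label for the counted unit.
#' @return One-row tibble of class `precision_report`: `unit`, `n`, `mean`,
#'   `sd`, `cv`.
#' @export
precision_report <- function(counts, unit = "units") {
  if (length(counts) < 2) abort("need at least two counts")
  m <- mean(counts)
  s <- sd(counts)
  out <- tibble(unit = unit, n = length(counts), mean = m, sd = s,
                cv = cv(m, s))
  class(out) <- c("precision_report", class(out))
  out
}
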