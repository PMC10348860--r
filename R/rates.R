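# World-standard age-standardization of incidence/mortality rates and
# presentation smoothing. Smoothing is presentation-only: all statistics run
# on the unsmoothed series.

#' Segi world standard population
#'
#' The classical 18-group (five-year bins, 85+) world standard population used
#' to age-standardize registry incidence and mortality rates. The table is the
#' package default and is overridable wherever a standard is accepted.
#'
#' @return A `data.frame` with `age_group` and `weight` (proportions summing
#'   to 1).
#' @export
segi_world_standard <- function() {
  lab <- c(paste(seq(0, 80, 5), seq(4, 84, 5), sep = "-"), "85+")
  w <- c(12, 10, 9, 9, 8, 8, 6, 6, 6, 6, 5, 4, 4, 3, 2, 1, 0.5, 0.5) / 100
  data.frame(age_group = lab, weight = w, stringsAsFactors = FALSE)
}

#' World-standard age-standardized rate (per 100 000)
#'
#' \deqn{ASR = \sum_g w_g \frac{cases_g}{person\_years_g} \times 100\,000}
#'
#' @param rates A `data.frame` for a single year with columns `age_group`,
#'   `cases`, `person_years` (one row per age group).
#' @param standard Standard population table with `age_group` and `weight`
#'   (default [segi_world_standard()]); weights must be non-negative and sum
#'   to 1 within 1e-12. Every group with positive weight must be present in
#'   `rates`.
#' @return The age-standardized rate per 100 000 person-years.
#' @export
world_asr <- function(rates, standard = segi_world_standard()) {
  if (any(standard$weight < 0) || abs(sum(standard$weight) - 1) > 1e-12) {
    .stopf("standard weights must be non-negative and sum to 1")
  }
  if (anyDuplicated(rates$age_group)) {
    .stopf("`rates` must contain one row per age group (a single year)")
  }
  idx <- match(standard$age_group, rates$age_group)
  need <- standard$weight > 0
  if (any(need & is.na(idx))) {
    .stopf("missing age group(s) with positive weight: %s",
           paste(standard$age_group[need & is.na(idx)], collapse = ", "))
  }
  use <- which(need)
  if (any(rates$person_years[idx[use]] <= 0)) .stopf("person-years must be positive")
  sum(standard$weight[use] * rates$cases[idx[use]] / rates$person_years[idx[use]]) * 1e5
}

#' Age-standardized rate series with presentation smoothing
#'
#' Computes the world-standard ASR for every year of a rate series and a
#' cubic-smoothing-spline smoothed version for display.
#'
#' @param rate_series Output of [simulate_rate_series()] (or a compatible
#'   `data.frame` with `country`, `site`, `year`, `age_group`, `cases`,
#'   `person_years`).
#' @param standard Standard population (default [segi_world_standard()]).
#' @param lambda Optional fixed smoothing parameter passed to
#'   [smooth_series()]; default NULL (generalized cross-validation).
#' @return A `data.frame` with `country`, `site`, `year`, `asr`,
#'   `smoothed_asr`.
#' @export
asr_series <- function(rate_series, standard = segi_world_standard(),
                       lambda = NULL) {
  years <- sort(unique(rate_series$year))
  asr <- vapply(years, function(y) {
    world_asr(rate_series[rate_series$year == y, , drop = FALSE], standard)
  }, numeric(1))
  sm <- if (length(years) >= 4L) smooth_series(years, asr, lambda = lambda)$smoothed else asr
  data.frame(country = rate_series$country[1L], site = rate_series$site[1L],
             year = years, asr = asr, smoothed_asr = sm,
             stringsAsFactors = FALSE)
}

#' Cubic smoothing spline for display series
#'
#' Natural cubic smoothing spline minimizing the penalized least squares
#' criterion \eqn{\sum_i (y_i - f(x_i))^2 + \lambda \int f''(x)^2 dx}
#' (Green & Silverman formulation, `lambda` on the raw predictor scale), with
#' the smoothing parameter chosen by generalized cross-validation unless
#' fixed. For comparison, [stats::smooth.spline()]'s `lambda` equals this one
#' divided by `diff(range(years))^3` (it rescales the predictor to [0, 1]).
#'
#' @param years Numeric predictor (>= 4 distinct values required, strictly
#'   increasing after sorting; ties are an error).
#' @param values Numeric response, same length.
#' @param lambda Optional fixed smoothing parameter (> 0); NULL (default)
#'   chooses lambda by GCV.
#' @return A list with `years`, `smoothed` (fit at the input grid, original
#'   order), and `lambda` (the smoothing parameter used).
#' @export
smooth_series <- function(years, values, lambda = NULL) {
  stopifnot(length(years) == length(values))
  if (length(unique(years)) < 4L) {
    .stopf("smoothing needs at least 4 distinct years; display the raw series instead")
  }
  if (anyDuplicated(years)) .stopf("`years` must be distinct")
  o <- order(years)
  x <- as.numeric(years[o])
  y <- as.numeric(values[o])
  K <- .natural_spline_penalty(x)
  n <- length(x)
  fit_at <- function(lam) solve(diag(n) + lam * K, y)
  if (is.null(lambda)) {
    gcv <- function(loglam) {
      A <- solve(diag(n) + exp(loglam) * K)
      f <- A %*% y
      edf <- sum(diag(A))
      n * sum((y - f)^2) / (n - edf)^2
    }
    r3 <- diff(range(x))^3
    opt <- stats::optimize(gcv, interval = log(r3 * c(1e-9, 1e3)))
    lambda <- exp(opt$minimum)
  }
  f <- fit_at(lambda)
  out <- numeric(n)
  out[o] <- f
  list(years = years, smoothed = out, lambda = lambda)
}

# Penalty matrix K = Q R^-1 Q' of the natural cubic smoothing spline
# (Green & Silverman 1994, ch. 2): f' (I + lambda K)^-1 y minimizes
# penalized least squares with penalty integral of f''^2.
.natural_spline_penalty <- function(x) {
  n <- length(x)
  h <- diff(x)
  Q <- matrix(0, n, n - 2L)
  R <- matrix(0, n - 2L, n - 2L)
  for (j in 2:(n - 1L)) {
    i <- j - 1L
    Q[j - 1L, i] <- 1 / h[j - 1L]
    Q[j, i] <- -1 / h[j - 1L] - 1 / h[j]
    Q[j + 1L, i] <- 1 / h[j]
    R[i, i] <- (h[j - 1L] + h[j]) / 3
    if (i < n - 2L) {
      R[i, i + 1L] <- h[j] / 6
      R[i + 1L, i] <- h[j] / 6
    }
  }
  Q %*% solve(R, t(Q))
}
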