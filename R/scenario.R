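# Ground-truth scenarios for the synthetic registry: a known excess-hazard
# surface over (time since diagnosis, diagnosis year) with closed-form net
# survival, so downstream estimators can be validated by parameter recovery.

#' Define a ground-truth net-survival scenario
#'
#' A scenario fixes the *excess* (cancer-attributable) hazard experienced by
#' patients on top of general-population mortality. The excess hazard is
#' two-phase in time since diagnosis: a first-year level and a constant level
#' thereafter, both calibrated from target 1- and 5-year net survival as a
#' function of diagnosis year:
#' \deqn{\lambda_1(y) = -\log S_1(y), \qquad
#'       \lambda_2(y) = \{\log S_1(y) - \log S_5(y)\}/4.}
#' Net survival is then available in closed form,
#' \eqn{S(t, y) = e^{-\lambda_1(y) t}} for \eqn{t \le 1} and
#' \eqn{S_1(y) e^{-\lambda_2(y)(t-1)}} beyond, which is what parameter-recovery
#' tests compare against. Calendar trends of any shape (flat, linear,
#' piecewise-linear, logistic rise) are supplied through `s1` / `s5`; see
#' [trend_constant()] and friends.
#'
#' @param country,site Labels carried through to simulated records.
#' @param s1,s5 Functions of diagnosis year (decimal) returning target 1- and
#'   5-year net survival as proportions in (0, 1], with `s5(y) <= s1(y)`.
#' @return An object of class `scenario_truth` with elements `country`, `site`,
#'   `s1`, `s5`, `lambda1(y)`, `lambda2(y)`, `excess_hazard(t, year)` and
#'   `net_survival(t, year)`.
#' @examples
#' sc <- scenario_truth("SE", "breast",
#'                      s1 = trend_constant(0.9),
#'                      s5 = trend_constant(0.54))
#' sc$net_survival(5, 1990)  # 0.54
#' @export
scenario_truth <- function(country, site, s1, s5) {
  stopifnot(is.function(s1), is.function(s5))
  probe <- seq(1961, 2020.999, by = 0.5)
  v1 <- s1(probe); v5 <- s5(probe)
  if (any(!is.finite(v1)) || any(!is.finite(v5)) ||
      any(v1 > 1) || any(v5 <= 0) || any(v5 > v1 + 1e-12)) {
    .stopf("scenario targets must satisfy 0 < s5(y) <= s1(y) <= 1 on 1961-2021")
  }
  lambda1 <- function(y) -log(s1(y))
  lambda2 <- function(y) (log(s1(y)) - log(s5(y))) / 4
  excess_hazard <- function(t, year) {
    k <- max(length(t), length(year))
    t <- rep_len(t, k); year <- rep_len(year, k)
    ifelse(t < 1, lambda1(year), lambda2(year))
  }
  net_survival <- function(t, year) {
    k <- max(length(t), length(year))
    t <- rep_len(t, k); year <- rep_len(year, k)
    l1 <- lambda1(year); l2 <- lambda2(year)
    ifelse(t <= 1, exp(-l1 * t), exp(-l1) * exp(-l2 * (t - 1)))
  }
  structure(
    list(country = country, site = site, s1 = s1, s5 = s5,
         lambda1 = lambda1, lambda2 = lambda2,
         excess_hazard = excess_hazard, net_survival = net_survival),
    class = "scenario_truth"
  )
}

#' @export
print.scenario_truth <- function(x, ...) {
  cat(sprintf("<scenario_truth> %s / %s: S1(1971)=%.3f S5(1971)=%.3f -> S1(2020)=%.3f S5(2020)=%.3f\n",
              x$country, x$site, x$s1(1971), x$s5(1971), x$s1(2020), x$s5(2020)))
  invisible(x)
}

#' Calendar-trend builders for scenario targets
#'
#' Helpers returning functions of diagnosis year suitable as `s1` / `s5`
#' arguments of [scenario_truth()]. All values are survival *proportions*.
#'
#' * `trend_constant(level)`: flat trend.
#' * `trend_linear(y0, v0, slope)`: value `v0` at year `y0`, changing by
#'   `slope` per year (clamped to (0.001, 0.999)).
#' * `trend_piecewise(years, values)`: piecewise-linear interpolation through
#'   the given (year, value) nodes, constant beyond the end nodes.
#' * `trend_logistic(lower, upper, midpoint, scale)`: smooth logistic rise
#'   from `lower` to `upper`, centred at `midpoint` with time scale `scale`
#'   years.
#'
#' @param level,v0,slope,lower,upper,midpoint,scale Numeric scalars.
#' @param y0 Reference year for `trend_linear`.
#' @param years,values Nodes for `trend_piecewise`.
#' @return A function of diagnosis year.
#' @export
trend_constant <- function(level) {
  force(level)
  function(y) rep_len(level, length(y))
}

#' @rdname trend_constant
#' @export
trend_linear <- function(y0, v0, slope) {
  force(y0); force(v0); force(slope)
  function(y) .clamp(v0 + slope * (y - y0), 0.001, 0.999)
}

#' @rdname trend_constant
#' @export
trend_piecewise <- function(years, values) {
  stopifnot(length(years) == length(values), length(years) >= 2)
  f <- stats::approxfun(years, values, rule = 2)
  function(y) f(y)
}

#' @rdname trend_constant
#' @export
trend_logistic <- function(lower, upper, midpoint, scale = 8) {
  force(lower); force(upper); force(midpoint); force(scale)
  function(y) lower + (upper - lower) * stats::plogis((y - midpoint) / scale)
}

#' Default synthetic-registry scenarios
#'
#' One scenario per (country, site) for four Nordic-style countries and five
#' female cancer sites, chosen to reproduce the qualitative trend shapes seen
#' in long-run registry series: a steady rise (breast), a rise that levels off
#' (endometrial), a low start with a steepening, piecewise rise (ovarian), an
#' upward-bending rise (cervical) and an essentially flat trend (vulvar).
#' Country differences are small logit-scale offsets. Levels are synthetic:
#' they emulate shapes, not any national estimate.
#'
#' @param countries Country labels (default `c("DK", "FI", "NO", "SE")`).
#' @param sites Site labels (default the five female cancer sites).
#' @return Named list (`"<country>.<site>"`) of [scenario_truth()] objects.
#' @export
default_scenarios <- function(countries = c("DK", "FI", "NO", "SE"),
                              sites = c("breast", "endometrial", "ovarian",
                                        "cervical", "vulvar")) {
  base <- list(
    breast = list(
      s5 = trend_piecewise(c(1961, 1971, 2000, 2020), c(0.58, 0.60, 0.72, 0.90)),
      s1 = trend_logistic(0.85, 0.96, 1995, 10)
    ),
    endometrial = list(
      s5 = trend_logistic(0.68, 0.85, 1990, 8),
      s1 = trend_logistic(0.87, 0.95, 1990, 8)
    ),
    ovarian = list(
      s5 = trend_piecewise(c(1961, 1971, 2000, 2020), c(0.24, 0.25, 0.38, 0.52)),
      s1 = trend_piecewise(c(1961, 1971, 2020), c(0.49, 0.50, 0.82))
    ),
    cervical = list(
      s5 = trend_logistic(0.59, 0.76, 2005, 9),
      s1 = trend_logistic(0.84, 0.91, 2000, 10)
    ),
    vulvar = list(
      s5 = trend_constant(0.70),
      s1 = trend_constant(0.85)
    )
  )
  offsets <- c(DK = -0.10, FI = -0.15, NO = 0.05, SE = 0.10)
  shift <- function(f, off) {
    force(f); force(off)
    function(y) stats::plogis(stats::qlogis(f(y)) + off)
  }
  out <- list()
  for (cn in countries) {
    off <- if (cn %in% names(offsets)) offsets[[cn]] else 0
    for (st in sites) {
      if (!st %in% names(base)) .stopf("no default scenario for site '%s'", st)
      out[[paste(cn, st, sep = ".")]] <-
        scenario_truth(cn, st, s1 = shift(base[[st]]$s1, off),
                       s5 = shift(base[[st]]$s5, off))
    }
  }
  out
}
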