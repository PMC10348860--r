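# Quantities derived from trend posteriors: conditional 5/1-year survival by
# draw-wise division, per-draw finite-difference derivative curves, and the
# credible-interval run rules for significant change windows (1st derivative,
# >= 5-year runs) and trend breakpoints (2nd derivative, >= 3-year runs, peak
# of the posterior-mean curvature). All interval rules are pointwise
# equal-tailed credible intervals with run-length guards as the multiplicity
# control.

#' Conditional 5/1-year survival posterior
#'
#' Divides, draw by draw and grid point by grid point, the posterior of the
#' 5-year survival curve by the posterior of the 1-year curve, yielding the
#' full posterior of the conditional probability of surviving to year 5 given
#' survival through year 1 (in %).
#'
#' @param post5,post1 `trend_posterior` objects for the same country on
#'   identical grids with equal draw counts. The pairing of draw i of one
#'   model with draw i of the other is an arbitrary but reproducible coupling
#'   of two independently fitted models.
#' @return A `trend_posterior` with `measure = "cond5_1"`.
#' @export
conditional_ratio <- function(post5, post1) {
  stopifnot(inherits(post5, "trend_posterior"), inherits(post1, "trend_posterior"))
  if (!isTRUE(all.equal(post5$grid, post1$grid))) .stopf("grids differ")
  if (!all(dim(post5$draws) == dim(post1$draws))) .stopf("draw dimensions differ")
  if (any(post1$draws <= 0)) {
    .stopf("degenerate 1-year posterior: draws <= 0 at some grid point")
  }
  structure(
    list(country = post5$country, site = post5$site, measure = "cond5_1",
         grid = post5$grid, draws = post5$draws / post1$draws * 100,
         seed = post5$seed, basis_dim = post5$basis_dim,
         rhat = max(post5$rhat, post1$rhat)),
    class = "trend_posterior"
  )
}

#' Posterior derivative curves by central finite differences
#'
#' Applies, per draw, the central difference stencils
#' `(f(t+h) - f(t-h)) / 2h` (order 1, %/year) or
#' `(f(t+h) - 2 f(t) + f(t-h)) / h^2` (order 2, %/year^2) with `h` equal to
#' the grid step; the boundary points consumed by the stencil are dropped.
#'
#' @param tp A `trend_posterior` on a uniform grid.
#' @param order Derivative order, 1 or 2.
#' @param level Credible level for the attached pointwise summary.
#' @return An object of class `derivative_curve`: list with `order`, `grid`,
#'   `draws`, `mean`, `lower`, `upper`, and the source labels.
#' @export
derivative_curves <- function(tp, order = 1L, level = 0.95) {
  stopifnot(inherits(tp, "trend_posterior"), order %in% c(1L, 2L))
  g <- tp$grid
  if (length(g) < 3L) .stopf("grid too short for the central-difference stencil")
  h <- diff(g)
  if (max(h) - min(h) > 1e-8) .stopf("grid step must be uniform")
  h <- h[1L]
  n <- length(g)
  f <- tp$draws
  d <- if (order == 1L) {
    (f[, 3:n, drop = FALSE] - f[, 1:(n - 2), drop = FALSE]) / (2 * h)
  } else {
    (f[, 3:n, drop = FALSE] - 2 * f[, 2:(n - 1), drop = FALSE] +
       f[, 1:(n - 2), drop = FALSE]) / h^2
  }
  a <- (1 - level) / 2
  qs <- apply(d, 2L, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  structure(
    list(country = tp$country, site = tp$site, measure = tp$measure,
         order = order, grid = g[2:(n - 1)], draws = d,
         mean = colMeans(d), lower = qs[1L, ], upper = qs[2L, ],
         level = level),
    class = "derivative_curve"
  )
}

# Maximal runs of grid points where the pointwise CrI excludes zero with a
# constant sign; runs spanning at least `min_years` (t_end - t_start,
# boundaries inclusive) are returned.
.cri_runs <- function(grid, lower, upper, min_years) {
  sgn <- ifelse(lower > 0, 1L, ifelse(upper < 0, -1L, 0L))
  r <- rle(sgn)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- data.frame(t_start = numeric(0), t_end = numeric(0),
                    direction = character(0), i_start = integer(0),
                    i_end = integer(0), stringsAsFactors = FALSE)
  for (k in seq_along(r$values)) {
    if (r$values[k] == 0L) next
    span <- grid[ends[k]] - grid[starts[k]]
    if (span >= min_years - 1e-9) {
      out <- rbind(out, data.frame(
        t_start = grid[starts[k]], t_end = grid[ends[k]],
        direction = if (r$values[k] > 0L) "increase" else "decrease",
        i_start = starts[k], i_end = ends[k], stringsAsFactors = FALSE
      ))
    }
  }
  out
}

#' Significant change windows from the 1st-derivative posterior
#'
#' Maximal runs of consecutive grid points where the pointwise credible
#' interval of the annual change excludes zero with constant sign; only runs
#' spanning at least `min_years` (default 5) are reported. An empty
#' `data.frame` is a valid result.
#'
#' @param d1 A `derivative_curve` of order 1.
#' @param min_years Minimum window span in years (default 5).
#' @return `data.frame` with `t_start`, `t_end`, `direction`
#'   (`"increase"`/`"decrease"`).
#' @export
significant_change_windows <- function(d1, min_years = 5) {
  stopifnot(inherits(d1, "derivative_curve"))
  if (d1$order != 1L) .stopf("`d1` must be a 1st-derivative curve")
  .cri_runs(d1$grid, d1$lower, d1$upper, min_years)[, c("t_start", "t_end", "direction")]
}

#' Breakpoints from the 2nd-derivative posterior
#'
#' Within each maximal run (>= `min_years`, default 3) where the pointwise
#' credible interval of the 2nd derivative excludes zero with constant sign,
#' the breakpoint is the peak value: the time of the largest absolute
#' posterior-mean 2nd derivative in the run (ties broken toward the earliest
#' time).
#'
#' @param d2 A `derivative_curve` of order 2.
#' @param min_years Minimum run span in years (default 3).
#' @return `data.frame` with `time`, `t_start`, `t_end`, `curvature_sign`
#'   (`"+"`/`"-"`).
#' @export
detect_breakpoints <- function(d2, min_years = 3) {
  stopifnot(inherits(d2, "derivative_curve"))
  if (d2$order != 2L) .stopf("`d2` must be a 2nd-derivative curve")
  runs <- .cri_runs(d2$grid, d2$lower, d2$upper, min_years)
  if (nrow(runs) == 0L) {
    return(data.frame(time = numeric(0), t_start = numeric(0),
                      t_end = numeric(0), curvature_sign = character(0),
                      stringsAsFactors = FALSE))
  }
  time <- vapply(seq_len(nrow(runs)), function(k) {
    i <- runs$i_start[k]:runs$i_end[k]
    d2$grid[i][which.max(abs(d2$mean[i]))] # which.max returns the earliest tie
  }, numeric(1))
  data.frame(time = time, t_start = runs$t_start, t_end = runs$t_end,
             curvature_sign = ifelse(runs$direction == "increase", "+", "-"),
             stringsAsFactors = FALSE)
}

#' Posterior of the survival improvement between two times
#'
#' Draw-wise difference `f(t1) - f(t0)` (% units).
#'
#' @param tp A `trend_posterior`.
#' @param t0,t1 Times on the posterior grid (matched within 1e-8; off-grid
#'   times are an error).
#' @param level Credible level (default 0.95).
#' @return List with `mean`, `ci` (length 2) and `draws`.
#' @export
survival_improvement <- function(tp, t0, t1, level = 0.95) {
  stopifnot(inherits(tp, "trend_posterior"))
  i0 <- .grid_index(tp$grid, t0)
  i1 <- .grid_index(tp$grid, t1)
  d <- tp$draws[, i1] - tp$draws[, i0]
  a <- (1 - level) / 2
  list(mean = mean(d),
       ci = unname(stats::quantile(d, c(a, 1 - a))),
       draws = d)
}

.grid_index <- function(grid, t) {
  i <- which(abs(grid - t) < 1e-8)
  if (length(i) != 1L) .stopf("time %g is not on the posterior grid", t)
  i
}

#' Between-country contrast of trend posteriors
#'
#' Draw-wise difference A - B of two posteriors for the same measure on the
#' same grid, with windows where the pointwise credible interval of the
#' difference excludes zero for at least `min_years` (the same run rule as
#' [significant_change_windows()]; the sign convention is
#' `"increase"` = A above B).
#'
#' @param tpA,tpB `trend_posterior` objects with identical measure, grid and
#'   draw count.
#' @param min_years Minimum window span in years (default 5).
#' @param level Credible level (default 0.95).
#' @return List with `difference` (a `trend_posterior`-like object of the
#'   draw-wise differences) and `windows` (`data.frame` as in
#'   [significant_change_windows()]).
#' @export
country_contrast <- function(tpA, tpB, min_years = 5, level = 0.95) {
  stopifnot(inherits(tpA, "trend_posterior"), inherits(tpB, "trend_posterior"))
  if (!identical(tpA$measure, tpB$measure)) .stopf("measures differ")
  if (!isTRUE(all.equal(tpA$grid, tpB$grid))) .stopf("grids differ")
  if (!all(dim(tpA$draws) == dim(tpB$draws))) .stopf("draw dimensions differ")
  d <- tpA$draws - tpB$draws
  a <- (1 - level) / 2
  qs <- apply(d, 2L, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  diff_tp <- structure(
    list(country = paste(tpA$country, tpB$country, sep = "-"),
         site = tpA$site, measure = paste0("diff_", tpA$measure),
         grid = tpA$grid, draws = d, seed = tpA$seed,
         basis_dim = tpA$basis_dim, rhat = max(tpA$rhat, tpB$rhat)),
    class = "trend_posterior"
  )
  windows <- .cri_runs(tpA$grid, qs[1L, ], qs[2L, ],
                       min_years)[, c("t_start", "t_end", "direction")]
  list(difference = diff_tp, windows = windows)
}
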