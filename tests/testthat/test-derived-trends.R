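# Hand-built posteriors with known analytic structure.
fake_tp <- function(draws, grid, measure = "surv5", country = "A") {
  structure(list(country = country, site = "s", measure = measure,
                 grid = grid, draws = draws, seed = 1, basis_dim = 8,
                 rhat = 1),
            class = "trend_posterior")
}

grid <- seq(1973, 2018, by = 0.1)

test_that("conditional ratio divides draws index-pairwise", {
  d5 <- matrix(45, 200, length(grid))
  d1 <- matrix(90, 200, length(grid))
  r <- conditional_ratio(fake_tp(d5, grid), fake_tp(d1, grid, "surv1"))
  expect_true(all(r$draws == 50))
  expect_equal(r$measure, "cond5_1")
  # identity: tp / tp is exactly 100 with zero CrI width at every draw
  set.seed(20)
  d <- matrix(rnorm(200 * length(grid), 70, 5), 200)
  tp <- fake_tp(d, grid)
  same <- conditional_ratio(tp, tp)
  expect_true(all(same$draws == 100))
  # degenerate 1-year posterior rejected
  dneg <- d1; dneg[3, 7] <- 0
  expect_error(conditional_ratio(fake_tp(d5, grid), fake_tp(dneg, grid, "surv1")),
               "degenerate")
  # grid mismatch rejected
  expect_error(conditional_ratio(fake_tp(d5, grid), fake_tp(d1, grid + 1, "surv1")),
               "grids")
})

test_that("finite-difference derivatives are exact on linear and quadratic draws", {
  lin <- matrix(rep(10 + 0.8 * (grid - 1973), each = 50), nrow = 50)
  d1 <- derivative_curves(fake_tp(lin, grid), 1)
  expect_lt(max(abs(d1$draws - 0.8)), 1e-8)
  d2 <- derivative_curves(fake_tp(lin, grid), 2)
  expect_lt(max(abs(d2$draws)), 1e-6)
  # quadratic a t^2: 2nd derivative exactly 2a under the central stencil
  a <- 0.03
  quad <- matrix(rep(a * (grid - 1990)^2, each = 50), nrow = 50)
  d2q <- derivative_curves(fake_tp(quad, grid), 2)
  expect_lt(max(abs(d2q$draws - 2 * a)), 1e-6)
  # derivative of a per-draw-constant posterior is exactly zero
  cst <- matrix(rep(rnorm(50, 70, 3), times = length(grid)), nrow = 50)
  expect_true(all(derivative_curves(fake_tp(cst, grid), 1)$draws == 0))
  # grid consumed by the stencil
  expect_equal(d1$grid, grid[2:(length(grid) - 1)])
})

test_that("finite differences match the analytic derivative of a smooth curve", {
  f <- function(t) 70 + 10 * sin((t - 1973) / 8)
  fp <- function(t) 10 / 8 * cos((t - 1973) / 8)
  sm <- matrix(rep(f(grid), each = 20), nrow = 20)
  d1 <- derivative_curves(fake_tp(sm, grid), 1)
  # central differences are O(h^2): at h = 0.1 the error is ~ f'''(t) h^2/6
  expect_lt(max(abs(d1$mean - fp(d1$grid))), 1e-4)
})

test_that("change windows obey the 5-year run rule strictly", {
  n_draws <- 400
  # a 1st-derivative curve that is credibly positive only on [1990, 1994.9]:
  # 4.9-year span -> below threshold -> no window
  base <- function(width) {
    m <- matrix(rnorm(n_draws * length(grid), 0, 0.02), n_draws)
    on <- grid >= 1990 - 1e-9 & grid <= 1990 + width + 1e-9
    m[, on] <- m[, on] + 1
    m
  }
  mk_d1 <- function(width) {
    tp <- fake_tp(base(width), grid)
    structure(list(country = "A", site = "s", measure = "surv5", order = 1L,
                   grid = grid, draws = tp$draws,
                   mean = colMeans(tp$draws),
                   lower = apply(tp$draws, 2, quantile, 0.025),
                   upper = apply(tp$draws, 2, quantile, 0.975), level = 0.95),
              class = "derivative_curve")
  }
  set.seed(21)
  expect_equal(nrow(significant_change_windows(mk_d1(4.9))), 0L)
  w <- significant_change_windows(mk_d1(5.4))
  expect_equal(nrow(w), 1L)
  expect_equal(w$direction, "increase")
  expect_gte(w$t_end - w$t_start, 5)
})

test_that("breakpoints sit at the curvature peak inside qualifying runs", {
  n_draws <- 300
  # credibly positive 2nd derivative on [1995, 1999], peaked at 1997
  bump <- pmax(0, 1 - abs(grid - 1997) / 2) # triangular, support 1995-1999
  m <- matrix(rep(bump, each = n_draws), n_draws) + 0.5 +
    matrix(rnorm(n_draws * length(grid), 0, 0.01), n_draws)
  off <- grid < 1995 | grid > 1999
  m[, off] <- matrix(rnorm(n_draws * sum(off), 0, 0.01), n_draws)
  d2 <- structure(list(country = "A", site = "s", measure = "surv5",
                       order = 2L, grid = grid, draws = m,
                       mean = colMeans(m),
                       lower = apply(m, 2, quantile, 0.025),
                       upper = apply(m, 2, quantile, 0.975), level = 0.95),
                  class = "derivative_curve")
  bp <- detect_breakpoints(d2)
  expect_equal(nrow(bp), 1L)
  expect_equal(bp$time, 1997, tolerance = 0.15)
  expect_equal(bp$curvature_sign, "+")
  # a 2.9-year run is not reported
  bp_short <- detect_breakpoints(d2, min_years = 4.2)
  expect_equal(nrow(bp_short), 0L)
})

test_that("survival improvements are draw-wise differences on the grid", {
  set.seed(22)
  slope <- 0.4
  d <- matrix(rep(60 + slope * (grid - 1973), each = 100), nrow = 100) +
    rnorm(100, 0, 0.5) # draw-level offsets cancel in differences
  tp <- fake_tp(d, grid)
  imp <- survival_improvement(tp, 1973, 2018)
  expect_equal(imp$mean, slope * 45, tolerance = 1e-8)
  expect_equal(unname(diff(imp$ci)), 0, tolerance = 1e-8)
  # t0 = t1: identically zero; swapped arguments: negated posterior
  expect_true(all(survival_improvement(tp, 1990, 1990)$draws == 0))
  expect_equal(survival_improvement(tp, 2018, 1973)$draws, -imp$draws)
  expect_error(survival_improvement(tp, 1990.05, 2000), "not on the posterior grid")
})

test_that("country contrasts difference draws and reuse the run rule", {
  set.seed(23)
  dA <- matrix(rnorm(300 * length(grid), 75, 1), 300)
  dB <- dA - 5
  tpA <- fake_tp(dA, grid, country = "A")
  tpB <- fake_tp(dB, grid, country = "B")
  ct <- country_contrast(tpA, tpB)
  expect_true(all(abs(ct$difference$draws - 5) < 1e-9))
  expect_equal(nrow(ct$windows), 1L)
  expect_equal(ct$windows$direction, "increase")
  # antisymmetry, draw-wise
  ct2 <- country_contrast(tpB, tpA)
  expect_equal(ct2$difference$draws, -ct$difference$draws)
  # identical posteriors: no windows
  ct3 <- country_contrast(tpA, tpA)
  expect_true(all(ct3$difference$draws == 0))
  expect_equal(nrow(ct3$windows), 0L)
  # measure mismatch rejected
  expect_error(country_contrast(tpA, fake_tp(dB, grid, "surv1", "B")), "measure")
})
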