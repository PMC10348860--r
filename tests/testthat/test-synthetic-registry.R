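test_that("scenario truths expose consistent closed-form net survival", {
  sc <- scenario_truth("X", "s", s1 = trend_constant(0.9),
                       s5 = trend_constant(0.54))
  expect_equal(sc$net_survival(0, 1990), 1)
  expect_equal(sc$net_survival(1, 1990), 0.9)
  expect_equal(sc$net_survival(5, 1990), 0.54)
  # non-increasing in t, vectorized over diagnosis year
  tt <- seq(0, 8, by = 0.25)
  expect_true(all(diff(sc$net_survival(tt, 1990)) <= 0))
  expect_length(sc$net_survival(5, c(1980, 1990, 2000)), 3L)
  # ordering violation rejected
  expect_error(scenario_truth("X", "s", s1 = trend_constant(0.5),
                              s5 = trend_constant(0.6)), "s5")
})

test_that("cohort simulation honours caps, censoring horizon and determinism", {
  scs <- default_scenarios("NO", "breast")
  lt <- build_life_table("NO", baseline = 2.5e-5, slope = 0.095, decline = 0.01)
  coh <- simulate_cohort(scs$NO.breast, lt, n_per_year = 30, seed = 11)
  expect_true(all(coh$age_at_diagnosis >= 0 & coh$age_at_diagnosis <= 89))
  expect_true(all(coh$diagnosis_year + coh$follow_up_years <= 2021 + 1e-9))
  expect_true(all(coh$follow_up_years >= 0))
  # bit-identical regeneration under the same seed
  coh2 <- simulate_cohort(scs$NO.breast, lt, n_per_year = 30, seed = 11)
  expect_identical(coh, coh2)
  coh3 <- simulate_cohort(scs$NO.breast, lt, n_per_year = 30, seed = 12)
  expect_false(identical(coh, coh3))
  # country mismatch between scenario and life table
  expect_error(simulate_cohort(scs$NO.breast, zero_life_table("SE"),
                               n_per_year = 5, seed = 1), "country")
})

test_that("immortal and limiting cohorts behave as expected", {
  lt0 <- zero_life_table()
  # zero excess hazard + zero life table: everyone censored at end of 2020
  sc0 <- scenario_truth("X", "s", s1 = trend_constant(1 - 1e-15),
                        s5 = trend_constant(1 - 1e-15))
  coh <- simulate_cohort(sc0, lt0, n_per_year = 40, years = 2000:2005, seed = 3)
  expect_true(all(coh$event == "censored"))
  expect_equal(coh$diagnosis_year + coh$follow_up_years, rep(2021, nrow(coh)))
  # enormous excess hazard: essentially everyone dies within the first year
  # survival 1e-300 within the first year, i.e. excess hazard ~ 690/yr
  schi <- scenario_truth("X", "s", s1 = trend_constant(1e-300),
                         s5 = trend_constant(1e-300))
  cohhi <- simulate_cohort(schi, lt0, n_per_year = 200, years = 2000, seed = 4)
  expect_true(all(cohhi$event == "death"))
  expect_true(all(cohhi$follow_up_years < 1))
})

test_that("large-cohort empirical survival recovers the closed-form truth", {
  # constant excess hazard 0.1/yr, zero background: KM at 5 within 0.6% units
  # of exp(-0.5) = 60.65% (closed-form oracle; n = 50000 => MC SE ~ 0.22%)
  lt0 <- zero_life_table()
  sc <- scenario_truth("X", "s", s1 = trend_constant(exp(-0.1)),
                       s5 = trend_constant(exp(-0.5)))
  coh <- simulate_cohort(sc, lt0, n_per_year = 50000, years = 2000, seed = 42)
  km5 <- oracle_km(coh$follow_up_years, coh$event == "death", 5)
  expect_lt(abs(km5 - exp(-0.5)), 0.006)
  km1 <- oracle_km(coh$follow_up_years, coh$event == "death", 1)
  expect_lt(abs(km1 - exp(-0.1)), 0.006)
})

test_that("background-only mortality matches the life table's own survival", {
  # pure background (excess ~ 0): empirical 5-year survival of a single-age
  # cohort equals prod_k (1 - q(age+k, y0+k)) within 3 MC SEs
  sc0 <- scenario_truth("X", "s", s1 = trend_constant(1 - 1e-15),
                        s5 = trend_constant(1 - 1e-15))
  lt <- build_life_table("X", baseline = 4e-4, slope = 0.085, decline = 0.005)
  dist80 <- stats::setNames(1, 80)
  n <- 40000
  coh <- simulate_cohort(sc0, lt, n_per_year = n, years = 2000,
                         age_distribution = dist80, seed = 5)
  surv5 <- mean(coh$follow_up_years >= 5)
  expected <- prod(1 - life_table_prob(lt, 80:84, 2000:2004))
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(surv5 - expected), 3 * se)
})

test_that("rate series are Poisson draws with the requested means", {
  # zero rate: all counts zero
  rs0 <- simulate_rate_series("X", "s", rate = function(a, y) 0 * a, seed = 1)
  expect_true(all(rs0$cases == 0))
  # constant rate, large person-years: empirical ASR -> r within 3 SE
  r <- 3e-4
  py <- 4e5
  rs <- simulate_rate_series("X", "s", rate = function(a, y) rep(r, length(a)),
                             person_years = py, years = 2000, seed = 2)
  asr <- world_asr(rs)
  w <- segi_world_standard()$weight
  se_asr <- sqrt(sum(w^2 * r / py)) * 1e5
  expect_lt(abs(asr - r * 1e5), 3 * se_asr)
  # determinism
  rs2 <- simulate_rate_series("X", "s", rate = function(a, y) rep(r, length(a)),
                              person_years = py, years = 2000, seed = 2)
  expect_identical(rs, rs2)
  expect_error(simulate_rate_series("X", "s", rate = function(a, y) -a, seed = 1),
               "non-negative")
})

test_that("cohorts round-trip through CSV and violations are rejected", {
  scs <- default_scenarios("SE", "ovarian")
  lt <- build_life_table("SE", baseline = 2.5e-5, slope = 0.095)
  coh <- simulate_cohort(scs$SE.ovarian, lt, n_per_year = 10,
                         years = 2000:2002, seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh, path)
  back <- read_cohort_csv(path)
  expect_equal(back$follow_up_years, coh$follow_up_years, tolerance = 1e-12)
  bad <- coh
  bad$age_at_diagnosis[1] <- 95L
  expect_error(write_cohort_csv(bad, withr::local_tempfile()), "0-89")
})
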