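test_that("expected-survival integration matches hand integration", {
  lt <- constant_q_life_table(0.02)
  p <- make_cohort(10, "censored")
  # constant annual q: Lambda_E(t) = -t log(1 - q)
  expect_equal(cumulative_expected_hazard(p, lt, 1), -log(0.98), tolerance = 1e-12)
  expect_equal(cumulative_expected_hazard(p, lt, 5), -5 * log(0.98), tolerance = 1e-12)
  expect_equal(cumulative_expected_hazard(p, lt, 2.5), -2.5 * log(0.98), tolerance = 1e-12)
  # empty interval and zero life table
  expect_equal(cumulative_expected_hazard(p, lt, 0), 0)
  expect_equal(cumulative_expected_hazard(p, zero_life_table(), 7), 0)
  expect_equal(expected_survival(p, zero_life_table(), 7), 1)
  # integration stops at the observed follow-up by default
  p2 <- make_cohort(2, "death")
  expect_equal(cumulative_expected_hazard(p2, lt, 5), -2 * log(0.98), tolerance = 1e-12)
  expect_equal(cumulative_expected_hazard(p2, lt, 5, cap_at_followup = FALSE),
               -5 * log(0.98), tolerance = 1e-12)
  # age-varying path: hand sum over the attained-age diagonal
  ltg <- build_life_table("X", baseline = 3e-4, slope = 0.09, decline = 0.004)
  p3 <- make_cohort(10, "censored", diagnosis_year = 1987.3, age = 72)
  hand <- sum(-log(1 - life_table_prob(ltg, 72:74, 1987:1989))) +
    0.5 * -log(1 - life_table_prob(ltg, 75, 1990))
  expect_equal(cumulative_expected_hazard(p3, ltg, 3.5), hand, tolerance = 1e-12)
})

test_that("Pohar Perme matches the frozen term-by-term oracle on the hand cohort", {
  # 5 patients: deaths at 0.5, 1.2, 3.5; censored at 2.0, 5.0; constant q=0.02.
  # Expected values computed with the literal counting-process oracle before
  # the estimator was built.
  coh <- make_cohort(follow_up = c(0.5, 1.2, 2.0, 3.5, 5.0),
                     event = c("death", "death", "censored", "death", "censored"))
  lt <- constant_q_life_table(0.02)
  pp <- pohar_perme_net_survival(coh, lt, t = 5)
  expect_equal(pp$estimate, 0.331859297188952, tolerance = 1e-10)
  expect_equal(pp$se_cumhaz^2, 0.3525, tolerance = 1e-10)
  expect_equal(pp$n_events, 3L)
})

test_that("Pohar Perme equals the oracle on randomized small cohorts", {
  lt <- build_life_table("X", baseline = 3e-4, slope = 0.09, decline = 0.005)
  for (seed in 1:8) {
    coh <- random_cohort(n = 5 + (seed %% 12), seed = 200 + seed)
    or <- oracle_pp(coh, lt, t = 5)
    pp <- pohar_perme_net_survival(coh, lt, t = 5)
    expect_equal(pp$estimate, or$estimate, tolerance = 1e-10)
    expect_equal(pp$se_cumhaz^2, or$var_cumhaz, tolerance = 1e-10)
  }
})

test_that("with a zero life table the estimator equals Kaplan-Meier exactly", {
  lt0 <- zero_life_table()
  for (seed in 1:5) {
    coh <- random_cohort(n = 30, seed = 300 + seed)
    pp <- pohar_perme_net_survival(coh, lt0, t = 5)
    km <- oracle_km(coh$follow_up_years, coh$event == "death", 5)
    expect_identical(pp$estimate, km)
  }
  # and against survival::survfit as an external cross-check
  coh <- random_cohort(n = 60, seed = 310)
  fit <- survival::survfit(
    survival::Surv(pmin(follow_up_years, 5),
                   event == "death" & follow_up_years <= 5) ~ 1, data = coh)
  km5 <- summary(fit, times = 5)$surv
  pp <- pohar_perme_net_survival(coh, lt0, t = 5)
  expect_equal(pp$estimate, km5, tolerance = 1e-12)
})

test_that("single censored patient and row-order invariance", {
  # a lone censored patient has net survival exactly 1 in the absence of
  # background mortality; with background mortality the estimator credits the
  # expected deaths and exceeds 1 by exp(+Lambda_E) on the monthly grid
  one <- make_cohort(5, "censored")
  expect_equal(pohar_perme_net_survival(one, zero_life_table(), t = 5)$estimate,
               1, tolerance = 1e-12)
  lt <- constant_q_life_table(0.01)
  h <- -log(1 - 0.01)
  expect_equal(pohar_perme_net_survival(one, lt, t = 5)$estimate,
               (1 + h / 12)^60, tolerance = 1e-10)

  coh <- random_cohort(n = 40, seed = 320)
  pp1 <- pohar_perme_net_survival(coh, lt, t = 5)
  perm <- sample(nrow(coh))
  pp2 <- pohar_perme_net_survival(coh[perm, ], lt, t = 5)
  expect_equal(pp1$estimate, pp2$estimate, tolerance = 1e-12)
  expect_equal(pp1$se_cumhaz, pp2$se_cumhaz, tolerance = 1e-12)
})

test_that("exhausted risk sets carry the estimate forward with a flag", {
  lt <- constant_q_life_table(0.01)
  coh <- make_cohort(c(0.4, 0.9), c("death", "death"))
  pp <- pohar_perme_net_survival(coh, lt, t = 5)
  expect_true("carried_forward" %in% pp$flags)
  expect_equal(pp$estimate, 0)
  # relative survival above 100% is flagged, not clipped
  coh2 <- make_cohort(rep(5, 30), "censored", age = 85)
  lth <- constant_q_life_table(0.10)
  pph <- pohar_perme_net_survival(coh2, lth, t = 5)
  expect_gt(pph$estimate, 1)
  expect_true("above_unity" %in% pph$flags)
})

test_that("age standardization reweights individuals by w_g / p_g", {
  lt <- constant_q_life_table(0.02)
  # self-standardization: cohort shares exactly equal to the standard weights
  w <- default_age_weights()
  n_per <- round(100 * w$weight)
  ages <- rep(c(40, 55, 65, 75, 85), times = n_per)
  set.seed(7)
  coh <- make_cohort(follow_up = round(stats::runif(length(ages), 0.1, 6), 3),
                     event = sample(c("death", "censored"), length(ages), TRUE),
                     age = ages)
  std <- age_standardized_net_survival(coh, lt, t = 5)
  raw <- pohar_perme_net_survival(coh, lt, t = 5)
  expect_equal(std$estimate, raw$estimate, tolerance = 1e-10)
  expect_equal(std$se_cumhaz, raw$se_cumhaz, tolerance = 1e-10)

  # group-wise oracle: equivalence (up to Op(n^-1/2) second-order terms) to
  # the weighted mean of group-specific estimates under unequal sampling
  set.seed(8)
  ages2 <- rep(c(40, 55, 65, 75, 85), times = c(60, 180, 480, 300, 180))
  coh2 <- make_cohort(follow_up = round(stats::runif(length(ages2), 0.1, 6), 3),
                      event = sample(c("death", "censored"), length(ages2), TRUE),
                      age = ages2)
  std2 <- age_standardized_net_survival(coh2, lt, t = 5)
  g <- findInterval(coh2$age_at_diagnosis, w$lower)
  by_group <- vapply(seq_len(5), function(k) {
    pohar_perme_net_survival(coh2[g == k, ], lt, t = 5)$estimate
  }, numeric(1))
  expect_equal(std2$estimate, sum(w$weight * by_group), tolerance = 0.02)

  # empty weighted group errors, naming the group
  coh3 <- coh2[coh2$age_at_diagnosis > 49, ]
  expect_error(age_standardized_net_survival(coh3, lt, t = 5), "0-49")
})

test_that("two equal-sized groups with survival 0.8 / 0.6 average to 0.7", {
  # weighted mean at the group level: exact when groups are exchangeable
  # apart from their survival (checked on the group-specific estimates)
  lt0 <- zero_life_table()
  w2 <- age_weights(lower = c(0, 60), upper = c(59, 89), weight = c(0.5, 0.5))
  # group A: 10 patients, 2 deaths before t; group B: 10 patients, 4 deaths
  fuA <- c(rep(1, 2), rep(6, 8))
  fuB <- c(rep(1, 4), rep(6, 6))
  coh <- make_cohort(c(fuA, fuB),
                     c(rep("death", 2), rep("censored", 8),
                       rep("death", 4), rep("censored", 6)),
                     age = c(rep(40, 10), rep(70, 10)))
  g <- findInterval(coh$age_at_diagnosis, w2$lower)
  estA <- pohar_perme_net_survival(coh[g == 1, ], lt0, t = 5)$estimate
  estB <- pohar_perme_net_survival(coh[g == 2, ], lt0, t = 5)$estimate
  expect_equal(estA, 0.8, tolerance = 1e-12)
  expect_equal(estB, 0.6, tolerance = 1e-12)
  expect_equal(0.5 * estA + 0.5 * estB, 0.7, tolerance = 1e-12)
  # the reweighted estimator agrees here because both groups share event times
  std <- age_standardized_net_survival(coh, lt0, t = 5, weights = w2)
  expect_equal(std$estimate, 0.7, tolerance = 1e-12)
})

test_that("age-weight tables are validated", {
  expect_error(age_weights(weight = c(0.3, 0.3, 0.2, 0.1, 0.2) + 0.01), "sum to 1")
  expect_error(age_weights(lower = c(0, 50, 60, 70, 81),
                           upper = c(49, 59, 69, 79, 89),
                           weight = c(0.25, 0.25, 0.2, 0.2, 0.1)),
               "partition")
})
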