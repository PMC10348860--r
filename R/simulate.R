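# Synthetic registry cohorts: excess and background mortality are independent
# competing risks (the assumption under which relative survival estimates net
# survival). Background death times are simulated year-by-year along the
# attained-age / calendar diagonal at the life table's annual resolution.

#' Default age-at-diagnosis distribution
#'
#' Discretized Normal(mean 65, sd 12) truncated to ages 30-89: a typical
#' cancer age profile that keeps all five age-standardization groups populated.
#'
#' @param mean,sd Normal parameters (years).
#' @param ages Integer support (default 30:89).
#' @return Named numeric vector of probabilities over `ages` (sums to 1).
#' @export
default_age_distribution <- function(mean = 65, sd = 12, ages = 30:89) {
  p <- stats::dnorm(ages, mean, sd)
  stats::setNames(p / sum(p), ages)
}

#' Simulate a patient-level registry cohort
#'
#' Draws diagnoses uniformly within each calendar year, ages from
#' `age_distribution`, an excess-cause death time from the scenario's
#' two-phase excess hazard (exact inverse-CDF sampling) and a background death
#' time from the life table along the patient's attained-age / calendar path
#' (piecewise-constant annual hazard; during follow-up year `k` the hazard is
#' that of age `age + k` in calendar year `floor(diagnosis_year) + k`, clamped
#' to the table). The observed follow-up is the minimum of the two death times,
#' optional independent censoring, and administrative censoring at
#' `end_of_followup` (default end of 2020, i.e. calendar time 2021.0).
#'
#' @param truth A [scenario_truth()].
#' @param lifetable A [build_life_table()] `life_table` for the same country.
#' @param n_per_year Diagnoses per calendar year (>= 1).
#' @param years Diagnosis years (default 1971:2020).
#' @param age_distribution Named probability vector over integer ages 0-89
#'   (default [default_age_distribution()]).
#' @param seed Integer seed; the cohort is bit-identical for a given seed.
#' @param censoring_rate Optional independent (emigration-style) censoring
#'   hazard per year (default 0).
#' @param end_of_followup Administrative censoring horizon as decimal calendar
#'   time (default 2021.0 = end of 2020).
#' @return A `data.frame` with columns `country`, `site`, `diagnosis_year`
#'   (decimal), `age_at_diagnosis` (integer, <= 89), `follow_up_years`,
#'   `event` (`"death"` or `"censored"`).
#' @export
simulate_cohort <- function(truth, lifetable, n_per_year, years = 1971:2020,
                            age_distribution = default_age_distribution(),
                            seed = 1, censoring_rate = 0,
                            end_of_followup = 2021) {
  stopifnot(inherits(truth, "scenario_truth"), inherits(lifetable, "life_table"))
  if (!identical(truth$country, lifetable$country)) {
    .stopf("scenario country '%s' does not match life-table country '%s'",
           truth$country, lifetable$country)
  }
  if (n_per_year < 1) .stopf("`n_per_year` must be >= 1")
  ages_support <- as.integer(names(age_distribution))
  if (any(ages_support < 0 | ages_support > 89)) {
    .stopf("age distribution support must lie within 0-89")
  }
  .with_seed(seed, {
    n <- n_per_year * length(years)
    dy <- rep(years, each = n_per_year) + stats::runif(n)
    dy <- pmin(dy, end_of_followup - 1e-9)
    age <- ages_support[sample.int(length(ages_support), n, replace = TRUE,
                                   prob = age_distribution)]

    # Excess-cause death time: two-phase exponential, exact inversion.
    l1 <- truth$lambda1(dy)
    l2 <- truth$lambda2(dy)
    u <- stats::runif(n)
    s1v <- exp(-l1)
    t_exc <- rep(Inf, n)
    first <- u >= s1v & l1 > 0 # dies within year 1
    t_exc[first] <- -log(u[first]) / l1[first]
    later <- !first & l2 > 0
    t_exc[later] <- 1 + (-log(u[later]) - l1[later]) / l2[later]

    # Background death time: annual piecewise-constant hazard along the
    # attained-age / calendar diagonal.
    t_bg <- .simulate_background_time(lifetable, age, floor(dy))

    t_adm <- end_of_followup - dy
    t_cen <- if (censoring_rate > 0) stats::rexp(n, censoring_rate) else rep(Inf, n)

    t_death <- pmin(t_exc, t_bg)
    fu <- pmin(t_death, t_adm, t_cen)
    event <- ifelse(t_death <= pmin(t_adm, t_cen), "death", "censored")

    data.frame(
      country = truth$country, site = truth$site,
      diagnosis_year = dy, age_at_diagnosis = as.integer(age),
      follow_up_years = fu, event = event,
      stringsAsFactors = FALSE
    )
  })
}

# Vectorized background death-time draw: cumulative annual hazards are scanned
# until a unit-exponential target is exceeded; the crossing year gives the
# death time (uniformly placed within the year via the exponential residual).
.simulate_background_time <- function(lifetable, age, year0, max_years = 110) {
  n <- length(age)
  target <- stats::rexp(n)
  cum <- numeric(n)
  t_bg <- rep(Inf, n)
  alive <- rep(TRUE, n)
  for (k in 0:max_years) {
    if (!any(alive)) break
    idx <- which(alive)
    h <- life_table_hazard(lifetable, age[idx] + k, year0[idx] + k)
    dies <- target[idx] <= cum[idx] + h
    if (any(dies)) {
      di <- idx[dies]
      t_bg[di] <- k + (target[di] - cum[di]) / h[dies]
      alive[di] <- FALSE
    }
    cum[idx] <- cum[idx] + h
  }
  t_bg
}

#' Simulate an incidence or mortality rate series
#'
#' Case counts are Poisson draws with mean `rate(age_mid, year) * person_years`
#' in 5-year age groups, emulating registry incidence/mortality tabulations.
#'
#' @param country,site Labels.
#' @param rate Function `(age_mid, year) -> events per person-year` (>= 0).
#' @param person_years Person-years per (age group, year) cell: a single
#'   number or a function `(age_mid, year) -> person-years` (> 0).
#' @param years Calendar years (default 1961:2020).
#' @param age_groups Age-group labels; defaults to the 18 five-year groups
#'   `"0-4"` ... `"85+"` used by the world standard population.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `country`, `site`, `year`, `age_group`,
#'   `cases`, `person_years`.
#' @export
simulate_rate_series <- function(country, site, rate, person_years = 1e5,
                                 years = 1961:2020,
                                 age_groups = segi_world_standard()$age_group,
                                 seed = 1) {
  stopifnot(is.function(rate))
  mids <- .age_group_midpoints(age_groups)
  py_fun <- if (is.function(person_years)) person_years else {
    if (any(person_years <= 0)) .stopf("`person_years` must be positive")
    function(a, y) rep_len(person_years, length(a))
  }
  grid <- expand.grid(age_group = age_groups, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$age_mid <- mids[match(grid$age_group, age_groups)]
  mu_rate <- rate(grid$age_mid, grid$year)
  if (any(!is.finite(mu_rate)) || any(mu_rate < 0)) {
    .stopf("`rate` must return finite non-negative values")
  }
  py <- py_fun(grid$age_mid, grid$year)
  if (any(!is.finite(py)) || any(py <= 0)) .stopf("person-years must be positive")
  .with_seed(seed, {
    cases <- stats::rpois(nrow(grid), mu_rate * py)
    data.frame(country = country, site = site, year = grid$year,
               age_group = grid$age_group, cases = cases, person_years = py,
               stringsAsFactors = FALSE)
  })
}

.age_group_midpoints <- function(labels) {
  lo <- suppressWarnings(as.numeric(sub("[-+].*$", "", labels)))
  hi <- suppressWarnings(as.numeric(sub("^.*-", "", labels)))
  hi[grepl("\\+$", labels)] <- lo[grepl("\\+$", labels)] + 4
  if (anyNA(lo)) .stopf("age-group labels must look like '10-14' or '85+'")
  (lo + hi + 1) / 2
}

#' Write / read a patient cohort as CSV
#'
#' One row per patient with the columns produced by [simulate_cohort()].
#'
#' @param cohort A cohort `data.frame`.
#' @param path File path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the validated cohort `data.frame`.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(.validate_cohort(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  .validate_cohort(utils::read.csv(path, stringsAsFactors = FALSE))
}

.validate_cohort <- function(df, end_of_followup = 2021) {
  need <- c("country", "site", "diagnosis_year", "age_at_diagnosis",
            "follow_up_years", "event")
  if (!all(need %in% names(df))) {
    .stopf("cohort must have columns %s", paste(need, collapse = ", "))
  }
  if (any(df$age_at_diagnosis < 0 | df$age_at_diagnosis > 89)) {
    .stopf("ages at diagnosis must lie in 0-89")
  }
  if (any(df$follow_up_years < 0)) .stopf("follow-up times must be non-negative")
  if (any(df$diagnosis_year + df$follow_up_years > end_of_followup + 1e-6)) {
    .stopf("follow-up extends beyond the administrative censoring horizon (%s)",
           format(end_of_followup))
  }
  if (!all(df$event %in% c("death", "censored"))) {
    .stopf("`event` must be 'death' or 'censored'")
  }
  df
}

#' Write a scenario/pipeline configuration as structured text (JSON)
#'
#' @param config Named list (must include `seed`).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_config_json <- function(config, path) {
  if (is.null(config$seed)) .stopf("configuration must include a `seed`")
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
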