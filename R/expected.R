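# Expected (background) survival of patients along their attained-age /
# calendar path, from a life table. The background hazard is piecewise
# constant on follow-up years: during follow-up year k the hazard is that of
# age (age_at_diagnosis + k) in calendar year (floor(diagnosis_year) + k) --
# the same convention the simulator uses, so the estimator sees exactly the
# background mortality the synthetic patients experienced.

# Internal: annual background hazard paths for a cohort.
# Returns haz (n x K matrix: hazard during follow-up year k = 1..K) and
# cum (n x (K+1): cumulative hazard at integer follow-up times 0..K).
.expected_hazard_paths <- function(patients, lifetable, horizon) {
  n <- nrow(patients)
  K <- as.integer(ceiling(horizon + 1e-9))
  age <- patients$age_at_diagnosis
  y0 <- floor(patients$diagnosis_year)
  haz <- matrix(0, n, K)
  for (k in seq_len(K)) {
    haz[, k] <- life_table_hazard(lifetable, age + (k - 1L), y0 + (k - 1L))
  }
  cum <- matrix(0, n, K + 1L)
  for (k in seq_len(K)) cum[, k + 1L] <- cum[, k] + haz[, k]
  list(haz = haz, cum = cum, K = K)
}

# Internal: cumulative expected hazard at arbitrary follow-up times s (vector,
# one per patient) given precomputed paths.
.cum_expected_at <- function(paths, s) {
  k <- pmin(floor(s + 1e-12), paths$K - 1L)
  k <- pmax(k, 0)
  idx <- cbind(seq_along(s), k + 1L)
  paths$cum[idx] + (s - k) * paths$haz[idx]
}

#' Cumulative expected (background) hazard of patients
#'
#' Integrates the life-table hazard along each patient's attained-age /
#' calendar path from diagnosis to `min(t, follow_up_years)` (or to `t`
#' regardless of follow-up when `cap_at_followup = FALSE`). Expected survival
#' is `exp(-`result`)`.
#'
#' @param patients Cohort `data.frame` (see [simulate_cohort()]).
#' @param lifetable A `life_table`.
#' @param t Follow-up horizon in years (>= 0).
#' @param cap_at_followup Stop integrating at each patient's observed
#'   follow-up (default TRUE).
#' @return Numeric vector of cumulative expected hazards, one per patient.
#' @export
cumulative_expected_hazard <- function(patients, lifetable, t,
                                       cap_at_followup = TRUE) {
  if (t < 0) .stopf("`t` must be non-negative")
  patients <- .validate_cohort(patients)
  if (nrow(patients) == 0L) return(numeric(0))
  if (t == 0) return(numeric(nrow(patients)))
  paths <- .expected_hazard_paths(patients, lifetable, t)
  s <- if (cap_at_followup) pmin(t, patients$follow_up_years) else rep(t, nrow(patients))
  .cum_expected_at(paths, s)
}

#' Expected survival of patients
#'
#' `exp(-`[cumulative_expected_hazard()]`)`.
#' @inheritParams cumulative_expected_hazard
#' @return Numeric vector of expected survival probabilities.
#' @export
expected_survival <- function(patients, lifetable, t, cap_at_followup = TRUE) {
  exp(-cumulative_expected_hazard(patients, lifetable, t, cap_at_followup))
}
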