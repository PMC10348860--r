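# Period-wise survival series: cohort analysis for completed 5-year diagnosis
# periods and a hybrid period/cohort analysis for the most recent period,
# where follow-up is restricted (by left truncation and right censoring) to
# the person-time falling inside the recent calendar window, so that recent
# diagnoses inform early follow-up intervals and slightly older diagnoses the
# late intervals.

#' Default 5-year diagnosis period grid, 1971-2020
#'
#' @return A `data.frame` with `start`, `end` (inclusive calendar years),
#'   `label` and `midpoint` for the ten periods 1971-1975 ... 2016-2020.
#' @export
default_periods <- function() {
  start <- seq(1971L, 2016L, by = 5L)
  data.frame(start = start, end = start + 4L,
             label = .period_label(start, start + 4L),
             midpoint = start + 2, stringsAsFactors = FALSE)
}

#' Assemble a period-wise age-standardized net-survival series
#'
#' Periods 1-9 use the cohort method: all patients diagnosed in the period are
#' followed to `horizon` years. The final period uses a hybrid period/cohort
#' analysis: patients diagnosed in `hybrid_diagnosis_window` contribute only
#' the person-time their follow-up spends inside `hybrid_calendar_window`
#' (delayed entry at `max(0, window_start - diagnosis_year)`, right censoring
#' at the window end).
#'
#' A period with no eligible patients (or a failed estimate) yields an `NA`
#' row flagged `"no-patients"`; the series is always returned with one row per
#' period.
#'
#' @param patients Cohort `data.frame` for one country and site.
#' @param lifetable Matching `life_table`.
#' @param horizon Survival horizon in years (1 or 5 in the standard analysis).
#' @param weights [age_weights()] for external age standardization.
#' @param periods Period grid (default [default_periods()]).
#' @param hybrid_calendar_window Calendar window (decimal years, half-open) of
#'   the hybrid analysis; default `c(2016, 2021)`.
#' @param hybrid_diagnosis_window Diagnosis-year window (half-open) of patients
#'   entering the hybrid analysis; default `c(2012, 2021)`.
#' @param grid_step,conf_level Passed to [pohar_perme_net_survival()].
#' @return A `data.frame` of class `survival_series` with columns `country`,
#'   `site`, `period`, `midpoint`, `horizon`, `method` (`"cohort"`/`"hybrid"`),
#'   `n`, `estimate`, `se`, `ci_low`, `ci_high` (all on the % scale) and
#'   `flag`.
#' @export
assemble_period_series <- function(patients, lifetable, horizon,
                                   weights = default_age_weights(),
                                   periods = default_periods(),
                                   hybrid_calendar_window = c(2016, 2021),
                                   hybrid_diagnosis_window = c(2012, 2021),
                                   grid_step = 1 / 12, conf_level = 0.95) {
  patients <- .validate_cohort(patients)
  country <- unique(patients$country)
  site <- unique(patients$site)
  if (length(country) != 1L || length(site) != 1L) {
    .stopf("`patients` must contain a single country and site")
  }
  np <- nrow(periods)
  rows <- vector("list", np)
  for (i in seq_len(np)) {
    hybrid <- i == np
    if (!hybrid) {
      sel <- patients$diagnosis_year >= periods$start[i] &
        patients$diagnosis_year < periods$end[i] + 1
      sub <- patients[sel, , drop = FALSE]
      entry <- NULL
    } else {
      sel <- patients$diagnosis_year >= hybrid_diagnosis_window[1L] &
        patients$diagnosis_year < hybrid_diagnosis_window[2L]
      sub <- patients[sel, , drop = FALSE]
      if (nrow(sub) > 0L) {
        # right-censor at the calendar window end ...
        cap <- hybrid_calendar_window[2L] - sub$diagnosis_year
        capped <- sub$follow_up_years > cap
        sub$event[capped] <- "censored"
        sub$follow_up_years <- pmin(sub$follow_up_years, cap)
        # ... and enter the risk set when the window opens
        entry <- pmax(0, hybrid_calendar_window[1L] - sub$diagnosis_year)
        keep <- sub$follow_up_years > entry
        sub <- sub[keep, , drop = FALSE]
        entry <- entry[keep]
      } else {
        entry <- NULL
      }
    }
    est <- tryCatch(
      age_standardized_net_survival(sub, lifetable, t = horizon,
                                    weights = weights, entry = entry,
                                    grid_step = grid_step,
                                    conf_level = conf_level),
      error = function(e) NULL
    )
    rows[[i]] <- if (is.null(est)) {
      data.frame(country = country, site = site, period = periods$label[i],
                 midpoint = periods$midpoint[i], horizon = horizon,
                 method = if (hybrid) "hybrid" else "cohort",
                 n = nrow(sub), estimate = NA_real_, se = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, flag = "no-patients",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(country = country, site = site, period = periods$label[i],
                 midpoint = periods$midpoint[i], horizon = horizon,
                 method = if (hybrid) "hybrid" else "cohort",
                 n = est$n, estimate = 100 * est$estimate, se = 100 * est$se,
                 ci_low = 100 * est$ci[1L], ci_high = 100 * est$ci[2L],
                 flag = if (length(est$flags)) paste(est$flags, collapse = ";") else "",
                 stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("survival_series", "data.frame")
  out
}

#' Write / read a survival series as CSV
#'
#' Columns as produced by [assemble_period_series()].
#' @param series A `survival_series` (or compatible `data.frame`).
#' @param path File path.
#' @return `write_survival_series_csv` returns `path` invisibly;
#'   `read_survival_series_csv` returns the series `data.frame`.
#' @export
write_survival_series_csv <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival_series_csv
#' @export
read_survival_series_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  class(df) <- c("survival_series", "data.frame")
  df
}
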