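# Life tables: expected (background) mortality of the general population by
# attained age and calendar year. These drive the expected-survival weights of
# the net-survival estimator and the background cause in the simulator.

#' Build a synthetic national life table
#'
#' Constructs an annual life table from a Gompertz age gradient with a secular
#' (calendar-time) decline in mortality. The annual death probability is
#' \deqn{q(a, y) = 1 - \exp\{-h_0 e^{b a} e^{-c (y - y_0)}\}}
#' clamped to \eqn{[0, 0.999]}, with anchor year \eqn{y_0 = 1961}.
#'
#' This is a synthetic substitute for national life tables: it reproduces their
#' shape (exponential rise of mortality with age, slow secular improvement)
#' without matching any real population.
#'
#' @param country Country label.
#' @param baseline Baseline hazard \eqn{h_0} at age 0 in the anchor year
#'   (per year, >= 0; 0 gives an immortal population).
#' @param slope Gompertz log-hazard slope \eqn{b} per year of age (>= 0).
#' @param decline Secular decline rate \eqn{c} per calendar year (default 0).
#' @param ages Integer ages covered (default 0:99). Lookups above the maximum
#'   age clamp to the oldest age.
#' @param years Calendar years covered (default 1961:2020). Lookups outside
#'   clamp to the nearest covered year.
#' @param sex Sex label (default "female").
#' @param anchor_year Anchor for the secular trend (default 1961).
#' @return An object of class `life_table`: a list with `country`, `sex`,
#'   `ages`, `years` and a matrix `q` (ages x years) of annual death
#'   probabilities.
#' @examples
#' lt <- build_life_table("NO", baseline = 1e-4, slope = 0.09, decline = 0.005)
#' life_table_prob(lt, age = 70, year = 1990)
#' @export
build_life_table <- function(country, baseline, slope, decline = 0,
                             ages = 0:99, years = 1961:2020,
                             sex = "female", anchor_year = 1961) {
  if (!is.numeric(baseline) || length(baseline) != 1L || is.na(baseline) || baseline < 0) {
    .stopf("`baseline` must be a single non-negative number (got %s)", format(baseline))
  }
  if (!is.numeric(slope) || length(slope) != 1L || is.na(slope) || slope < 0) {
    .stopf("`slope` must be a single non-negative number (got %s)", format(slope))
  }
  haz <- outer(baseline * exp(slope * ages), exp(-decline * (years - anchor_year)))
  q <- .clamp(1 - exp(-haz), 0, 0.999)
  dimnames(q) <- list(age = ages, year = years)
  structure(
    list(country = country, sex = sex, ages = as.integer(ages),
         years = as.integer(years), q = q),
    class = "life_table"
  )
}

#' Construct a life table from explicit annual death probabilities
#'
#' @param country Country label.
#' @param q Matrix of annual death probabilities, rows = ages, columns = years.
#' @param ages,years Integer ages / calendar years labelling the rows / columns.
#' @param sex Sex label.
#' @return A `life_table` object (see [build_life_table()]).
#' @export
life_table <- function(country, q, ages, years, sex = "female") {
  q <- as.matrix(q)
  if (nrow(q) != length(ages) || ncol(q) != length(years)) {
    .stopf("life table dimensions (%d x %d) do not match ages (%d) x years (%d)",
           nrow(q), ncol(q), length(ages), length(years))
  }
  ok <- is.na(q) | (q >= 0 & q < 1)
  if (!all(ok)) .stopf("life-table probabilities must lie in [0, 1)")
  dimnames(q) <- list(age = ages, year = years)
  structure(
    list(country = country, sex = sex, ages = as.integer(ages),
         years = as.integer(years), q = q),
    class = "life_table"
  )
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("<life_table> %s (%s): ages %d-%d, years %d-%d\n",
              x$country, x$sex, min(x$ages), max(x$ages),
              min(x$years), max(x$years)))
  invisible(x)
}

#' Look up annual death probabilities
#'
#' Vectorized lookup of the annual death probability `q(age, year)`. Ages above
#' the table maximum clamp to the oldest age; years outside the covered range
#' clamp to the nearest covered year. A missing (`NA`) cell is an error naming
#' the gap.
#'
#' @param lt A `life_table`.
#' @param age,year Integer vectors (recycled to common length).
#' @return Numeric vector of annual death probabilities.
#' @export
life_table_prob <- function(lt, age, year) {
  stopifnot(inherits(lt, "life_table"))
  k <- max(length(age), length(year))
  age <- rep_len(as.integer(age), k)
  year <- rep_len(as.integer(year), k)
  ai <- match(.clamp(age, min(lt$ages), max(lt$ages)), lt$ages)
  yi <- match(.clamp(year, min(lt$years), max(lt$years)), lt$years)
  if (anyNA(ai) || anyNA(yi)) {
    bad <- which(is.na(ai) | is.na(yi))[1L]
    .stopf("life table for %s has no cell for age %d, year %d",
           lt$country, age[bad], year[bad])
  }
  q <- lt$q[cbind(ai, yi)]
  if (anyNA(q)) {
    bad <- which(is.na(q))[1L]
    .stopf("life table for %s has a missing value at age %d, year %d",
           lt$country, age[bad], year[bad])
  }
  q
}

# Annual background hazard (piecewise-constant within a life-table year):
# h = -log(1 - q).
life_table_hazard <- function(lt, age, year) {
  -log(1 - life_table_prob(lt, age, year))
}

#' Write / read a life table as CSV
#'
#' One row per (age, year) cell with columns `country`, `sex`, `age`, `year`,
#' `q` (annual death probability).
#'
#' @param lt A `life_table`.
#' @param path File path.
#' @return `write_life_table_csv` returns `path` invisibly;
#'   `read_life_table_csv` returns a `life_table`.
#' @export
write_life_table_csv <- function(lt, path) {
  stopifnot(inherits(lt, "life_table"))
  df <- expand.grid(age = lt$ages, year = lt$years, KEEP.OUT.ATTRS = FALSE)
  df <- data.frame(country = lt$country, sex = lt$sex, df,
                   q = as.vector(lt$q), stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_life_table_csv
#' @export
read_life_table_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("country", "sex", "age", "year", "q")
  if (!all(need %in% names(df))) {
    .stopf("life-table CSV must have columns %s", paste(need, collapse = ", "))
  }
  ages <- sort(unique(df$age))
  years <- sort(unique(df$year))
  q <- matrix(NA_real_, length(ages), length(years))
  q[cbind(match(df$age, ages), match(df$year, years))] <- df$q
  life_table(df$country[1L], q, ages, years, sex = df$sex[1L])
}
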