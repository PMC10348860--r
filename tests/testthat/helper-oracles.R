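# Independent brute-force oracles, written before the implementations they
# check and kept deliberately naive (scalar loops, no shared code with the
# package internals beyond the life-table container).

# Naive annual background hazard lookup with the package's clamping
# convention: age clamps to the oldest table age, year to the covered range.
oracle_annual_hazard <- function(lt, age, year) {
  age <- min(max(age, min(lt$ages)), max(lt$ages))
  year <- min(max(year, min(lt$years)), max(lt$years))
  q <- lt$q[match(age, lt$ages), match(year, lt$years)]
  -log(1 - q)
}

# Naive cumulative expected hazard from diagnosis to follow-up time s:
# piecewise-constant annual hazard; during follow-up year k the hazard is that
# of age (age + k) in calendar year (floor(dy) + k).
oracle_cumhaz <- function(lt, age, dy, s) {
  y0 <- floor(dy)
  total <- 0
  k <- 0
  while (s > 0) {
    step <- min(1, s)
    total <- total + step * oracle_annual_hazard(lt, age + k, y0 + k)
    s <- s - step
    k <- k + 1
  }
  total
}

# Literal term-by-term Pohar Perme estimator on the package's discretization:
# interval bounds = monthly grid union observed death times; weights
# 1/S_E fixed at the start of the enclosing month; product-limit factors
# (1 - D_w/Y_w) at exact death times; one expected-mortality factor
# (1 + E_w/Ybar_w) per month; variance sum(w^2 dN)/Y_w^2 over death times.
oracle_pp <- function(cohort, lt, t, entry = NULL, mult = NULL,
                      grid_step = 1 / 12) {
  n <- nrow(cohort)
  entry <- if (is.null(entry)) rep(0, n) else rep_len(entry, n)
  mult <- if (is.null(mult)) rep(1, n) else rep_len(mult, n)
  exit <- pmin(cohort$follow_up_years, t)
  status <- cohort$event == "death" & cohort$follow_up_years <= t
  keep <- which(exit > entry & mult > 0)

  bounds <- sort(unique(c(seq(0, t, by = grid_step), t)))
  S <- 1
  V <- 0
  for (m in seq_len(length(bounds) - 1)) {
    a <- bounds[m]; b <- bounds[m + 1]
    w <- numeric(n)
    for (i in keep) {
      w[i] <- mult[i] * exp(oracle_cumhaz(lt, cohort$age_at_diagnosis[i],
                                          cohort$diagnosis_year[i], a))
    }
    # deaths at their exact times within (a, b]
    dts <- sort(unique(exit[keep][status[keep] & exit[keep] > a & exit[keep] <= b]))
    for (s in dts) {
      Y <- 0; D <- 0; D2 <- 0
      for (i in keep) {
        if (entry[i] < s && exit[i] >= s) Y <- Y + w[i]
        if (status[i] && exit[i] == s && entry[i] < s) {
          D <- D + w[i]; D2 <- D2 + w[i]^2
        }
      }
      if (Y > 0) {
        S <- S * (1 - D / Y)
        V <- V + D2 / Y^2
      }
    }
    # one expected-mortality factor per interval
    Ew <- 0; PT <- 0
    for (i in keep) {
      rt <- max(0, min(exit[i], b) - max(entry[i], a))
      if (rt > 0) {
        k <- floor(a + 1e-12)
        hz <- oracle_annual_hazard(lt, cohort$age_at_diagnosis[i] + k,
                                   floor(cohort$diagnosis_year[i]) + k)
        Ew <- Ew + w[i] * hz * rt
        PT <- PT + w[i] * rt
      }
    }
    Ybar <- PT / (b - a)
    if (Ybar > 0) S <- S * (1 + Ew / Ybar)
  }
  list(estimate = S, var_cumhaz = V)
}

# Naive Kaplan-Meier at horizon t (deaths after t censored at t).
oracle_km <- function(times, death, t) {
  exit <- pmin(times, t)
  status <- death & times <= t
  S <- 1
  for (s in sort(unique(exit[status]))) {
    Y <- sum(exit >= s)
    d <- sum(status & exit == s)
    S <- S * (1 - d / Y)
  }
  S
}

# Textbook Cox-de Boor recursion for B-spline basis functions.
oracle_deboor <- function(x, knots, j, k) {
  if (k == 0) {
    return(as.numeric(knots[j] <= x & x < knots[j + 1]))
  }
  d1 <- knots[j + k] - knots[j]
  d2 <- knots[j + k + 1] - knots[j + 1]
  a <- if (d1 > 0) (x - knots[j]) / d1 * oracle_deboor(x, knots, j, k - 1) else 0
  b <- if (d2 > 0) (knots[j + k + 1] - x) / d2 * oracle_deboor(x, knots, j + 1, k - 1) else 0
  a + b
}

# Reinsch-algorithm route for the natural smoothing spline (Green & Silverman
# 1994, ch. 2): solve (R + lambda Q'Q) gamma = Q'y, f = y - lambda Q gamma.
# Algebraically identical to the package's K-matrix route, independent code.
oracle_reinsch <- function(x, y, lambda) {
  n <- length(x)
  h <- diff(x)
  Q <- matrix(0, n, n - 2)
  R <- matrix(0, n - 2, n - 2)
  for (j in 2:(n - 1)) {
    i <- j - 1
    Q[j - 1, i] <- 1 / h[j - 1]
    Q[j, i] <- -1 / h[j - 1] - 1 / h[j]
    Q[j + 1, i] <- 1 / h[j]
    R[i, i] <- (h[j - 1] + h[j]) / 3
    if (i < n - 2) R[i, i + 1] <- R[i + 1, i] <- h[j] / 6
  }
  gamma <- solve(R + lambda * crossprod(Q), crossprod(Q, y))
  as.numeric(y - lambda * Q %*% gamma)
}

# Hand-constructable cohorts ------------------------------------------------

# A cohort data.frame from raw vectors (defaults: one country/site, all
# diagnosed mid-1990 at age 60).
make_cohort <- function(follow_up, event,
                        diagnosis_year = 1990.5, age = 60,
                        country = "X", site = "s") {
  n <- length(follow_up)
  data.frame(country = country, site = site,
             diagnosis_year = rep_len(diagnosis_year, n),
             age_at_diagnosis = rep_len(as.integer(age), n),
             follow_up_years = follow_up,
             event = rep_len(event, n),
             stringsAsFactors = FALSE)
}

# Random small cohort for oracle-equivalence checks.
random_cohort <- function(n, seed, t_max = 6) {
  set.seed(seed)
  make_cohort(
    follow_up = round(stats::runif(n, 0.05, t_max), 3),
    event = sample(c("death", "censored"), n, replace = TRUE),
    diagnosis_year = round(stats::runif(n, 1975, 2014), 3),
    age = sample(35:89, n, replace = TRUE)
  )
}

# Constant-q life table via the Gompertz builder with zero slope/decline.
constant_q_life_table <- function(q, country = "X") {
  build_life_table(country, baseline = -log(1 - q), slope = 0)
}

zero_life_table <- function(country = "X") {
  build_life_table(country, baseline = 0, slope = 0)
}
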