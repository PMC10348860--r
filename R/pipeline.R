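# End-to-end orchestration: simulate -> rates -> estimate -> fit-trends ->
# detect -> report, writing CSV artifacts and vector figures with a manifest
# of content hashes. Every number a figure shows is also present in a CSV
# artifact.

#' Pipeline configuration
#'
#' Collects and validates every tunable of the end-to-end pipeline. `seed` is
#' mandatory; all randomness derives from it.
#'
#' @param seed Integer seed (mandatory).
#' @param outdir Output directory (created if absent).
#' @param countries,sites Subsets of the default scenario grid.
#' @param n_per_year Diagnoses per calendar year per (country, site).
#' @param years Diagnosis years (default 1971:2020).
#' @param horizons Survival horizons (default `c(1, 5)`).
#' @param basis_dim,n_draws,chains,warmup,priors GAM settings (see
#'   [fit_trend_gam()]).
#' @param cri_level Credible level for all detection rules (default 0.95).
#' @param min_run_window,min_run_break Run-length guards in years for change
#'   windows (default 5) and breakpoints (default 3).
#' @param scenarios Named list of [scenario_truth()] objects
#'   (`"<country>.<site>"`); default [default_scenarios()].
#' @param life_tables Either a named list of `life_table` objects per country,
#'   or a named list of CSV paths (`life_table_files`) to read; by default
#'   synthetic tables are built per country.
#' @param life_table_files Optional named character vector of life-table CSV
#'   paths per country; a missing file aborts the pipeline naming the input.
#' @param age_std_weights [age_weights()] table.
#' @param standard_population Standard population for rate standardization.
#' @param write_draws Also write full posterior draw matrices as CSV (large;
#'   default FALSE -- summaries are always written).
#' @param make_figures Write per-country figure PDFs (default TRUE).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, outdir,
                            countries = c("DK", "FI", "NO", "SE"),
                            sites = c("breast", "endometrial", "ovarian",
                                      "cervical", "vulvar"),
                            n_per_year = 200, years = 1971:2020,
                            horizons = c(1, 5), basis_dim = 8L,
                            n_draws = 2000L, chains = 2L, warmup = 500L,
                            priors = list(), cri_level = 0.95,
                            min_run_window = 5, min_run_break = 3,
                            scenarios = NULL, life_tables = NULL,
                            life_table_files = NULL,
                            age_std_weights = default_age_weights(),
                            standard_population = segi_world_standard(),
                            write_draws = FALSE, make_figures = TRUE) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    .stopf("`seed` is mandatory in a pipeline configuration")
  }
  stopifnot(cri_level > 0, cri_level < 1, min_run_window > 0, min_run_break > 0)
  cfg <- list(seed = as.integer(seed), outdir = outdir, countries = countries,
              sites = sites, n_per_year = n_per_year, years = years,
              horizons = horizons, basis_dim = basis_dim, n_draws = n_draws,
              chains = chains, warmup = warmup, priors = priors,
              cri_level = cri_level, min_run_window = min_run_window,
              min_run_break = min_run_break, scenarios = scenarios,
              life_tables = life_tables, life_table_files = life_table_files,
              age_std_weights = age_std_weights,
              standard_population = standard_population,
              write_draws = write_draws, make_figures = make_figures)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full survival-trend pipeline
#'
#' Executes, in order: `simulate` (cohorts + life tables), `rates`
#' (age-standardized incidence series), `estimate` (period-wise 1- and 5-year
#' age-standardized net survival), `fit` (Bayesian trend GAMs per site and
#' horizon, plus the conditional 5/1-year posterior), `detect` (change
#' windows and breakpoints for all three measures) and `report` (per-country
#' figures). Any stage failure removes the partial outputs of this run and
#' aborts with a stage-named error.
#'
#' @param config A [pipeline_config()].
#' @param until Last stage to run (default `"report"`).
#' @return Invisibly, the manifest: a `data.frame` with `file` (relative
#'   path), `stage` and `md5` for every artifact written.
#' @export
run_pipeline <- function(config, until = c("report", "detect", "fit",
                                           "estimate", "rates", "simulate")) {
  stopifnot(inherits(config, "pipeline_config"))
  until <- match.arg(until)
  stages <- c("simulate", "rates", "estimate", "fit", "detect", "report")
  stages <- stages[seq_len(match(until, stages))]
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  created <- character(0)
  manifest <- data.frame(file = character(0), stage = character(0),
                         stringsAsFactors = FALSE)
  t_stage <- function(name) message(sprintf("[nordsurv] stage %-9s %s",
                                            name, format(Sys.time(), "%H:%M:%S")))
  add <- function(path, stage) {
    created <<- c(created, path)
    manifest <<- rbind(manifest, data.frame(file = basename(path),
                                            stage = stage,
                                            stringsAsFactors = FALSE))
    path
  }
  env <- new.env(parent = emptyenv())
  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    t_stage(name)
    tryCatch(fun(), error = function(e) {
      unlink(created)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  run_stage("simulate", function() {
    env$scenarios <- config$scenarios %||%
      default_scenarios(config$countries, config$sites)
    env$life_tables <- .resolve_life_tables(config)
    env$cohorts <- list()
    for (cn in config$countries) {
      write_life_table_csv(env$life_tables[[cn]],
                           add(file.path(outdir, sprintf("life_table_%s.csv", cn)),
                               "simulate"))
      for (st in config$sites) {
        key <- paste(cn, st, sep = ".")
        sc <- env$scenarios[[key]]
        if (is.null(sc)) .stopf("no scenario for %s", key)
        coh <- simulate_cohort(sc, env$life_tables[[cn]], config$n_per_year,
                               years = config$years,
                               seed = config$seed + 1000L * match(cn, config$countries) +
                                 match(st, config$sites))
        env$cohorts[[key]] <- coh
        write_cohort_csv(coh, add(file.path(outdir,
                                            sprintf("cohort_%s_%s.csv", cn, st)),
                                  "simulate"))
      }
    }
    write_config_json(list(seed = config$seed, countries = config$countries,
                           sites = config$sites, n_per_year = config$n_per_year,
                           horizons = config$horizons,
                           basis_dim = config$basis_dim,
                           n_draws = config$n_draws,
                           cri_level = config$cri_level,
                           min_run_window = config$min_run_window,
                           min_run_break = config$min_run_break),
                      add(file.path(outdir, "config.json"), "simulate"))
  })

  run_stage("rates", function() {
    base_rate <- c(breast = 70, endometrial = 20, ovarian = 15,
                   cervical = 12, vulvar = 2) # per 1e5 at age ~60, synthetic
    out <- list()
    for (cn in config$countries) {
      for (st in config$sites) {
        lvl <- if (st %in% names(base_rate)) base_rate[[st]] else 10
        rate <- local({
          lvl <- lvl
          function(a, y) {
            lvl * 1e-5 * exp(0.05 * (a - 60)) * (1 + 0.006 * (y - 1961))
          }
        })
        rs <- simulate_rate_series(cn, st, rate, person_years = 2e5,
                                   seed = config$seed + 77L +
                                     match(cn, config$countries) +
                                     10L * match(st, config$sites))
        out[[paste(cn, st)]] <- asr_series(rs, config$standard_population)
      }
    }
    utils::write.csv(do.call(rbind, out),
              add(file.path(outdir, "asr_series.csv"), "rates"),
              row.names = FALSE)
  })

  run_stage("estimate", function() {
    series <- list()
    for (key in names(env$cohorts)) {
      cn <- strsplit(key, ".", fixed = TRUE)[[1L]][1L]
      for (hz in config$horizons) {
        series[[paste(key, hz)]] <-
          assemble_period_series(env$cohorts[[key]], env$life_tables[[cn]],
                                 horizon = hz,
                                 weights = config$age_std_weights,
                                 conf_level = config$cri_level)
      }
    }
    env$series <- do.call(rbind, series)
    rownames(env$series) <- NULL
    write_survival_series_csv(env$series,
                              add(file.path(outdir, "survival_series.csv"),
                                  "estimate"))
  })

  run_stage("fit", function() {
    env$posteriors <- list() # [[site]][[measure]] -> list of tp per country
    summaries <- list()
    for (st in config$sites) {
      env$posteriors[[st]] <- list()
      for (hz in config$horizons) {
        measure <- sprintf("surv%d", hz)
        obs <- env$series[env$series$site == st & env$series$horizon == hz &
                            !is.na(env$series$estimate), ]
        tps <- fit_trend_gam(
          data.frame(country = obs$country, time = obs$midpoint,
                     value = obs$estimate, stringsAsFactors = FALSE),
          basis_dim = config$basis_dim, n_draws = config$n_draws,
          chains = config$chains, warmup = config$warmup,
          seed = config$seed + 31L * match(st, config$sites) + hz,
          priors = config$priors, site = st, measure = measure
        )
        env$posteriors[[st]][[measure]] <- tps
      }
      if (all(c(1, 5) %in% config$horizons)) {
        env$posteriors[[st]][["cond5_1"]] <- mapply(
          conditional_ratio, env$posteriors[[st]][["surv5"]],
          env$posteriors[[st]][["surv1"]], SIMPLIFY = FALSE
        )
      }
      for (measure in names(env$posteriors[[st]])) {
        for (tp in env$posteriors[[st]][[measure]]) {
          sm <- posterior_summary(tp, level = config$cri_level)
          summaries[[paste(st, measure, tp$country)]] <-
            data.frame(country = tp$country, site = st, measure = measure,
                       sm, stringsAsFactors = FALSE)
          if (config$write_draws) {
            utils::write.csv(t(tp$draws),
                      add(file.path(outdir, sprintf("draws_%s_%s_%s.csv",
                                                    tp$country, st, measure)),
                          "fit"), row.names = FALSE)
          }
        }
      }
    }
    env$trend_summaries <- do.call(rbind, summaries)
    rownames(env$trend_summaries) <- NULL
    utils::write.csv(env$trend_summaries,
              add(file.path(outdir, "trend_summaries.csv"), "fit"),
              row.names = FALSE)
  })

  run_stage("detect", function() {
    windows <- list(); breaks <- list(); deriv_sums <- list()
    for (st in names(env$posteriors)) {
      for (measure in names(env$posteriors[[st]])) {
        for (tp in env$posteriors[[st]][[measure]]) {
          d1 <- derivative_curves(tp, order = 1L, level = config$cri_level)
          d2 <- derivative_curves(tp, order = 2L, level = config$cri_level)
          w <- significant_change_windows(d1, min_years = config$min_run_window)
          b <- detect_breakpoints(d2, min_years = config$min_run_break)
          tag <- paste(tp$country, st, measure)
          if (nrow(w)) windows[[tag]] <-
            data.frame(country = tp$country, site = st, measure = measure,
                       type = "change_window", w, stringsAsFactors = FALSE)
          if (nrow(b)) breaks[[tag]] <-
            data.frame(country = tp$country, site = st, measure = measure,
                       type = "breakpoint", b, stringsAsFactors = FALSE)
          deriv_sums[[tag]] <-
            data.frame(country = tp$country, site = st, measure = measure,
                       time = d1$grid, mean = d1$mean, lower = d1$lower,
                       upper = d1$upper, stringsAsFactors = FALSE)
        }
      }
    }
    empty_w <- data.frame(country = character(0), site = character(0),
                          measure = character(0), type = character(0),
                          t_start = numeric(0), t_end = numeric(0),
                          direction = character(0), stringsAsFactors = FALSE)
    empty_b <- data.frame(country = character(0), site = character(0),
                          measure = character(0), type = character(0),
                          time = numeric(0), t_start = numeric(0),
                          t_end = numeric(0), curvature_sign = character(0),
                          stringsAsFactors = FALSE)
    env$windows <- if (length(windows)) do.call(rbind, windows) else empty_w
    env$breakpoints <- if (length(breaks)) do.call(rbind, breaks) else empty_b
    env$deriv_summaries <- do.call(rbind, deriv_sums)
    rownames(env$windows) <- rownames(env$breakpoints) <-
      rownames(env$deriv_summaries) <- NULL
    utils::write.csv(env$windows, add(file.path(outdir, "change_windows.csv"), "detect"),
              row.names = FALSE)
    utils::write.csv(env$breakpoints, add(file.path(outdir, "breakpoints.csv"), "detect"),
              row.names = FALSE)
    utils::write.csv(env$deriv_summaries,
              add(file.path(outdir, "annual_change_summaries.csv"), "detect"),
              row.names = FALSE)
  })

  run_stage("report", function() {
    if (!config$make_figures) return(invisible(NULL))
    for (cn in config$countries) {
      path <- add(file.path(outdir, sprintf("figure_%s.pdf", cn)), "report")
      .plot_country_figure(cn, env$trend_summaries, env$deriv_summaries,
                           env$breakpoints, env$windows, path)
      .scrub_pdf_dates(path)
    }
  })

  # content hashes; manifest written last, not listed in itself
  manifest$md5 <- unname(tools::md5sum(file.path(outdir, manifest$file)))
  manifest <- manifest[order(manifest$file), c("file", "stage", "md5")]
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

.resolve_life_tables <- function(config) {
  if (!is.null(config$life_tables)) return(config$life_tables)
  if (!is.null(config$life_table_files)) {
    out <- list()
    for (cn in config$countries) {
      p <- config$life_table_files[[cn]]
      if (is.null(p) || !file.exists(p)) {
        .stopf("life-table file for %s not found: %s", cn,
               if (is.null(p)) "<unset>" else p)
      }
      out[[cn]] <- read_life_table_csv(p)
    }
    return(out)
  }
  # synthetic defaults: Gompertz with mild secular decline
  out <- list()
  for (cn in config$countries) {
    out[[cn]] <- build_life_table(cn, baseline = 2.5e-5, slope = 0.095,
                                  decline = 0.01)
  }
  out
}

# Per-country two-page figure: survival curves with credible ribbons and
# breakpoint lines; annual-change curves drawn solid where the change is
# credibly nonzero (the >=95%-plausibility rule) and dashed elsewhere.
.plot_country_figure <- function(country, trend_summaries, deriv_summaries,
                                 breakpoints, windows, path) {
  ts <- trend_summaries[trend_summaries$country == country, ]
  ds <- deriv_summaries[deriv_summaries$country == country, ]
  bp <- breakpoints[breakpoints$country == country, , drop = FALSE]
  # mark significance of the annual change pointwise (solid vs dashed)
  ds$significant <- ds$lower > 0 | ds$upper < 0
  ds$segment <- with(ds, ave(as.numeric(significant),
                             paste(site, measure),
                             FUN = function(z) cumsum(c(1, diff(z) != 0))))
  p1 <- ggplot2::ggplot(ts, ggplot2::aes(x = time, y = mean, colour = measure,
                                         fill = measure)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lower, ymax = upper),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~site, scales = "free_y") +
    ggplot2::labs(title = sprintf("Relative survival, %s", country),
                  x = "Year of diagnosis", y = "Survival (%)") +
    ggplot2::theme_minimal()
  if (nrow(bp)) {
    p1 <- p1 + ggplot2::geom_vline(data = bp,
                                   ggplot2::aes(xintercept = time),
                                   linetype = 3, colour = "grey30")
  }
  p2 <- ggplot2::ggplot(ds, ggplot2::aes(x = time, y = mean, colour = measure,
                                         group = interaction(measure, segment))) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(ggplot2::aes(linetype = significant)) +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid", `FALSE` = "dashed"),
                                   name = ">95% plausibility") +
    ggplot2::facet_wrap(~site, scales = "free_y") +
    ggplot2::labs(title = sprintf("Estimated annual change, %s", country),
                  x = "Year of diagnosis", y = "Annual change (%-units/year)") +
    ggplot2::theme_minimal()
  grDevices::pdf(path, width = 10, height = 6, onefile = TRUE)
  on.exit(grDevices::dev.off())
  print(p1)
  print(p2)
  invisible(path)
}

# Overwrite the volatile /CreationDate and /ModDate digits a PDF device embeds
# so that identical plot content yields identical bytes (hash-stable
# manifests).
.scrub_pdf_dates <- function(path) {
  r <- readBin(path, "raw", n = file.info(path)$size)
  for (key in c("/CreationDate (D:", "/ModDate (D:")) {
    pat <- charToRaw(key)
    hits <- .raw_find(r, pat)
    for (h in hits) {
      i <- h + length(pat)
      while (i <= length(r) && r[i] >= charToRaw("0") && r[i] <= charToRaw("9")) {
        r[i] <- charToRaw("0")
        i <- i + 1L
      }
    }
  }
  writeBin(r, path)
  invisible(path)
}

.raw_find <- function(x, pat) {
  idx <- which(x == pat[1L])
  idx[vapply(idx, function(i) {
    i + length(pat) - 1L <= length(x) &&
      identical(x[i:(i + length(pat) - 1L)], pat)
  }, logical(1))]
}
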