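# End-to-end orchestration: compose and calibrate PM2.5 ensembles, fit and
# project death rates, evaluate attributable deaths per scenario-year, and
# expose state snapshots for decomposition, attainment scoring and
# intervention analysis.

#' Calibrated multi-model PM2.5 ensemble for one scenario
#'
#' Composes PM2.5 from each model's aerosol components year by year,
#' calibrates every model trajectory to the base-year observed grid, and
#' forms ensemble statistics.
#'
#' @param world a [generate_world()] result.
#' @param scenario scenario label.
#' @param method calibration dialect, `"ratio"` (default) or `"additive"`.
#' @param models optional model roster restriction.
#' @return List with `ensemble` (a `pm25_ensemble`) and `per_model`
#'   (calibrated trajectories).
#' @export
scenario_pm25 <- function(world, scenario, method = "ratio", models = NULL) {
  fields <- world$aerosol_fields[[scenario]]
  if (is.null(fields)) abort("scenario_pm25: unknown scenario '%s'", scenario)
  if (!is.null(models)) fields <- fields[models]
  calibrated <- lapply(fields, function(per_year) {
    sim <- lapply(per_year, compose_pm25)
    calibrate_trajectory(sim, world$observed_pm25_base,
                         world$config$base_year, method = method)
  })
  list(ensemble = ensemble_stats(calibrated), per_model = calibrated)
}

# death-rate table for one scenario covering all requested years: observed
# (generated) rates up to the base year, model projections beyond it
scenario_rates <- function(world, fit, residual_models, rates_all, scenario,
                           years) {
  by <- world$config$base_year
  hist_years <- years[years <= by]
  fut_years <- years[years > by]
  out <- list()
  if (length(hist_years)) {
    h <- rates_all[rates_all$scenario == scenario &
                   rates_all$year %in% hist_years, ]
    h <- h[, c("country", "year", "age_group", "disease", "rate")]
    h$rate_low <- h$rate; h$rate_high <- h$rate
    out$hist <- h
  }
  if (length(fut_years)) {
    sdi_f <- world$sdi[world$sdi$scenario == scenario,
                       c("country", "year", "sdi")]
    out$fut <- project_death_rates(fit, residual_models, sdi_f, fut_years)
  }
  do.call(rbind, out)
}

build_inputs <- function(world, curves, scenario, year, pm_grid, rates_df) {
  r <- rates_df[rates_df$year == year, ]
  burden_inputs(year = year, scenario = scenario, pm = pm_grid,
                pop = population_grid(world, scenario, year),
                age_fractions = age_fraction_table(world, scenario, year),
                death_rates = r, curves = curves,
                country_mask = world$country_mask,
                countries = world$countries)
}

#' Run the full burden projection
#'
#' Fits the death-rate model on the world's history (years up to the base
#' year, which coincide across scenarios), projects rates per scenario,
#' builds calibrated PM2.5 ensembles, and evaluates attributable deaths.
#' The headline series uses the ensemble-mean concentration with mid rates;
#' at `band_years` the 95 percent envelope is propagated from the model
#' spread crossed with the death-rate band, and the mean of per-model DAPP
#' is stored alongside the ensemble-mean-concentration DAPP (the two differ
#' because the attributable fraction is nonlinear in concentration).
#'
#' @param world a [generate_world()] result.
#' @param curves an `er_curve_set`, default [generate_rr_curves()].
#' @param scenarios scenario subset, default all configured.
#' @param years years to evaluate, default all configured.
#' @param band_years years at which the uncertainty envelope is computed
#'   (default: base year, 2030 and 2050 where covered).
#' @param calibration passed to [scenario_pm25()].
#' @param residual_order passed to [fit_residual_arima()].
#' @return Object of class `dapp_projection`.
#' @export
run_projection <- function(world, curves = generate_rr_curves(),
                           scenarios = world$config$scenarios,
                           years = world$config$years,
                           band_years = intersect(c(world$config$base_year,
                                                    2030, 2050), years),
                           calibration = "ratio",
                           residual_order = "auto") {
  stopifnot(inherits(world, "synthetic_world"))
  by <- world$config$base_year
  rates_all <- generate_death_rates(world)
  hist <- rates_all[rates_all$scenario == scenarios[1] &
                    rates_all$year <= by,
                    c("country", "year", "age_group", "disease", "rate")]
  sdi_hist <- world$sdi[world$sdi$scenario == scenarios[1],
                        c("country", "year", "sdi")]
  fit <- fit_mortality_model(hist, sdi_hist)
  residual_models <- fit_residual_arima(fit$residuals, order = residual_order)

  totals <- list(); country <- list(); shares <- list(); jensen <- list()
  pm <- list(); rates <- list()
  for (sc in scenarios) {
    pm_sc <- scenario_pm25(world, sc, method = calibration)
    pm[[sc]] <- pm_sc
    rates_sc <- scenario_rates(world, fit, residual_models, rates_all, sc,
                               years)
    rates[[sc]] <- rates_sc
    for (yr in years) {
      ykey <- as.character(yr)
      inp <- build_inputs(world, curves, sc, yr,
                          pm_sc$ensemble$mean[[ykey]], rates_sc)
      res <- compute_dapp(inp, "mid")
      totals[[length(totals) + 1L]] <-
        data.frame(scenario = sc, year = yr, band = "mid",
                   deaths = res$total)
      ag <- aggregate(res, "country")
      country[[length(country) + 1L]] <-
        data.frame(scenario = sc, year = yr, country = ag$scope_id,
                   deaths = ag$deaths)
      shares[[length(shares) + 1L]] <-
        data.frame(scenario = sc, year = yr, share65 = age_share(res, 65))
      if (yr %in% band_years) {
        per_model <- lapply(pm_sc$per_model, function(traj) {
          inp_m <- build_inputs(world, curves, sc, yr, traj[[ykey]],
                                rates_sc)
          list(low = compute_dapp(inp_m, "low"),
               mid = compute_dapp(inp_m, "mid"),
               high = compute_dapp(inp_m, "high"))
        })
        env <- propagate_uncertainty(per_model)
        totals[[length(totals) + 1L]] <-
          data.frame(scenario = sc, year = yr, band = c("low", "high"),
                     deaths = as.numeric(env[c("low", "high")]))
        jensen[[length(jensen) + 1L]] <-
          data.frame(scenario = sc, year = yr,
                     dapp_ensemble_mean_conc = res$total,
                     dapp_mean_over_models = as.numeric(env["mid"]))
      }
    }
  }
  structure(list(
    world = world, curves = curves, fit = fit,
    residual_models = residual_models,
    totals = do.call(rbind, totals),
    country = do.call(rbind, country),
    age_shares = do.call(rbind, shares),
    jensen = do.call(rbind, jensen),
    pm = pm, rates = rates,
    scenarios = scenarios, years = years, base_year = by
  ), class = "dapp_projection")
}

#' @export
print.dapp_projection <- function(x, ...) {
  cat(sprintf("<dapp_projection> %d scenario(s), years %d-%d, base %d\n",
              length(x$scenarios), min(x$years), max(x$years), x$base_year))
  base <- x$totals[x$totals$year == x$base_year & x$totals$band == "mid", ]
  for (i in seq_len(nrow(base)))
    cat(sprintf("  %s: %.0f attributable deaths in %d\n", base$scenario[i],
                base$deaths[i], x$base_year))
  invisible(x)
}

#' Factor-state snapshot of a projection
#'
#' Extracts the four substitutable factor blocks for one scenario-year,
#' for use in [decompose()] or intervention analyses.
#'
#' @param proj a [run_projection()] result.
#' @param scenario,year scenario label and calendar year.
#' @return A [factor_state()].
#' @export
projection_state <- function(proj, scenario, year) {
  stopifnot(inherits(proj, "dapp_projection"))
  rates <- proj$rates[[scenario]]
  factor_state(
    population = population_grid(proj$world, scenario, year),
    age_structure = age_fraction_table(proj$world, scenario, year),
    death_rate = rates[rates$year == year, ],
    concentration = proj$pm[[scenario]]$ensemble$mean[[as.character(year)]],
    period = year)
}

#' Decomposition frame of a projection
#' @param proj a [run_projection()] result.
#' @param band evaluation band.
#' @return A [decomp_frame()].
#' @export
projection_frame <- function(proj, band = "mid") {
  decomp_frame(proj$curves, proj$world$country_mask, proj$world$countries,
               band = band)
}

#' Decompose the projected change between two years
#'
#' @param proj a [run_projection()] result.
#' @param scenario scenario label.
#' @param year0,year1 period boundaries (default base year to 2030).
#' @param band evaluation band, default `"mid"`.
#' @return A [decompose()] result.
#' @export
decompose_projection <- function(proj, scenario, year0 = proj$base_year,
                                 year1 = 2030, band = "mid") {
  decompose(projection_state(proj, scenario, year0),
            projection_state(proj, scenario, year1),
            projection_frame(proj, band))
}

#' Intervention sensitivity analysis
#'
#' Evaluates the four intervention cells (no additional effort, additional
#' air-pollution control, additional healthcare, both) at a horizon year by
#' scaling concentrations and/or death rates and recomputing DAPP, and
#' reports each cell's change relative to the base year.
#'
#' @param proj a [run_projection()] result.
#' @param scenario scenario label.
#' @param year horizon year, default 2030.
#' @param pm_factor,rate_factor intervention multipliers, default 0.8
#'   (20 percent additional reduction).
#' @return Data frame `cell, pm_factor, rate_factor, deaths, change_pct`.
#' @export
intervention_analysis <- function(proj, scenario, year = 2030,
                                  pm_factor = 0.8, rate_factor = 0.8) {
  st <- projection_state(proj, scenario, year)
  frame <- projection_frame(proj)
  base_inp <- burden_inputs(year, scenario, st$concentration, st$population,
                            st$age_structure, st$death_rate, proj$curves,
                            proj$world$country_mask, proj$world$countries)
  base_total <- proj$totals[proj$totals$scenario == scenario &
                            proj$totals$year == proj$base_year &
                            proj$totals$band == "mid", "deaths"]
  cells <- list(
    none      = intervention_spec(1, 1),
    pm_only   = intervention_spec(pm_factor, 1),
    rate_only = intervention_spec(1, rate_factor),
    both      = intervention_spec(pm_factor, rate_factor))
  rows <- lapply(names(cells), function(nm) {
    sp <- cells[[nm]]
    total <- compute_dapp(apply_intervention(base_inp, sp), "mid")$total
    data.frame(cell = nm, pm_factor = sp$pm_factor,
               rate_factor = sp$rate_factor, deaths = total,
               change_pct = 100 * (total - base_total) / base_total)
  })
  do.call(rbind, rows)
}

#' SDG3.9 attainment of a projection
#'
#' @param proj a [run_projection()] result.
#' @param horizons horizon years, default 2030 and 2050 where covered.
#' @param thresholds named reduction thresholds, default [sdg_thresholds()].
#' @param scope `"global"` or `"country"`.
#' @return A [classify_attainment()] result with a `changes` element.
#' @export
attainment <- function(proj, horizons = intersect(c(2030, 2050), proj$years),
                       thresholds = sdg_thresholds(),
                       scope = c("global", "country")) {
  scope <- match.arg(scope)
  rows <- list()
  for (sc in proj$scenarios) {
    if (scope == "global") {
      ser <- proj$totals[proj$totals$scenario == sc &
                         proj$totals$band == "mid", ]
      for (hz in horizons)
        rows[[length(rows) + 1L]] <- data.frame(
          scope_id = "global", scenario = sc, horizon = hz,
          change = relative_change(stats::setNames(ser$deaths, ser$year),
                                   proj$base_year, hz))
    } else {
      ctab <- proj$country[proj$country$scenario == sc, ]
      for (cn in unique(ctab$country)) {
        ser <- ctab[ctab$country == cn, ]
        for (hz in horizons)
          rows[[length(rows) + 1L]] <- data.frame(
            scope_id = cn, scenario = sc, horizon = hz,
            change = relative_change(stats::setNames(ser$deaths, ser$year),
                                     proj$base_year, hz))
      }
    }
  }
  changes <- do.call(rbind, rows)
  out <- list()
  for (hz in horizons) {
    cls <- classify_attainment(changes[changes$horizon == hz, ], thresholds)
    out[[as.character(hz)]] <- cls
  }
  c(out, list(changes = changes))
}

#' Historical reduction distribution and data-driven target
#'
#' National percent reductions in attributable deaths over the historical
#' window (first projection year to base year) and the target derived from
#' their best-performing tail.
#'
#' @param proj a [run_projection()] result.
#' @param percentile performance percentile, default 10.
#' @return List with `reductions` (data frame `country, reduction_pct`) and
#'   `target` (percent).
#' @export
historical_target <- function(proj, percentile = 10) {
  sc <- proj$scenarios[1]
  ctab <- proj$country[proj$country$scenario == sc, ]
  y0 <- min(proj$years)
  red <- vapply(unique(ctab$country), function(cn) {
    ser <- ctab[ctab$country == cn, ]
    -relative_change(stats::setNames(ser$deaths, ser$year), y0,
                     proj$base_year)
  }, 0)
  list(reductions = data.frame(country = names(red),
                               reduction_pct = as.numeric(red),
                               row.names = NULL),
       target = derive_historical_target(red, percentile))
}
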