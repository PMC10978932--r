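# SDG3.9 attainment scoring, the data-driven target derivation, and the
# +/-20% intervention sensitivity analysis.

#' Default SDG3.9 ambition thresholds
#'
#' Weak, moderate and ambitious targets: 10, 20 and 30 percent reduction in
#' attributable deaths relative to the base year.
#'
#' @return Named numeric vector of positive reduction percentages.
#' @export
sdg_thresholds <- function() c(weak = 10, moderate = 20, ambitious = 30)

#' Relative change in attributable deaths
#'
#' `100 * (DAPP(target) - DAPP(base)) / DAPP(base)`.
#'
#' @param series named numeric vector of DAPP totals (names are years) or a
#'   data frame with columns `year` and `deaths`.
#' @param base_year,target_year years present in the series.
#' @return Percent change (negative = reduction).
#' @export
relative_change <- function(series, base_year, target_year) {
  if (is.data.frame(series))
    series <- stats::setNames(series$deaths, series$year)
  b <- unname(series[match(as.character(base_year), names(series))])
  t <- unname(series[match(as.character(target_year), names(series))])
  if (is.na(b) || is.na(t))
    abort("relative_change: year %s or %s not in series", base_year, target_year)
  if (b == 0) abort("relative_change: base-year DAPP is zero; change undefined")
  100 * (t - b) / b
}

#' Classify SDG3.9 attainment
#'
#' A threshold is met when the relative change is at most minus the
#' threshold (closed boundary: a change of exactly -20 percent meets the
#' moderate target). Counts, per scope, the number of scenarios meeting
#' each threshold.
#'
#' @param changes data frame `scope_id, scenario, change` (percent change
#'   vs the base year).
#' @param thresholds named positive percentages, default [sdg_thresholds()].
#' @return List with `report` (one row per scope/scenario with logical
#'   `met_<name>` flags) and `counts` (per scope: scenarios met per
#'   threshold).
#' @export
classify_attainment <- function(changes, thresholds = sdg_thresholds()) {
  if (any(thresholds <= 0))
    abort("classify_attainment: thresholds must be positive percents")
  rep_df <- changes
  for (nm in names(thresholds))
    rep_df[[paste0("met_", nm)]] <- changes$change <= -thresholds[[nm]]
  counts <- do.call(rbind, lapply(split(rep_df, rep_df$scope_id), function(d) {
    row <- data.frame(scope_id = d$scope_id[1], n_scenarios = nrow(d))
    for (nm in names(thresholds))
      row[[paste0("n_met_", nm)]] <- sum(d[[paste0("met_", nm)]])
    row
  }))
  rownames(counts) <- NULL
  list(report = rep_df, counts = counts)
}

#' Derive a data-driven reduction target from historical performance
#'
#' Takes the stated percentile of the best-performing tail of the national
#' reduction distribution (the "top 10th percentile of performance"
#' convention): with the default `percentile = 10` and `tail = "best"`,
#' this is the 90th percentile of the reductions, linearly interpolated on
#' the sorted values.
#'
#' @param reductions numeric vector of national percent reductions over the
#'   historical window (positive = reduction).
#' @param percentile performance percentile, default 10.
#' @param tail `"best"` (default) scores the top-performance tail;
#'   `"worst"` the opposite convention.
#' @return Positive percent reduction target.
#' @export
derive_historical_target <- function(reductions, percentile = 10,
                                     tail = c("best", "worst")) {
  tail <- match.arg(tail)
  if (!length(reductions)) abort("derive_historical_target: empty input")
  p <- if (tail == "best") 1 - percentile / 100 else percentile / 100
  stats::quantile(as.numeric(reductions), p, names = FALSE, type = 7)
}

#' Intervention specification
#'
#' Multiplicative interventions on the modifiable drivers: PM2.5
#' concentration (air-pollution control) and death rates (healthcare).
#'
#' @param pm_factor multiplier on concentrations, in (0, 1]; 0.8 encodes a
#'   20 percent reduction.
#' @param rate_factor multiplier on death rates, in (0, 1].
#' @param applied_to_bands also scale the low/high death-rate columns with
#'   the same multiplier (default `TRUE`).
#' @return Object of class `intervention_spec`.
#' @export
intervention_spec <- function(pm_factor = 1, rate_factor = 1,
                              applied_to_bands = TRUE) {
  if (pm_factor <= 0 || pm_factor > 1 || rate_factor <= 0 || rate_factor > 1)
    abort("intervention_spec: factors must lie in (0, 1]")
  structure(list(pm_factor = pm_factor, rate_factor = rate_factor,
                 applied_to_bands = applied_to_bands),
            class = "intervention_spec")
}

#' Apply an intervention to burden inputs
#'
#' Scales the concentration grid and/or death-rate columns; DAPP must then
#' be recomputed from the modified inputs, because the attributable
#' fraction is nonlinear in concentration.
#'
#' @param inputs a [burden_inputs()].
#' @param spec an [intervention_spec()].
#' @return Modified `burden_inputs`.
#' @export
apply_intervention <- function(inputs, spec) {
  stopifnot(inherits(inputs, "burden_inputs"), inherits(spec, "intervention_spec"))
  inputs$pm <- inputs$pm * spec$pm_factor
  cols <- "rate"
  if (spec$applied_to_bands)
    cols <- intersect(c("rate", "rate_low", "rate_high"),
                      names(inputs$death_rates))
  for (cc in cols)
    inputs$death_rates[[cc]] <- inputs$death_rates[[cc]] * spec$rate_factor
  inputs
}
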