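# Attributable-burden computation:
#   DAPP = sum over ages a and diseases d of
#          PAF_{a,d}(pm25_cell) * POP_cell * Rate_{a,d} * AgeP_a
# National death rates and age fractions are applied uniformly to all cells
# of a country; concentrations enter per cell.

#' Joined burden inputs for one scenario-year
#'
#' @param year calendar year.
#' @param scenario scenario label.
#' @param pm calibrated PM2.5 concentration grid (ug/m3).
#' @param pop population grid (persons), aligned with `pm`.
#' @param age_fractions data frame `country, age_group, fraction`; fractions
#'   sum to 1 within each country.
#' @param death_rates data frame `country, age_group, disease, rate` and
#'   optionally `rate_low, rate_high`.
#' @param curves an [curve_set()] with a curve for every (disease, age)
#'   pair in use.
#' @param country_mask integer grid of country indices (0 = ocean) aligned
#'   with `pm`.
#' @param countries character vector naming the mask indices.
#' @return Object of class `burden_inputs`.
#' @export
burden_inputs <- function(year, scenario, pm, pop, age_fractions,
                          death_rates, curves, country_mask, countries) {
  if (!identical(dim(pm), dim(pop)) || !identical(dim(pm), dim(country_mask)))
    abort("burden_inputs: pm, pop and country_mask grids must be aligned")
  if (any(pop < 0)) abort("burden_inputs: negative population")
  if (any(pm < 0)) abort("burden_inputs: negative concentration")
  used <- sort(unique(country_mask[pop > 0]))
  used <- used[used > 0]
  have_f <- unique(age_fractions$country)
  have_r <- unique(death_rates$country)
  for (ci in used) {
    cn <- countries[ci]
    if (!cn %in% have_f)
      abort("burden_inputs: no age fractions for populated country %s", cn)
    if (!cn %in% have_r)
      abort("burden_inputs: no death rates for populated country %s", cn)
  }
  sums <- tapply(age_fractions$fraction, age_fractions$country, sum)
  if (any(abs(sums - 1) > 1e-6))
    abort("burden_inputs: age fractions do not sum to 1 for %s",
          paste(names(sums)[abs(sums - 1) > 1e-6], collapse = ", "))
  structure(list(year = year, scenario = scenario, pm = pm, pop = pop,
                 age_fractions = age_fractions, death_rates = death_rates,
                 curves = curves, country_mask = country_mask,
                 countries = countries),
            class = "burden_inputs")
}

rate_column <- function(band) {
  switch(band, mid = "rate", low = "rate_low", high = "rate_high")
}

#' Compute deaths attributable to PM2.5 (DAPP)
#'
#' Evaluates the attributable-deaths sum per grid cell, age group and
#' disease, using each cell's country tables and the exposure-response
#' curve matching the (disease, age) pair (age-specific curves where they
#' exist, the all-ages curve otherwise). The same band label selects both
#' the curve band and the death-rate column.
#'
#' @param inputs a [burden_inputs()].
#' @param band `"mid"` (default), `"low"` or `"high"`.
#' @return Object of class `dapp_result`: `total` (deaths/year), `table`
#'   (data frame `country, age_group, disease, deaths`), `cell_total`
#'   (grid of deaths), and the year/scenario/band labels.
#' @export
compute_dapp <- function(inputs, band = "mid") {
  stopifnot(inherits(inputs, "burden_inputs"))
  band <- match.arg(band, c("mid", "low", "high"))
  rc <- rate_column(band)
  dr <- inputs$death_rates
  if (!rc %in% names(dr)) {
    if (band == "mid") abort("compute_dapp: death_rates lacks a 'rate' column")
    rc <- "rate"   # degenerate bands fall back to the mid rates
  }
  af <- inputs$age_fractions
  ages <- unique(af$age_group)
  dis <- unique(dr$disease)
  mask <- inputs$country_mask
  cell_total <- matrix(0, nrow(mask), ncol(mask))
  used <- sort(unique(mask[inputs$pop > 0])); used <- used[used > 0]

  # evaluate each distinct curve once over all populated cells
  pop_cells <- which(inputs$pop > 0)
  conc <- inputs$pm[pop_cells]
  paf_cache <- new.env(parent = emptyenv())
  paf_of <- function(d, a) {
    cu <- curve_for(inputs$curves, d, a)
    key <- paste(cu$disease, cu$age_group, sep = "|")
    got <- paf_cache[[key]]
    if (is.null(got)) {
      got <- compute_paf(evaluate_rr(cu, conc, band))
      paf_cache[[key]] <- got
    }
    got
  }
  fkey <- paste(af$country, af$age_group, sep = "\r")
  rkey <- paste(dr$country, dr$age_group, dr$disease, sep = "\r")
  cell_of_country <- lapply(used, function(ci) which(mask == ci & inputs$pop > 0))
  pos_in_conc <- lapply(cell_of_country, function(cells) match(cells, pop_cells))

  rows <- vector("list", length(used) * length(ages) * length(dis))
  k <- 0L
  for (u in seq_along(used)) {
    cn <- inputs$countries[used[u]]
    cells <- cell_of_country[[u]]
    pos <- pos_in_conc[[u]]
    popc <- inputs$pop[cells]
    for (a in ages) {
      frac <- af$fraction[match(paste(cn, a, sep = "\r"), fkey)]
      for (d in dis) {
        rate <- dr[[rc]][match(paste(cn, a, d, sep = "\r"), rkey)]
        if (is.na(rate))
          abort("compute_dapp: missing death rate for (%s, %s, %s)", cn, a, d)
        deaths_cells <- paf_of(d, a)[pos] * popc * rate * frac
        cell_total[cells] <- cell_total[cells] + deaths_cells
        k <- k + 1L
        rows[[k]] <- list(country = cn, age_group = a, disease = d,
                          deaths = sum(deaths_cells))
      }
    }
  }
  tab <- do.call(rbind.data.frame, c(rows[seq_len(k)],
                                     list(stringsAsFactors = FALSE)))
  structure(list(total = sum(tab$deaths), table = tab,
                 cell_total = cell_total, year = inputs$year,
                 scenario = inputs$scenario, band = band),
            class = "dapp_result")
}

#' @export
print.dapp_result <- function(x, ...) {
  cat(sprintf("<dapp_result> %s %s (%s band): %.0f attributable deaths/year\n",
              x$scenario, x$year, x$band, x$total))
  invisible(x)
}

#' Aggregate attributable deaths
#'
#' Exact sums of the per-country table at country, region or global scope.
#'
#' @param x a [compute_dapp()] result.
#' @param level `"country"`, `"region"` or `"global"`.
#' @param region_map data frame `country, region`; required for
#'   `level = "region"`.
#' @param ... unused.
#' @return Data frame `scope, scope_id, year, scenario, band, deaths`.
#' @export
aggregate.dapp_result <- function(x, level = c("country", "region", "global"),
                                  region_map = NULL, ...) {
  level <- match.arg(level)
  tab <- x$table
  id <- switch(level,
    country = tab$country,
    global = rep("global", nrow(tab)),
    region = {
      if (is.null(region_map))
        abort("aggregate: region_map required at region level")
      idx <- match(tab$country, region_map$country)
      if (anyNA(idx))
        abort("aggregate: unmapped country %s at region level",
              paste(unique(tab$country[is.na(idx)]), collapse = ", "))
      as.character(region_map$region[idx])
    })
  deaths <- tapply(tab$deaths, id, sum)
  data.frame(scope = level, scope_id = names(deaths), year = x$year,
             scenario = x$scenario, band = x$band,
             deaths = as.numeric(deaths), row.names = NULL)
}

#' Share of attributable deaths above an age threshold
#'
#' @param result a [compute_dapp()] result.
#' @param age_threshold age in years; must coincide with an age-group lower
#'   boundary (e.g. 65).
#' @return Fraction of total deaths in groups at or above the threshold.
#' @export
age_share <- function(result, age_threshold = 65) {
  stopifnot(inherits(result, "dapp_result"))
  lo <- unique(c(age_lower_bound(age_groups()),
                 age_lower_bound(unique(result$table$age_group))))
  if (!age_threshold %in% lo)
    abort("age_share: threshold %s does not align with an age-group boundary",
          age_threshold)
  tab <- result$table
  sum(tab$deaths[age_lower_bound(tab$age_group) >= age_threshold]) /
    sum(tab$deaths)
}

#' Propagate concentration and death-rate uncertainty to DAPP
#'
#' Combines per-climate-model DAPP results evaluated at each death-rate
#' band: the mid estimate is the mean over models at mid rates, the lower
#' bound the 2.5th percentile over models at low rates, and the upper bound
#' the 97.5th percentile over models at high rates.
#'
#' @param per_model_results list over models; each element a list with
#'   `dapp_result`s (or totals) named `low`, `mid`, `high` (degenerate
#'   bands may repeat the mid result).
#' @param probs lower/upper percentile probabilities.
#' @return Named numeric `c(low, mid, high)` total deaths/year.
#' @export
propagate_uncertainty <- function(per_model_results,
                                  probs = c(0.025, 0.975)) {
  if (!length(per_model_results)) abort("propagate_uncertainty: no models")
  tot <- function(x) if (inherits(x, "dapp_result")) x$total else as.numeric(x)
  g <- function(b) vapply(per_model_results, function(m) tot(m[[b]]), 0)
  lows <- g("low"); mids <- g("mid"); highs <- g("high")
  if (any(lows > mids + 1e-9) || any(mids > highs + 1e-9))
    abort("propagate_uncertainty: band ordering violated in inputs")
  out <- c(low = if (length(lows) > 1)
             stats::quantile(lows, probs[1], names = FALSE) else lows[[1]],
           mid = mean(mids),
           high = if (length(highs) > 1)
             stats::quantile(highs, probs[2], names = FALSE) else highs[[1]])
  out
}
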