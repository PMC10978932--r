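# Synthetic world generator: a self-contained grid-and-country world with
# the statistical structure the burden analysis assumes (multi-model
# aerosol trajectories, shifting age pyramids, SDI-driven death rates with
# known ground-truth parameters). Scenario defaults are expressed as
# interpretable anchors (population ratios, SDI increments, aging factors,
# PM2.5 ratios relative to the base year) and the generator solves for the
# underlying drivers.

#' Default scenario driver anchors
#'
#' One row per scenario. Anchors state, relative to the base year: the
#' population ratio, the SDI increment, the aging factor (the ratio of the
#' death-weighted age-structure sum, see the methods vignette) and the
#' population-weighted PM2.5 ratio, each at the 2030 and 2050 horizons.
#' The four defaults emulate a sustainability pathway (declining PM2.5,
#' fast socioeconomic development, strong aging), a middle-of-the-road
#' pathway, a regional-rivalry pathway (rising PM2.5, high population
#' growth, slow development) and a fossil-fuelled pathway (strong aging and
#' development with moderate air-quality gains).
#'
#' @return Data frame of scenario anchors.
#' @export
default_scenario_params <- function() {
  data.frame(
    scenario          = c("SSP1-2.6", "SSP2-4.5", "SSP3-7.0", "SSP5-8.5"),
    pm_ratio_2030     = c(0.69, 0.88, 1.12, 0.80),
    pm_ratio_2050     = c(0.62, 0.86, 1.30, 0.80),
    pm_tilt           = c(-0.30, 0.00, 0.75, -0.25),
    sdi_delta_2030    = c(0.146, 0.130, 0.102, 0.154),
    sdi_delta_2050    = c(0.200, 0.195, 0.165, 0.205),
    pop_ratio_2030    = c(1.06, 1.10, 1.14, 1.06),
    pop_ratio_2050    = c(1.08, 1.18, 1.28, 1.08),
    aging_factor_2030 = c(1.49, 1.43, 1.355, 1.50),
    aging_factor_2050 = c(1.70, 1.64, 1.56, 1.82),
    stringsAsFactors  = FALSE
  )
}

#' Synthetic world configuration
#'
#' @param n_countries number of countries (>= 2).
#' @param grid_shape `c(n_lat, n_lon)` cell counts.
#' @param cell_degrees grid resolution in degrees (default 1).
#' @param years inclusive run of calendar years (default 2000-2050).
#' @param base_year anchor year for observations and scenario divergence
#'   (default 2015); scenario drivers coincide before it.
#' @param n_models pseudo-climate-models per scenario.
#' @param scenarios scenario labels; must appear in `scenario_params`.
#' @param seed integer RNG seed.
#' @param scenario_params data frame of driver anchors, see
#'   [default_scenario_params()].
#' @param total_population world adult (25+) population in the base year,
#'   persons.
#' @param share65_2015 death share of ages 65+ in the base year used to
#'   anchor the age pyramid (default 0.65).
#' @param hist list of historical (first year relative to base year)
#'   anchors: `pop_ratio` (population ratio first-year/base), `aging_factor`
#'   (base relative to first year), `sdi_delta` range and `pm_rate` range
#'   (per-year log trend) across countries.
#' @param noise list of stochastic amplitudes: `model_offset_sd` (log-scale
#'   inter-model bias), `ar1_sd` and `ar1_phi` (year-to-year log-scale
#'   wiggle), `component_jitter_sd` (aerosol composition), `rate_sigma`
#'   (ln death-rate residual sd).
#' @return Object of class `world_config`.
#' @export
world_config <- function(n_countries = 12L,
                         grid_shape = c(20L, 40L),
                         cell_degrees = 1,
                         years = 2000:2050,
                         base_year = 2015L,
                         n_models = 5L,
                         scenarios = default_scenario_params()$scenario,
                         seed = 1L,
                         scenario_params = default_scenario_params(),
                         total_population = 4.2e9,
                         share65_2015 = 0.65,
                         hist = list(pop_ratio = 0.847,
                                     aging_factor = 1.08,
                                     sdi_delta = c(0.03, 0.13),
                                     pm_rate = c(-0.050, 0.008)),
                         noise = list(model_offset_sd = 0.05,
                                      ar1_sd = 0.02, ar1_phi = 0.6,
                                      component_jitter_sd = 0.10,
                                      rate_sigma = 0.05)) {
  if (length(grid_shape) != 2L || any(grid_shape < 3))
    abort("world_config: grid_shape must be two cell counts >= 3")
  if (n_countries < 2L) abort("world_config: need at least 2 countries")
  if (!length(scenarios)) abort("world_config: empty scenario list")
  if (!base_year %in% years)
    abort("world_config: base_year must lie within years")
  miss <- setdiff(scenarios, scenario_params$scenario)
  if (length(miss))
    abort("world_config: no driver anchors for scenario(s) %s",
          paste(miss, collapse = ", "))
  land_cells <- (grid_shape[1] - 2L) * (grid_shape[2] - 2L)
  if (land_cells < n_countries)
    abort("world_config: grid too small for %d countries (%d land cells)",
          n_countries, land_cells)
  structure(list(
    n_countries = as.integer(n_countries),
    grid_shape = as.integer(grid_shape),
    cell_degrees = cell_degrees,
    years = as.integer(years),
    base_year = as.integer(base_year),
    n_models = as.integer(n_models),
    scenarios = scenarios,
    seed = as.integer(seed),
    scenario_params = scenario_params,
    total_population = total_population,
    share65_2015 = share65_2015,
    hist = hist,
    noise = noise
  ), class = "world_config")
}

# ---- age-pyramid solvers -------------------------------------------------
# Pyramid: fraction of group a (index 0..14) proportional to exp(-lambda*a).
# Death weighting is Gompertz-like: relative rate exp(g*a). The
# death-weighted sum D(lambda) = sum_a p_a(lambda) exp(g*a) controls both
# the 65+ death share and the aging factor between two pyramid states.

gompertz_slope <- 0.43  # ln-rate increment per 5-year age group

# The age-specific curves attenuate relative risk at older ages, which
# tilts the age profile of *attributable* deaths slightly young of the
# all-cause Gompertz profile; the pyramid solvers use this effective slope
# so that configured death-share anchors refer to attributable deaths.
age_weight_correction <- 0.033

pyramid_fractions <- function(lambda, n_age = 15L) {
  w <- exp(-lambda * (seq_len(n_age) - 1))
  w / sum(w)
}

death_weight <- function(lambda, g = gompertz_slope - age_weight_correction,
                         n_age = 15L) {
  p <- pyramid_fractions(lambda, n_age)
  sum(p * exp(g * (seq_len(n_age) - 1)))
}

share65_of_lambda <- function(lambda,
                              g = gompertz_slope - age_weight_correction,
                              n_age = 15L) {
  p <- pyramid_fractions(lambda, n_age)
  w <- p * exp(g * (seq_len(n_age) - 1))
  sum(w[9:n_age]) / sum(w)   # groups with lower bound >= 65
}

solve_lambda_share65 <- function(target,
                                 g = gompertz_slope - age_weight_correction) {
  stats::uniroot(function(l) share65_of_lambda(l, g) - target,
                 interval = c(-2, 4), tol = 1e-12)$root
}

solve_lambda_aging <- function(lambda0, factor,
                               g = gompertz_slope - age_weight_correction) {
  d0 <- death_weight(lambda0, g)
  stats::uniroot(function(l) death_weight(l, g) / d0 - factor,
                 interval = c(-2, 4), tol = 1e-12)$root
}

# piecewise-linear interpolation through year anchors
anchor_path <- function(years, anchor_years, anchor_values) {
  stats::approx(anchor_years, anchor_values, xout = years, rule = 2)$y
}

# deterministic low-discrepancy permutation value in [0, 1] for country i
spread01 <- function(i, n, mult = 7L) {
  if (n == 1L) return(0.5)
  ((i * mult) %% n) / (n - 1)
}

# ---- generator -----------------------------------------------------------

#' Generate a synthetic world
#'
#' Builds the full synthetic state deterministically from the seed: country
#' mask (contiguous blocks of land cells, one-cell ocean border), per-year
#' national populations with fixed within-country spatial weights, shifting
#' age pyramids, SDI component series, ground-truth death-rate model
#' parameters, per-scenario/per-model aerosol component trajectories and a
#' base-year observed PM2.5 grid.
#'
#' @param config a [world_config()].
#' @return Object of class `synthetic_world`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  with_seed(config$seed, generate_world_impl(config))
}

generate_world_impl <- function(config) {
  nlat <- config$grid_shape[1]; nlon <- config$grid_shape[2]
  n <- config$n_countries
  years <- config$years
  by <- config$base_year
  scen <- config$scenarios
  sp <- config$scenario_params
  sp <- sp[match(scen, sp$scenario), , drop = FALSE]
  countries <- sprintf("C%02d", seq_len(n))
  ages <- age_groups(); n_age <- length(ages)
  dis <- diseases()

  # -- country mask: contiguous runs of land cells (column-major) ----------
  mask <- matrix(0L, nlat, nlon)
  land <- which(row(mask) > 1 & row(mask) < nlat &
                col(mask) > 1 & col(mask) < nlon)
  runs <- split(land, cut(seq_along(land), breaks = n, labels = FALSE))
  for (i in seq_len(n)) mask[runs[[i]]] <- i
  lat <- seq(-(nlat - 1) / 2, (nlat - 1) / 2) * config$cell_degrees
  lon <- seq(-(nlon - 1) / 2, (nlon - 1) / 2) * config$cell_degrees

  # -- static country attributes (deterministic spreads) -------------------
  pop_share <- exp(2 * vapply(seq_len(n), spread01, 0, n = n, mult = 5L) - 1)
  pop_share <- pop_share / sum(pop_share)
  sdi_2015 <- 0.48 + 0.37 * (seq_len(n) - 1) / (n - 1)
  hist_sdi <- config$hist$sdi_delta
  sdi_hist_delta <- hist_sdi[1] +
    diff(hist_sdi) * vapply(seq_len(n), spread01, 0, n = n, mult = 7L)
  pm_base <- 8 + 44 * vapply(seq_len(n), spread01, 0, n = n, mult = 11L)
  hist_pm <- config$hist$pm_rate
  pm_hist_rate <- hist_pm[1] +
    diff(hist_pm) * vapply(seq_len(n), spread01, 0, n = n, mult = 13L)
  sdi_mod <- 0.8 + 0.4 * vapply(seq_len(n), spread01, 0, n = n, mult = 3L)
  alpha_country <- 0.6 * vapply(seq_len(n), spread01, 0, n = n, mult = 9L) - 0.3

  # -- ground-truth death-rate model parameters ----------------------------
  a0 <- c(lung_cancer = -8.3, copd = -8.0, lri = -8.5, ihd = -7.1,
          stroke = -7.4, diabetes = -8.8)[dis]
  theta <- seq(-0.0025, -0.0015, length.out = n_age)
  names(theta) <- ages
  alpha <- expand.grid(region = countries, age_group = ages, disease = dis,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  alpha$alpha <- a0[alpha$disease] +
    gompertz_slope * (match(alpha$age_group, ages) - 1) +
    alpha_country[match(alpha$region, countries)]
  truth <- mortality_params(beta1 = -3, beta2 = -1, theta = theta,
                            alpha = alpha, ln_r = 0,
                            sigma = config$noise$rate_sigma,
                            knot = 0.8, t_ref = by)

  # -- SDI paths (history shared across scenarios) -------------------------
  last <- max(years); first <- min(years)
  sdi_rows <- list()
  for (s in seq_along(scen)) {
    delta30 <- sp$sdi_delta_2030[s]; delta50 <- sp$sdi_delta_2050[s]
    for (l in seq_len(n)) {
      av <- c(sdi_2015[l] - sdi_hist_delta[l], sdi_2015[l],
              sdi_2015[l] + delta30 * sdi_mod[l],
              sdi_2015[l] + delta50 * sdi_mod[l])
      path <- pmin(pmax(anchor_path(years, c(first, by, 2030, max(2050, last)),
                                    av), 0), 1)
      sdi_rows[[length(sdi_rows) + 1L]] <-
        data.frame(scenario = scen[s], country = countries[l], year = years,
                   sdi = path)
    }
  }
  sdi <- do.call(rbind, sdi_rows)
  b <- sdi_default_bounds()
  li <- log(b$income)
  sdi$income <- exp(li[1] + sdi$sdi * (li[2] - li[1]))
  sdi$education <- b$education[1] + sdi$sdi * diff(b$education)
  sdi$fertility <- b$fertility[2] - sdi$sdi * diff(b$fertility)

  # -- age pyramids --------------------------------------------------------
  lambda0 <- solve_lambda_share65(config$share65_2015)
  lambda_hist <- solve_lambda_aging(lambda0, 1 / config$hist$aging_factor)
  age_rows <- list()
  for (s in seq_along(scen)) {
    l30 <- solve_lambda_aging(lambda0, sp$aging_factor_2030[s])
    l50 <- solve_lambda_aging(lambda0, sp$aging_factor_2050[s])
    lam <- anchor_path(years, c(first, by, 2030, max(2050, last)),
                       c(lambda_hist, lambda0, l30, l50))
    fr <- vapply(lam, pyramid_fractions, numeric(n_age))  # n_age x n_years
    age_rows[[s]] <- data.frame(
      scenario = scen[s],
      year = rep(years, each = n_age),
      age_group = rep(ages, length(years)),
      fraction = as.numeric(fr))
  }
  age_fractions <- do.call(rbind, age_rows)  # shared by all countries

  # -- population ----------------------------------------------------------
  pop_2015 <- config$total_population * pop_share
  pop_totals <- list()  # [[scenario]] matrix years x countries
  for (s in seq_along(scen)) {
    ratio <- anchor_path(years, c(first, by, 2030, max(2050, last)),
                         c(config$hist$pop_ratio, 1,
                           sp$pop_ratio_2030[s], sp$pop_ratio_2050[s]))
    m <- outer(ratio, pop_2015)
    dimnames(m) <- list(years, countries)
    pop_totals[[scen[s]]] <- m
  }
  pop_weights <- matrix(0, nlat * nlon, 1)[, 0]  # placeholder removal
  pop_weights <- vector("list", n)
  for (l in seq_len(n)) {
    w <- stats::rgamma(length(runs[[l]]), shape = 2)
    pop_weights[[l]] <- w / sum(w)
  }

  # -- aerosol fields ------------------------------------------------------
  # per-cell base total PM2.5 with a within-country gradient, normalised so
  # the population-weighted national mean equals pm_base[l]
  base_total <- matrix(5, nlat, nlon)  # ocean background, flat trend
  for (l in seq_len(n)) {
    cells <- runs[[l]]
    ramp <- 0.7 + 0.6 * (seq_along(cells) - 1) / max(length(cells) - 1, 1)
    jit <- exp(stats::rnorm(length(cells), 0, 0.05))
    f <- ramp * jit
    f <- f / sum(pop_weights[[l]] * f)      # pop-weighted mean factor = 1
    base_total[cells] <- pm_base[l] * f
  }
  # aerosol composition shares (so4 counts with derived ammonium; sea salt
  # and dust enter the composition with factors 0.25 and 0.1)
  s0 <- c(bc = 0.07, oa = 0.38, so4 = 0.24, ss = 0.32, dust = 1.40)
  cw <- c(bc = 1, oa = 1, so4 = 1 + 36 / 96, ss = 0.25, dust = 0.1)
  jit <- lapply(s0, function(x)
    x * exp(stats::rnorm(nlat * nlon, 0, config$noise$component_jitter_sd)))
  denom <- Reduce(`+`, Map(function(j, w) j * w, jit, cw))
  shares <- lapply(jit, function(j) j / denom)  # sum_i shares_i * cw_i = 1

  # Per-country trend paths: history is country-specific; the future ratio
  # follows the scenario anchor with a pollution-control tilt (under strong
  # control the most polluted countries clean up faster; under weak control
  # they deteriorate faster), renormalised so the population-weighted mean
  # PM2.5 ratio equals the scenario anchor exactly.
  pm_rank <- 2 * (rank(pm_base) - 1) / (n - 1) - 1   # in [-1, 1]
  trend_grid <- function(s) {
    tilt <- exp(sp$pm_tilt[s] * pm_rank)
    wgt <- pop_share * pm_base
    tilt <- tilt / sum(wgt * tilt) * sum(wgt)
    tr <- matrix(1, length(years), n, dimnames = list(years, countries))
    for (l in seq_len(n)) {
      hist_ratio <- exp(pm_hist_rate[l] * (first - by))
      av <- c(hist_ratio, 1, sp$pm_ratio_2030[s] * tilt[l],
              sp$pm_ratio_2050[s] * tilt[l])
      tr[, l] <- exp(anchor_path(years, c(first, by, 2030, max(2050, last)),
                                 log(av)))
    }
    tr
  }
  model_offset <- exp(stats::rnorm(config$n_models, 0,
                                   config$noise$model_offset_sd))
  models <- sprintf("M%02d", seq_len(config$n_models))
  # one internal-variability draw per model, shared across scenarios so
  # that pre-base-year fields coincide exactly (scenarios differ by trend)
  phi <- config$noise$ar1_phi; sd1 <- config$noise$ar1_sd
  ar1 <- lapply(seq_len(config$n_models), function(m)
    as.numeric(stats::filter(stats::rnorm(length(years), 0,
                                          sd1 * sqrt(1 - phi^2)),
                             phi, method = "recursive")))
  cmask <- mask
  aerosol_fields <- list()
  for (s in seq_along(scen)) {
    tr <- trend_grid(s)
    per_model <- list()
    for (m in seq_len(config$n_models)) {
      e <- ar1[[m]]
      per_year <- vector("list", length(years))
      names(per_year) <- years
      for (t in seq_along(years)) {
        fac <- matrix(1, nlat, nlon)
        fac[cmask > 0] <- tr[t, cmask[cmask > 0]]
        total <- base_total * fac * model_offset[m] * exp(e[t])
        comp <- lapply(shares, function(sh)
          matrix(sh, nlat, nlon) * total)
        per_year[[t]] <- aerosol_components(
          bc = comp$bc, oa = comp$oa, so4 = comp$so4, ss = comp$ss,
          dust = comp$dust,
          nh4 = if (m <= 2) estimate_nh4(comp$so4) else NULL)
      }
      per_model[[models[m]]] <- per_year
    }
    aerosol_fields[[scen[s]]] <- per_model
  }

  structure(list(
    config = config,
    countries = countries,
    models = models,
    country_mask = mask,
    country_cells = runs,
    lat = lat, lon = lon,
    pop_totals = pop_totals,
    pop_weights = pop_weights,
    age_fractions = age_fractions,
    sdi = sdi,
    truth_mortality_params = truth,
    aerosol_fields = aerosol_fields,
    observed_pm25_base = base_total
  ), class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world> %d countries on a %dx%d grid, years %d-%d, %d scenarios x %d models\n",
    x$config$n_countries, x$config$grid_shape[1], x$config$grid_shape[2],
    min(x$config$years), max(x$config$years), length(x$config$scenarios),
    x$config$n_models))
  invisible(x)
}

#' Population grid for one scenario-year
#'
#' Distributes national totals over each country's cells with the fixed
#' within-country weights; ocean cells carry zero population.
#'
#' @param world a [generate_world()] result.
#' @param scenario scenario label.
#' @param year calendar year.
#' @return Matrix of person counts (adults 25+).
#' @export
population_grid <- function(world, scenario, year) {
  tot <- world$pop_totals[[scenario]]
  if (is.null(tot)) abort("population_grid: unknown scenario '%s'", scenario)
  yi <- match(as.character(year), rownames(tot))
  if (is.na(yi)) abort("population_grid: year %s not in world", year)
  g <- matrix(0, nrow(world$country_mask), ncol(world$country_mask))
  for (l in seq_along(world$countries))
    g[world$country_cells[[l]]] <- tot[yi, l] * world$pop_weights[[l]]
  g
}

#' Age-fraction table for one scenario-year
#'
#' @inheritParams population_grid
#' @return Data frame `country, age_group, fraction` (fractions sum to 1
#'   per country; pyramids are national-level and shared across countries).
#' @export
age_fraction_table <- function(world, scenario, year) {
  af <- world$age_fractions
  af <- af[af$scenario == scenario & af$year == year, ]
  if (!nrow(af)) abort("age_fraction_table: no pyramid for %s/%s",
                       scenario, year)
  out <- expand.grid(country = world$countries, age_group = af$age_group,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$fraction <- af$fraction[match(out$age_group, af$age_group)]
  out
}

#' Generate cause-specific death rates from the ground truth
#'
#' Rates are `exp(yhat + noise)` where yhat is the ground-truth linear
#' predictor evaluated on the world's SDI paths and the noise is Gaussian
#' on the ln scale with standard deviation `noise_scale`. The noise draw is
#' indexed by (country, year, age, disease) and shared across scenarios, so
#' scenario tables coincide for history years where drivers coincide.
#'
#' @param world a [generate_world()] result.
#' @param noise_scale ln-scale noise standard deviation (>= 0); default the
#'   world's configured residual sd.
#' @param seed RNG seed for the noise draw; derived from the world seed by
#'   default.
#' @return Data frame `scenario, country, year, age_group, disease, rate`
#'   (deaths per person-year).
#' @export
generate_death_rates <- function(world,
                                 noise_scale = world$config$noise$rate_sigma,
                                 seed = derive_seed(world$config$seed, 1L)) {
  stopifnot(inherits(world, "synthetic_world"))
  if (noise_scale < 0) abort("generate_death_rates: noise_scale must be >= 0")
  ages <- rownames(world$truth_mortality_params$theta)
  dis <- colnames(world$truth_mortality_params$theta)
  sdi <- world$sdi
  tab <- merge(sdi[, c("scenario", "country", "year", "sdi")],
               expand.grid(age_group = ages, disease = dis,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
  yhat <- predict_ln_rate(world$truth_mortality_params, tab)
  cells <- expand.grid(country = world$countries,
                       year = world$config$years, age_group = ages,
                       disease = dis, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  noise <- with_seed(seed, stats::rnorm(nrow(cells), 0, max(noise_scale, 1e-300)))
  if (noise_scale == 0) noise <- numeric(nrow(cells))
  key <- function(d) paste(d$country, d$year, d$age_group, d$disease, sep = "\r")
  tab$rate <- exp(yhat + noise[match(key(tab), key(cells))])
  tab[order(tab$scenario, tab$country, tab$year, tab$age_group, tab$disease),
      c("scenario", "country", "year", "age_group", "disease", "rate")]
}

# fixed shape parameters of the saturating relative-risk family per disease
rr_family_params <- function(d, i) {
  known <- list(
    ihd         = c(A = 1.30, s = 70, k = 1.00),
    stroke      = c(A = 1.10, s = 70, k = 1.00),
    copd        = c(A = 0.65, s = 65, k = 1.00),
    lri         = c(A = 0.80, s = 60, k = 1.00),
    lung_cancer = c(A = 0.70, s = 65, k = 1.00),
    diabetes    = c(A = 0.55, s = 55, k = 0.95)
  )
  if (!is.null(known[[d]])) known[[d]] else
    c(A = 0.5 + 0.2 * (i %% 7), s = 50 + 10 * (i %% 5), k = 0.9 + 0.05 * (i %% 3))
}

#' Generate tabulated exposure-response curves
#'
#' Curves follow the saturating family
#' `RR(c) = 1 + A * (1 - exp(-((c - cf)/s)^k))` for `c` above the
#' counterfactual `cf` (steep at low concentrations, levelling off at high
#' ones), sampled onto a knot grid. Diseases in `age_specific` get one
#' curve per age group with the amplitude attenuating at older ages; other
#' diseases get a single all-ages curve. Bands scale the amplitude by 0.85
#' (low) and 1.15 (high).
#'
#' @param diseases disease labels (non-empty).
#' @param age_specific subset of `diseases` with age-specific curves.
#' @param knots ascending concentration grid (ug/m3).
#' @param counterfactual concentration below which RR = 1 (default 2.5).
#' @return An `er_curve_set`.
#' @export
generate_rr_curves <- function(diseases = pm25burden::diseases(),
                               age_specific = age_specific_diseases(),
                               knots = c(0, 2.5, 5, 7.5, 10, 15, 20, 30, 45,
                                         60, 80, 105, 135, 170, 210),
                               counterfactual = 2.5) {
  if (!length(diseases)) abort("generate_rr_curves: empty disease list")
  bad <- setdiff(age_specific, diseases)
  if (length(bad))
    abort("generate_rr_curves: age_specific not a subset of diseases (%s)",
          paste(bad, collapse = ", "))
  ages <- age_groups()
  curve_of <- function(d, i, age, amp_mult) {
    p <- rr_family_params(d, i)
    shape <- 1 - exp(-(pmax(knots - counterfactual, 0) / p["s"])^p["k"])
    mk <- function(mult) 1 + p["A"] * amp_mult * mult * shape
    er_curve(d, age, knots, rr_mid = mk(1), rr_low = mk(0.85),
             rr_high = mk(1.15), counterfactual = counterfactual)
  }
  out <- list()
  for (i in seq_along(diseases)) {
    d <- diseases[i]
    if (d %in% age_specific) {
      for (a in seq_along(ages)) {
        amp <- 1.35 - 0.05 * (a - 1)  # risk attenuates at older ages
        out[[length(out) + 1L]] <- curve_of(d, i, ages[a], amp)
      }
    } else {
      out[[length(out) + 1L]] <- curve_of(d, i, "all", 1)
    }
  }
  curve_set(out)
}
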