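# shared fixtures built in code

tiny_config <- function(seed = 7L, ...) {
  world_config(n_countries = 4L, grid_shape = c(8L, 12L), years = 2005:2035,
               n_models = 3L, seed = seed, ...)
}

# built once per test run
tiny_world <- local({
  w <- NULL
  function() {
    if (is.null(w)) w <<- generate_world(tiny_config())
    w
  }
})

tiny_projection <- local({
  p <- NULL
  function() {
    if (is.null(p))
      p <<- run_projection(tiny_world(), years = c(2005, 2015, 2030),
                           band_years = c(2015, 2030))
    p
  }
})

# a flat relative-risk curve: RR = rr everywhere above 0
flat_curve <- function(disease, rr, age_group = "all") {
  er_curve(disease, age_group, knots = c(0, 300), rr_mid = c(rr, rr),
           counterfactual = 0)
}

# random monotone concave-ish curve for property tests
random_curve <- function(seed, disease = "d", age_group = "all") {
  set.seed(seed)
  knots <- c(0, sort(runif(6, 1, 120)))
  inc <- cumsum(runif(7, 0, 0.3))
  er_curve(disease, age_group, knots, rr_mid = 1 + inc,
           rr_low = 1 + 0.8 * inc, rr_high = 1 + 1.25 * inc,
           counterfactual = knots[1])
}

# hand-rolled single-country burden inputs on an n-cell strip
toy_inputs <- function(pop, rate, rr, conc = 10, n_cells = 1,
                       age_group = "95+", curves = NULL) {
  mask <- matrix(1L, 1, n_cells)
  pmg <- matrix(conc, 1, n_cells)
  popg <- matrix(pop / n_cells, 1, n_cells)
  if (is.null(curves)) curves <- curve_set(list(flat_curve("d", rr)))
  burden_inputs(
    year = 2015, scenario = "toy", pm = pmg, pop = popg,
    age_fractions = data.frame(country = "C1", age_group = age_group,
                               fraction = 1),
    death_rates = data.frame(country = "C1", age_group = age_group,
                             disease = "d", rate = rate),
    curves = curves, country_mask = mask, countries = "C1")
}

# independent brute-force DAPP oracle: plain nested loops over cells,
# ages, diseases with scalar curve interpolation
oracle_dapp <- function(inputs, band = "mid") {
  total <- 0
  af <- inputs$age_fractions; dr <- inputs$death_rates
  rc <- switch(band, mid = "rate", low = "rate_low", high = "rate_high")
  if (!rc %in% names(dr)) rc <- "rate"
  for (i in seq_along(inputs$pm)) {
    ci <- inputs$country_mask[i]
    if (ci == 0 || inputs$pop[i] == 0) next
    cn <- inputs$countries[ci]
    for (a in unique(af$age_group[af$country == cn])) {
      frac <- af$fraction[af$country == cn & af$age_group == a]
      for (d in unique(dr$disease[dr$country == cn])) {
        rate <- dr[[rc]][dr$country == cn & dr$age_group == a &
                         dr$disease == d]
        cu <- curve_for(inputs$curves, d, a)
        rr <- evaluate_rr(cu, inputs$pm[i], band)
        total <- total + (rr - 1) / rr * inputs$pop[i] * rate * frac
      }
    }
  }
  total
}

# random two-period decomposition instance on a small strip world
random_decomp_instance <- function(seed) {
  set.seed(seed)
  n_cells <- 4L
  mask <- matrix(rep(1:2, each = 2), 1, n_cells)
  countries <- c("C1", "C2")
  ages <- c("65-70", "95+")
  diseases <- c("d1", "d2")
  curves <- curve_set(list(random_curve(seed + 1000, "d1"),
                           random_curve(seed + 2000, "d2")))
  mk_state <- function(period) {
    af <- expand.grid(country = countries, age_group = ages,
                      stringsAsFactors = FALSE)
    af$fraction <- NA
    for (cn in countries) {
      f <- runif(2); f <- f / sum(f)
      af$fraction[af$country == cn] <- f
    }
    dr <- expand.grid(country = countries, age_group = ages,
                      disease = diseases, stringsAsFactors = FALSE)
    dr$rate <- runif(nrow(dr), 1e-4, 5e-2)
    factor_state(
      population = matrix(runif(n_cells, 1e4, 1e6), 1, n_cells),
      age_structure = af, death_rate = dr,
      concentration = matrix(runif(n_cells, 5, 90), 1, n_cells),
      period = period)
  }
  list(state0 = mk_state(0), state1 = mk_state(1),
       frame = decomp_frame(curves, mask, countries))
}

# closed-form Shapley value via subset enumeration (independent oracle)
shapley_oracle <- function(state0, state1, frame) {
  factors <- c("population", "age_structure", "death_rate", "concentration")
  v <- function(sw) {
    st <- state0
    for (f in sw) st[[f]] <- state1[[f]]
    inp <- burden_inputs(2015, "oracle", st$concentration, st$population,
                         st$age_structure, st$death_rate, frame$curves,
                         frame$country_mask, frame$countries)
    oracle_dapp(inp, frame$band)
  }
  n <- length(factors)
  subsets <- lapply(0:(2^n - 1), function(code)
    factors[bitwAnd(code, 2^(seq_len(n) - 1)) > 0])
  skey <- function(s) paste(c("S", sort(s)), collapse = ",")
  vals <- vapply(subsets, v, 0)
  names(vals) <- vapply(subsets, skey, "")
  phi <- numeric(n); names(phi) <- factors
  for (f in factors) {
    for (s in subsets) {
      if (f %in% s) next
      w <- factorial(length(s)) * factorial(n - length(s) - 1) / factorial(n)
      key0 <- skey(s)
      key1 <- skey(c(s, f))
      phi[f] <- phi[f] + w * (vals[[key1]] - vals[[key0]])
    }
  }
  phi
}
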