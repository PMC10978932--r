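test_that("identical configurations generate bit-identical worlds", {
  w1 <- generate_world(tiny_config(seed = 7))
  w2 <- generate_world(tiny_config(seed = 7))
  expect_identical(w1, w2)
  w3 <- generate_world(tiny_config(seed = 8))
  expect_false(identical(w1$observed_pm25_base, w3$observed_pm25_base))
})

test_that("country mask partitions land into the requested countries", {
  w <- generate_world(world_config(n_countries = 5, grid_shape = c(10, 20),
                                   years = 2010:2020, base_year = 2015,
                                   n_models = 2, seed = 1))
  labels <- sort(unique(as.integer(w$country_mask)))
  expect_identical(labels, 0:5)
  expect_identical(length(w$countries), 5L)
  # ocean border carries no population
  pop <- population_grid(w, w$config$scenarios[1], 2015)
  expect_true(all(pop[w$country_mask == 0] == 0))
})

test_that("configuration invariants are enforced", {
  expect_error(world_config(scenarios = character(0)), "empty scenario")
  expect_error(world_config(grid_shape = c(2, 2)), "grid_shape")
  expect_error(world_config(n_countries = 1), "2 countries")
  expect_error(world_config(years = 2000:2010, base_year = 2015),
               "base_year")
  expect_error(world_config(n_countries = 400, grid_shape = c(10, 10)),
               "too small")
})

test_that("age fractions are a probability distribution per country-year", {
  w <- tiny_world()
  sums <- tapply(w$age_fractions$fraction,
                 paste(w$age_fractions$scenario, w$age_fractions$year),
                 sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  af <- age_fraction_table(w, "SSP1-2.6", 2030)
  per_country <- tapply(af$fraction, af$country, sum)
  expect_true(all(abs(per_country - 1) < 1e-9))
})

test_that("national population equals the sum of its grid cells", {
  w <- tiny_world()
  for (yr in c(2005, 2015, 2035)) {
    pop <- population_grid(w, "SSP3-7.0", yr)
    for (l in seq_along(w$countries)) {
      expect_equal(sum(pop[w$country_cells[[l]]]),
                   w$pop_totals[["SSP3-7.0"]][as.character(yr),
                                              w$countries[l]],
                   tolerance = 1e-9)
    }
  }
})

test_that("scenario structure: sustainability PM declines, rivalry PM rises", {
  w <- tiny_world()
  pw_mean <- function(sc, yr) {
    pm <- scenario_pm25(w, sc)$ensemble$mean[[as.character(yr)]]
    pop <- population_grid(w, sc, yr)
    sum(pm * pop) / sum(pop)
  }
  expect_lt(pw_mean("SSP1-2.6", 2030), pw_mean("SSP1-2.6", 2015))
  expect_gt(pw_mean("SSP3-7.0", 2030), pw_mean("SSP3-7.0", 2015))
})

test_that("aerosol components are non-negative and compose consistently", {
  w <- tiny_world()
  comp <- w$aerosol_fields[["SSP1-2.6"]][["M01"]][["2015"]]
  for (v in c("bc", "oa", "so4", "ss", "dust"))
    expect_true(all(comp[[v]] >= 0))
  # models 1-2 ship ammonium explicitly at the ammonium-sulfate ratio
  expect_equal(comp$nh4, estimate_nh4(comp$so4))
  expect_null(w$aerosol_fields[["SSP1-2.6"]][["M03"]][["2015"]]$nh4)
})

test_that("zero-noise death rates equal the exact model surface", {
  w <- tiny_world()
  r0 <- generate_death_rates(w, noise_scale = 0)
  tab <- merge(r0, w$sdi[, c("scenario", "country", "year", "sdi")],
               by = c("scenario", "country", "year"))
  expect_equal(tab$rate,
               exp(predict_ln_rate(w$truth_mortality_params, tab)),
               tolerance = 1e-12)
  expect_error(generate_death_rates(w, noise_scale = -0.1), ">= 0")
})

test_that("death rates decline with SDI and rise with age in the truth model", {
  w <- tiny_world()
  tp <- w$truth_mortality_params
  row <- data.frame(country = "C01", year = 2015, age_group = "65-70",
                    disease = "ihd")
  y <- vapply(c(0.5, 0.6, 0.7, 0.85, 0.9),
              function(s) predict_ln_rate(tp, transform(row, sdi = s)), 0)
  expect_true(all(diff(y) < 0))
  ages <- age_groups()
  ya <- vapply(ages, function(a)
    predict_ln_rate(tp, data.frame(country = "C01", year = 2015,
                                   age_group = a, disease = "ihd",
                                   sdi = 0.6)), 0)
  expect_true(all(diff(ya) > 0))
})

test_that("noisy rate tables share the lognormal expectation surface", {
  cfg <- world_config(n_countries = 2, grid_shape = c(4, 6),
                      years = 2012:2018, base_year = 2015,
                      scenarios = "SSP2-4.5", n_models = 2, seed = 5)
  w <- generate_world(cfg)
  r0 <- generate_death_rates(w, noise_scale = 0)
  sigma <- 0.05
  acc <- 0
  n_rep <- 200
  for (i in seq_len(n_rep))
    acc <- acc + generate_death_rates(w, noise_scale = sigma, seed = i)$rate
  ratio <- (acc / n_rep) / r0$rate
  # mean of replicate averages approaches exp(sigma^2 / 2)
  expect_equal(mean(ratio), exp(sigma^2 / 2), tolerance = 5e-4)
  r_a <- generate_death_rates(w, noise_scale = sigma, seed = 1)
  r_b <- generate_death_rates(w, noise_scale = sigma, seed = 2)
  expect_false(identical(r_a$rate, r_b$rate))
})

test_that("generated curves satisfy the exposure-response contract", {
  set <- generate_rr_curves()
  # age-specific diseases: one curve per age group that differs across ages
  rr_ihd <- vapply(age_groups(), function(a)
    evaluate_rr(curve_for(set, "ihd", a), 50), 0)
  expect_gt(length(unique(rr_ihd)), 2)
  # other diseases: identical across ages (single all-ages curve)
  rr_copd <- vapply(age_groups(), function(a)
    evaluate_rr(curve_for(set, "copd", a), 50), 0)
  expect_identical(length(unique(rr_copd)), 1L)
  for (cu in set) {
    expect_identical(evaluate_rr(cu, 0), 1)
    expect_gte(evaluate_rr(cu, 100), evaluate_rr(cu, 10))
    expect_true(all(cu$rr_low <= cu$rr_mid & cu$rr_mid <= cu$rr_high))
  }
  expect_error(generate_rr_curves(character(0)), "empty")
  expect_error(generate_rr_curves("copd", age_specific = "ihd"), "subset")
})

test_that("history coincides across scenarios and diverges after the base year", {
  w <- tiny_world()
  r <- generate_death_rates(w, noise_scale = 0.05)
  h1 <- r[r$scenario == "SSP1-2.6" & r$year <= 2015, ]
  h3 <- r[r$scenario == "SSP3-7.0" & r$year <= 2015, ]
  expect_equal(h1$rate, h3$rate)
  f1 <- r[r$scenario == "SSP1-2.6" & r$year == 2030, ]
  f3 <- r[r$scenario == "SSP3-7.0" & r$year == 2030, ]
  expect_false(isTRUE(all.equal(f1$rate, f3$rate)))
})
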