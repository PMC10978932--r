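# small ground-truth model used across this file
mk_truth <- function(n_country = 6, n_age = 4, n_dis = 2, sigma = 0,
                     t_ref = 2014) {
  countries <- sprintf("C%d", seq_len(n_country))
  ages <- age_groups()[seq_len(n_age)]
  dis <- diseases()[seq_len(n_dis)]
  theta <- matrix(seq(-0.004, -0.001, length.out = n_age * n_dis),
                  n_age, n_dis, dimnames = list(ages, dis))
  alpha <- expand.grid(region = countries, age_group = ages, disease = dis,
                       stringsAsFactors = FALSE)
  alpha$alpha <- -6 + 0.4 * match(alpha$age_group, ages) -
    0.3 * match(alpha$disease, dis) + 0.1 * match(alpha$region, countries)
  mortality_params(beta1 = -3, beta2 = -1, theta = theta, alpha = alpha,
                   sigma = sigma, t_ref = t_ref)
}

mk_history <- function(truth, years = 2000:2014, sdi_lo = 0.5, sdi_hi = 0.95,
                       noise = 0, seed = 1) {
  countries <- unique(truth$alpha$region)
  sdi <- expand.grid(country = countries, year = years,
                     stringsAsFactors = FALSE)
  base <- seq(sdi_lo, sdi_hi, length.out = length(countries))
  # country-specific growth: a shared slope would be collinear with the
  # age-specific year trend once the intercepts are absorbed
  slope <- seq(0.002, 0.008, length.out = length(countries))
  i <- match(sdi$country, countries)
  sdi$sdi <- pmin(base[i] + slope[i] * (sdi$year - max(years)), 1)
  tab <- merge(sdi, expand.grid(age_group = rownames(truth$theta),
                                disease = colnames(truth$theta),
                                stringsAsFactors = FALSE))
  set.seed(seed)
  tab$rate <- exp(predict_ln_rate(truth, tab) +
                  stats::rnorm(nrow(tab), 0, max(noise, 1e-300)) *
                    (noise > 0))
  list(history = tab, sdi = sdi)
}

test_that("SDI scaling anchors, geometric mean and errors", {
  b <- sdi_default_bounds()
  expect_identical(compute_sdi(b$income[2], b$education[2], b$fertility[1]), 1)
  expect_identical(compute_sdi(b$income[1], b$education[1], b$fertility[2]), 0)
  # components each rescaling to 0.5
  inc <- exp(mean(log(b$income)))
  expect_equal(compute_sdi(inc, mean(b$education), mean(b$fertility)), 0.5)
  expect_error(compute_sdi(1000, 10, 1,
                           bounds = list(income = c(100, 100),
                                         education = c(0, 17),
                                         fertility = c(0, 3))), "width")
  expect_error(compute_sdi(-5, 10, 1), "positive")
})

test_that("noiseless data reproduces the generating parameters exactly", {
  truth <- mk_truth()
  d <- mk_history(truth, noise = 0)
  fit <- fit_mortality_model(d$history, d$sdi)
  expect_equal(fit$beta1, truth$beta1, tolerance = 1e-9)
  expect_equal(fit$beta2, truth$beta2, tolerance = 1e-9)
  expect_equal(fit$theta[rownames(truth$theta), colnames(truth$theta)],
               truth$theta, tolerance = 1e-8)
  a_fit <- fit$alpha[order(fit$alpha$region, fit$alpha$age_group,
                           fit$alpha$disease), ]
  a_tr <- truth$alpha[order(truth$alpha$region, truth$alpha$age_group,
                            truth$alpha$disease), ]
  expect_equal(a_fit$alpha, a_tr$alpha, tolerance = 1e-8)
  expect_lt(fit$sigma, 1e-9)
})

test_that("noisy recovery is unbiased within a few percent", {
  truth <- mk_truth(n_country = 20, n_age = 5, n_dis = 3)
  d <- mk_history(truth, years = 1995:2014, noise = 0.02, seed = 99)
  fit <- fit_mortality_model(d$history, d$sdi)
  expect_lt(abs(fit$beta1 / truth$beta1 - 1), 0.05)
  expect_lt(abs(fit$beta2 / truth$beta2 - 1), 0.05)
  expect_equal(fit$sigma, 0.02, tolerance = 0.1)
})

test_that("risk-factor offset is a pure reparameterisation", {
  truth <- mk_truth()
  d <- mk_history(truth, noise = 0.02, seed = 3)
  f0 <- fit_mortality_model(d$history, d$sdi, ln_r = 0)
  f1 <- fit_mortality_model(d$history, d$sdi, ln_r = 0.7)
  expect_equal(f1$alpha$alpha, f0$alpha$alpha - 0.7, tolerance = 1e-9)
  newd <- d$history[1:50, ]
  newd <- merge(newd, d$sdi, by = c("country", "year"))
  expect_equal(predict_ln_rate(f1, newd), predict_ln_rate(f0, newd),
               tolerance = 1e-9)
})

test_that("the linear predictor is continuous in SDI at the hinge", {
  truth <- mk_truth()
  d <- mk_history(truth, noise = 0.02, seed = 4)
  fit <- fit_mortality_model(d$history, d$sdi)
  row <- data.frame(country = "C1", year = 2010,
                    age_group = rownames(fit$theta)[1],
                    disease = colnames(fit$theta)[1])
  eps <- 1e-10
  y_lo <- predict_ln_rate(fit, transform(row, sdi = 0.8 - eps))
  y_hi <- predict_ln_rate(fit, transform(row, sdi = 0.8 + eps))
  expect_lt(abs(y_lo - y_hi), 1e-9)
})

test_that("degenerate designs raise identifiability errors", {
  truth <- mk_truth()
  d <- mk_history(truth, noise = 0)
  sdi_const <- d$sdi; sdi_const$sdi <- 0.6
  hist_const <- d$history
  hist_const$rate <- 1e-3
  expect_error(fit_mortality_model(hist_const, sdi_const), "SDI")
  # all SDI below the knot: the upper segment is unidentifiable
  d_lo <- mk_history(truth, sdi_lo = 0.3, sdi_hi = 0.6)
  expect_error(fit_mortality_model(d_lo$history, d_lo$sdi), "beta2")
})

test_that("ARIMA residual models: white noise, AR(1) recovery, zero series", {
  set.seed(7)
  mk_res <- function(x) data.frame(country = "C1", year = seq_along(x),
                                   age_group = "65-70", disease = "ihd",
                                   resid = x)
  rm_wn <- fit_residual_arima(mk_res(rnorm(60, 0, 0.05)))
  fc <- forecast_residual(rm_wn, "C1", "65-70", "ihd", 5)
  expect_true(all(abs(fc[2:5]) < 0.05))
  ar <- as.numeric(arima.sim(list(ar = 0.7), 200, sd = 0.05))
  rm_ar <- fit_residual_arima(mk_res(ar))
  m <- rm_ar$models[[1]]
  expect_identical(m$order[1], 1L)
  expect_lt(abs(m$fit$coef[["ar1"]] - 0.7), 0.15)
  rm_zero <- fit_residual_arima(mk_res(rep(0, 20)))
  expect_identical(forecast_residual(rm_zero, "C1", "65-70", "ihd", 3),
                   rep(0, 3))
  expect_error(fit_residual_arima(mk_res(c(1, NA, 3, 4, 5, 6, 7, 8, 9, 10))),
               "non-finite")
  expect_error(fit_residual_arima(mk_res(rnorm(5))), "fewer than 10")
})

test_that("projections: frozen drivers, SDI trend sign, band ordering", {
  countries <- c("C1", "C2")
  ages <- c("65-70", "95+")
  theta0 <- matrix(0, 2, 1, dimnames = list(ages, "ihd"))
  alpha <- expand.grid(region = countries, age_group = ages,
                       disease = "ihd", stringsAsFactors = FALSE)
  alpha$alpha <- -5
  frozen <- mortality_params(-3, -1, theta0, alpha, sigma = 0.05,
                             t_ref = 2015)
  sdi_const <- expand.grid(country = countries, year = 2015:2030,
                           stringsAsFactors = FALSE)
  sdi_const$sdi <- 0.6
  pr <- project_death_rates(frozen, NULL, sdi_const, 2016:2030)
  expect_equal(length(unique(round(pr$rate, 15))), 1)  # constant over horizon
  expect_true(all(pr$rate_low <= pr$rate & pr$rate <= pr$rate_high))
  # rising SDI with negative slopes: rates decline monotonically
  sdi_rise <- sdi_const
  sdi_rise$sdi <- 0.5 + 0.01 * (sdi_rise$year - 2015)
  pr2 <- project_death_rates(frozen, NULL, sdi_rise, 2016:2030)
  ser <- pr2$rate[pr2$country == "C1" & pr2$age_group == "65-70"]
  expect_true(all(diff(ser[order(pr2$year[pr2$country == "C1" &
                                          pr2$age_group == "65-70"])]) < 0))
  expect_error(project_death_rates(frozen, NULL, sdi_const, 2040),
               "cover")
})

test_that("projection at the reference year reproduces the fitted predictor", {
  truth <- mk_truth()
  d <- mk_history(truth, noise = 0.03, seed = 11)
  fit <- fit_mortality_model(d$history, d$sdi)
  rm <- fit_residual_arima(fit$residuals, order = c(1, 0, 0))
  pr <- project_death_rates(fit, rm, d$sdi, max(d$sdi$year))
  key <- function(df) paste(df$country, df$year, df$age_group, df$disease)
  m <- merge(pr, d$sdi, by = c("country", "year"))
  expect_equal(log(m$rate), predict_ln_rate(fit, m), tolerance = 1e-12)
})
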