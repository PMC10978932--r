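test_that("single-cell worked example: RR 2, rate 0.01, 1000 people -> 5 deaths", {
  inp <- toy_inputs(pop = 1000, rate = 0.01, rr = 2)
  res <- compute_dapp(inp)
  expect_identical(res$total, 5)   # 1000 x 0.01 x 0.5
})

test_that("concentration at the counterfactual yields zero deaths", {
  cu <- er_curve("d", "all", knots = c(5, 50), rr_mid = c(1, 2),
                 counterfactual = 5)
  inp <- toy_inputs(pop = 1e5, rate = 0.02, rr = 2, conc = 5,
                    curves = curve_set(list(cu)))
  expect_identical(compute_dapp(inp)$total, 0)
})

test_that("DAPP is exactly linear in population and death rates", {
  inp <- toy_inputs(pop = 12345, rate = 0.013, rr = 1.7, n_cells = 3)
  base <- compute_dapp(inp)
  inp2 <- inp; inp2$pop <- inp$pop * 2
  doubled <- compute_dapp(inp2)
  expect_equal(doubled$table$deaths, 2 * base$table$deaths, tolerance = 1e-15)
  expect_equal(doubled$cell_total, 2 * base$cell_total, tolerance = 1e-15)
  inp3 <- inp; inp3$death_rates$rate <- inp$death_rates$rate * 0.8
  expect_equal(compute_dapp(inp3)$total, 0.8 * base$total, tolerance = 1e-15)
})

test_that("cell deaths are non-decreasing in concentration", {
  cu <- random_curve(3)
  tot <- vapply(c(2, 10, 30, 60, 120), function(conc)
    compute_dapp(toy_inputs(1e5, 0.01, 2, conc = conc,
                            curves = curve_set(list(cu))))$total, 0)
  expect_true(all(diff(tot) >= 0))
})

test_that("burden matches a brute-force oracle on a random small grid", {
  ins <- random_decomp_instance(21)
  st <- ins$state0
  inp <- burden_inputs(2015, "t", st$concentration, st$population,
                       st$age_structure, st$death_rate, ins$frame$curves,
                       ins$frame$country_mask, ins$frame$countries)
  res <- compute_dapp(inp)
  expect_equal(res$total, oracle_dapp(inp), tolerance = 1e-12)
  expect_equal(sum(res$cell_total), res$total, tolerance = 1e-9)
  expect_equal(sum(res$table$deaths), res$total, tolerance = 1e-9)
})

test_that("aggregation sums exactly across scopes", {
  ins <- random_decomp_instance(22)
  st <- ins$state0
  inp <- burden_inputs(2015, "t", st$concentration, st$population,
                       st$age_structure, st$death_rate, ins$frame$curves,
                       ins$frame$country_mask, ins$frame$countries)
  res <- compute_dapp(inp)
  by_country <- aggregate(res, "country")
  glob <- aggregate(res, "global")
  expect_equal(sum(by_country$deaths), glob$deaths)
  rmap <- data.frame(country = c("C1", "C2"), region = c("R1", "R1"))
  by_region <- aggregate(res, "region", region_map = rmap)
  expect_equal(by_region$deaths, glob$deaths)
  expect_error(aggregate(res, "region"), "region_map")
  expect_error(aggregate(res, "region",
                         region_map = data.frame(country = "C1",
                                                 region = "R1")),
               "unmapped")
  # single-country world: country total equals global total
  one <- toy_inputs(pop = 5e4, rate = 0.01, rr = 1.5)
  r1 <- compute_dapp(one)
  expect_equal(aggregate(r1, "country")$deaths, aggregate(r1, "global")$deaths)
})

test_that("age share: degenerate, uniform and oracle cases", {
  # all deaths in the 95+ group
  expect_identical(age_share(compute_dapp(toy_inputs(1000, 0.01, 2)), 65), 1)
  # uniform deaths across the 15 groups -> 7/15 above 65
  ages <- age_groups()
  af <- data.frame(country = "C1", age_group = ages, fraction = 1 / 15)
  dr <- data.frame(country = "C1", age_group = ages, disease = "d",
                   rate = 0.01)
  inp <- burden_inputs(2015, "t", matrix(20), matrix(1e5), af, dr,
                       curve_set(list(flat_curve("d", 2))),
                       matrix(1L), "C1")
  res <- compute_dapp(inp)
  expect_equal(age_share(res, 65), 7 / 15, tolerance = 1e-12)
  expect_error(age_share(res, 67), "boundary")
  # random table vs direct filtered sum
  ins <- random_decomp_instance(23)
  st <- ins$state0
  inp2 <- burden_inputs(2015, "t", st$concentration, st$population,
                        st$age_structure, st$death_rate, ins$frame$curves,
                        ins$frame$country_mask, ins$frame$countries)
  r2 <- compute_dapp(inp2)
  direct <- sum(r2$table$deaths[r2$table$age_group == "95+"]) /
    sum(r2$table$deaths)
  expect_equal(age_share(r2, 95), direct)
})

test_that("missing inputs are reported with the offending pair", {
  ages <- c("65-70")
  af <- data.frame(country = "C1", age_group = ages, fraction = 1)
  dr <- data.frame(country = "C1", age_group = ages, disease = "d",
                   rate = 0.01)
  curves_wrong <- curve_set(list(flat_curve("other", 2)))
  inp <- burden_inputs(2015, "t", matrix(20), matrix(1000), af, dr,
                       curves_wrong, matrix(1L), "C1")
  expect_error(compute_dapp(inp), "'d'")
  expect_error(
    burden_inputs(2015, "t", matrix(20), matrix(1000), af,
                  dr[0, ], curves_wrong, matrix(1L), "C1"),
    "death rates")
  af_bad <- transform(af, fraction = 0.7)
  expect_error(
    burden_inputs(2015, "t", matrix(20), matrix(1000), af_bad, dr,
                  curves_wrong, matrix(1L), "C1"),
    "sum to 1")
})

test_that("uncertainty propagation: degenerate, ordered, and mean paths", {
  one <- list(list(low = 10, mid = 10, high = 10))
  expect_equal(unname(propagate_uncertainty(one)), c(10, 10, 10))
  set.seed(8)
  models <- lapply(1:11, function(i) {
    mid <- runif(1, 90, 110)
    list(low = mid - runif(1, 0, 10), mid = mid,
         high = mid + runif(1, 0, 10))
  })
  env <- propagate_uncertainty(models)
  expect_true(env["low"] <= env["mid"] && env["mid"] <= env["high"])
  # mid equals the explicit mean over models
  expect_equal(unname(env["mid"]),
               mean(vapply(models, function(m) m$mid, 0)))
  bad <- list(list(low = 5, mid = 4, high = 6))
  expect_error(propagate_uncertainty(bad), "ordering")
  expect_error(propagate_uncertainty(list()), "no models")
})

test_that("the ensemble-mean path and the per-model mean path differ (Jensen)", {
  cu <- random_curve(4)
  conc_a <- 10; conc_b <- 80
  mk <- function(conc) compute_dapp(
    toy_inputs(1e5, 0.01, 2, conc = conc, curves = curve_set(list(cu))))$total
  mean_conc_path <- mk((conc_a + conc_b) / 2)
  model_mean_path <- (mk(conc_a) + mk(conc_b)) / 2
  expect_false(isTRUE(all.equal(mean_conc_path, model_mean_path)))
})
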