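# Cause-specific death-rate model:
#   ln(m) ~ N(yhat + eps_forecast, sigma)
#   yhat  = beta1 * min(SDI, knot) + beta2 * max(SDI - knot, 0)
#           + theta[a, d] * (year - t_ref) + alpha[region, a, d] + ln(R)
# The hinge parameterisation makes yhat continuous in SDI at the knot by
# construction. eps_forecast comes from per-series ARIMA fits to the
# regression residuals.

#' Death-rate model parameters
#'
#' Parameter container for the log-linear death-rate model driven by the
#' Socio-Demographic Index (two-segment slope with a hinge at `knot`),
#' an age-specific secular trend, region-by-age(-by-cause) intercepts and a
#' scalar risk-factor offset `ln_r`.
#'
#' @param beta1 SDI slope below the knot (per unit SDI, ln-rate scale).
#' @param beta2 SDI slope at/above the knot.
#' @param theta secular trend per year: either a named vector by age group
#'   (recycled across diseases) or a matrix `age x disease` with dimnames.
#' @param alpha data frame with columns `region, age_group, disease, alpha`
#'   (ln-rate intercepts).
#' @param ln_r scalar risk-factor offset on the ln scale (default 0).
#' @param sigma residual standard deviation (>= 0).
#' @param knot SDI hinge location, default 0.8.
#' @param t_ref reference year at which the secular-trend term vanishes.
#' @param region_map optional data frame `country, region`; when absent,
#'   each country is its own region.
#' @return Object of class `mortality_params`.
#' @export
mortality_params <- function(beta1, beta2, theta, alpha, ln_r = 0,
                             sigma = 0, knot = 0.8, t_ref,
                             region_map = NULL) {
  if (sigma < 0) abort("mortality_params: sigma must be >= 0")
  if (is.null(dim(theta))) {
    if (is.null(names(theta))) abort("mortality_params: theta needs age names")
    theta <- matrix(theta, nrow = length(theta),
                    ncol = length(unique(alpha$disease)),
                    dimnames = list(names(theta), unique(alpha$disease)))
  }
  need <- c("region", "age_group", "disease", "alpha")
  if (!all(need %in% names(alpha)))
    abort("mortality_params: alpha must have columns %s",
          paste(need, collapse = ", "))
  structure(list(beta1 = beta1, beta2 = beta2, theta = theta,
                 alpha = alpha, ln_r = ln_r, sigma = sigma, knot = knot,
                 t_ref = t_ref, region_map = region_map),
            class = "mortality_params")
}

# map countries to regions (identity when no map supplied)
region_of <- function(params, country) {
  rm <- params$region_map
  if (is.null(rm)) return(as.character(country))
  idx <- match(as.character(country), rm$country)
  if (anyNA(idx))
    abort("region mapping missing for country %s",
          paste(unique(country[is.na(idx)]), collapse = ", "))
  as.character(rm$region[idx])
}

#' Linear predictor of the death-rate model
#'
#' Evaluates the deterministic part yhat of the model on a table of
#' observations.
#'
#' @param params a [mortality_params()] (or fitted `mortality_fit`).
#' @param newdata data frame with columns `country, year, age_group,
#'   disease, sdi`.
#' @return Numeric vector of yhat values (ln-rate scale).
#' @export
predict_ln_rate <- function(params, newdata) {
  stopifnot(inherits(params, "mortality_params"))
  region <- region_of(params, newdata$country)
  h1 <- pmin(newdata$sdi, params$knot)
  h2 <- pmax(newdata$sdi - params$knot, 0)
  th <- params$theta
  ti <- match(as.character(newdata$age_group), rownames(th))
  tj <- match(as.character(newdata$disease), colnames(th))
  if (anyNA(ti) || anyNA(tj))
    abort("predict_ln_rate: age group or disease not covered by theta")
  a <- params$alpha
  akey <- paste(a$region, a$age_group, a$disease, sep = "\r")
  ai <- match(paste(region, newdata$age_group, newdata$disease, sep = "\r"), akey)
  if (anyNA(ai)) {
    bad <- which(is.na(ai))[1]
    abort("predict_ln_rate: no intercept for (%s, %s, %s)",
          region[bad], newdata$age_group[bad], newdata$disease[bad])
  }
  params$beta1 * h1 + params$beta2 * h2 +
    th[cbind(ti, tj)] * (newdata$year - params$t_ref) +
    a$alpha[ai] + params$ln_r
}

#' Fit the death-rate model
#'
#' Least-squares fit of `ln(rate)` on the SDI hinge spline (continuity at
#' the knot enforced by the parameterisation), age-by-cause linear year
#' terms, and region-by-age-by-cause intercepts, with `ln_r` absorbed as a
#' supplied offset. The high-dimensional intercept block is absorbed by
#' within-group demeaning (Frisch-Waugh), so the solved system has only the
#' two SDI columns plus the trend columns.
#'
#' @param history data frame `country, year, age_group, disease, rate`
#'   with strictly positive rates; needs >= 2 regions, >= 2 age groups and
#'   >= 10 years.
#' @param sdi data frame `country, year, sdi`.
#' @param region_map optional data frame `country, region`.
#' @param ln_r known risk-factor offset (scalar, ln scale), default 0.
#' @param knot SDI hinge, default 0.8.
#' @param t_ref reference year for the trend term; defaults to the last
#'   history year so that a projection at that year reproduces the fit.
#' @return Object of class `c("mortality_fit", "mortality_params")` with
#'   elements `beta1, beta2, se_beta, theta, alpha, sigma, residuals`
#'   (data frame `country, region, year, age_group, disease, resid`) and
#'   the fit metadata.
#' @export
fit_mortality_model <- function(history, sdi, region_map = NULL, ln_r = 0,
                                knot = 0.8, t_ref = NULL) {
  need <- c("country", "year", "age_group", "disease", "rate")
  if (!all(need %in% names(history)))
    abort("fit_mortality_model: history must have columns %s",
          paste(need, collapse = ", "))
  if (any(history$rate <= 0))
    abort("fit_mortality_model: rates must be strictly positive")
  if (length(unique(history$year)) < 10)
    abort("fit_mortality_model: need >= 10 years of history")
  if (length(unique(history$age_group)) < 2)
    abort("fit_mortality_model: need >= 2 age groups")
  df <- merge(history[, need], sdi[, c("country", "year", "sdi")],
              by = c("country", "year"), sort = FALSE)
  if (nrow(df) != nrow(history))
    abort("fit_mortality_model: SDI series does not cover the history table")
  if (is.null(t_ref)) t_ref <- max(df$year)
  dummy <- mortality_params(0, 0,
                            theta = matrix(0, 1, 1, dimnames = list("x", "x")),
                            alpha = data.frame(region = "x", age_group = "x",
                                               disease = "x", alpha = 0),
                            region_map = region_map, t_ref = t_ref)
  df$region <- region_of(dummy, df$country)
  if (length(unique(df$region)) < 2)
    abort("fit_mortality_model: need >= 2 regions")

  y <- log(df$rate) - ln_r
  u <- df$year - t_ref
  g <- paste(df$region, df$age_group, df$disease, sep = "\r")
  ad <- paste(df$age_group, df$disease, sep = "\r")
  h1 <- pmin(df$sdi, knot)
  h2 <- pmax(df$sdi - knot, 0)

  dm <- function(x) x - stats::ave(x, g)
  yd <- dm(y); h1d <- dm(h1); h2d <- dm(h2); ud <- dm(u)
  ad_levels <- sort(unique(ad))
  Z <- matrix(0, nrow(df), length(ad_levels))
  Z[cbind(seq_len(nrow(df)), match(ad, ad_levels))] <- ud
  X <- cbind(sdi_lo = h1d, sdi_hi = h2d, Z)

  ssq <- colSums(X^2)
  if (ssq[1] < 1e-10)
    abort("fit_mortality_model: SDI below the knot is collinear with the region-age intercepts (SDI constant within regions?)")
  if (ssq[2] < 1e-10)
    abort("fit_mortality_model: no within-region variation in SDI above the knot %.2f; beta2 is not identifiable", knot)
  if (any(ssq[-(1:2)] < 1e-10))
    abort("fit_mortality_model: year term collinear with intercepts for some age-cause block")

  # normal equations; the demeaned design is well-conditioned and the
  # year-trend block is row-disjoint across age-cause groups
  xtx <- crossprod(X)
  ch <- tryCatch(chol(xtx), error = function(e)
    abort("fit_mortality_model: singular design (collinear SDI/trend block)"))
  xtx_inv <- chol2inv(ch)
  coefs <- drop(xtx_inv %*% crossprod(X, yd))
  beta1 <- coefs[[1]]; beta2 <- coefs[[2]]
  theta_flat <- coefs[-(1:2)]
  res <- yd - drop(X %*% coefs)

  n_groups <- length(unique(g))
  dof <- nrow(df) - ncol(X) - n_groups
  if (dof <= 0) abort("fit_mortality_model: not enough observations")
  sigma <- sqrt(sum(res^2) / dof)
  se_beta <- sigma * sqrt(diag(xtx_inv)[1:2])

  parts <- do.call(rbind, strsplit(ad_levels, "\r", fixed = TRUE))
  ages <- sort(unique(df$age_group))
  dis <- sort(unique(df$disease))
  theta <- matrix(NA_real_, length(ages), length(dis),
                  dimnames = list(ages, dis))
  theta[cbind(match(parts[, 1], ages), match(parts[, 2], dis))] <- theta_flat

  # recover absorbed intercepts from group means
  gm <- function(x) tapply(x, g, mean)
  keys <- names(gm(y))
  kp <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  th_g <- theta[cbind(match(kp[, 2], ages), match(kp[, 3], dis))]
  alpha_val <- gm(y) - beta1 * gm(h1) - beta2 * gm(h2) - th_g * gm(u)
  alpha <- data.frame(region = kp[, 1], age_group = kp[, 2], disease = kp[, 3],
                      alpha = as.numeric(alpha_val), row.names = NULL)

  out <- mortality_params(beta1, beta2, theta, alpha, ln_r = ln_r,
                          sigma = sigma, knot = knot, t_ref = t_ref,
                          region_map = region_map)
  out$se_beta <- c(beta1 = se_beta[[1]], beta2 = se_beta[[2]])
  # demeaned residuals equal full-model residuals: the intercepts absorb
  # the group means by construction
  out$residuals <- data.frame(country = df$country, region = df$region,
                              year = df$year, age_group = df$age_group,
                              disease = df$disease, resid = res)
  out$n_obs <- nrow(df)
  class(out) <- c("mortality_fit", class(out))
  out
}

#' @export
print.mortality_fit <- function(x, ...) {
  cat(sprintf(
    "<mortality_fit> beta1 = %.4f (se %.4f), beta2 = %.4f (se %.4f), sigma = %.4f, n = %d\n",
    x$beta1, x$se_beta[1], x$beta2, x$se_beta[2], x$sigma, x$n_obs))
  invisible(x)
}

arima_order_grid <- function() {
  list(c(0L, 0L, 0L), c(1L, 0L, 0L), c(0L, 1L, 0L), c(1L, 0L, 1L))
}

aicc <- function(fit, n) {
  k <- length(fit$coef) + 1  # + innovation variance
  stats::AIC(fit) + 2 * k * (k + 1) / max(n - k - 1, 1)
}

fit_one_arima <- function(x, order) {
  tryCatch(
    suppressWarnings(stats::arima(x, order = order, include.mean = FALSE,
                                  method = "ML")),
    error = function(e) NULL)
}

#' Fit ARIMA models to death-rate model residuals
#'
#' One model per residual series (country by age group by cause). With
#' `order = "auto"` the order is chosen per series by AICc over the small
#' grid (0,0,0), (1,0,0), (0,1,0), (1,0,1); a fixed order can be supplied
#' instead. Series are fitted without a mean term: residuals are centred by
#' construction, so forecasts revert to zero. Forecasts are additionally
#' damped geometrically (factor `damp` per step ahead) so that even
#' difference-order models cannot drift without bound.
#'
#' @param residuals data frame `country, year, age_group, disease, resid`
#'   (as returned in a `mortality_fit`); >= 10 residuals per series.
#' @param order `"auto"` or an integer vector `c(p, d, q)`.
#' @param damp geometric damping factor per forecast step, in (0, 1].
#' @return Object of class `residual_models`.
#' @export
fit_residual_arima <- function(residuals, order = "auto", damp = 0.95) {
  if (any(!is.finite(residuals$resid)))
    abort("fit_residual_arima: non-finite residuals")
  if (damp <= 0 || damp > 1) abort("fit_residual_arima: damp must be in (0, 1]")
  key <- paste(residuals$country, residuals$age_group, residuals$disease,
               sep = "\r")
  grid <- if (identical(order, "auto")) arima_order_grid() else
    list(as.integer(order))
  models <- lapply(split(residuals[, c("year", "resid")], key), function(d) {
    x <- d$resid[order(d$year)]
    if (length(x) < 10)
      abort("fit_residual_arima: series has fewer than 10 residuals")
    if (stats::sd(x) < 1e-12)
      return(list(order = c(0L, 0L, 0L), fit = NULL))
    best <- NULL; best_ic <- Inf; best_order <- c(0L, 0L, 0L)
    for (o in grid) {
      f <- fit_one_arima(x, o)
      if (is.null(f)) next
      ic <- aicc(f, length(x))
      if (ic < best_ic) { best <- f; best_ic <- ic; best_order <- o }
    }
    list(order = best_order, fit = best)
  })
  structure(list(models = models, damp = damp), class = "residual_models")
}

#' Forecast residuals for one series
#'
#' @param rm a [fit_residual_arima()] result.
#' @param country,age_group,disease series identifiers.
#' @param h forecast horizon (steps ahead, >= 1).
#' @return Numeric vector of damped residual forecasts, length `h`.
#' @export
forecast_residual <- function(rm, country, age_group, disease, h) {
  stopifnot(inherits(rm, "residual_models"))
  key <- paste(country, age_group, disease, sep = "\r")
  m <- rm$models[[key]]
  if (is.null(m)) abort("forecast_residual: unknown series (%s, %s, %s)",
                        country, age_group, disease)
  if (is.null(m$fit)) return(rep(0, h))
  as.numeric(stats::predict(m$fit, n.ahead = h)$pred) * rm$damp^(seq_len(h))
}

#' Project cause-specific death rates
#'
#' Combines the fitted linear predictor with per-series residual forecasts:
#' the mid rate is `exp(yhat + eps_hat)` and the nominal 95 percent band is
#' `exp(yhat + eps_hat -/+ 1.96 sigma)`; history years (at or before the
#' fit's reference year) carry no residual forecast.
#'
#' @param params a `mortality_fit` or [mortality_params()].
#' @param residual_models a [fit_residual_arima()] result, or `NULL` for a
#'   zero residual forecast.
#' @param sdi_future data frame `country, year, sdi` covering `years`.
#' @param years calendar years to project.
#' @param level band coverage level, default 0.95.
#' @return Data frame `country, year, age_group, disease, rate, rate_low,
#'   rate_high`.
#' @export
project_death_rates <- function(params, residual_models, sdi_future, years,
                                level = 0.95) {
  stopifnot(inherits(params, "mortality_params"))
  miss <- setdiff(years, sdi_future$year)
  if (length(miss))
    abort("project_death_rates: SDI series does not cover year(s) %s",
          paste(miss, collapse = ", "))
  ages <- rownames(params$theta)
  dis <- colnames(params$theta)
  countries <- unique(sdi_future$country)
  tab <- expand.grid(country = countries, year = years, age_group = ages,
                     disease = dis, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  skey <- paste(sdi_future$country, sdi_future$year, sep = "\r")
  tab$sdi <- sdi_future$sdi[match(paste(tab$country, tab$year, sep = "\r"), skey)]
  yhat <- predict_ln_rate(params, tab)

  eps <- numeric(nrow(tab))
  h <- tab$year - params$t_ref
  if (!is.null(residual_models) && any(h > 0)) {
    hmax <- max(h)
    series <- unique(tab[h > 0, c("country", "age_group", "disease")])
    fc <- lapply(seq_len(nrow(series)), function(i)
      forecast_residual(residual_models, series$country[i],
                        series$age_group[i], series$disease[i], hmax))
    names(fc) <- paste(series$country, series$age_group, series$disease,
                       sep = "\r")
    idx <- h > 0
    eps[idx] <- mapply(function(k, hh) fc[[k]][hh],
                       paste(tab$country, tab$age_group, tab$disease,
                             sep = "\r")[idx], h[idx])
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(tab[, c("country", "year", "age_group", "disease")],
             rate = exp(yhat + eps),
             rate_low = exp(yhat + eps - z * params$sigma),
             rate_high = exp(yhat + eps + z * params$sigma))
}
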