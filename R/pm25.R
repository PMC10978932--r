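#' Aerosol component fields
#'
#' Container for surface concentrations of the PM2.5 components on a shared
#' grid: black carbon (`bc`), organic aerosol (`oa`), sulfate (`so4`),
#' sea salt (`ss`), dust, and optionally ammonium (`nh4`). When `nh4` is
#' absent it is derived from sulfate on composition (see [estimate_nh4()]).
#' Nitrate is deliberately not part of the composition.
#'
#' @param bc,oa,so4,ss,dust numeric matrices (ug/m3), identical dimensions,
#'   non-negative.
#' @param nh4 optional ammonium matrix (ug/m3).
#' @return Object of class `aerosol_components`.
#' @export
aerosol_components <- function(bc, oa, so4, ss, dust, nh4 = NULL) {
  comp <- list(bc = bc, oa = oa, so4 = so4, ss = ss, dust = dust)
  if (!is.null(nh4)) comp$nh4 <- nh4
  dims <- lapply(comp, dim)
  ref <- dims[[1]]
  for (nm in names(comp)) {
    m <- comp[[nm]]
    if (!is.numeric(m)) abort("aerosol_components: '%s' must be numeric", nm)
    if (!identical(dim(m), ref))
      abort("aerosol_components: grid shape of '%s' differs from 'bc'", nm)
    if (any(!is.finite(m)) || any(m < 0))
      abort("aerosol_components: '%s' must be finite and non-negative", nm)
  }
  structure(comp, class = "aerosol_components")
}

#' Ammonium from sulfate
#'
#' Estimates ammonium assuming it is present only as ammonium sulfate,
#' (NH4)2SO4: NH4 = 36 x SO4 / 96 (mass ratio of two ammonium ions to one
#' sulfate ion).
#'
#' @param so4 sulfate concentration(s), ug/m3, non-negative.
#' @return Ammonium concentration(s), same shape as `so4`.
#' @export
estimate_nh4 <- function(so4) {
  if (any(!is.finite(so4)) || any(so4 < 0))
    abort("estimate_nh4: so4 must be finite and non-negative")
  so4 * 36 / 96
}

#' Compose PM2.5 from aerosol components
#'
#' PM2.5 = BC + OA + SO4 + NH4 + 0.25 x SS + 0.1 x dust, cell-wise. The
#' factors 0.25 and 0.1 approximate the sea-salt and dust mass fractions in
#' the PM2.5 size range. Ammonium is taken from the components when present
#' and otherwise derived via [estimate_nh4()].
#'
#' @param components an [aerosol_components()] object.
#' @return Matrix of PM2.5 concentrations (ug/m3).
#' @export
compose_pm25 <- function(components) {
  stopifnot(inherits(components, "aerosol_components"))
  nh4 <- components$nh4
  if (is.null(nh4)) nh4 <- estimate_nh4(components$so4)
  components$bc + components$oa + components$so4 + nh4 +
    0.25 * components$ss + 0.1 * components$dust
}

#' Calibrate a simulated PM2.5 trajectory to base-year observations
#'
#' Anchors a simulated per-year trajectory to an observed base-year field so
#' that the simulated *trend* is preserved. Under the default ratio rule,
#' `calibrated(t) = observed_base * sim(t) / sim(base_year)` cell-wise, so
#' the base year reproduces the observations exactly. The additive dialect
#' `observed_base + (sim(t) - sim(base_year))` is available as a sensitivity
#' switch. Cells where the base-year simulation falls below `eps` have an
#' undefined trend ratio and are held at the observed value (their indices
#' are returned in the `"flagged_cells"` attribute).
#'
#' @param sim named list of per-year matrices (names are years).
#' @param observed_base observed base-year matrix (ug/m3, non-negative).
#' @param base_year calendar year present in `names(sim)`.
#' @param method `"ratio"` (default) or `"additive"`.
#' @param eps floor (ug/m3) below which the base-year simulation is treated
#'   as zero; default 0.01.
#' @return Named list of calibrated per-year matrices with attribute
#'   `flagged_cells` (integer indices, ratio method only).
#' @export
calibrate_trajectory <- function(sim, observed_base, base_year,
                                 method = c("ratio", "additive"),
                                 eps = 0.01) {
  method <- match.arg(method)
  by <- as.character(base_year)
  if (!by %in% names(sim))
    abort("calibrate_trajectory: base year %s not present in simulation", by)
  if (any(!is.finite(observed_base)) || any(observed_base < 0))
    abort("calibrate_trajectory: observed_base must be finite and non-negative")
  sim_b <- sim[[by]]
  if (!identical(dim(sim_b), dim(observed_base)))
    abort("calibrate_trajectory: grid shapes of simulation and observations differ")
  flagged <- integer(0)
  if (method == "ratio") {
    flagged <- which(sim_b < eps)
    out <- lapply(sim, function(m) {
      r <- m / sim_b
      cal <- observed_base * r
      if (length(flagged)) cal[flagged] <- observed_base[flagged]
      cal
    })
  } else {
    out <- lapply(sim, function(m) pmax(observed_base + (m - sim_b), 0))
  }
  attr(out, "flagged_cells") <- flagged
  out
}

#' Multi-model ensemble statistics for PM2.5 fields
#'
#' Cell-wise mean and empirical 2.5th/97.5th percentiles (linear
#' interpolation, default quantile type 7) across models, per year. Where a
#' model supplies several ensemble members (an unnamed list of trajectories),
#' the member mean is taken first, so members never dilute the across-model
#' statistics.
#'
#' @param model_grids named list, one entry per model. Each entry is either a
#'   trajectory (named list of per-year matrices) or an unnamed list of such
#'   trajectories (ensemble members).
#' @param models optional character vector restricting the roster to a
#'   consistent model subset.
#' @param probs lower/upper percentile probabilities, default `c(0.025, 0.975)`.
#' @return Object of class `pm25_ensemble`: list with `mean`, `q_low`,
#'   `q_high` (named lists of per-year matrices), `roster`, `probs`.
#' @export
ensemble_stats <- function(model_grids, models = NULL,
                           probs = c(0.025, 0.975)) {
  if (!length(model_grids)) abort("ensemble_stats: empty model roster")
  if (!is.null(models)) {
    miss <- setdiff(models, names(model_grids))
    if (length(miss))
      abort("ensemble_stats: unknown model(s) %s", paste(miss, collapse = ", "))
    model_grids <- model_grids[models]
  }
  # member mean within model first
  collapse <- function(entry) {
    if (is.list(entry) && is.null(names(entry))) {
      yrs <- names(entry[[1]])
      out <- lapply(yrs, function(y)
        Reduce(`+`, lapply(entry, `[[`, y)) / length(entry))
      names(out) <- yrs
      out
    } else entry
  }
  trajs <- lapply(model_grids, collapse)
  yrs <- names(trajs[[1]])
  for (tr in trajs)
    if (!identical(names(tr), yrs))
      abort("ensemble_stats: models cover different years")
  nm <- length(trajs)
  stat_year <- function(y) {
    mats <- lapply(trajs, `[[`, y)
    arr <- array(unlist(mats), dim = c(dim(mats[[1]]), nm))
    mean_m <- apply(arr, c(1, 2), mean)
    if (nm > 1) {
      qs <- apply(arr, c(1, 2), stats::quantile, probs = probs, names = FALSE)
      list(mean = mean_m, q_low = matrix(qs[1, , ], nrow = nrow(mean_m)),
           q_high = matrix(qs[2, , ], nrow = nrow(mean_m)))
    } else {
      list(mean = mean_m, q_low = mean_m, q_high = mean_m)
    }
  }
  per_year <- lapply(yrs, stat_year)
  names(per_year) <- yrs
  structure(list(
    mean = lapply(per_year, `[[`, "mean"),
    q_low = lapply(per_year, `[[`, "q_low"),
    q_high = lapply(per_year, `[[`, "q_high"),
    roster = names(trajs), probs = probs
  ), class = "pm25_ensemble")
}
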