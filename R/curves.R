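#' Tabulated exposure-response curve
#'
#' Construct an exposure-response curve for one disease (optionally one age
#' group) as relative risk (RR) tabulated on an ascending grid of PM2.5
#' concentration knots, with a low/mid/high uncertainty band. Below the
#' counterfactual concentration (the theoretical minimum-risk exposure
#' level) the RR is 1 by definition. Curves are required to be monotone
#' non-decreasing in concentration with RR >= 1 at every knot at or above
#' the counterfactual; violating inputs are rejected unless `repair = TRUE`,
#' in which case an isotonic (pool-adjacent-violators) projection is applied
#' per band.
#'
#' @param disease disease code.
#' @param age_group age-group label, or `"all"` for an age-invariant curve.
#' @param knots strictly ascending concentrations (ug/m3).
#' @param rr_mid,rr_low,rr_high RR at each knot (dimensionless);
#'   `rr_low <= rr_mid <= rr_high` knot-wise.
#' @param counterfactual concentration below which RR := 1. Defaults to the
#'   first knot.
#' @param repair apply isotonic repair instead of rejecting non-monotone
#'   input.
#' @return An object of class `er_curve`.
#' @seealso [evaluate_rr()], [compute_paf()], [read_curves()]
#' @export
er_curve <- function(disease, age_group = "all", knots, rr_mid,
                     rr_low = rr_mid, rr_high = rr_mid,
                     counterfactual = knots[1], repair = FALSE) {
  knots <- as.numeric(knots)
  if (length(knots) < 2L) abort("er_curve: need at least 2 knots")
  if (any(diff(knots) <= 0)) abort("er_curve: knots must be strictly ascending")
  bands <- list(low = as.numeric(rr_low), mid = as.numeric(rr_mid),
                high = as.numeric(rr_high))
  for (b in names(bands)) {
    if (length(bands[[b]]) != length(knots))
      abort("er_curve: rr_%s length does not match knots", b)
    if (any(!is.finite(bands[[b]])))
      abort("er_curve: non-finite RR in band '%s'", b)
    if (any(diff(bands[[b]]) < 0)) {
      if (!repair)
        abort(paste0("er_curve: band '%s' of curve (%s, %s) is not monotone ",
                     "non-decreasing; pass repair = TRUE for isotonic repair"),
              b, disease, age_group)
      bands[[b]] <- stats::isoreg(knots, bands[[b]])$yf
    }
  }
  above <- knots >= counterfactual
  for (b in names(bands)) {
    if (any(bands[[b]][above] < 1))
      abort("er_curve: band '%s' of curve (%s, %s) has RR < 1 above the counterfactual",
            b, disease, age_group)
  }
  if (any(bands$low > bands$mid) || any(bands$mid > bands$high))
    abort("er_curve: band ordering rr_low <= rr_mid <= rr_high violated for (%s, %s)",
          disease, age_group)
  structure(
    list(disease = as.character(disease), age_group = as.character(age_group),
         knots = knots, rr_low = bands$low, rr_mid = bands$mid,
         rr_high = bands$high, counterfactual = as.numeric(counterfactual)),
    class = "er_curve"
  )
}

#' @export
print.er_curve <- function(x, ...) {
  cat(sprintf("<er_curve> %s / %s: %d knots on [%g, %g] ug/m3, counterfactual %g\n",
              x$disease, x$age_group, length(x$knots), min(x$knots),
              max(x$knots), x$counterfactual))
  invisible(x)
}

#' Evaluate relative risk at a concentration
#'
#' Piecewise-linear interpolation between knots, RR = 1 at and below the
#' counterfactual concentration, and flat (constant) extrapolation beyond
#' the last knot, preserving the saturating shape of the tabulated curve.
#'
#' @param curve an [er_curve()].
#' @param concentration PM2.5 concentration(s), ug/m3, non-negative.
#' @param band `"low"`, `"mid"` or `"high"`.
#' @return Numeric RR, same length as `concentration`.
#' @export
evaluate_rr <- function(curve, concentration, band = "mid") {
  stopifnot(inherits(curve, "er_curve"))
  band <- match.arg(band, c("low", "mid", "high"))
  concentration <- as.numeric(concentration)
  if (any(!is.finite(concentration)) || any(concentration < 0))
    abort("evaluate_rr: concentrations must be finite and non-negative")
  x <- curve$knots
  y <- curve[[paste0("rr_", band)]]
  cf <- curve$counterfactual
  if (cf < x[1]) {          # anchor RR = 1 at the counterfactual
    x <- c(cf, x)
    y <- c(1, y)
  }
  rr <- stats::approx(x, y, xout = concentration, rule = 2, ties = "ordered")$y
  rr[concentration <= cf] <- 1
  rr
}

#' Population attributable fraction from relative risk
#'
#' PAF = (RR - 1) / RR, the proportion of cause-specific deaths attributable
#' to the exposure. Strictly increasing in RR on `[1, Inf)` and bounded
#' above by 1.
#'
#' @param rr relative risk(s), each >= 1.
#' @return Numeric PAF in `[0, 1)`.
#' @export
compute_paf <- function(rr) {
  rr <- as.numeric(rr)
  if (any(!is.finite(rr)) || any(rr < 1))
    abort("compute_paf: RR must be finite and >= 1 (a value below 1 signals a curve violating the monotone contract)")
  (rr - 1) / rr
}

#' Curve set container
#'
#' A named list of [er_curve()] objects keyed by `"disease|age_group"`.
#'
#' @param curves list of `er_curve` objects.
#' @return Object of class `er_curve_set`.
#' @export
curve_set <- function(curves) {
  stopifnot(all(vapply(curves, inherits, logical(1), "er_curve")))
  names(curves) <- vapply(curves, function(cu)
    paste(cu$disease, cu$age_group, sep = "|"), character(1))
  if (anyDuplicated(names(curves)))
    abort("curve_set: duplicate (disease, age_group) pairs")
  structure(curves, class = "er_curve_set")
}

#' Look up the curve for a (disease, age group) pair
#'
#' Returns the age-specific curve when one exists, else the disease's
#' `"all"`-ages curve; errors naming the pair when neither is present.
#'
#' @param set an [curve_set()].
#' @param disease,age_group labels.
#' @return An `er_curve`.
#' @export
curve_for <- function(set, disease, age_group) {
  key <- paste(disease, age_group, sep = "|")
  cu <- set[[key]]
  if (is.null(cu)) cu <- set[[paste(disease, "all", sep = "|")]]
  if (is.null(cu))
    abort("no exposure-response curve for disease '%s', age group '%s'",
          disease, age_group)
  cu
}

#' Read exposure-response curves from CSV
#'
#' Expected columns: `disease, age_group, concentration, rr_low, rr_mid,
#' rr_high` and optionally `counterfactual` (constant within a curve;
#' defaults to the curve's first knot).
#'
#' @param path CSV file path.
#' @param repair passed to [er_curve()].
#' @return An `er_curve_set`.
#' @export
read_curves <- function(path, repair = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("disease", "age_group", "concentration", "rr_low", "rr_mid", "rr_high")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort("read_curves: %s is missing column(s) %s", path,
          paste(miss, collapse = ", "))
  keys <- paste(df$disease, df$age_group, sep = "|")
  curves <- lapply(split(df, keys), function(d) {
    d <- d[order(d$concentration), ]
    cf <- if ("counterfactual" %in% names(d)) d$counterfactual[1] else
      d$concentration[1]
    er_curve(d$disease[1], d$age_group[1], d$concentration,
             rr_mid = d$rr_mid, rr_low = d$rr_low, rr_high = d$rr_high,
             counterfactual = cf, repair = repair)
  })
  curve_set(unname(curves))
}

#' Write exposure-response curves to CSV
#'
#' @param set an `er_curve_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(set, path) {
  stopifnot(inherits(set, "er_curve_set"))
  rows <- lapply(unname(set), function(cu) {
    data.frame(disease = cu$disease, age_group = cu$age_group,
               concentration = cu$knots, rr_low = cu$rr_low,
               rr_mid = cu$rr_mid, rr_high = cu$rr_high,
               counterfactual = cu$counterfactual)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$disease, df$age_group, df$concentration), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
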