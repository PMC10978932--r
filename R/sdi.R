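#' Default scaling bounds for the Socio-Demographic Index
#'
#' Bounds used to min-max rescale the three SDI components: income per
#' person (used through its logarithm, favourable high), educational
#' attainment in years (favourable high), and total fertility rate under
#' age 25 in births per woman (favourable low, hence inverted).
#'
#' @return Named list of `c(low, high)` bounds per component.
#' @export
sdi_default_bounds <- function() {
  list(income = c(250, 60000), education = c(0, 17), fertility = c(0, 3))
}

#' Socio-Demographic Index
#'
#' Composite of log income per person, educational attainment, and total
#' fertility under 25. Each component is min-max rescaled to `[0, 1]`
#' (income on the log scale; fertility inverted so that low fertility is
#' favourable), clipped, and combined as a geometric mean.
#'
#' @param income income per person (currency units), positive.
#' @param education educational attainment (years), non-negative.
#' @param fertility total fertility rate under 25 (births per woman),
#'   non-negative.
#' @param bounds named list of `c(low, high)` bounds as in
#'   [sdi_default_bounds()].
#' @return SDI value(s) in `[0, 1]`.
#' @export
compute_sdi <- function(income, education, fertility,
                        bounds = sdi_default_bounds()) {
  for (nm in c("income", "education", "fertility")) {
    b <- bounds[[nm]]
    if (is.null(b) || length(b) != 2L || !all(is.finite(b)))
      abort("compute_sdi: bounds$%s must be c(low, high)", nm)
    if (b[2] <= b[1]) abort("compute_sdi: bounds$%s has zero or negative width", nm)
  }
  if (any(income <= 0)) abort("compute_sdi: income must be positive")
  if (any(education < 0) || any(fertility < 0))
    abort("compute_sdi: education and fertility must be non-negative")
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  bi <- log(bounds$income)
  r_inc <- clip01((log(income) - bi[1]) / (bi[2] - bi[1]))
  be <- bounds$education
  r_edu <- clip01((education - be[1]) / (be[2] - be[1]))
  bf <- bounds$fertility
  r_fer <- clip01((bf[2] - fertility) / (bf[2] - bf[1]))
  clip01((r_inc * r_edu * r_fer)^(1 / 3))
}
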