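#' @keywords internal
"_PACKAGE"

# Canonical 15 five-year adult age groups (25-30 ... 95+) used throughout.
#' Adult age-group labels
#'
#' Fifteen five-year age groups from 25--30 up to the open-ended 95+ group,
#' the resolution at which attributable deaths are computed.
#'
#' @return Character vector of 15 labels, ordered by age.
#' @export
age_groups <- function() {
  lo <- seq(25L, 95L, by = 5L)
  c(paste0(lo[-length(lo)], "-", lo[-length(lo)] + 5L), "95+")
}

#' Lower age bound of an age-group label
#'
#' @param labels character vector of age-group labels as produced by
#'   [age_groups()].
#' @return Integer vector of lower bounds in years.
#' @export
age_lower_bound <- function(labels) {
  as.integer(sub("[-+].*$|\\+$", "", labels))
}

#' Disease labels for PM2.5-related causes of death
#'
#' The six causes with evidence judged consistent with a causal link to
#' long-term ambient PM2.5 exposure: lung cancer, chronic obstructive
#' pulmonary disease, lower respiratory infection, ischaemic heart disease,
#' stroke, and type-2 diabetes. Ischaemic heart disease and stroke carry
#' age-specific exposure-response curves.
#'
#' @return Character vector of 6 disease codes.
#' @export
diseases <- function() {
  c("lung_cancer", "copd", "lri", "ihd", "stroke", "diabetes")
}

#' Diseases with age-specific exposure-response curves
#' @return Character vector (subset of [diseases()]).
#' @export
age_specific_diseases <- function() c("ihd", "stroke")

# stop() with sprintf-style formatting, no call in the condition
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# run expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# stable small-integer stream offsets for derived seeds (keep < 2^31)
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}
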