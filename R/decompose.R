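# Four-factor decomposition of the change in attributable deaths between
# two states by sequential substitution: starting from the first period,
# factors are switched one at a time to their second-period values; each
# step's difference is that factor's contribution along the path, and the
# final attribution averages the paths over all 4! = 24 factor orderings,
# which equals the Shapley value of the set function
# v(S) = DAPP(state0 with the factors in S switched).

decomp_factors <- c("population", "age_structure", "death_rate",
                    "concentration")

#' Factor state for decomposition
#'
#' Bundles the four substitutable factor blocks of the burden identity for
#' one period.
#'
#' @param population population grid (persons).
#' @param age_structure data frame `country, age_group, fraction`.
#' @param death_rate data frame `country, age_group, disease, rate` (plus
#'   optional band columns).
#' @param concentration PM2.5 grid (ug/m3).
#' @param period optional period label (e.g. a year).
#' @return Object of class `factor_state`.
#' @export
factor_state <- function(population, age_structure, death_rate,
                         concentration, period = NULL) {
  structure(list(population = population, age_structure = age_structure,
                 death_rate = death_rate, concentration = concentration,
                 period = period),
            class = "factor_state")
}

# shared evaluation frame: everything in the burden identity that is not a
# substitutable factor (curves are scenario-invariant and never switched)
#' Decomposition frame
#'
#' The non-substitutable context shared by both periods: curves, country
#' mask and labels, and the evaluation band.
#'
#' @param curves an [curve_set()].
#' @param country_mask integer country-index grid (0 = ocean).
#' @param countries mask index labels.
#' @param band band used for evaluation, default `"mid"`.
#' @return Object of class `decomp_frame`.
#' @export
decomp_frame <- function(curves, country_mask, countries, band = "mid") {
  structure(list(curves = curves, country_mask = country_mask,
                 countries = countries, band = band),
            class = "decomp_frame")
}

dapp_of_state <- function(state, frame) {
  inp <- burden_inputs(year = state$period %||% NA, scenario = "decomp",
                       pm = state$concentration, pop = state$population,
                       age_fractions = state$age_structure,
                       death_rates = state$death_rate,
                       curves = frame$curves,
                       country_mask = frame$country_mask,
                       countries = frame$countries)
  compute_dapp(inp, band = frame$band)$total
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mixed_state <- function(state0, state1, switched) {
  s <- state0
  for (f in switched) s[[f]] <- state1[[f]]
  s
}

#' Contributions along one substitution path
#'
#' Switches the four factors from their first- to second-period values in
#' the given order; the contribution of a factor is the change in DAPP at
#' its switching step. Path contributions telescope exactly to
#' `DAPP(state1) - DAPP(state0)`.
#'
#' @param state0,state1 [factor_state()]s sharing the frame's grids.
#' @param frame a [decomp_frame()].
#' @param ordering permutation of
#'   `c("population", "age_structure", "death_rate", "concentration")`.
#' @return Named numeric vector of per-factor contributions (deaths/year).
#' @export
decompose_path <- function(state0, state1, frame, ordering) {
  if (!setequal(ordering, decomp_factors) ||
      length(ordering) != length(decomp_factors))
    abort("decompose_path: ordering must be a permutation of the four factors")
  v_prev <- dapp_of_state(state0, frame)
  out <- stats::setNames(numeric(length(ordering)), ordering)
  switched <- character(0)
  for (f in ordering) {
    switched <- c(switched, f)
    v_now <- dapp_of_state(mixed_state(state0, state1, switched), frame)
    out[f] <- v_now - v_prev
    v_prev <- v_now
  }
  out[decomp_factors]
}

#' Average decomposition over all factor orderings
#'
#' Evaluates DAPP for every subset of switched factors (16 evaluations) and
#' averages the sequential-substitution contributions over all 24 orderings
#' of the four factors. Contributions sum exactly to the total change and
#' equal the Shapley values of the factors.
#'
#' @inheritParams decompose_path
#' @param keep_paths also return the per-ordering contribution table.
#' @return Object of class `decomposition_result`: data frame
#'   `contributions` (`factor, contribution_deaths, contribution_pct`, the
#'   percentage relative to the period-0 total), `dapp0`, `dapp1`,
#'   `total_change`, `n_orderings`, and optionally `paths`.
#' @export
decompose <- function(state0, state1, frame, keep_paths = FALSE) {
  nf <- length(decomp_factors)
  subset_v <- numeric(2^nf)
  for (code in 0:(2^nf - 1)) {
    switched <- decomp_factors[bitwAnd(code, 2^(seq_len(nf) - 1)) > 0]
    subset_v[code + 1] <-
      dapp_of_state(mixed_state(state0, state1, switched), frame)
  }
  v_of <- function(switched) {
    code <- sum(2^(match(switched, decomp_factors) - 1))
    subset_v[code + 1]
  }
  orderings <- perms(decomp_factors)
  paths <- matrix(NA_real_, length(orderings), nf,
                  dimnames = list(NULL, decomp_factors))
  for (i in seq_along(orderings)) {
    ord <- orderings[[i]]
    prev <- v_of(character(0))
    switched <- character(0)
    for (f in ord) {
      switched <- c(switched, f)
      now <- v_of(switched)
      paths[i, f] <- now - prev
      prev <- now
    }
  }
  contrib <- colMeans(paths)
  dapp0 <- subset_v[1]; dapp1 <- subset_v[2^nf]
  structure(list(
    contributions = data.frame(factor = decomp_factors,
                               contribution_deaths = as.numeric(contrib),
                               contribution_pct = 100 * as.numeric(contrib) / dapp0,
                               row.names = NULL),
    dapp0 = dapp0, dapp1 = dapp1, total_change = dapp1 - dapp0,
    n_orderings = length(orderings),
    paths = if (keep_paths) as.data.frame(paths) else NULL
  ), class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf("<decomposition_result> DAPP %.0f -> %.0f (%+.1f%%), %d orderings\n",
              x$dapp0, x$dapp1, 100 * x$total_change / x$dapp0, x$n_orderings))
  df <- x$contributions
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-14s %+12.0f deaths  (%+.1f%%)\n", df$factor[i],
                df$contribution_deaths[i], df$contribution_pct[i]))
  invisible(x)
}

# all permutations of a character vector (n! small here)
perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(perms(x[-i]), function(p) c(x[i], p)))
  out
}
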