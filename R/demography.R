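# Two-age-class demographic projection: per-nest productivity and annual
# survival rates to young per 100 pairs and annual % population change.
# Accounting: n_pairs pairs = 2*n_pairs adults; both adults survive at the
# adult rate; fledged young recruit at the juvenile rate.

#' Demographic projection parameters
#'
#' Bundles the inputs of the projection with validation.  Defaults are the
#' published yellowhammer rates: 1.66 nesting attempts per pair per season,
#' 45% per-nest success, adult survival 0.449 and juvenile (first-year)
#' survival 0.440.  `young_per_successful_nest` has no default: it is the
#' management-specific model prediction (e.g. 2.42 fledglings on organic
#' farms, 3.19 on conventional).
#'
#' @param young_per_successful_nest Mean fledglings per successful nest.
#' @param n_pairs Number of breeding pairs projected (default 100).
#' @param renest_rate Nesting attempts per pair per season.
#' @param nest_success Probability a nesting attempt fledges young.
#' @param adult_survival,juvenile_survival Annual survival probabilities.
#' @return Object of class `dn_demog_params`.
#' @export
demographic_params <- function(young_per_successful_nest, n_pairs = 100,
                               renest_rate = 1.66, nest_success = 0.45,
                               adult_survival = 0.449,
                               juvenile_survival = 0.440) {
  stopifnot(n_pairs > 0, renest_rate >= 0, young_per_successful_nest >= 0,
            nest_success >= 0, nest_success <= 1,
            adult_survival >= 0, adult_survival <= 1,
            juvenile_survival >= 0, juvenile_survival <= 1)
  structure(list(n_pairs = n_pairs, renest_rate = renest_rate,
                 nest_success = nest_success,
                 young_per_successful_nest = young_per_successful_nest,
                 adult_survival = adult_survival,
                 juvenile_survival = juvenile_survival),
            class = "dn_demog_params")
}

#' Project annual population change from productivity and survival
#'
#' Computes, at full precision:
#' successful nests per pair = `renest_rate * nest_success`;
#' total young = `n_pairs * successful_nests_per_pair *
#' young_per_successful_nest`; adults next year = `2 * n_pairs *
#' adult_survival + young_total * juvenile_survival`; and the annual
#' percentage change `100 * (adults_next_year - 2 n_pairs) / (2 n_pairs)`.
#' Rounding to one decimal is left to presentation.
#'
#' @param params A `dn_demog_params` (or a plain list with the same
#'   fields).
#' @return List of class `dn_demog_result` with `successful_nests_per_pair`,
#'   `young_total`, `adults_next_year`, `annual_change_pct`.
#' @examples
#' organic <- demographic_params(young_per_successful_nest = 2.42)
#' project_population(organic)$annual_change_pct  # about -15.3
#' @export
project_population <- function(params) {
  p <- params
  snp <- p$renest_rate * p$nest_success
  young <- p$n_pairs * snp * p$young_per_successful_nest
  adults0 <- 2 * p$n_pairs
  adults1 <- adults0 * p$adult_survival + young * p$juvenile_survival
  structure(list(successful_nests_per_pair = snp,
                 young_total = young,
                 adults_next_year = adults1,
                 annual_change_pct = 100 * (adults1 - adults0) / adults0),
            class = "dn_demog_result")
}

#' @method print dn_demog_result
#' @export
print.dn_demog_result <- function(x, ...) {
  cat(sprintf(paste0("Successful nests per pair: %.3f\n",
                     "Young produced:            %.1f\n",
                     "Adults next year:          %.1f\n",
                     "Annual change:             %+.1f%%\n"),
              x$successful_nests_per_pair, x$young_total,
              x$adults_next_year, x$annual_change_pct))
  invisible(x)
}

#' One-parameter sensitivity of the projection
#'
#' Re-projects over a grid of values of one parameter, all others held at
#' their supplied values.  Annual change is monotone increasing in every
#' productivity and survival parameter, so the output preserves grid order.
#'
#' @param params A `dn_demog_params`.
#' @param vary Name of the parameter to vary.
#' @param grid Numeric vector of values (must satisfy the parameter's
#'   validity range).
#' @return Data frame with the grid values and `annual_change_pct`.
#' @export
demographic_sensitivity <- function(params, vary, grid) {
  stopifnot(vary %in% setdiff(names(params), "n_pairs") || vary == "n_pairs")
  out <- lapply(grid, function(v) {
    p <- params
    p[[vary]] <- v
    p2 <- do.call(demographic_params,
                  p[c("young_per_successful_nest", "n_pairs", "renest_rate",
                      "nest_success", "adult_survival", "juvenile_survival")])
    r <- project_population(p2)
    data.frame(value = v, annual_change_pct = r$annual_change_pct)
  })
  res <- do.call(rbind, out)
  names(res)[1] <- vary
  res
}
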