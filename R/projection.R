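# Population-level extrapolation of a per-visit probability difference.

#' Project additional non-SSB purchases from a placement move
#'
#' Linear extrapolation of the per-visit purchase-probability difference
#' between two placements to a population over a year:
#' `population * visits_per_year * (P(to) - P(from))`, rounded to the
#' nearest whole purchase. Negative when the move is adverse. The
#' population size and annual visit rate are required inputs — the model
#' provides only the per-visit probabilities.
#'
#' @param population number of adolescents covered.
#' @param visits_per_year mean beverage-purchase store visits per
#'   adolescent per year.
#' @param from,to `c(cooler, shelf)` placements before and after the move.
#' @param params a `bev_params` object.
#' @return projected count of additional purchases (integer-valued).
#' @examples
#' p <- default_params()
#' project_additional_purchases(1e6, 430, from = c(6, 6), to = c(1, 2), p)
#' @export
project_additional_purchases <- function(population, visits_per_year,
                                         from, to, params) {
  stopifnot(is.numeric(population), population >= 0,
            is.numeric(visits_per_year), visits_per_year >= 0)
  delta <- purchase_probability(to[1], to[2], params) -
    purchase_probability(from[1], from[2], params)
  round(population * visits_per_year * delta)
}
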