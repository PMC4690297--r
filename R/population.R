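# Monte-Carlo counterpart of the expectation model: a synthetic cohort of
# adolescents with Bernoulli shopper-type and purchase outcomes.

#' Derive a reproducible sub-stream seed
#'
#' Maps a root seed plus a purpose label and replicate index to a distinct
#' 31-bit seed, so cohort generation and purchase draws are independently
#' reproducible from one root seed.
#'
#' @param root integer root seed.
#' @param purpose short label naming the random stream.
#' @param index replicate index (0-based or 1-based, any non-negative int).
#' @return a positive integer seed below 2^31.
#' @export
derive_seed <- function(root, purpose = "", index = 0L) {
  stopifnot(is.numeric(root), length(root) == 1, is.finite(root))
  chars <- utf8ToInt(purpose)
  code <- if (length(chars)) sum(chars * seq_along(chars)) else 0
  s <- (abs(as.double(root)) * 48271 + code * 69621 +
        as.double(index) * 16807) %% 2147483629
  as.integer(s) + 1L
}

#' Generate a synthetic adolescent cohort
#'
#' Individuals are assigned to the four preference groups in balanced
#' round-robin order (group sizes differ by at most one). Each individual
#' gets a base purchase preference from their group's quartile range
#' (midpoint by default, or a uniform draw under
#' `base_rule = "uniform_draw"`) and a Bernoulli convenience-shopper flag
#' with the group's loyalty-scaled probability.
#'
#' @param n cohort size (the published simulation used 1000).
#' @param params a `bev_params` object.
#' @param seed integer seed; identical inputs give identical cohorts.
#' @return a data frame with columns `id`, `group`, `base_pref`,
#'   `is_convenience`.
#' @export
generate_cohort <- function(n, params, seed) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n <= 0)
    stop("cohort size n must be a positive integer")
  n <- as.integer(n)
  group <- rep_len(GROUP_NAMES, n)
  set.seed(derive_seed(seed, "cohort"))
  base_pref <- numeric(n)
  conv_p <- numeric(n)
  for (nm in GROUP_NAMES) {
    idx <- which(group == nm)
    g <- params$groups[[nm]]
    base_pref[idx] <- if (params$base_rule == "uniform_draw")
      base_preference(g, "uniform_draw", n = length(idx))
    else
      base_preference(g, "midpoint")
    conv_p[idx] <- convenience_probability(g, params)
  }
  is_convenience <- stats::rbinom(n, 1L, conv_p) == 1L
  data.frame(id = seq_len(n), group = group, base_pref = base_pref,
             is_convenience = is_convenience)
}

#' Simulate one-visit purchase outcomes for a cohort
#'
#' Each individual buys the non-SSB with probability
#' `base_pref * location_share(cooler, shelf, shopper type)` — one
#' Bernoulli outcome per individual, one beverage per store visit.
#'
#' @param cohort a data frame from [generate_cohort()].
#' @param cooler,shelf the non-SSB placement being evaluated.
#' @param params a `bev_params` object.
#' @param seed integer seed for the purchase draws.
#' @return a `simulation_result`: list with `n`, `seed`, `location`,
#'   `purchases_total`, `purchases_by_group` (named integer vector),
#'   `estimated_probability`.
#' @export
simulate_purchases <- function(cohort, cooler, shelf, params, seed) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0)
    stop("cohort must be a non-empty data frame")
  check_location(cooler, shelf, params)
  share_conv   <- location_share(cooler, shelf, "convenience", params)
  share_browse <- location_share(cooler, shelf, "browser", params)
  p <- cohort$base_pref *
    ifelse(cohort$is_convenience, share_conv, share_browse)
  set.seed(derive_seed(seed, "purchase"))
  buy <- stats::rbinom(nrow(cohort), 1L, p)
  by_group <- vapply(GROUP_NAMES,
                     function(nm) sum(buy[cohort$group == nm]), integer(1))
  structure(list(
    n = nrow(cohort),
    seed = seed,
    location = c(cooler = cooler, shelf = shelf),
    purchases_total = sum(buy),
    purchases_by_group = by_group,
    estimated_probability = sum(buy) / nrow(cohort)
  ), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("Simulated purchases: %d of %d individuals (p_hat = %.4f) at cooler %d, shelf %d\n",
              x$purchases_total, x$n, x$estimated_probability,
              x$location["cooler"], x$location["shelf"]))
  print(x$purchases_by_group)
  invisible(x)
}

#' @export
as.data.frame.simulation_result <- function(x, ...) {
  data.frame(seed = x$seed, cooler = x$location["cooler"],
             shelf = x$location["shelf"], n = x$n,
             t(x$purchases_by_group),
             purchases_total = x$purchases_total,
             estimated_probability = x$estimated_probability,
             row.names = NULL)
}

#' Distribution of the simulated purchase-count ratio between two locations
#'
#' For each replicate, draws an independent cohort at each location,
#' simulates purchases, and forms the count ratio (location a over
#' location b). Replicates whose denominator count is zero are discarded,
#' tallied, and redrawn — at the published cohort size of 1000 the worst
#' location expects only ~6.5 purchases, so zero denominators do occur.
#'
#' @param n cohort size per replicate.
#' @param loc_a,loc_b `c(cooler, shelf)` numerator / denominator locations.
#' @param params a `bev_params` object.
#' @param seed root seed; replicate sub-streams are derived from it.
#' @param reps number of retained replicates.
#' @return a `ratio_summary`: list with `mean`, `sd`, `lo95`, `hi95`
#'   (central 95% interval), `n_discarded`, and the vector `ratios`.
#' @export
simulated_relative_ratio <- function(n, loc_a, loc_b, params, seed,
                                     reps = 500L) {
  stopifnot(n > 0, reps >= 1)
  check_location(loc_a[1], loc_a[2], params)
  check_location(loc_b[1], loc_b[2], params)
  ratios <- numeric(0)
  discarded <- 0L
  attempt <- 0L
  max_attempts <- max(50L * as.integer(reps), 1000L)
  while (length(ratios) < reps) {
    attempt <- attempt + 1L
    if (attempt > max_attempts)
      stop("all replicates degenerate: denominator purchase count was 0 in ",
           discarded, " of ", attempt - 1L, " attempts")
    ca <- generate_cohort(n, params, derive_seed(seed, "rep_a", attempt))
    cb <- generate_cohort(n, params, derive_seed(seed, "rep_b", attempt))
    ra <- simulate_purchases(ca, loc_a[1], loc_a[2], params,
                             derive_seed(seed, "buy_a", attempt))
    rb <- simulate_purchases(cb, loc_b[1], loc_b[2], params,
                             derive_seed(seed, "buy_b", attempt))
    if (rb$purchases_total == 0L) {
      discarded <- discarded + 1L
      next
    }
    ratios <- c(ratios, ra$purchases_total / rb$purchases_total)
  }
  structure(list(
    mean = mean(ratios),
    sd = stats::sd(ratios),
    lo95 = unname(stats::quantile(ratios, 0.025)),
    hi95 = unname(stats::quantile(ratios, 0.975)),
    n = n, reps = as.integer(reps), n_discarded = discarded,
    ratios = ratios
  ), class = "ratio_summary")
}

#' @export
print.ratio_summary <- function(x, ...) {
  cat(sprintf("Simulated count ratio over %d replicates of n = %d: mean %.3f (sd %.3f), central 95%% [%.3f, %.3f]\n",
              x$reps, x$n, x$mean, x$sd, x$lo95, x$hi95))
  if (x$n_discarded > 0)
    cat("  (", x$n_discarded,
        " replicate(s) redrawn for a zero denominator count)\n", sep = "")
  invisible(x)
}
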