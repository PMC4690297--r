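# Model parameter bundle: preference groups, convenience-shopper baseline,
# horizontal (cooler) and vertical (shelf) selection shares, layout size.

#' Names of the four SSB-preference groups
#'
#' Quartile groups of the proportion of non-SSB beverages an adolescent
#' purchases, from "always buys SSBs" to "rarely or never does".
#'
#' @export
GROUP_NAMES <- c("always_ssb", "usually_ssb", "sometimes_ssb",
                 "rarely_never_ssb")

new_preference_group <- function(name, base_range, loyalty) {
  structure(list(name = name,
                 base_range = as.numeric(base_range),
                 loyalty = as.numeric(loyalty)),
            class = "preference_group")
}

#' Default model parameters
#'
#' The published base case: four preference groups defined by quartiles of
#' the proportion of non-SSB purchases (ranges in percent), group-specific
#' brand-loyalty weights, a 32.6% baseline probability of being a
#' convenience shopper, and the horizontal/vertical selection shares for a
#' 6-cooler x 6-shelf layout (cooler 1 nearest the entrance, shelf 1 on
#' top). Loyalty is stored as a proportion; selection shares stay in
#' percent, as printed.
#'
#' @param base_rule how a point purchase probability is taken from a
#'   group's quartile range: `"midpoint"` (deterministic, the expectation
#'   of a uniform draw) or `"uniform_draw"` (per-individual uniform sample,
#'   Monte-Carlo mode).
#' @return An object of class `bev_params`.
#' @examples
#' p <- default_params()
#' p$conv_baseline           # 0.326
#' p$horizontal              # 17.9 ... 15.4 (percent, cooler 1 first)
#' @export
default_params <- function(base_rule = c("midpoint", "uniform_draw")) {
  base_rule <- match.arg(base_rule)
  groups <- list(
    always_ssb       = new_preference_group("always_ssb",       c(0, 0),       0.27),
    usually_ssb      = new_preference_group("usually_ssb",      c(0, 28.4),    0.75),
    sometimes_ssb    = new_preference_group("sometimes_ssb",    c(28.5, 54.4), 1.00),
    rarely_never_ssb = new_preference_group("rarely_never_ssb", c(54.4, 100),  0.27)
  )
  params <- structure(list(
    groups        = groups,
    group_weights = stats::setNames(rep(0.25, 4), GROUP_NAMES),
    conv_baseline = 0.326,
    horizontal    = c(17.9, 17.4, 16.9, 16.4, 15.9, 15.4),
    vertical      = c(17.0, 17.2, 17.1, 16.8, 16.3, 15.5),
    n_coolers     = 6L,
    n_shelves     = 6L,
    base_rule     = base_rule
  ), class = "bev_params")
  validate_params(params)
}

#' Validate a parameter bundle
#'
#' Checks every structural invariant: probability bounds, share positivity,
#' share sums within \[99, 101\] (the printed defaults sum to 99.9 and are
#' used without renormalisation), layout dimensions consistent with the
#' share vectors, group weights summing to one, and quartile ranges ordered
#' without overlap (adjacent boundaries may touch; degenerate point ranges,
#' e.g. a sensitivity override of the always-SSB group, are exempt from the
#' partition check).
#'
#' @param params a `bev_params` object.
#' @return `params`, invisibly unchanged, or an error.
#' @export
validate_params <- function(params) {
  stopifnot(inherits(params, "bev_params"))
  if (!identical(sort(names(params$groups)), sort(GROUP_NAMES)))
    stop("params must contain exactly the four preference groups: ",
         paste(GROUP_NAMES, collapse = ", "))
  for (g in params$groups) {
    r <- g$base_range
    if (length(r) != 2 || anyNA(r) || r[1] > r[2] || r[1] < 0 || r[2] > 100)
      stop("base_range of group '", g$name,
           "' must satisfy 0 <= lo <= hi <= 100 (percent)")
    if (is.na(g$loyalty) || g$loyalty < 0 || g$loyalty > 1)
      stop("loyalty of group '", g$name, "' must lie in [0, 1]")
  }
  # quartile ranges must not overlap (point ranges are scenario overrides)
  spans <- Filter(function(g) diff(g$base_range) > 0, params$groups)
  if (length(spans) > 1) {
    ord <- order(vapply(spans, function(g) g$base_range[1], numeric(1)))
    spans <- spans[ord]
    for (i in seq_len(length(spans) - 1)) {
      if (spans[[i + 1]]$base_range[1] < spans[[i]]$base_range[2] - 1e-9)
        stop("preference-group ranges overlap: '", spans[[i]]$name,
             "' and '", spans[[i + 1]]$name, "'")
    }
  }
  if (is.na(params$conv_baseline) ||
      params$conv_baseline < 0 || params$conv_baseline > 1)
    stop("conv_baseline must be a probability in [0, 1]")
  if (abs(sum(params$group_weights) - 1) > 1e-9)
    stop("group weights must sum to 1")
  if (params$n_coolers != length(params$horizontal))
    stop("n_coolers (", params$n_coolers,
         ") must equal the number of horizontal shares (",
         length(params$horizontal), ")")
  if (params$n_shelves != length(params$vertical))
    stop("n_shelves (", params$n_shelves,
         ") must equal the number of vertical shares (",
         length(params$vertical), ")")
  for (ax in c("horizontal", "vertical")) {
    sh <- params[[ax]]
    if (any(is.na(sh)) || any(sh <= 0) || any(sh >= 100))
      stop(ax, " shares must each lie in (0, 100) percent")
    if (sum(sh) < 99 || sum(sh) > 101)
      stop(ax, " shares must sum to within [99, 101] percent (got ",
           format(sum(sh)), ")")
  }
  if (!params$base_rule %in% c("midpoint", "uniform_draw"))
    stop("base_rule must be 'midpoint' or 'uniform_draw'")
  invisible(params)
}

# bev_params <-> plain nested list (the YAML config schema)
as_config_list <- function(params) {
  list(
    conv_baseline = params$conv_baseline,
    horizontal    = params$horizontal,
    vertical      = params$vertical,
    n_coolers     = as.integer(params$n_coolers),
    n_shelves     = as.integer(params$n_shelves),
    base_rule     = params$base_rule,
    groups = lapply(params$groups, function(g)
      list(base_lo = g$base_range[1], base_hi = g$base_range[2],
           loyalty = g$loyalty))
  )
}

from_config_list <- function(cfg) {
  known <- c("conv_baseline", "horizontal", "vertical", "n_coolers",
             "n_shelves", "base_rule", "groups")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  extra_g <- setdiff(names(cfg$groups), GROUP_NAMES)
  if (length(extra_g))
    stop("unknown preference group(s): ", paste(extra_g, collapse = ", "))
  groups <- lapply(GROUP_NAMES, function(nm) {
    g <- cfg$groups[[nm]]
    new_preference_group(nm, c(g$base_lo, g$base_hi), g$loyalty)
  })
  names(groups) <- GROUP_NAMES
  params <- structure(list(
    groups        = groups,
    group_weights = stats::setNames(rep(0.25, 4), GROUP_NAMES),
    conv_baseline = as.numeric(cfg$conv_baseline),
    horizontal    = as.numeric(cfg$horizontal),
    vertical      = as.numeric(cfg$vertical),
    n_coolers     = as.integer(cfg$n_coolers),
    n_shelves     = as.integer(cfg$n_shelves),
    base_rule     = as.character(cfg$base_rule)
  ), class = "bev_params")
  validate_params(params)
}

# recursive overlay of user config onto defaults; lists replace wholesale
merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(user[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Load model parameters from a YAML config
#'
#' Reads a key/value YAML document mirroring the `bev_params` fields
#' (`conv_baseline`, `horizontal`, `vertical`, `n_coolers`, `n_shelves`,
#' `base_rule`, and a `groups` map with `base_lo`/`base_hi` in percent and
#' `loyalty` as a proportion). Omitted keys fall back to the published
#' defaults; any invariant violation is an error, never a warning.
#'
#' @param file path to a YAML file, or `NULL` when `text` is given.
#' @param text a YAML document as a string (alternative to `file`).
#' @return A validated `bev_params` object.
#' @seealso [write_params()] for the inverse; round-trips are exact.
#' @export
load_params <- function(file = NULL, text = NULL) {
  if (is.null(file) == is.null(text))
    stop("supply exactly one of 'file' or 'text'")
  if (!is.null(file) && !file.exists(file))
    stop("config file not found: ", file)
  cfg <- if (is.null(file)) yaml::yaml.load(text) else yaml::read_yaml(file)
  if (is.null(cfg)) cfg <- list()                  # empty document
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  from_config_list(merge_config(as_config_list(default_params()), cfg))
}

#' Write model parameters to a YAML config
#'
#' @param params a `bev_params` object.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_params <- function(params, file) {
  validate_params(params)
  yaml::write_yaml(as_config_list(params), file, precision = 15L)
  invisible(file)
}

#' Point purchase probability of a preference group
#'
#' Collapses a group's quartile range of non-SSB purchase proportion to a
#' single base probability. `"midpoint"` takes the midpoint of the range
#' (the expectation of a uniform draw, so expectation-mode results agree
#' with the Monte-Carlo mode on average); `"uniform_draw"` samples
#' uniformly within the range using the current random stream.
#'
#' @param group a `preference_group` (an element of `params$groups`).
#' @param rule `"midpoint"` or `"uniform_draw"`.
#' @param n number of draws (uniform rule only).
#' @return probability (proportion in \[0, 1\]); a vector of length `n`
#'   under `"uniform_draw"`.
#' @examples
#' p <- default_params()
#' base_preference(p$groups$usually_ssb)        # 0.142
#' base_preference(p$groups$always_ssb)         # exactly 0
#' @export
base_preference <- function(group, rule = c("midpoint", "uniform_draw"),
                            n = 1L) {
  rule <- match.arg(rule)
  r <- group$base_range / 100
  if (rule == "midpoint") mean(r) else stats::runif(n, r[1], r[2])
}

#' Probability that a group member is a convenience shopper
#'
#' The baseline convenience-shopper probability scaled by the group's
#' brand-loyalty weight, clipped to \[0, 1\] (the clip guards user
#' overrides; the defaults never reach it).
#'
#' @inheritParams base_preference
#' @param params a `bev_params` object.
#' @return probability in \[0, 1\].
#' @examples
#' p <- default_params()
#' convenience_probability(p$groups$sometimes_ssb, p)   # 0.326
#' convenience_probability(p$groups$always_ssb, p)      # 0.326 * 0.27
#' @export
convenience_probability <- function(group, params) {
  min(1, max(0, params$conv_baseline * group$loyalty))
}

#' @export
print.bev_params <- function(x, ...) {
  cat("Beverage-placement model parameters\n")
  cat(sprintf("  layout: %d coolers x %d shelves (cooler 1 = entrance, shelf 1 = top)\n",
              x$n_coolers, x$n_shelves))
  cat(sprintf("  convenience-shopper baseline: %.3f  (base rule: %s)\n",
              x$conv_baseline, x$base_rule))
  cat("  horizontal shares (%):", paste(format(x$horizontal), collapse = " "), "\n")
  cat("  vertical shares   (%):", paste(format(x$vertical), collapse = " "), "\n")
  for (g in x$groups)
    cat(sprintf("  %-17s base %5.1f-%5.1f%%  loyalty %.2f\n",
                g$name, g$base_range[1], g$base_range[2], g$loyalty))
  invisible(x)
}
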