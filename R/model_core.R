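# The decision tree: preference group -> convenience shopper vs browser ->
# location selection (horizontal x vertical shares) -> purchase gated by
# the group's base preference. All probabilities are exact expectations
# (the rolled-back tree); Monte-Carlo counterparts live in population.R.

check_location <- function(cooler, shelf, params) {
  if (length(cooler) != 1 || length(shelf) != 1 ||
      is.na(cooler) || is.na(shelf) ||
      cooler != as.integer(cooler) || shelf != as.integer(shelf) ||
      cooler < 1 || cooler > params$n_coolers ||
      shelf < 1 || shelf > params$n_shelves)
    stop("location (", cooler, ", ", shelf, ") outside the ",
         params$n_coolers, " x ", params$n_shelves, " layout")
  invisible(NULL)
}

#' Probability that a shopper stands in front of a given location
#'
#' Convenience shoppers walk only to cooler 1 and pick a shelf by the
#' vertical share; browsers pick a cooler by the horizontal share and a
#' shelf by the vertical share. Shares are used exactly as printed
#' (they sum to 99.9%), without renormalisation.
#'
#' @param cooler,shelf location indices; cooler 1 is nearest the entrance,
#'   shelf 1 is the top shelf.
#' @param shopper `"convenience"` or `"browser"`.
#' @param params a `bev_params` object.
#' @return probability in \[0, 1\].
#' @examples
#' p <- default_params()
#' location_share(3, 2, "convenience", p)  # 0: never reaches cooler 3
#' location_share(1, 6, "convenience", p)  # 0.155
#' location_share(1, 2, "browser", p)      # 0.179 * 0.172
#' @export
location_share <- function(cooler, shelf,
                           shopper = c("convenience", "browser"), params) {
  shopper <- match.arg(shopper)
  check_location(cooler, shelf, params)
  v <- params$vertical[shelf] / 100
  if (shopper == "convenience") {
    if (cooler == 1) v else 0
  } else {
    (params$horizontal[cooler] / 100) * v
  }
}

#' Purchase probability of one preference group at one location
#'
#' The group's base preference (midpoint of its quartile range) times the
#' mixture of convenience and browser location shares:
#' `base_g * (conv_g * share_conv + (1 - conv_g) * share_browse)`.
#'
#' @inheritParams location_share
#' @param group a `preference_group` or its name.
#' @return probability in \[0, 1\].
#' @export
group_purchase_probability <- function(group, cooler, shelf, params) {
  if (is.character(group)) group <- params$groups[[group]]
  base_g <- base_preference(group, "midpoint")
  conv_g <- convenience_probability(group, params)
  base_g * (conv_g * location_share(cooler, shelf, "convenience", params) +
            (1 - conv_g) * location_share(cooler, shelf, "browser", params))
}

#' Population purchase probability at one location
#'
#' Equal-weight mean over the four preference groups of
#' [group_purchase_probability()].
#'
#' @inheritParams location_share
#' @return probability in \[0, 1\].
#' @examples
#' p <- default_params()
#' purchase_probability(6, 6, p)   # worst location, ~0.0065
#' purchase_probability(1, 2, p)   # optimal location, ~0.0186
#' @export
purchase_probability <- function(cooler, shelf, params) {
  vals <- vapply(params$groups, group_purchase_probability,
                 numeric(1), cooler = cooler, shelf = shelf, params = params)
  sum(params$group_weights[names(vals)] * vals)
}

new_purchase_grid <- function(values, mode, reference = NULL,
                              group = NULL, no_effect = FALSE) {
  dimnames(values) <- list(paste0("cooler_", seq_len(nrow(values))),
                           paste0("shelf_", seq_len(ncol(values))))
  structure(values, class = c("purchase_grid", class(values)),
            mode = mode, reference = reference, group = group,
            no_effect = no_effect)
}

#' Absolute purchase-probability grid
#'
#' @param params a `bev_params` object.
#' @param group optional group name for a stratified grid; default is the
#'   population (equal-weight mean over groups).
#' @return a `purchase_grid` matrix, coolers in rows (1 = entrance), shelves
#'   in columns (1 = top), each cell a probability.
#' @export
absolute_grid <- function(params, group = NULL) {
  f <- if (is.null(group)) {
    function(c, s) purchase_probability(c, s, params)
  } else {
    function(c, s) group_purchase_probability(group, c, s, params)
  }
  vals <- outer(seq_len(params$n_coolers), seq_len(params$n_shelves),
                Vectorize(f))
  new_purchase_grid(vals, "absolute", group = group)
}

#' Purchase grid relative to a reference (worst) location
#'
#' Each cell is the ratio of its purchase probability to the probability at
#' the reference location, by convention cooler 6 shelf 6 (back of the
#' store, bottom shelf). The reference cell is exactly 1.
#'
#' @inheritParams absolute_grid
#' @param reference `c(cooler, shelf)` of the normalisation location.
#' @return a relative-mode `purchase_grid`.
#' @examples
#' rg <- relative_grid(default_params())
#' rg["cooler_1", "shelf_2"]     # ~2.86: optimal vs worst
#' @export
relative_grid <- function(params, reference = c(6, 6)) {
  check_location(reference[1], reference[2], params)
  abs_g <- absolute_grid(params)
  ref_p <- abs_g[reference[1], reference[2]]
  if (ref_p <= 0)
    stop("purchase probability at the reference location is 0; ",
         "relative grid undefined (degenerate parameters)")
  vals <- unclass(abs_g) / ref_p
  vals[reference[1], reference[2]] <- 1
  new_purchase_grid(vals, "relative", reference = reference)
}

#' Group-stratified relative purchase grid
#'
#' As [relative_grid()] but for a single preference group. A group whose
#' purchase probability is zero everywhere (the always-SSB group under the
#' defaults) experiences no placement effect: every cell is reported as 1
#' and the grid carries a `no_effect` attribute instead of raising a
#' division error.
#'
#' @inheritParams relative_grid
#' @param group group name or `preference_group`.
#' @return a relative-mode `purchase_grid`, possibly flagged `no_effect`.
#' @export
stratified_relative_grid <- function(group, params, reference = c(6, 6)) {
  if (inherits(group, "preference_group")) group <- group$name
  check_location(reference[1], reference[2], params)
  abs_g <- absolute_grid(params, group = group)
  if (all(abs_g == 0)) {
    vals <- matrix(1, params$n_coolers, params$n_shelves)
    return(new_purchase_grid(vals, "relative", reference = reference,
                             group = group, no_effect = TRUE))
  }
  ref_p <- abs_g[reference[1], reference[2]]
  if (ref_p <= 0)
    stop("group '", group, "' has zero purchase probability at the ",
         "reference location; relative grid undefined")
  vals <- unclass(abs_g) / ref_p
  vals[reference[1], reference[2]] <- 1
  new_purchase_grid(vals, "relative", reference = reference, group = group)
}

#' Locations within a tie tolerance of the grid maximum
#'
#' @param grid a `purchase_grid`.
#' @param tie_tolerance relative tolerance: cells within
#'   `tie_tolerance * max` of the maximum count as tied. The 1% default
#'   groups near-eye-level shelves whose shares differ by well under a
#'   percent.
#' @return a data frame with columns `cooler`, `shelf`, `value`, in
#'   row-major (cooler-then-shelf) order.
#' @examples
#' find_optimal(relative_grid(default_params()))   # cooler 1, shelves 2 & 3
#' @export
find_optimal <- function(grid, tie_tolerance = 0.01) {
  stopifnot(inherits(grid, "purchase_grid"), tie_tolerance >= 0)
  vals <- unclass(grid)
  top <- max(vals)
  hit <- which(vals >= top * (1 - tie_tolerance), arr.ind = TRUE)
  out <- data.frame(cooler = hit[, 1], shelf = hit[, 2],
                    value = vals[hit])
  out <- out[order(out$cooler, out$shelf), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a purchase grid to CSV
#'
#' Layout: one row per cooler (cooler 1 = entrance), one column per shelf
#' (shelf 1 = top), labels `cooler_i` / `shelf_j`, values rounded to 4
#' decimal places.
#'
#' @param grid a `purchase_grid`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_grid_csv <- function(grid, file) {
  stopifnot(inherits(grid, "purchase_grid"))
  df <- data.frame(cooler = rownames(grid),
                   round(unclass(grid), 4),
                   check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @export
print.purchase_grid <- function(x, digits = 4, ...) {
  mode <- attr(x, "mode")
  grp <- attr(x, "group")
  cat(sprintf("%s purchase grid%s (coolers in rows, 1 = entrance; shelves in columns, 1 = top)\n",
              mode, if (is.null(grp)) "" else paste0(", group ", grp)))
  if (!is.null(attr(x, "reference")))
    cat("  reference location: cooler ", attr(x, "reference")[1],
        ", shelf ", attr(x, "reference")[2], "\n", sep = "")
  if (isTRUE(attr(x, "no_effect")))
    cat("  NOTE: group purchase probability is zero everywhere;",
        "placement has no effect (all cells reported as 1)\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}
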