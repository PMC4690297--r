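p_default <- default_params()

test_that("location shares follow the convenience/browser split", {
  p <- p_default
  # convenience shoppers never reach coolers 2-6
  for (ck in 2:6)
    expect_identical(location_share(ck, 3, "convenience", p), 0)
  expect_equal(location_share(1, 6, "convenience", p), 0.155)
  expect_equal(location_share(1, 2, "convenience", p), 0.172)
  # browsers multiply horizontal and vertical shares
  expect_equal(location_share(1, 2, "browser", p), 0.179 * 0.172)
  expect_equal(location_share(6, 6, "browser", p), 0.154 * 0.155)
  expect_error(location_share(0, 1, "browser", p), "layout")
  expect_error(location_share(7, 1, "browser", p), "layout")
  expect_error(location_share(1, 7, "browser", p), "layout")
})

test_that("group purchase probabilities gate the location mix by base preference", {
  p <- p_default
  for (loc in list(c(1, 1), c(3, 4), c(6, 6)))
    expect_identical(
      group_purchase_probability("always_ssb", loc[1], loc[2], p), 0)
  # sometimes-SSB at the optimal cell: 0.4145 * (0.326*0.172 + 0.674*0.179*0.172)
  expect_equal(group_purchase_probability("sometimes_ssb", 1, 2, p),
               0.4145 * (0.326 * 0.172 + 0.674 * 0.179 * 0.172),
               tolerance = 1e-12)
  # rarely/never at the worst cell: 0.772 * 0.91198 * 0.154 * 0.155
  expect_equal(group_purchase_probability("rarely_never_ssb", 6, 6, p),
               0.772 * (1 - 0.326 * 0.27) * 0.154 * 0.155,
               tolerance = 1e-12)
})

test_that("purchase probability equals the brute-force path enumeration everywhere", {
  p <- p_default
  for (ck in 1:6) for (sh in 1:6)
    expect_equal(purchase_probability(ck, sh, p),
                 oracle_purchase_probability(ck, sh, p), tolerance = 1e-12)
  # and per group, including a perturbed parameter set
  q <- load_params(text = "conv_baseline: 0.5\ngroups:\n  usually_ssb:\n    loyalty: 0.4")
  for (nm in GROUP_NAMES)
    expect_equal(group_purchase_probability(nm, 4, 5, q),
                 oracle_purchase_probability(4, 5, q, group = nm),
                 tolerance = 1e-12)
})

test_that("absolute grid cells are probabilities matching the pointwise model", {
  p <- p_default
  g <- absolute_grid(p)
  expect_equal(dim(g), c(6, 6))
  expect_true(all(g >= 0 & g <= 1))
  expect_equal(g[6, 6], purchase_probability(6, 6, p), tolerance = 1e-15)
  expect_equal(g[6, 6], 0.0065088, tolerance = 1e-4)
  expect_equal(g[1, 2], 0.0186204, tolerance = 1e-4)
})

test_that("relative grid reproduces the headline placement ratios", {
  rg <- relative_grid(p_default)
  expect_identical(rg[6, 6], 1)          # reference cell exact
  expect_equal(rg[1, 2], 2.8608, tolerance = 1e-4)
  expect_equal(rg[1, 6], 2.5781, tolerance = 1e-4)
  expect_equal(rg[2, 2], 1.2538, tolerance = 1e-4)
  # every cooler-1 cell beats every cell of coolers 2-6
  expect_true(min(rg[1, ]) > max(rg[2:6, ]))
})

test_that("relative grid fails loudly on degenerate parameters", {
  zero <- load_params(text = paste(
    "groups:",
    "  always_ssb: {base_lo: 0, base_hi: 0}",
    "  usually_ssb: {base_lo: 0, base_hi: 0}",
    "  sometimes_ssb: {base_lo: 0, base_hi: 0}",
    "  rarely_never_ssb: {base_lo: 0, base_hi: 0}", sep = "\n"))
  expect_identical(purchase_probability(3, 3, zero), 0)
  expect_error(relative_grid(zero), "degenerate")
})

test_that("stratified grids match the published per-group picture", {
  p <- p_default
  sg <- stratified_relative_grid("sometimes_ssb", p)
  expect_equal(sg[1, 2], 4.7751, tolerance = 1e-4)
  expect_identical(sg[6, 6], 1)
  # the always-SSB stratum shows no placement effect, flagged not errored
  ag <- stratified_relative_grid("always_ssb", p)
  expect_true(isTRUE(attr(ag, "no_effect")))
  expect_true(all(ag == 1))
  # base preference cancels in a stratified ratio: group grid ratios equal
  # oracle absolute ratios
  og <- oracle_grid(p, group = "rarely_never_ssb")
  expect_equal(unclass(stratified_relative_grid("rarely_never_ssb", p)),
               og / og[6, 6], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("browsers-only model is separable into share products", {
  p <- p_default
  p$conv_baseline <- 0
  p <- validate_params(p)
  rg <- unclass(relative_grid(p))
  h <- p$horizontal; v <- p$vertical
  for (ck in 1:6) for (sh in 1:6)
    expect_equal(rg[ck, sh], (h[ck] * v[sh]) / (h[6] * v[6]),
                 tolerance = 1e-12)
})

test_that("flat shares and no convenience shoppers give a flat relative grid", {
  rg <- relative_grid(flat_share_params(conv_baseline = 0))
  expect_true(all(abs(rg - 1) < 1e-12))
  expect_equal(nrow(find_optimal(rg)), 36)
})

test_that("raising the convenience baseline strictly widens cooler-1 contrast", {
  prev <- NULL
  for (cb in c(0.1, 0.3, 0.5, 0.7)) {
    p <- p_default
    p$conv_baseline <- cb
    rg <- unclass(relative_grid(p))
    if (!is.null(prev)) expect_true(all(rg[1, ] > prev))
    prev <- rg[1, ]
  }
})

test_that("optimal-location search honours the tie tolerance", {
  rg <- relative_grid(p_default)
  opt <- find_optimal(rg)
  expect_equal(opt$cooler, c(1, 1))
  expect_equal(opt$shelf, c(2, 3))
  strict <- find_optimal(rg, tie_tolerance = 0)
  expect_equal(nrow(strict), 1)
  expect_equal(c(strict$cooler, strict$shelf), c(1, 2))
})

test_that("grid CSV export uses the labelled 6x6 layout at 4 decimals", {
  f <- withr::local_tempfile(fileext = ".csv")
  rg <- relative_grid(p_default)
  write_grid_csv(rg, f)
  got <- utils::read.csv(f, check.names = FALSE)
  expect_equal(names(got), c("cooler", paste0("shelf_", 1:6)))
  expect_equal(got$cooler, paste0("cooler_", 1:6))
  expect_equal(as.matrix(got[, -1]), round(unclass(rg), 4),
               ignore_attr = TRUE)
})
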