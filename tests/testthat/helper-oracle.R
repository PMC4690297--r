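# Independent brute-force oracle: enumerate every path of the decision
# tree (group -> shopper type -> cooler pick -> shelf pick -> purchase
# gate) and sum the probability of the paths that buy the non-SSB at the
# queried location. Deliberately structured as explicit path enumeration,
# not the closed-form product used by the package.
oracle_purchase_probability <- function(cooler, shelf, params,
                                        group = NULL) {
  groups <- if (is.null(group)) params$groups else params$groups[group]
  total <- 0
  for (g in groups) {
    w <- if (is.null(group)) params$group_weights[[g$name]] else 1
    base_g <- mean(g$base_range) / 100
    conv_g <- min(1, params$conv_baseline * g$loyalty)
    for (shopper in c("convenience", "browser")) {
      p_type <- if (shopper == "convenience") conv_g else 1 - conv_g
      for (ck in seq_len(params$n_coolers)) {
        for (sh in seq_len(params$n_shelves)) {
          p_loc <- if (shopper == "convenience") {
            if (ck == 1) params$vertical[sh] / 100 else 0
          } else {
            (params$horizontal[ck] / 100) * (params$vertical[sh] / 100)
          }
          for (buys in c(TRUE, FALSE)) {
            p_buy <- if (buys) base_g else 1 - base_g
            if (buys && ck == cooler && sh == shelf)
              total <- total + w * p_type * p_loc * p_buy
          }
        }
      }
    }
  }
  total
}

oracle_grid <- function(params, group = NULL) {
  outer(seq_len(params$n_coolers), seq_len(params$n_shelves),
        Vectorize(function(c, s)
          oracle_purchase_probability(c, s, params, group = group)))
}

# frozen total purchases for cohort+purchase seed 123, n = 1000, cell (1,2)
PINNED_TOTAL_SEED123 <- 22L

# parameters with every placement share flat (sum 99.9, like the printed
# defaults) — used by the separability / no-contrast properties
flat_share_params <- function(conv_baseline = 0) {
  p <- default_params()
  p$horizontal <- rep(16.65, 6)
  p$vertical <- rep(16.65, 6)
  p$conv_baseline <- conv_baseline
  validate_params(p)
}
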