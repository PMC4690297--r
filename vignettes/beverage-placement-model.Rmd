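---
title: "A decision-analytic model of healthy-beverage placement in corner stores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision-analytic model of healthy-beverage placement in corner stores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bevnudge)
```

## The question

Corner stores are a major beverage source for adolescents in low-income
urban neighbourhoods, and product placement is known to steer purchases.
`bevnudge` models a simple "nudge": move the healthy (non-sugar-sweetened)
beverage to a better cooler and shelf, and ask how much more often an
adolescent walks out with it. The store is a grid of 6 coolers (cooler 1
nearest the entrance) with 6 shelves each (shelf 1 on top); the outcome is
the probability that one adolescent, on one visit, buys the non-SSB from a
given cell of that grid.

## The model

Each adolescent belongs to one of four SSB-preference groups — quartiles
of the proportion of non-SSB beverages they purchase — with equal
population weight 1/4:

| group | base non-SSB purchase range (%) | loyalty |
|---|---|---|
| always SSB | 0 | 0.27 |
| usually SSB | 0–28.4 | 0.75 |
| sometimes SSB | 28.5–54.4 | 1.00 |
| rarely/never SSB | >54.4 (closed at 100) | 0.27 |

The upper quartile has no printed upper bound; we close it at 100 because
a proportion of purchases cannot exceed 100%. A group's point base
preference $b_g$ is by default the **midpoint** of its range (the
expectation of a uniform draw, so expectation-mode results coincide with
the average of the Monte-Carlo mode); `base_rule = "uniform_draw"` samples
per-individual values instead.

With baseline convenience-shopper probability $c_0 = 0.326$ and
group loyalty $\ell_g$, a group member is a *convenience shopper* with
probability $c_g = c_0\,\ell_g$ (clipped to $[0,1]$ as a guard for user
overrides) and otherwise a *browser*. Convenience shoppers reach only
cooler 1 and pick a shelf by the vertical selection shares
$v = (17.0, 17.2, 17.1, 16.8, 16.3, 15.5)\%$; browsers pick a cooler by
the horizontal shares $h = (17.9, 17.4, 16.9, 16.4, 15.9, 15.4)\%$ and a
shelf by $v$. The purchase probability of group $g$ at cooler $i$,
shelf $j$ is

$$P_g(i,j) = b_g\Big[c_g\,v_j\,\mathbf{1}\{i=1\} + (1-c_g)\,h_i\,v_j\Big],$$

and the population probability is $P(i,j) = \tfrac14\sum_g P_g(i,j)$.
Each share vector sums to 99.9% as printed and is used **without
renormalisation**: renormalising the vertical axis cancels in every
ratio, and renormalising the horizontal axis would shift ratios by less
than 0.2%, well inside the Monte-Carlo noise of any 1000-draw simulation.

All results are expressed relative to the *worst* location, cooler 6
shelf 6: $R(i,j) = P(i,j)/P(6,6)$, with the reference cell pinned to
exactly 1.

```{r headline}
params <- default_params()
rg <- relative_grid(params)
print(rg, digits = 2)
find_optimal(rg)
```

The optimal placements are cooler 1, shelves 2 and 3 — roughly eye
level — at about 2.86 times the worst location. Their analytic values
differ by only ~0.6%, which is why `find_optimal()` defaults to a 1%
relative tie tolerance: shelves whose selection shares differ by a few
tenths of a percent are scientifically tied. At `tie_tolerance = 0` the
strict argmax is shelf 2 (share 17.2% vs 17.1%).

Stratified grids divide each group's own probabilities (the base
preference cancels, so the stratum ratio isolates the shopper-type
mixture). The "sometimes SSB" stratum — fully loyal, hence the largest
convenience-shopper fraction — shows the strongest effect (~4.8×); the
"always SSB" stratum has zero base preference everywhere, so its grid is
reported as all 1s with a `no_effect` flag rather than a 0/0 error.

## Monte-Carlo cohort

`generate_cohort()` draws the simulated cohort: balanced round-robin
group assignment (sizes differ by at most one), a Bernoulli
convenience-shopper flag at $c_g$, and a base preference per the
`base_rule`. `simulate_purchases()` then gives each individual one
Bernoulli purchase at probability $b_g \times$ (their location-selection
share). The default cohort size is 1000, the published simulation size.

Randomness runs through one root seed; sub-stream seeds are derived
deterministically per purpose and replicate (`derive_seed()`), so cohort
generation and purchase draws are independently reproducible.

A caution the package surfaces explicitly: at $n = 1000$ the worst cell
expects only ~6.5 purchases, so the per-replicate count ratio
$X/Y$ is noisy *and biased upward* (the convexity of $1/Y$ inflates its
mean by roughly 18% at these counts). `simulated_relative_ratio()`
therefore reports the full distribution — mean, SD and central 95%
interval — and replicates with a zero denominator are redrawn and
tallied rather than silently dropped. Ratios quoted as point results
should come from the expectation model or from pooled counts at large
$n$, not from averaging small-cohort ratios.

## Sensitivity scenarios

Five one-way scenarios, evaluated at the fixed contrast (cooler 1,
shelf 2) vs (cooler 6, shelf 6) — the optimal cell does not move across
scenarios:

1. always-SSB base preference raised to a point value of 25%;
2. convenience-shopper baseline doubled (0.652);
3. convenience-shopper baseline halved (0.163);
4. both effect-share vectors doubled;
5. both effect-share vectors halved.

"Doubling the effects" means doubling the *contrast between locations*,
not the shares themselves: each share is transformed by the
mean-preserving spread $s \mapsto \bar s + f\,(s - \bar s)$ with
$\bar s$ the axis mean (16.65), then rounded **half-up** to one decimal
(`rounding = "printed_1dp"`; base R's banker's rounding would turn 19.15
into 19.1). This rule regenerates 23 of the 24 published doubled/halved
shares exactly; the one exception (halved vertical, shelf 1) is
internally inconsistent with every neighbouring cell and is treated as a
typo — the rule value 16.8 is used. Neither cell enters the reported
contrast. Similarly, a published "18.3 (half)" convenience value can only
be a typo for 16.3 (half of the 32.6 baseline in percent); the package
uses 0.163.

```{r sensitivity}
suite <- run_sensitivity_suite(params)
suite[, c("scenario", "parameter", "value", "analytic_ratio")]
```

The always-SSB-25% row is flagged in its `note` column: the exact
reconstruction gives ~2.71 where the published simulated table shows
3.50. No loyalty re-assignment we consider plausible closes that gap
analytically; a high draw in a single 1000-individual simulation can —
the per-replicate ratio distribution at $n = 1000$ covers 3.50 well
inside its central 95% interval, and its upward bias pushes the *mean*
simulated ratio for this scenario to ~3.2. The package reports the
discrepancy rather than matching it.

## Population projection

`project_additional_purchases()` extrapolates a per-visit probability
difference linearly:
$\text{population} \times \text{visits/year} \times [P(\text{to}) -
P(\text{from})]$, rounded to a whole purchase count. Population size and
annual visit rate are **required inputs**: city-level projections depend
on census counts and purchase-frequency survey data that are not part of
the model, so the package hard-codes neither. The analysis driver uses an
illustrative configuration (10^6 adolescents, 430 visits/year) to show
the order of magnitude — about 5.2 million extra non-SSBs for the
worst-to-optimal move. Moves are additive before rounding:
worst→optimal equals worst→second plus second→optimal.

## Numerical and design choices

* **Exactness.** All grid probabilities are exact expectations of the
  decision tree; the test suite checks all 36 cells against an
  independent brute-force path enumeration at 10⁻¹² tolerance.
* **Reference cell.** $R$ at the reference is set to exactly 1, not
  merely computed as a ratio of equal floats.
* **Degenerate inputs.** A parameter set with zero purchase probability
  at the reference raises an error for the population grid; a single
  all-zero stratum is flagged `no_effect` instead, matching the
  qualitative claim that placement cannot move a group that never buys
  the product.
* **Validation.** Config loading errors on any invariant violation
  (share lists of the wrong length, probabilities outside $[0,1]$,
  overlapping quartile ranges, share sums outside $[99, 101]$) — never a
  warning. Degenerate point ranges (the always-SSB default and scenario
  overrides) are exempt from the quartile-partition check.
* **Problem sizes.** Tests use cohorts of 10⁵ for convergence checks
  (3-standard-error bands), 300 replicates of 1000 for ratio-coverage
  checks, and one 4×10⁵ cohort for the large-sample ratio; these sizes
  put the binomial noise floor well below every asserted tolerance while
  the full suite runs in seconds.

## What the synthetic cohort does and does not emulate

The generator reproduces the *study conditions*: four equally weighted
preference quartiles, loyalty-scaled convenience-shopper assignment, and
one purchase per visit driven by placement shares. It does not emulate
features of real shoppers that the model itself abstracts away — prices,
package sizes, facings, repeat visits, habit formation, or within-group
preference heterogeneity beyond the uniform-in-quartile option. Passing
tests therefore demonstrate internal consistency of the model and
faithful reproduction of its published outputs, not predictive validity
for real store interventions.
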