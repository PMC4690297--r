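#!/usr/bin/env Rscript
# Population-level projection: additional non-SSB purchases per year from
# moving the healthy beverage between the worst, second-best and optimal
# placements. Population size and visit rate are inputs, not model
# outputs — the values below are an illustrative configuration (a
# million-adolescent population at 430 beverage-purchase visits/year
# reproduces the order of magnitude of published city-level projections).

library(bevnudge)

dir.create("results", showWarnings = FALSE)
params <- default_params()

population <- 1e6
visits_per_year <- 430

moves <- list(
  worst_to_optimal = list(from = c(6, 6), to = c(1, 2)),
  worst_to_second  = list(from = c(6, 6), to = c(2, 2)),
  second_to_optimal = list(from = c(2, 2), to = c(1, 2)))

proj <- do.call(rbind, lapply(names(moves), function(nm) {
  m <- moves[[nm]]
  data.frame(scenario = nm,
             population = population, visits_per_year = visits_per_year,
             from_cooler = m$from[1], from_shelf = m$from[2],
             to_cooler = m$to[1], to_shelf = m$to[2],
             additional_purchases = project_additional_purchases(
               population, visits_per_year, m$from, m$to, params))
}))
write.csv(proj, "results/projection.csv", row.names = FALSE)
print(proj)
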