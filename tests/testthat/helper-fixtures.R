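# shared fixtures, built in code

mouse_const_cycle <- function() cell_cycle_model("constant", Tc = 14.3)

mouse_age_cycle <- function()
  cell_cycle_model("age_dependent",
                   anchors = data.frame(day = c(12, 16), hours = c(10.2, 18.4)))

macaque_age_anchors <- function()
  data.frame(day = c(40, 60, 80), hours = c(23, 54, 27))

mouse_strategy <- function() strategy(0.4, 0.5, 0.7, 14)

# random valid strategy on a window, reproducible under the caller's seed
random_strategy <- function(window) {
  a0 <- runif(1, 0.05, 0.9)
  aS <- runif(1, a0 + 0.01, 1)
  bF <- runif(1, 0.05, 1)
  tS <- runif(1, window[1] + 0.1 * diff(window), window[2] - 0.1 * diff(window))
  strategy(a0, aS, bF, tS)
}

# synthetic species parameterization for property tests
synth_species <- function(id = 1) {
  t0 <- runif(1, 5, 50)
  dur <- runif(1, 5, 80)
  tM <- t0 + runif(1, 0.2, 0.8) * dur
  species_params(
    name = paste0("synthetic", id),
    t0 = t0, tF = t0 + dur, tM = tM,
    phi = runif(1, 0.2, 0.8),
    N_adult = 10^runif(1, 6, 10),
    death_fraction = runif(1, 0, 0.5),
    migration_fraction = runif(1, 0, 0.5),
    Tc_constant = runif(1, 8, 60),
    Tc_anchors = data.frame(day = sort(runif(3, t0, t0 + dur)),
                            hours = runif(3, 8, 60))
  )
}
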