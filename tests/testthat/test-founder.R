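test_that("the output target adjusts adult counts for death and migration", {
  tgt <- neurogenic_output_target("mouse")
  expect_equal(tgt$N_target, 13.69e6 * 0.75 / 0.7)   # ~1.4668e7
  # no adjustment: identity
  none <- neurogenic_output_target("mouse", death_fraction = 0,
                                   migration_fraction = 0)
  expect_equal(none$N_target, 13.69e6)
  # migration acts proportionally
  half <- neurogenic_output_target("mouse", migration_fraction = 0.5)
  expect_equal(half$N_target / tgt$N_target, 0.5 / 0.75)
  expect_error(neurogenic_output_target("mouse", death_fraction = 1), "death")
})

test_that("the analytic estimator inverts the per-founder output exactly", {
  sp <- load_species("mouse")
  s <- mouse_strategy()
  cc <- mouse_const_cycle()
  tr <- simulate_neurogenesis(s, cc, c(sp$t0, sp$tF))
  Ntilde <- tr$N[length(tr$N)]
  tgt <- structure(list(N_target = Ntilde,
                        provenance = list()), class = "output_target")
  expect_equal(estimate_founder_analytic(tgt, s, sp, cc), 1)
  tgt$N_target <- 2 * Ntilde
  expect_equal(estimate_founder_analytic(tgt, s, sp, cc), 2)
  # mouse with the packaged inputs lands within order of magnitude of the
  # literature founder population (375,000)
  P0 <- estimate_founder_analytic(neurogenic_output_target(sp), s, sp, cc)
  expect_gt(P0, 375000 / 10)
  expect_lt(P0, 375000 * 10)
})

test_that("rejection ABC recovers the analytic founder estimate", {
  sp <- load_species("mouse")
  s <- mouse_strategy()
  cc <- mouse_const_cycle()
  tgt <- neurogenic_output_target(sp)
  est <- estimate_founder_abc(tgt, s, sp, cc, n_draws = 5e4, seed = 11,
                              step = 0.02)
  expect_equal(est$posterior_mean, est$analytic_P0,
               tolerance = est$tolerance)
  expect_true(all(est$posterior_samples >= est$prior[1] &
                    est$posterior_samples <= est$prior[2]))
  expect_true(est$posterior_CI[1] <= est$posterior_mean &&
                est$posterior_mean <= est$posterior_CI[2])
})

test_that("the ABC posterior concentrates on the analytic value as the tolerance shrinks", {
  sp <- load_species("mouse")
  s <- mouse_strategy()
  cc <- mouse_const_cycle()
  tgt <- neurogenic_output_target(sp)
  errs <- sapply(c(0.1, 0.01, 0.001), function(tol) {
    est <- estimate_founder_abc(tgt, s, sp, cc, tolerance = tol,
                                n_draws = 4e5, seed = 3, step = 0.02)
    abs(est$posterior_mean - est$analytic_P0) / est$analytic_P0
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-3)
})

test_that("the same seed reproduces the posterior exactly", {
  sp <- load_species("mouse")
  tgt <- neurogenic_output_target(sp)
  a <- estimate_founder_abc(tgt, mouse_strategy(), sp, n_draws = 1e4,
                            seed = 42, step = 0.05)
  b <- estimate_founder_abc(tgt, mouse_strategy(), sp, n_draws = 1e4,
                            seed = 42, step = 0.05)
  expect_identical(a$posterior_samples, b$posterior_samples)
})

test_that("a prior collapsed onto the analytic value accepts every draw", {
  sp <- load_species("mouse")
  s <- mouse_strategy()
  cc <- mouse_const_cycle()
  tgt <- neurogenic_output_target(sp)
  P0 <- estimate_founder_analytic(tgt, s, sp, cc, step = 0.02)
  est <- estimate_founder_abc(tgt, s, sp, cc,
                              prior = c(P0 * 0.9999, P0 * 1.0001),
                              n_draws = 1e3, seed = 5, step = 0.02)
  expect_equal(est$acceptance_rate, 1)
})

test_that("founder estimates scale linearly with the output target", {
  sp <- load_species("mouse")
  s <- mouse_strategy()
  cc <- mouse_const_cycle()
  t1 <- neurogenic_output_target(sp)
  t2 <- t1; t2$N_target <- 3 * t1$N_target
  expect_equal(estimate_founder_analytic(t2, s, sp, cc),
               3 * estimate_founder_analytic(t1, s, sp, cc))
})

test_that("the robustness sweep emits one row per setting and reuses strategies", {
  tab <- robustness_sweep(c("mouse", "human"),
                          death_fractions = c(0.3, 0.5),
                          migration_fractions = c(0.25, 0.5),
                          cycle_modes = "constant", step = 0.02)
  expect_equal(nrow(tab), 2 * 2 * 2)
  # death/migration only rescale the target: per-founder output is constant
  # within a species
  for (spn in c("mouse", "human"))
    expect_equal(length(unique(tab$N_per_founder[tab$species == spn])), 1)
  # P0 = N_target / N_per_founder
  expect_equal(tab$P0, tab$N_target / tab$N_per_founder)
})
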