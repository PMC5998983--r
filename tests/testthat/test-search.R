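# small grids and coarser steps keep these fast; the full default searches
# run once in test-acceptance.R

small_grid <- function(objective = "eq4_absolute")
  search_grid(alpha0_values = c(0.3, 0.4, 0.5),
              alphaS_values = c(0.5, 0.6),
              betaF_values = c(0.6, 0.7),
              tS_values = c(13.5, 14, 14.5),
              objective = objective)

test_that("default grid spans the spec'd lattice", {
  mouse <- load_species("mouse")
  g <- default_grid(mouse, hypothesis_filter = FALSE)
  expect_equal(g$tS_values, seq(11.5, 18.5, by = 0.5))
  expect_equal(g$alpha0_values, seq(0.1, 0.9, by = 0.1))
  expect_equal(g$betaF_values, seq(0.1, 1, by = 0.1))
  expect_true(94 %in% default_grid("human")$tS_values)
  # prevalence-hypothesis restriction
  gf <- default_grid(mouse)
  expect_equal(max(gf$alpha0_values), 0.5)
  expect_equal(min(gf$betaF_values), 0.5)
})

test_that("every generated candidate passes strategy validation", {
  mouse <- load_species("mouse")
  g <- default_grid(mouse)
  cand <- corticogen:::grid_candidates(g, c(mouse$t0, mouse$tF))
  ok <- vapply(seq_len(nrow(cand)), function(i)
    isTRUE(validate_strategy(strategy(cand$alpha0[i], cand$alphaS[i],
                                      cand$betaF[i], cand$tS[i]),
                             c(mouse$t0, mouse$tF))), TRUE)
  expect_true(all(ok))
  # alphaS > alpha0 everywhere
  expect_true(all(cand$alphaS > cand$alpha0))
})

test_that("a single-candidate grid returns that candidate with its mismatch", {
  g <- search_grid(0.4, 0.5, 0.7, 14)
  fit <- fit_strategy("mouse", grid = g, step = 0.02)
  expect_equal(as.numeric(fit$best), c(alpha0 = 0.4, alphaS = 0.5,
                                       betaF = 0.7, tS = 14))
  expect_equal(fit$n_evaluated, 1)
  tr <- simulate_neurogenesis(fit$best, mouse_const_cycle(), c(11, 19),
                              step = 0.02)
  n <- length(tr$N)
  expect_equal(fit$epsilon,
               abs(tr$N[n] - trajectory_at(tr, 17)$N / 0.52),
               tolerance = 1e-9)
})

test_that("the ranked table is exhaustive, sorted, and deterministic", {
  fit1 <- fit_strategy("mouse", grid = small_grid(), step = 0.05)
  fit2 <- fit_strategy("mouse", grid = small_grid(), step = 0.05)
  expect_identical(fit1$ranked_table, fit2$ranked_table)
  expect_identical(as.numeric(fit1$best), as.numeric(fit2$best))
  # 5 valid (alpha0, alphaS) pairs x 2 betaF x 3 tS
  expect_equal(nrow(fit1$ranked_table), 5 * 2 * 3)
  expect_true(!is.unsorted(fit1$ranked_table$epsilon))
  expect_equal(fit1$epsilon, min(fit1$ranked_table$epsilon))
})

test_that("refining the grid never increases the minimal mismatch", {
  coarse <- search_grid(c(0.3, 0.5), c(0.5, 0.7), c(0.5, 0.7), c(13, 15),
                        objective = "fraction_error")
  fine <- search_grid(c(0.3, 0.4, 0.5), c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7),
                      c(13, 14, 15), objective = "fraction_error")
  f1 <- fit_strategy("mouse", grid = coarse, step = 0.05)
  f2 <- fit_strategy("mouse", grid = fine, step = 0.05)
  expect_lte(f2$epsilon, f1$epsilon)
})

test_that("both objectives agree on the ranking scale they use", {
  fa <- fit_strategy("mouse", grid = small_grid("eq4_absolute"), step = 0.05)
  ff <- fit_strategy("mouse", grid = small_grid("fraction_error"), step = 0.05)
  # the absolute residual equals the fraction error times N(tF)/phi
  ta <- fa$ranked_table
  key <- paste(ta$alpha0, ta$alphaS, ta$betaF, ta$tS)
  tf <- ff$ranked_table
  tf <- tf[match(key, paste(tf$alpha0, tf$alphaS, tf$betaF, tf$tS)), ]
  expect_equal(ta$epsilon, tf$epsilon * ta$N_tF / 0.52, tolerance = 1e-9)
})

test_that("an empty candidate set is an error", {
  g <- search_grid(0.5, 0.4, 0.7, 14)    # alphaS < alpha0: no valid tuple
  expect_error(fit_strategy("mouse", grid = g), "no valid candidate")
})
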