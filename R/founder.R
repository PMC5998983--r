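#' Neurogenic output target from adult neuron counts
#'
#' The neurons present at the end of neurogenesis exceed the adult count:
#' a fraction of them dies after neurogenesis, while a fraction of adult
#' cortical neurons immigrated (mostly interneurons from the ganglionic
#' eminences) and was never produced by the local progenitor pool.  The
#' locally generated neurogenic output to be matched by the model is
#' therefore
#' \deqn{N_{target} = N_{adult} (1 - migration) / (1 - death).}
#'
#' @param species a [species_params()] object or species name.
#' @param death_fraction,migration_fraction optional overrides of the
#'   species defaults (0.30 and 0.25).
#' @return An object of class `output_target`: list with `N_target` and
#'   `provenance` (the inputs used).
#' @examples
#' neurogenic_output_target("mouse")$N_target   # 13.69e6 * 0.75 / 0.7
#' @export
neurogenic_output_target <- function(species, death_fraction = NULL,
                                     migration_fraction = NULL) {
  if (is.character(species)) species <- load_species(species)
  d <- death_fraction %||% species$death_fraction
  m <- migration_fraction %||% species$migration_fraction
  if (d >= 1) stop("death_fraction must be < 1", call. = FALSE)
  if (m >= 1 || m < 0 || d < 0)
    stop("fractions must lie in [0, 1)", call. = FALSE)
  N_target <- species$N_adult * (1 - m) / (1 - d)
  structure(list(N_target = N_target,
                 provenance = list(species = species$name,
                                   N_adult = species$N_adult,
                                   death_fraction = d,
                                   migration_fraction = m)),
            class = "output_target")
}

#' @export
print.output_target <- function(x, ...) {
  p <- x$provenance
  cat(sprintf(
    "Neurogenic output target: %.4g cells (%s: %.4g adults, death %g, migration %g)\n",
    x$N_target, p$species, p$N_adult, p$death_fraction, p$migration_fraction))
  invisible(x)
}

#' Reference strategy for a species and cycle model
#'
#' Returns the packaged fitted strategy for the requested cell-cycle
#' model (`"constant"` or `"age_dependent"`; human additionally has
#' `age_dependent` variants at cell-cycle scale 1.5 and 2).
#'
#' @param species a [species_params()] object or species name.
#' @param cycle_mode `"constant"` or `"age_dependent"`.
#' @param tc_scale cell-cycle scale of the variant (1, 1.5 or 2).
#' @return A [strategy()], or `NULL` when no reference exists.
#' @export
reference_strategy <- function(species, cycle_mode = c("constant", "age_dependent"),
                               tc_scale = 1) {
  if (is.character(species)) species <- load_species(species)
  cycle_mode <- match.arg(cycle_mode)
  key <- if (cycle_mode == "constant") "constant"
         else if (tc_scale == 1) "age_dependent"
         else sprintf("age_dependent_tc%g", tc_scale)
  v <- species$reference_strategy[[key]]
  if (is.null(v)) return(NULL)
  strategy(v[1], v[2], v[3], v[4])
}

#' Analytic founder-population estimate
#'
#' The model is linear in the founder population, so the number of
#' founders needed to produce the neurogenic output target is exactly
#' `P0 = N_target / Ntilde(tF)`, where `Ntilde(tF)` is the per-founder
#' output of the strategy.
#'
#' @param target an [neurogenic_output_target()] result.
#' @param strat a [strategy()].
#' @param species a [species_params()] object or species name.
#' @param cycle a [cell_cycle_model()]; defaults to the species'
#'   constant-cycle model.
#' @param alphaF terminal convention, see [resolve_alphaF()].
#' @param step integration step in days.
#' @return Founder population size (cells).
#' @export
estimate_founder_analytic <- function(target, strat, species, cycle = NULL,
                                      alphaF = "zero", step = 0.01) {
  if (is.character(species)) species <- load_species(species)
  if (is.null(cycle)) cycle <- species_cycle(species, "constant")
  stopifnot(inherits(target, "output_target"))
  Ntilde <- final_output(strat, cycle, c(species$t0, species$tF), alphaF, step)
  if (Ntilde <= 0) stop("per-founder output is zero", call. = FALSE)
  target$N_target / Ntilde
}

#' Founder-population estimate by rejection ABC
#'
#' Approximate Bayesian computation with a rejection kernel: founder
#' sizes are drawn log-uniformly from the prior, the model is run forward
#' for each draw, and a draw is accepted when its simulated output lies
#' within a relative `tolerance` of the target,
#' `|N(tF) - N_target| / N_target <= tolerance`.  Because the model is
#' exactly linear in the founder population (a tested invariant), the
#' forward output for each draw is obtained by scaling one per-founder
#' integration, which makes the sampler essentially free; the analytic
#' estimator [estimate_founder_analytic()] serves as its oracle.
#'
#' @inheritParams estimate_founder_analytic
#' @param prior length-2 numeric, founder-count bounds of the log-uniform
#'   prior (default `c(1e2, 1e9)`).
#' @param tolerance relative acceptance tolerance (default 0.01).
#' @param n_draws number of prior draws (default 1e5).
#' @param seed integer seed; the estimate is fully reproducible from it.
#' @return An object of class `founder_estimate`: list with
#'   `analytic_P0`, `posterior_samples`, `posterior_mean`, `posterior_CI`
#'   (2.5 and 97.5 percent quantiles), `acceptance_rate`, `tolerance`,
#'   `n_draws`, `seed`.
#' @export
estimate_founder_abc <- function(target, strat, species, cycle = NULL,
                                 prior = c(1e2, 1e9), tolerance = 0.01,
                                 n_draws = 1e5, seed = 1,
                                 alphaF = "zero", step = 0.01) {
  if (is.character(species)) species <- load_species(species)
  if (is.null(cycle)) cycle <- species_cycle(species, "constant")
  stopifnot(inherits(target, "output_target"), length(prior) == 2,
            prior[1] > 0, prior[2] > prior[1], tolerance > 0, n_draws >= 1)
  Ntilde <- final_output(strat, cycle, c(species$t0, species$tF), alphaF, step)
  if (Ntilde <= 0) stop("per-founder output is zero", call. = FALSE)
  analytic <- target$N_target / Ntilde
  set.seed(as.integer(seed))
  draws <- exp(runif(n_draws, log(prior[1]), log(prior[2])))
  N_sim <- draws * Ntilde           # exact: the system is linear in P0
  acc <- abs(N_sim - target$N_target) / target$N_target <= tolerance
  samples <- draws[acc]
  if (length(samples) == 0)
    stop("no accepted draws: widen the prior or the tolerance", call. = FALSE)
  structure(list(analytic_P0 = analytic,
                 posterior_samples = samples,
                 posterior_mean = mean(samples),
                 posterior_CI = quantile(samples, c(0.025, 0.975),
                                         names = FALSE),
                 acceptance_rate = mean(acc),
                 tolerance = tolerance, n_draws = n_draws,
                 prior = prior, seed = seed),
            class = "founder_estimate")
}

#' @export
print.founder_estimate <- function(x, ...) {
  cat(sprintf("Founder population estimate (rejection ABC, %d draws, seed %s)\n",
              x$n_draws, format(x$seed)))
  cat(sprintf("  analytic P0      : %.5g\n", x$analytic_P0))
  cat(sprintf("  posterior mean   : %.5g  (95%% CI %.5g - %.5g, %d accepted)\n",
              x$posterior_mean, x$posterior_CI[1], x$posterior_CI[2],
              length(x$posterior_samples)))
  invisible(x)
}

#' Robustness sweep of founder-population estimates
#'
#' Re-estimates founder populations across ranges of the demographic
#' adjustment fractions and, for human, amplified cell-cycle lengths.
#' Death and migration fractions only rescale the output target, so the
#' fitted strategy is reused; changing the cell-cycle scale changes the
#' dynamics, so the strategy is re-derived (packaged reference variants
#' where available, otherwise a fresh grid search).
#'
#' @param species_names character vector of registered species.
#' @param death_fractions,migration_fractions numeric vectors swept over.
#' @param tc_scales cell-cycle scale factors applied to human (default 1).
#' @param cycle_modes subset of `c("constant", "age_dependent")`.
#' @param use_reference use packaged reference strategies (default) or
#'   refit each strategy with [fit_strategy()].
#' @param alphaF,step see [simulate_neurogenesis()].
#' @return Long-format data frame with one row per species, cycle mode,
#'   cell-cycle scale and fraction setting: the strategy used, the output
#'   target and the founder estimate `P0`.
#' @export
robustness_sweep <- function(species_names = c("mouse", "macaque", "human"),
                             death_fractions = 0.30,
                             migration_fractions = 0.25,
                             tc_scales = 1,
                             cycle_modes = c("constant", "age_dependent"),
                             use_reference = TRUE,
                             alphaF = "zero", step = 0.01) {
  cycle_modes <- match.arg(cycle_modes, several.ok = TRUE)
  rows <- list()
  for (sp_name in species_names) {
    sp <- load_species(sp_name)
    scales <- if (sp_name == "human") tc_scales else 1
    for (mode in cycle_modes) for (sc in scales) {
      cyc <- species_cycle(sp, mode, scale = sc)
      strat <- if (use_reference) reference_strategy(sp, mode, sc) else NULL
      if (is.null(strat))
        strat <- fit_strategy(sp, cyc, alphaF = alphaF, step = step)$best
      Ntilde <- final_output(strat, cyc, c(sp$t0, sp$tF), alphaF, step)
      for (d in death_fractions) for (m in migration_fractions) {
        tgt <- neurogenic_output_target(sp, d, m)
        rows[[length(rows) + 1]] <- data.frame(
          species = sp_name, cycle_mode = mode, tc_scale = sc,
          death_fraction = d, migration_fraction = m,
          alpha0 = strat$alpha0, alphaS = strat$alphaS,
          betaF = strat$betaF, tS = strat$tS,
          N_target = tgt$N_target, N_per_founder = Ntilde,
          P0 = tgt$N_target / Ntilde)
      }
    }
  }
  do.call(rbind, rows)
}
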