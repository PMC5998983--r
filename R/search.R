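#' Strategy search grids
#'
#' A search grid is the Cartesian product of candidate values for the four
#' strategy parameters, together with the mismatch objective used to rank
#' candidates.  Tuples violating the strategy constraints (notably
#' `alphaS > alpha0`) are dropped at evaluation time.
#'
#' @param alpha0_values,alphaS_values,betaF_values numeric probability
#'   candidates.
#' @param tS_values switch-time candidates (embryonic days).
#' @param objective `"eq4_absolute"`, the absolute residual
#'   `|N(tF) - N(tM)/phi|` of the layer-ratio constraint, or
#'   `"fraction_error"`, the scale-free `|N(tM)/N(tF) - phi|`.
#' @return An object of class `search_grid`.
#' @seealso [default_grid()], [fit_strategy()]
#' @export
search_grid <- function(alpha0_values, alphaS_values, betaF_values,
                        tS_values,
                        objective = c("eq4_absolute", "fraction_error")) {
  objective <- match.arg(objective)
  stopifnot(length(alpha0_values) > 0, length(alphaS_values) > 0,
            length(betaF_values) > 0, length(tS_values) > 0)
  structure(list(alpha0_values = sort(unique(alpha0_values)),
                 alphaS_values = sort(unique(alphaS_values)),
                 betaF_values = sort(unique(betaF_values)),
                 tS_values = sort(unique(tS_values)),
                 objective = objective),
            class = "search_grid")
}

#' Default strategy search grid for a species
#'
#' Candidate probabilities move in steps of 0.1 and the switch time in
#' steps of 0.5 day across the open neurogenesis window — the lattice on
#' which the fitted species strategies lie.  By default the grid is
#' restricted to the biological hypothesis underlying the strategy shape:
#' self-amplification is the prevalent division mode at onset
#' (`alpha0 <= 0.5`) and symmetric neurogenic division the prevalent mode
#' at the end (`betaF >= 0.5`).  The layer-ratio constraint alone leaves a
#' nearly flat ridge of equivalent strategies; the prevalence restriction
#' is what makes the ranked search reproducible and biologically
#' interpretable.  Set `hypothesis_filter = FALSE` for the unrestricted
#' lattice.
#'
#' @param species a [species_params()] object or species name.
#' @param prob_step probability step (default 0.1).
#' @param tS_step switch-time step in days (default 0.5).
#' @param hypothesis_filter restrict to `alpha0 <= 0.5`, `betaF >= 0.5`
#'   (default `TRUE`).
#' @param objective see [search_grid()].
#' @return A `search_grid`.
#' @export
default_grid <- function(species, prob_step = 0.1, tS_step = 0.5,
                         hypothesis_filter = TRUE,
                         objective = c("eq4_absolute", "fraction_error")) {
  if (is.character(species)) species <- load_species(species)
  a0_max <- if (hypothesis_filter) 0.5 else 1 - prob_step
  bF_min <- if (hypothesis_filter) 0.5 else prob_step
  search_grid(
    alpha0_values = seq(prob_step, a0_max, by = prob_step),
    alphaS_values = seq(2 * prob_step, 1, by = prob_step),
    betaF_values = seq(bF_min, 1, by = prob_step),
    tS_values = seq(species$t0 + tS_step, species$tF - tS_step, by = tS_step),
    objective = match.arg(objective)
  )
}

grid_candidates <- function(grid, window, alphaF = "zero") {
  cand <- expand.grid(alpha0 = grid$alpha0_values,
                      alphaS = grid$alphaS_values,
                      betaF = grid$betaF_values,
                      tS = grid$tS_values,
                      KEEP.OUT.ATTRS = FALSE)
  keep <- cand$alphaS > cand$alpha0 + 1e-12 &
    cand$alpha0 > 0 & cand$alpha0 < 1 &
    cand$alphaS <= 1 & cand$betaF > 0 & cand$betaF <= 1 &
    cand$tS > window[1] & cand$tS < window[2]
  if (!is.numeric(alphaF) && alphaF == "zero") {
    # terminal alpha 0 is always admissible
  } else {
    aF <- vapply(cand$betaF, function(b) resolve_alphaF(alphaF, b), 0)
    keep <- keep & aF >= 0 & aF + cand$betaF <= 1 + 1e-12
  }
  cand[keep, , drop = FALSE]
}

#' Fit a division strategy by exhaustive grid search
#'
#' Simulates the per-founder system for every valid tuple of the grid and
#' ranks tuples by the configured mismatch between the model's
#' deeper-layer output and the anatomical target: the strategy should
#' produce a fraction `phi` of its final neurons by `tM`.  The best tuple
#' minimizes the objective; exact ties are broken lexicographically on
#' `(tS, alpha0, alphaS, betaF)`, smallest first.
#'
#' @param species a [species_params()] object or species name.
#' @param cycle a [cell_cycle_model()]; defaults to the species'
#'   constant-cycle model.
#' @param grid a [search_grid()]; defaults to [default_grid()].
#' @param alphaF terminal convention, see [resolve_alphaF()].
#' @param step integration step in days (default 0.01).
#' @return An object of class `strategy_fit`: list with `best` (a
#'   [strategy()]), `epsilon`, `ranked_table` (all evaluated tuples with
#'   per-founder `N_tM`, `N_tF` and `epsilon`, sorted), `objective`,
#'   `species`, `n_evaluated`.
#' @examples
#' \donttest{
#' fit <- fit_strategy("mouse")   # a few seconds
#' fit$best                       # (0.4, 0.6, 0.6, 14)
#' }
#' @export
fit_strategy <- function(species, cycle = NULL, grid = NULL,
                         alphaF = "zero", step = 0.01) {
  if (is.character(species)) species <- load_species(species)
  if (is.null(cycle)) cycle <- species_cycle(species, "constant")
  if (is.null(grid)) grid <- default_grid(species)
  window <- c(species$t0, species$tF)
  cand <- grid_candidates(grid, window, alphaF)
  if (nrow(cand) == 0)
    stop("no valid candidate strategies in the search grid", call. = FALSE)
  ca <- cycle_args(cycle)
  aF_mode <- if (!is.numeric(alphaF) && alphaF == "one_minus_betaF") 1L else 0L
  if (is.numeric(alphaF) && alphaF != 0)
    stop("grid search supports alphaF = 'zero' or 'one_minus_betaF'",
         call. = FALSE)
  ep <- grid_endpoints_cpp(as.matrix(cand), window[1], window[2],
                           species$tM, step, aF_mode,
                           ca$cycle_mode, ca$tc_const, ca$anchor_day,
                           ca$anchor_tc, ca$scale, ca$extrap, ca$floor_h)
  eps <- switch(grid$objective,
                eq4_absolute = abs(ep[, "N_tF"] - ep[, "N_tM"] / species$phi),
                fraction_error = abs(ep[, "N_tM"] / ep[, "N_tF"] - species$phi))
  tab <- cbind(cand, N_tM = ep[, "N_tM"], N_tF = ep[, "N_tF"], epsilon = eps)
  ord <- order(tab$epsilon, tab$tS, tab$alpha0, tab$alphaS, tab$betaF)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  best <- strategy(tab$alpha0[1], tab$alphaS[1], tab$betaF[1], tab$tS[1])
  structure(list(best = best, epsilon = tab$epsilon[1], ranked_table = tab,
                 objective = grid$objective, species = species$name,
                 n_evaluated = nrow(tab)),
            class = "strategy_fit")
}

#' @export
print.strategy_fit <- function(x, ...) {
  cat(sprintf("Strategy fit (%s, %s objective, %d candidates)\n",
              x$species, x$objective, x$n_evaluated))
  cat(sprintf("  best: (%g, %g, %g, %g), epsilon = %.4g\n",
              x$best$alpha0, x$best$alphaS, x$best$betaF, x$best$tS,
              x$epsilon))
  invisible(x)
}
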