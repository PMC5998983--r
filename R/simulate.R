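#' Simulate progenitor and neuron dynamics
#'
#' Integrates the two-population system
#' \deqn{dP/dt = \rho(t) P (1 - \alpha(t) - 2\beta(t)), \quad
#'       dN/dt = \rho(t) P (\alpha(t) + 2\beta(t))}
#' with `P(t0) = P0`, `N(t0) = 0`, where `alpha` and `beta` are the
#' strategy's asymmetric- and symmetric-neurogenic probabilities and
#' `rho(t)` the division rate of the cell-cycle model.  A fixed-step
#' 4th-order Runge-Kutta scheme is used, with the strategy switch time and
#' cell-cycle anchor days inserted exactly into the step grid so the
#' integrator never straddles a kink of the right-hand side; this keeps
#' the solution deterministic across platforms and 4th-order accurate.
#'
#' With `P0 = 1` the returned trajectory is the per-founder system, which
#' is all the strategy search needs: the model is linear in `P0`.
#'
#' @param strat a [strategy()].
#' @param cycle a [cell_cycle_model()].
#' @param window numeric length-2, `(t0, tF)` in embryonic days.
#' @param P0 founder population (default 1: per-founder normalization).
#' @param step integration step in days (default 0.01).
#' @param alphaF terminal convention, see [resolve_alphaF()].
#' @return An object of class `neuro_trajectory`: list with `times`, `P`,
#'   `N`, `P0`, `window`.
#' @examples
#' s <- strategy(0.4, 0.5, 0.7, 14)
#' cc <- cell_cycle_model("constant", Tc = 14.3)
#' tr <- simulate_neurogenesis(s, cc, window = c(11, 19))
#' deeper_layer_fraction(tr, tM = 17)
#' @export
simulate_neurogenesis <- function(strat, cycle, window, P0 = 1, step = 0.01,
                                  alphaF = "zero") {
  stopifnot(inherits(strat, "strategy"), inherits(cycle, "cell_cycle_model"),
            length(window) == 2, step > 0, P0 > 0)
  ok <- validate_strategy(strat, window, alphaF)
  if (!ok)
    stop("invalid strategy: ", paste(attr(ok, "reasons"), collapse = "; "),
         call. = FALSE)
  aF <- resolve_alphaF(alphaF, strat$betaF)
  ca <- cycle_args(cycle)
  m <- sim_trajectory_cpp(window[1], window[2], step,
                          0L, strat$alpha0, strat$alphaS, strat$betaF,
                          strat$tS, aF, 0, 0,
                          ca$cycle_mode, ca$tc_const, ca$anchor_day,
                          ca$anchor_tc, ca$scale, ca$extrap, ca$floor_h, P0)
  new_trajectory(m, P0, window, strat = strat, cycle = cycle)
}

#' Simulate with constant division-mode probabilities
#'
#' Degenerate variant with time-independent `alpha` and `beta`; with
#' constant division rate the system then has a closed-form solution
#' ([closed_form_constant()]), making this the integration test bed: the
#' progenitor pool goes extinct, stays constant, or grows without bound
#' according to the sign of `1 - alpha - 2*beta`.
#'
#' @param alpha,beta constant probabilities, `alpha + beta <= 1`.
#' @inheritParams simulate_neurogenesis
#' @return A `neuro_trajectory`.
#' @export
simulate_constant <- function(alpha, beta, cycle, window, P0 = 1,
                              step = 0.01) {
  stopifnot(alpha >= 0, beta >= 0, alpha + beta <= 1,
            inherits(cycle, "cell_cycle_model"), step > 0, P0 > 0)
  ca <- cycle_args(cycle)
  m <- sim_trajectory_cpp(window[1], window[2], step,
                          1L, 0, 0, 0, 0, 0, alpha, beta,
                          ca$cycle_mode, ca$tc_const, ca$anchor_day,
                          ca$anchor_tc, ca$scale, ca$extrap, ca$floor_h, P0)
  new_trajectory(m, P0, window, cycle = cycle)
}

new_trajectory <- function(m, P0, window, strat = NULL, cycle = NULL) {
  structure(list(times = m[, "time"], P = m[, "P"], N = m[, "N"],
                 P0 = P0, window = window, strategy = strat, cycle = cycle),
            class = "neuro_trajectory")
}

#' Closed-form solution for constant probabilities and rate
#'
#' For constant `alpha`, `beta` and constant rate `rho`, with
#' `k = 1 - alpha - 2*beta`:
#' \deqn{P(t) = P_0 e^{\rho k (t - t_0)}}
#' \deqn{N(t) = P_0 \frac{\alpha + 2\beta}{k}\left(e^{\rho k (t-t_0)} - 1\right)
#'   \quad (k \neq 0), \qquad N(t) = \rho P_0 (\alpha + 2\beta)(t - t_0)
#'   \quad (k = 0).}
#' Used as the independent oracle for the numerical integrator.
#'
#' @param alpha,beta constant probabilities with `alpha + beta <= 1`.
#' @param rho division rate, per day.
#' @param window numeric length-2, `(t0, tF)`.
#' @param P0 founder population.
#' @param t times at which to evaluate.
#' @return Data frame with columns `t`, `P`, `N`.
#' @export
closed_form_constant <- function(alpha, beta, rho, window, P0 = 1,
                                 t = window[2]) {
  stopifnot(alpha >= 0, beta >= 0, alpha + beta <= 1, rho > 0)
  t0 <- window[1]
  k <- 1 - alpha - 2 * beta
  e <- exp(rho * k * (t - t0))
  P <- P0 * e
  N <- if (abs(k) < .Machine$double.eps^0.5)
    rho * P0 * (alpha + 2 * beta) * (t - t0)
  else
    P0 * (alpha + 2 * beta) / k * (e - 1)
  data.frame(t = t, P = P, N = N)
}

#' Interpolate a trajectory at arbitrary times
#'
#' Linear interpolation on the stored step grid (step 0.01 day by
#' default, so the induced error is negligible relative to the strategy
#' search resolution).
#'
#' @param traj a `neuro_trajectory`.
#' @param t times within the trajectory's window.
#' @return Data frame with columns `t`, `P`, `N`.
#' @export
trajectory_at <- function(traj, t) {
  stopifnot(inherits(traj, "neuro_trajectory"))
  if (any(t < traj$window[1] - 1e-9 | t > traj$window[2] + 1e-9))
    stop("query time outside the simulated window", call. = FALSE)
  data.frame(t = t,
             P = approx(traj$times, traj$P, t, rule = 2)$y,
             N = approx(traj$times, traj$N, t, rule = 2)$y)
}

#' Deeper-layer neuron fraction
#'
#' The fraction `N(tM) / N(tF)` of final neurons born before `tM`, the
#' day deeper-layer (V/VI) production completes.  Under the inside-first
#' outside-last layering rule this is the model's deeper-layer fraction,
#' compared against the anatomical `phi` during strategy fitting.
#'
#' @param traj a `neuro_trajectory` spanning `tM`.
#' @param tM embryonic day, strictly inside the window.
#' @return A fraction in \[0, 1\].
#' @export
deeper_layer_fraction <- function(traj, tM) {
  stopifnot(inherits(traj, "neuro_trajectory"))
  NtF <- traj$N[length(traj$N)]
  if (NtF <= 0) stop("N(tF) is zero: deeper-layer fraction undefined",
                     call. = FALSE)
  trajectory_at(traj, tM)$N / NtF
}

#' @export
print.neuro_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Neurogenesis trajectory: E%g - E%g (%d grid points), P0 = %g\n",
              x$window[1], x$window[2], n, x$P0))
  cat(sprintf("  P(tF) = %.6g   N(tF) = %.6g   max P = %.6g\n",
              x$P[n], x$N[n], max(x$P)))
  invisible(x)
}

#' @export
as.data.frame.neuro_trajectory <- function(x, ...) {
  data.frame(time_day = x$times, P = x$P, N = x$N)
}

#' @export
plot.neuro_trajectory <- function(x, ...) {
  graphics::matplot(x$times, cbind(x$P, x$N), type = "l", lty = 1,
                    col = c("firebrick", "steelblue"),
                    xlab = "embryonic day", ylab = "cells", ...)
  graphics::legend("topleft", legend = c("progenitors P", "neurons N"),
                   col = c("firebrick", "steelblue"), lty = 1, bty = "n")
  invisible(x)
}
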