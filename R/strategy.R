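#' Division strategies
#'
#' A strategy is the 4-tuple `(alpha0, alphaS, betaF, tS)` describing how
#' the three division-mode probabilities are modulated across the
#' neurogenesis window `(t0, tF)`:
#'
#' * phase 1 (`t0 <= t <= tS`): the asymmetric-neurogenic probability
#'   `alpha(t)` rises linearly from `alpha0` to `alphaS`; the
#'   symmetric-neurogenic probability `beta(t)` is 0.
#' * phase 2 (`tS <= t <= tF`): `beta(t)` rises linearly from 0 to
#'   `betaF`; `alpha(t)` moves linearly from `alphaS` to a terminal value
#'   `alphaF` (see [resolve_alphaF()]).
#'
#' The self-amplifying probability is `1 - alpha(t) - beta(t)` throughout.
#'
#' @param alpha0 asymmetric-neurogenic probability at onset, in (0, 1).
#' @param alphaS asymmetric-neurogenic probability at the switch, in
#'   `(alpha0, 1]`.
#' @param betaF symmetric-neurogenic probability at the end of
#'   neurogenesis, in (0, 1].
#' @param tS switch time (embryonic day); must satisfy `t0 < tS < tF` for
#'   the window the strategy is used on.
#' @return An object of class `strategy`.
#' @examples
#' s <- strategy(0.4, 0.5, 0.7, 14)   # fitted mouse strategy, constant cycle
#' validate_strategy(s, window = c(11, 19))
#' @export
strategy <- function(alpha0, alphaS, betaF, tS) {
  structure(list(alpha0 = as.numeric(alpha0), alphaS = as.numeric(alphaS),
                 betaF = as.numeric(betaF), tS = as.numeric(tS)),
            class = "strategy")
}

#' @export
print.strategy <- function(x, ...) {
  cat(sprintf("Division strategy: alpha0 = %g, alphaS = %g, betaF = %g, tS = E%g\n",
              x$alpha0, x$alphaS, x$betaF, x$tS))
  invisible(x)
}

#' @export
as.double.strategy <- function(x, ...) {
  c(alpha0 = x$alpha0, alphaS = x$alphaS, betaF = x$betaF, tS = x$tS)
}

#' Terminal asymmetric-division probability
#'
#' The value `alpha(tF)` at the end of neurogenesis is not constrained by
#' the four strategy parameters; the model's hypothesis only requires the
#' asymmetric mode to decline so that symmetric neurogenic divisions
#' dominate late neurogenesis.  Two conventions are supported, plus an
#' arbitrary numeric value:
#'
#' * `"zero"` (default): asymmetric divisions vanish at `tF`, leaving the
#'   terminal mode split `betaF` symmetric-neurogenic versus `1 - betaF`
#'   self-amplifying (a non-depleted progenitor pool remains available for
#'   gliogenesis).
#' * `"one_minus_betaF"`: self-amplification vanishes at `tF`; every
#'   terminal division is neurogenic.
#' * a number in `[0, 1 - betaF]`.
#'
#' @param alphaF `"zero"`, `"one_minus_betaF"`, or a number.
#' @param betaF the strategy's terminal symmetric-neurogenic probability.
#' @return The numeric terminal value of `alpha`.
#' @export
resolve_alphaF <- function(alphaF = c("zero", "one_minus_betaF"), betaF) {
  if (is.numeric(alphaF)) return(alphaF)
  switch(match.arg(alphaF), zero = 0, one_minus_betaF = 1 - betaF)
}

#' Validate a strategy on a neurogenesis window
#'
#' Checks the parameter constraints `0 < alpha0 < 1`,
#' `alpha0 < alphaS <= 1`, `0 < betaF <= 1`, `t0 < tS < tF` (the upper
#' bounds on `alphaS` and `betaF` are closed: fitted strategies reach 1),
#' and the pointwise bounds `alpha, beta >= 0`, `alpha + beta <= 1` over
#' the whole window for the given terminal convention.
#'
#' @param strat a [strategy()].
#' @param window numeric length-2, `(t0, tF)`.
#' @param alphaF terminal convention, see [resolve_alphaF()].
#' @return `TRUE` or `FALSE`, with a character vector of failure reasons
#'   in `attr(, "reasons")`.
#' @export
validate_strategy <- function(strat, window, alphaF = "zero") {
  stopifnot(inherits(strat, "strategy"), length(window) == 2)
  t0 <- window[1]; tF <- window[2]
  aF <- resolve_alphaF(alphaF, strat$betaF)
  reasons <- character(0)
  if (!(strat$alpha0 > 0 && strat$alpha0 < 1))
    reasons <- c(reasons, "alpha0 must lie in (0, 1)")
  if (!(strat$alphaS > strat$alpha0 && strat$alphaS <= 1))
    reasons <- c(reasons, "alphaS must lie in (alpha0, 1]")
  if (!(strat$betaF > 0 && strat$betaF <= 1))
    reasons <- c(reasons, "betaF must lie in (0, 1]")
  if (!(strat$tS > t0 && strat$tS < tF))
    reasons <- c(reasons, sprintf("tS must lie in (%g, %g)", t0, tF))
  if (!(aF >= 0 && aF + strat$betaF <= 1 + 1e-12))
    reasons <- c(reasons,
                 "terminal alpha must lie in [0, 1 - betaF] for valid probabilities")
  structure(length(reasons) == 0, reasons = reasons)
}

#' Division-mode probabilities at given times
#'
#' Evaluates the piecewise-linear probability functions of a strategy.
#' Both linear pieces are continuous across the switch time, the
#' symmetric-neurogenic mode appears only after the switch, and the three
#' probabilities sum to one exactly at every time point.
#'
#' @param strat a [strategy()].
#' @param t numeric vector of embryonic days within the window.
#' @param window numeric length-2, `(t0, tF)`.
#' @param alphaF terminal convention, see [resolve_alphaF()].
#' @return A data frame with columns `t`, `pSymP`, `pAsymN`, `pSymN`.
#' @examples
#' s <- strategy(0.4, 0.5, 0.7, 14)
#' division_probabilities(s, c(11, 14, 19), window = c(11, 19))
#' @export
division_probabilities <- function(strat, t, window, alphaF = "zero") {
  stopifnot(inherits(strat, "strategy"))
  t0 <- window[1]; tF <- window[2]
  if (any(t < t0 - 1e-9 | t > tF + 1e-9))
    stop(sprintf("t outside the neurogenesis window (%g, %g)", t0, tF),
         call. = FALSE)
  ok <- validate_strategy(strat, window, alphaF)
  if (!ok)
    stop("invalid strategy: ", paste(attr(ok, "reasons"), collapse = "; "),
         call. = FALSE)
  aF <- resolve_alphaF(alphaF, strat$betaF)
  tS <- strat$tS
  u1 <- pmin(pmax((t - t0) / (tS - t0), 0), 1)
  u2 <- pmin(pmax((t - tS) / (tF - tS), 0), 1)
  alpha <- ifelse(t <= tS, strat$alpha0 + (strat$alphaS - strat$alpha0) * u1,
                  strat$alphaS + (aF - strat$alphaS) * u2)
  beta <- ifelse(t <= tS, 0, strat$betaF * u2)
  stopifnot(all(alpha >= -1e-12), all(beta >= -1e-12),
            all(alpha + beta <= 1 + 1e-12))
  data.frame(t = t, pSymP = 1 - alpha - beta, pAsymN = alpha, pSymN = beta)
}
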