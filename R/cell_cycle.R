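#' Cell-cycle models
#'
#' The progenitor division rate is tied to the cell-cycle length `T_C` by
#' `rho(t) = ln(2) * 24 / T_C(t)` (per day, with `T_C` in hours), so that
#' a purely self-amplifying population doubles once per cycle.  Two modes
#' are available: a constant `T_C`, and an age-dependent `T_C(t)` obtained
#' by piecewise-linear interpolation through measured anchors
#' `(embryonic day, hours)`.  Outside the anchor range the nearest
#' segment's slope is continued by default (`extrapolation = "linear"`),
#' floored at `floor_hours`; `"hold"` keeps the boundary value instead.
#'
#' @param mode `"constant"` or `"age_dependent"`.
#' @param Tc constant cell-cycle length in hours (constant mode).
#' @param anchors data frame with columns `day` and `hours`, strictly
#'   increasing in `day` (age-dependent mode).
#' @param scale dimensionless multiplier applied to `T_C(t)`; `1.5` and
#'   `2` reproduce the amplified human cell-cycle variants.
#' @param extrapolation `"linear"` or `"hold"`.
#' @param floor_hours lower bound on the scaled cell-cycle length (hours).
#' @return An object of class `cell_cycle_model`.
#' @examples
#' cc <- cell_cycle_model("constant", Tc = 14.3)
#' division_rate(cc, 12)               # ln(2) * 24 / 14.3 per day
#' @export
cell_cycle_model <- function(mode = c("constant", "age_dependent"),
                             Tc = NULL, anchors = NULL, scale = 1,
                             extrapolation = c("linear", "hold"),
                             floor_hours = 1) {
  mode <- match.arg(mode)
  extrapolation <- match.arg(extrapolation)
  stopifnot(scale > 0, floor_hours > 0)
  if (mode == "constant") {
    if (is.null(Tc) || !is.finite(Tc) || Tc <= 0)
      stop("constant mode needs a positive Tc (hours)", call. = FALSE)
    anchors <- NULL
  } else {
    anchors <- as.data.frame(anchors)
    stopifnot(all(c("day", "hours") %in% names(anchors)),
              nrow(anchors) >= 1, all(anchors$hours > 0))
    anchors <- anchors[order(anchors$day), c("day", "hours")]
    if (nrow(anchors) > 1 && any(diff(anchors$day) <= 0))
      stop("anchor days must be strictly increasing", call. = FALSE)
    Tc <- NA_real_
  }
  structure(list(mode = mode, Tc_constant = Tc, anchors = anchors,
                 scale = scale, extrapolation = extrapolation,
                 floor_hours = floor_hours),
            class = "cell_cycle_model")
}

#' Cell-cycle model for a packaged species
#'
#' Convenience constructor using the registry's cell-cycle data.  The
#' human entry carries the macaque anchors and constant-model average as
#' proxies.
#'
#' @param species a [species_params()] object or species name.
#' @param mode `"constant"` or `"age_dependent"`.
#' @param scale multiplier on `T_C(t)` (see [cell_cycle_model()]).
#' @param ... passed on to [cell_cycle_model()].
#' @return A `cell_cycle_model`.
#' @export
species_cycle <- function(species, mode = c("constant", "age_dependent"),
                          scale = 1, ...) {
  if (is.character(species)) species <- load_species(species)
  mode <- match.arg(mode)
  if (mode == "constant")
    cell_cycle_model("constant", Tc = species$Tc_constant, scale = scale, ...)
  else
    cell_cycle_model("age_dependent", anchors = species$Tc_anchors,
                     scale = scale, ...)
}

#' Cell-cycle length at given times
#'
#' @param model a [cell_cycle_model()].
#' @param t numeric vector of embryonic days.
#' @return Cell-cycle lengths in hours (scaled, floored).
#' @examples
#' cc <- cell_cycle_model("age_dependent",
#'                        anchors = data.frame(day = c(12, 16),
#'                                             hours = c(10.2, 18.4)))
#' cell_cycle_length(cc, c(12, 14, 16))   # 10.2, 14.3, 18.4
#' @export
cell_cycle_length <- function(model, t) {
  stopifnot(inherits(model, "cell_cycle_model"))
  if (model$mode == "constant") {
    tc <- rep(model$Tc_constant, length(t))
  } else {
    d <- model$anchors$day
    v <- model$anchors$hours
    n <- length(d)
    if (n == 1) {
      tc <- rep(v, length(t))
    } else if (model$extrapolation == "hold") {
      tc <- approx(d, v, t, rule = 2)$y
    } else {
      tc <- approx(d, v, t)$y
      lo <- t < d[1]; hi <- t > d[n]
      tc[lo] <- v[1] + (t[lo] - d[1]) * (v[2] - v[1]) / (d[2] - d[1])
      tc[hi] <- v[n] + (t[hi] - d[n]) * (v[n] - v[n - 1]) / (d[n] - d[n - 1])
    }
  }
  pmax(tc * model$scale, model$floor_hours)
}

#' Division rate at given times
#'
#' `rho(t) = ln(2) * 24 / T_C(t)` per day; the natural-log convention
#' makes a purely self-amplifying population double exactly once per cell
#' cycle.
#'
#' @inheritParams cell_cycle_length
#' @return Division rates in day^-1.
#' @export
division_rate <- function(model, t) {
  log(2) * 24 / cell_cycle_length(model, t)
}

#' @export
print.cell_cycle_model <- function(x, ...) {
  if (x$mode == "constant") {
    cat(sprintf("Cell-cycle model: constant, T_C = %g h", x$Tc_constant))
  } else {
    cat(sprintf("Cell-cycle model: age-dependent through %s (%s extrapolation)",
                paste(sprintf("E%g:%gh", x$anchors$day, x$anchors$hours),
                      collapse = ", "), x$extrapolation))
  }
  if (x$scale != 1) cat(sprintf(", scale x%g", x$scale))
  cat("\n")
  invisible(x)
}

# flatten for the C++ core
cycle_args <- function(model) {
  list(cycle_mode = if (model$mode == "constant") 0L else 1L,
       tc_const = if (is.na(model$Tc_constant)) 0 else model$Tc_constant,
       anchor_day = if (is.null(model$anchors)) numeric(0) else model$anchors$day,
       anchor_tc = if (is.null(model$anchors)) numeric(0) else model$anchors$hours,
       scale = model$scale,
       extrap = if (model$extrapolation == "linear") 0L else 1L,
       floor_h = model$floor_hours)
}
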