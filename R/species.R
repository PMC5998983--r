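#' Species parameter sets for cortical neurogenesis
#'
#' A `species_params` object bundles everything the model needs to know
#' about one species: the neurogenesis window on the embryonic-day axis,
#' the deeper-layer neuron fraction used as the strategy-fitting
#' constraint, the adult neocortical neuron count, the demographic
#' adjustment fractions that convert adult counts into a neurogenic-output
#' target, cell-cycle data, and (where available) reference division
#' strategies and a literature founder-population size.
#'
#' @param name species identifier.
#' @param t0,tF embryonic days of neurogenesis onset and end.
#' @param tM embryonic day at which deeper-layer (V/VI) neuron production
#'   completes and layer IV production starts.
#' @param phi fraction of final neurons residing in the deeper layers,
#'   strictly between 0 and 1.
#' @param N_adult adult neocortical neuron count.
#' @param P0_literature literature founder-population size (cells), or `NA`
#'   when no experimental estimate exists.
#' @param death_fraction fraction of locally produced neurons lost to
#'   post-neurogenesis cell death (default 0.30).
#' @param migration_fraction fraction of adult cortical neurons that
#'   immigrated from outside the neocortical proliferative zone, mostly
#'   interneurons (default 0.25).
#' @param Tc_constant constant-model cell-cycle length in hours.
#' @param Tc_anchors data frame (or list) with columns/fields `day` and
#'   `hours` giving measured cell-cycle lengths for the age-dependent model.
#' @param reference_strategy named list of reference strategies, each a
#'   numeric 4-vector `(alpha0, alphaS, betaF, tS)`.
#'
#' @return An object of class `species_params`.
#' @seealso [load_species()], [load_config()], [write_config()]
#' @export
species_params <- function(name, t0, tF, tM, phi, N_adult,
                           P0_literature = NA_real_,
                           death_fraction = 0.30,
                           migration_fraction = 0.25,
                           Tc_constant = NA_real_,
                           Tc_anchors = NULL,
                           reference_strategy = list()) {
  if (!is.null(Tc_anchors)) {
    Tc_anchors <- as.data.frame(Tc_anchors)
    stopifnot(all(c("day", "hours") %in% names(Tc_anchors)))
    Tc_anchors <- Tc_anchors[order(Tc_anchors$day), c("day", "hours")]
  }
  obj <- structure(list(
    name = as.character(name),
    t0 = as.numeric(t0), tF = as.numeric(tF), tM = as.numeric(tM),
    phi = as.numeric(phi), N_adult = as.numeric(N_adult),
    P0_literature = as.numeric(P0_literature),
    death_fraction = as.numeric(death_fraction),
    migration_fraction = as.numeric(migration_fraction),
    Tc_constant = as.numeric(Tc_constant),
    Tc_anchors = Tc_anchors,
    reference_strategy = reference_strategy
  ), class = "species_params")
  validate_species_params(obj)
  obj
}

#' Validate a species parameter set
#'
#' Checks the ordering `t0 < tM < tF`, that `phi` lies in (0, 1), that the
#' demographic fractions lie in \[0, 1), that `N_adult` is positive, and
#' that any cell-cycle data are positive with strictly increasing anchor
#' days.  Errors name the offending field.
#'
#' @param x a `species_params` object.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_species_params <- function(x) {
  stopifnot(inherits(x, "species_params"))
  fail <- function(field, msg) {
    stop(sprintf("invalid species parameters ('%s'): field '%s' %s",
                 x$name, field, msg), call. = FALSE)
  }
  if (!is.finite(x$t0) || !is.finite(x$tF) || !is.finite(x$tM))
    fail("t0/tM/tF", "must be finite")
  if (!(x$t0 < x$tM)) fail("tM", sprintf("must exceed t0 = %g", x$t0))
  if (!(x$tM < x$tF)) fail("tM", sprintf("must be below tF = %g", x$tF))
  if (!is.finite(x$phi) || x$phi <= 0 || x$phi >= 1)
    fail("phi", "must lie strictly between 0 and 1")
  if (!is.finite(x$N_adult) || x$N_adult <= 0)
    fail("N_adult", "must be positive")
  if (!is.finite(x$death_fraction) || x$death_fraction < 0 ||
      x$death_fraction >= 1)
    fail("death_fraction", "must lie in [0, 1)")
  if (!is.finite(x$migration_fraction) || x$migration_fraction < 0 ||
      x$migration_fraction >= 1)
    fail("migration_fraction", "must lie in [0, 1)")
  if (!is.na(x$Tc_constant) && x$Tc_constant <= 0)
    fail("Tc_constant", "must be positive")
  if (!is.null(x$Tc_anchors)) {
    if (any(x$Tc_anchors$hours <= 0))
      fail("Tc_anchors", "hours must be positive")
    if (nrow(x$Tc_anchors) > 1 && any(diff(x$Tc_anchors$day) <= 0))
      fail("Tc_anchors", "days must be strictly increasing")
  }
  invisible(x)
}

species_registry <- function() {
  if (is.null(.corticogen$registry)) {
    path <- system.file("extdata", "species.yaml", package = "corticogen",
                        mustWork = TRUE)
    .corticogen$registry <- yaml::read_yaml(path)
  }
  .corticogen$registry
}

params_from_list <- function(name, lst) {
  anchors <- lst$Tc_anchors
  if (!is.null(anchors)) anchors <- data.frame(day = unlist(anchors$day),
                                               hours = unlist(anchors$hours))
  refs <- lapply(lst$reference_strategy, function(v) as.numeric(unlist(v)))
  species_params(
    name = name,
    t0 = lst$t0, tF = lst$tF, tM = lst$tM, phi = lst$phi,
    N_adult = lst$N_adult,
    P0_literature = if (is.null(lst$P0_literature)) NA_real_ else lst$P0_literature,
    death_fraction = lst$death_fraction %||% 0.30,
    migration_fraction = lst$migration_fraction %||% 0.25,
    Tc_constant = lst$Tc_constant %||% NA_real_,
    Tc_anchors = anchors,
    reference_strategy = refs
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a packaged species parameter set
#'
#' Returns the registry entry for one of the packaged species
#' (`"mouse"`, `"macaque"`, `"human"`).  Mouse values come from direct
#' experimental measurements; the macaque neurogenesis end uses the 60-day
#' primary-visual-cortex duration; human cell-cycle data and deeper-layer
#' fraction are macaque proxies (no in-vivo human quantification exists)
#' and should be treated as first approximations.
#'
#' @param name species identifier.
#' @return A [species_params()] object.
#' @examples
#' mouse <- load_species("mouse")
#' mouse$tM        # 17
#' mouse$phi       # 0.52
#' @export
load_species <- function(name) {
  reg <- species_registry()
  if (!name %in% names(reg))
    stop(sprintf("unknown species '%s'; registered species: %s", name,
                 paste(names(reg), collapse = ", ")), call. = FALSE)
  params_from_list(name, reg[[name]])
}

#' Read a species configuration file
#'
#' Reads a YAML configuration that either names a base species (key
#' `species:`) with any subset of fields overridden, or specifies a full
#' parameter set under a `name:` key.  The merged result is validated;
#' violations name the offending field.
#'
#' @param path path to a YAML file.
#' @return A [species_params()] object.
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines(c("species: human", "death_fraction: 0.8"), cfg)
#' load_config(cfg)$death_fraction  # 0.8
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("configuration must be a YAML mapping", call. = FALSE)
  if (!is.null(cfg$species)) {
    base <- load_species(cfg$species)
    over <- cfg[setdiff(names(cfg), "species")]
    lst <- modifyList(as_config_list(base), over)
    params_from_list(base$name, lst)
  } else {
    if (is.null(cfg$name))
      stop("configuration needs either a 'species' base or a full set with 'name'",
           call. = FALSE)
    params_from_list(cfg$name, cfg)
  }
}

as_config_list <- function(params) {
  lst <- unclass(params)
  lst$name <- NULL
  if (!is.null(lst$Tc_anchors))
    lst$Tc_anchors <- list(day = lst$Tc_anchors$day,
                           hours = lst$Tc_anchors$hours)
  if (is.na(lst$P0_literature)) lst$P0_literature <- NULL
  lst
}

#' Write a species parameter set to a configuration file
#'
#' The written file reloads via [load_config()] to an identical parameter
#' set (round-trip property).
#'
#' @param params a [species_params()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  stopifnot(inherits(params, "species_params"))
  lst <- c(list(name = params$name), as_config_list(params))
  yaml::write_yaml(lst, path, precision = 15)
  invisible(path)
}

#' @export
print.species_params <- function(x, ...) {
  cat(sprintf("Species parameters: %s\n", x$name))
  cat(sprintf("  neurogenesis window : E%g - E%g (tM = E%g)\n",
              x$t0, x$tF, x$tM))
  cat(sprintf("  deeper-layer fraction phi : %g\n", x$phi))
  cat(sprintf("  adult neocortical neurons : %.4g\n", x$N_adult))
  if (!is.na(x$P0_literature))
    cat(sprintf("  literature founder population : %g\n", x$P0_literature))
  cat(sprintf("  death / migration fractions : %g / %g\n",
              x$death_fraction, x$migration_fraction))
  if (!is.na(x$Tc_constant))
    cat(sprintf("  cell cycle (constant) : %g h\n", x$Tc_constant))
  if (!is.null(x$Tc_anchors))
    cat(sprintf("  cell cycle anchors : %s\n",
                paste(sprintf("E%g:%gh", x$Tc_anchors$day,
                              x$Tc_anchors$hours), collapse = ", ")))
  if (length(x$reference_strategy))
    cat(sprintf("  reference strategies : %s\n",
                paste(names(x$reference_strategy), collapse = ", ")))
  invisible(x)
}
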