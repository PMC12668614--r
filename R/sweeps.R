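# Simulation sweeps over molecular composition: vary one molecule group (or
# all dry groups jointly), trace the sinking-velocity curve with its
# first-order density/volume split, locate buoyancy-reversal thresholds, and
# attribute observed sinking changes to measured component changes.

.DRY_COMPONENTS <- c("protein", "lipid", "carbohydrate", "other")

.sweep_targets <- function(component) {
  component <- match.arg(component, c(.COMPONENTS, "dry"))
  if (component == "dry") .DRY_COMPONENTS else component
}

# scale the target group volume(s) by `fold`
.scale_composition <- function(comp, targets, fold) {
  v <- unclass(comp)
  v[targets] <- v[targets] * fold
  if (sum(v) <= 0) .psk_error("fold yields zero total volume", "psk_domain")
  structure(v, class = "psk_composition")
}

#' Default fold grid for composition sweeps
#'
#' 48 log-spaced points from 0.25-fold (strong depletion) to 20-fold
#' accumulation, covering the multi-fold compositional changes starvation
#' can produce.
#' @return numeric vector of folds.
#' @export
default_fold_grid <- function() exp(seq(log(0.25), log(20), length.out = 48))

#' Sweep one molecular component and trace the sinking curve
#'
#' Scales the volume of one molecule group (or, for `component = "dry"`, all
#' non-water groups together) by each fold in `folds` while all other groups
#' stay fixed, recomputes the cell state and Stokes velocity, and splits the
#' velocity change into its density and volume contributions using the
#' first-order Taylor expansion at fold = 1. Rows where the first-order
#' split misses the exact change by more than `taylor_tol` (relative) are
#' flagged `taylor_valid = FALSE`; this happens for large water increases,
#' where the expansion breaks down.
#'
#' @param baseline a [molecular_composition()].
#' @param dens a [component_densities()].
#' @param component one of water, protein, lipid, carbohydrate, other, dry.
#' @param folds positive fold factors (default [default_fold_grid()]).
#' @param fluid a [fluid_environment()].
#' @param shape a [cell_shape()].
#' @param taylor_tol relative discrepancy above which the first-order split
#'   is flagged invalid (default 0.2).
#' @return data.frame of class `psk_sweep` with columns `component`, `fold`,
#'   `volume_fl`, `density_g_ml`, `velocity_um_s`, `density_contribution`,
#'   `volume_contribution`, `taylor_valid`; the baseline [cell_state()] is
#'   attached as attribute `baseline_state`.
#' @export
sweep_component <- function(baseline, dens = component_densities(),
                            component = "water", folds = default_fold_grid(),
                            fluid = fluid_environment(), shape = cell_shape(),
                            taylor_tol = 0.2) {
  if (any(!is.finite(folds)) || any(folds <= 0)) {
    .psk_error("folds must be positive", "psk_domain")
  }
  if (is.unsorted(folds, strictly = TRUE) && length(folds) > 1) {
    folds <- sort(folds)
  }
  targets <- .sweep_targets(component)
  base_state <- composition_to_cell_state(baseline, dens, shape)
  v0 <- sinking_velocity(base_state, fluid)
  partials <- taylor_partials(
    "density_volume", c(density = base_state$density,
                        radius = base_state$radius), fluid, shape)

  rows <- lapply(folds, function(f) {
    st <- composition_to_cell_state(.scale_composition(baseline, targets, f),
                                    dens, shape)
    v <- sinking_velocity(st, fluid)
    term_rho <- partials[["density"]] * (st$density - base_state$density)
    term_r <- partials[["radius"]] * (st$radius - base_state$radius)
    dv <- v - v0
    valid <- if (dv == 0) TRUE else
      abs((term_rho + term_r) - dv) <= taylor_tol * abs(dv)
    data.frame(component = component, fold = f, volume_fl = st$volume,
               density_g_ml = st$density, velocity_um_s = v,
               density_contribution = term_rho, volume_contribution = term_r,
               taylor_valid = valid)
  })
  out <- suppressWarnings(do.call(rbind, rows))
  attr(out, "baseline_state") <- base_state
  class(out) <- c("psk_sweep", class(out))
  out
}

#' Fold change at which a component reverses cell buoyancy
#'
#' Finds the fold factor on one molecule group (or on all dry contents) at
#' which the cell density equals the fluid density, i.e. the cell becomes
#' neutrally buoyant. `mode = "accumulate"` searches folds >= 1,
#' `mode = "deplete"` searches folds in (0, 1]. As fold grows the cell
#' density tends to the (volume-weighted) density of the scaled group(s);
#' when that limit does not cross the fluid density the threshold is
#' reported unreachable rather than an error.
#'
#' @inheritParams sweep_component
#' @param mode `"accumulate"` or `"deplete"`.
#' @param max_fold upper bracket for accumulation (default 1e6).
#' @param tol density residual tolerance at the solution, g/mL.
#' @return list of class `psk_threshold`: `component`, `mode`, `reachable`,
#'   `fold` (NA when unreachable), `residual` (g/mL).
#' @export
#' @examples
#' comp <- molecular_composition(water = 50, protein = 50)
#' buoyancy_threshold(comp, component = "water")  # fold ~ 11.57
buoyancy_threshold <- function(baseline, dens = component_densities(),
                               component = "water",
                               mode = c("accumulate", "deplete"),
                               fluid = fluid_environment(),
                               max_fold = 1e6, tol = 1e-6) {
  mode <- match.arg(mode)
  targets <- .sweep_targets(component)
  v <- unclass(baseline)
  if (sum(v[targets]) <= 0) {
    .psk_error(sprintf(
      "component '%s' has zero baseline volume; scaling it cannot change buoyancy",
      component), "psk_domain")
  }
  rho_at <- function(f) {
    composition_to_cell_state(.scale_composition(baseline, targets, f),
                              dens)$density
  }
  g <- function(f) suppressWarnings(rho_at(f)) - fluid$density
  g1 <- g(1)
  if (abs(g1) < tol) {
    out <- list(component = component, mode = mode, reachable = TRUE,
                fold = 1, residual = g1)
    class(out) <- "psk_threshold"
    return(out)
  }
  # asymptotic density: fold -> Inf gives the scaled set's mean density,
  # fold -> 0 gives the complement's mean density
  other <- setdiff(.COMPONENTS, targets)
  rho_target <- sum(v[targets] * dens[targets]) / sum(v[targets])
  rho_limit <- if (mode == "accumulate") rho_target else {
    if (sum(v[other]) > 0) sum(v[other] * dens[other]) / sum(v[other]) else
      rho_target
  }
  g_limit <- rho_limit - fluid$density
  reachable <- sign(g1) != sign(g_limit) && g_limit != 0
  if (!reachable && sign(g1) == sign(g_limit)) {
    out <- list(component = component, mode = mode, reachable = FALSE,
                fold = NA_real_, residual = NA_real_)
    class(out) <- "psk_threshold"
    return(out)
  }
  # expand bracket geometrically until the sign flips
  if (mode == "accumulate") {
    hi <- 2
    while (hi <= max_fold && sign(g(hi)) == sign(g1)) hi <- hi * 2
    if (hi > max_fold) {
      out <- list(component = component, mode = mode, reachable = FALSE,
                  fold = NA_real_, residual = NA_real_)
      class(out) <- "psk_threshold"
      return(out)
    }
    bracket <- c(hi / 2, hi)
  } else {
    lo <- 0.5
    while (lo >= 1e-9 && sign(g(lo)) == sign(g1)) lo <- lo / 2
    if (lo < 1e-9) {
      out <- list(component = component, mode = mode, reachable = FALSE,
                  fold = NA_real_, residual = NA_real_)
      class(out) <- "psk_threshold"
      return(out)
    }
    bracket <- c(lo, min(1, lo * 2))
  }
  root <- stats::uniroot(g, interval = bracket, tol = 1e-12)
  out <- list(component = component, mode = mode, reachable = TRUE,
              fold = root$root, residual = g(root$root))
  class(out) <- "psk_threshold"
  out
}

#' @export
print.psk_threshold <- function(x, ...) {
  if (x$reachable) {
    cat(sprintf("<buoyancy threshold> %s %s: fold = %.4f (residual %.2e g/mL)\n",
                x$mode, x$component, x$fold, x$residual))
  } else {
    cat(sprintf("<buoyancy threshold> %s %s: unreachable\n",
                x$mode, x$component))
  }
  invisible(x)
}

#' Attribute an observed sinking change to measured component changes
#'
#' Applies the stated per-group volume changes to the baseline composition,
#' simulates the resulting velocity change, and expresses it as a percentage
#' of the experimentally observed change. Values near 100% mean the stated
#' compositional change alone explains the observation.
#'
#' @param baseline a [molecular_composition()].
#' @param dens a [component_densities()].
#' @param component_deltas named numeric vector of volume changes in fL
#'   (names among water, protein, lipid, carbohydrate, other).
#' @param observed_delta_v observed sinking-velocity change, um/s (non-zero).
#' @param fluid a [fluid_environment()].
#' @param shape a [cell_shape()].
#' @return list of class `psk_attribution`: `components`,
#'   `simulated_delta_v`, `observed_delta_v`, `percent_explained`.
#' @export
attribute_observed_change <- function(baseline, dens = component_densities(),
                                      component_deltas, observed_delta_v,
                                      fluid = fluid_environment(),
                                      shape = cell_shape()) {
  if (!is.finite(observed_delta_v) || observed_delta_v == 0) {
    .psk_error("observed velocity change must be non-zero",
               "psk_attribution_undefined")
  }
  bad <- setdiff(names(component_deltas), .COMPONENTS)
  if (length(bad)) {
    .psk_error(paste("unknown components:", paste(bad, collapse = ", ")),
               "psk_domain")
  }
  v <- unclass(baseline)
  v[names(component_deltas)] <- v[names(component_deltas)] + component_deltas
  if (any(v < 0)) .psk_error("deltas drive a component volume negative",
                             "psk_domain")
  perturbed <- structure(v, class = "psk_composition")
  v0 <- sinking_velocity(composition_to_cell_state(baseline, dens, shape),
                         fluid)
  v1 <- sinking_velocity(composition_to_cell_state(perturbed, dens, shape),
                         fluid)
  sim <- v1 - v0
  structure(list(components = names(component_deltas),
                 simulated_delta_v = sim,
                 observed_delta_v = observed_delta_v,
                 percent_explained = 100 * sim / observed_delta_v),
            class = "psk_attribution")
}
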