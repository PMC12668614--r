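# First-order Taylor attribution of sinking-velocity changes.
#
# Two factorisations of Stokes velocity are supported:
#   density_volume: v = f(rho, r)                 (biophysical level)
#   water_dry:      v = f(Vwater, Vdry, rho_dry)  (molecular level,
#                                                  water density constant)
# The influence of a factor is its Taylor term at the baseline (control)
# state divided by the sum of all terms; influences are signed and sum to 1.

.psk_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "psk_error")))
}

# Stokes prefactor C such that v[um/s] = C * (rho - rho_fluid)[g/mL] * r[um]^2
.stokes_prefactor <- function(fluid, shape) {
  2 * fluid$gravity * shape$phi / (9 * fluid$viscosity) *
    .GML_TO_SI * .UM_TO_M^2 * .MS_TO_UMS
}

#' Closed-form partial derivatives of sinking velocity
#'
#' Exposes the partials the Taylor decompositions are built from, in package
#' units, so they can be verified against finite differences.
#'
#' For `mode = "density_volume"` the baseline is `c(density=, radius=)`
#' (g/mL, um) and the partials are with respect to density (um/s per g/mL)
#' and radius (um/s per um).
#'
#' For `mode = "water_dry"` the baseline is
#' `c(water_volume=, dry_volume=, dry_density=)` (fL, fL, g/mL); the cell is
#' `V = Vw + Vd`, `rho = (Vw rho_w + Vd rho_d)/V`, `r = (3V/4pi)^(1/3)`,
#' and the partials are per fL, per fL and per g/mL respectively.
#'
#' @param mode `"density_volume"` or `"water_dry"`.
#' @param baseline named numeric baseline state (see above).
#' @param fluid a [fluid_environment()].
#' @param shape a [cell_shape()].
#' @param water_density intracellular water density, g/mL (water_dry mode).
#' @return named numeric vector of partial derivatives.
#' @export
taylor_partials <- function(mode = c("density_volume", "water_dry"),
                            baseline, fluid = fluid_environment(),
                            shape = cell_shape(), water_density = 0.998) {
  mode <- match.arg(mode)
  C <- .stokes_prefactor(fluid, shape)
  if (mode == "density_volume") {
    rho <- baseline[["density"]]
    r <- baseline[["radius"]]
    c(density = C * r^2,
      radius = 2 * C * (rho - fluid$density) * r)
  } else {
    vw <- baseline[["water_volume"]]
    vd <- baseline[["dry_volume"]]
    rd <- baseline[["dry_density"]]
    v_tot <- vw + vd
    if (v_tot <= 0) .psk_error("total volume must be positive", "psk_domain")
    m <- vw * water_density + vd * rd
    a <- (3 / (4 * pi))^(2 / 3)
    common <- C * a * v_tot^(-1 / 3)
    c(water_volume = common *
        (water_density - m / (3 * v_tot) - 2 / 3 * fluid$density),
      dry_volume = common * (rd - m / (3 * v_tot) - 2 / 3 * fluid$density),
      dry_density = common * vd)
  }
}

# shared core: terms -> influences with degeneracy guards
.influence_from_terms <- function(terms, deltas, mode, baseline, perturbed) {
  if (all(deltas == 0)) {
    .psk_error("baseline and perturbed states are identical; no change to attribute",
               "psk_no_change")
  }
  total <- sum(terms)
  if (abs(total) < 1e-9 * max(abs(terms))) {
    .psk_error("Taylor terms cancel; decomposition undefined",
               "psk_decomposition_undefined")
  }
  infl <- terms / total
  structure(list(mode = mode, baseline = baseline, perturbed = perturbed,
                 terms = terms, influences = infl,
                 first_order_delta_v = total, valid = TRUE),
            class = "psk_influence")
}

#' @export
print.psk_influence <- function(x, ...) {
  cat(sprintf("<influence decomposition: %s>\n", x$mode))
  print(round(x$influences, 4))
  invisible(x)
}

#' Influence of cell density vs cell volume on a sinking change
#'
#' First-order Taylor expansion of Stokes velocity in (density, radius)
#' about the baseline (high-nutrient) state. `I_density` is the density
#' term's share of the total first-order change and `I_volume = 1 -
#' I_density`. Influences are signed: values outside `[0, 1]` mean the two
#' factors pushed the velocity in opposite directions.
#'
#' @param baseline,perturbed named vectors `c(density=, radius=)` in g/mL
#'   and um, or [cell_state()] objects. Volume changes enter through the
#'   equivalent radius.
#' @param fluid a [fluid_environment()].
#' @param shape a [cell_shape()].
#' @return A `psk_influence` with influences `density` and `volume`.
#' @export
#' @examples
#' influence_density_volume(c(density = 1.08, radius = 2),
#'                          c(density = 1.10, radius = 2.1))
influence_density_volume <- function(baseline, perturbed,
                                     fluid = fluid_environment(),
                                     shape = cell_shape()) {
  as_dr <- function(x) {
    if (inherits(x, "psk_cell_state")) c(density = x$density, radius = x$radius)
    else x[c("density", "radius")]
  }
  b <- as_dr(baseline); p <- as_dr(perturbed)
  partials <- taylor_partials("density_volume", b, fluid, shape)
  deltas <- p - b
  terms <- partials * deltas
  res <- .influence_from_terms(terms, deltas, "density_volume", b, p)
  names(res$influences) <- names(res$terms) <- c("density", "volume")
  # exact identity of the two-factor split
  res$influences[["volume"]] <- 1 - res$influences[["density"]]
  res
}

#' Influence of water volume, dry volume and dry density on a sinking change
#'
#' Stokes velocity is rewritten as `f(Vwater, Vdry, rho_dry)` with water
#' density held constant; the three Taylor terms at the baseline
#' (high-nutrient) state are each divided by their sum. The dry-content
#' influence is reported as `I_dry = I_dry_volume + I_dry_density`.
#'
#' @param baseline,perturbed named vectors
#'   `c(water_volume=, dry_volume=, dry_density=)` (fL, fL, g/mL).
#' @param fluid a [fluid_environment()].
#' @param water_density intracellular water density, g/mL.
#' @param shape a [cell_shape()].
#' @return A `psk_influence` with influences `water`, `dry_volume`,
#'   `dry_density` and derived `dry`.
#' @export
influence_water_dry <- function(baseline, perturbed,
                                fluid = fluid_environment(),
                                water_density = 0.998,
                                shape = cell_shape()) {
  keys <- c("water_volume", "dry_volume", "dry_density")
  b <- baseline[keys]; p <- perturbed[keys]
  if (any(b[1:2] < 0) || any(p[1:2] < 0) || sum(b[1:2]) <= 0 ||
      sum(p[1:2]) <= 0) {
    .psk_error("volumes must be non-negative with positive totals",
               "psk_domain")
  }
  partials <- taylor_partials("water_dry", b, fluid, shape, water_density)
  deltas <- p - b
  terms <- partials * deltas
  res <- .influence_from_terms(terms, deltas, "water_dry", b, p)
  names(res$influences) <- names(res$terms) <- c("water", "dry_volume",
                                                 "dry_density")
  res$influences[["dry"]] <-
    res$influences[["dry_volume"]] + res$influences[["dry_density"]]
  res
}
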