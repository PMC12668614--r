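# Core physical model: molecular composition -> cell state -> Stokes sinking.
#
# Unit convention (all user-facing numbers):
#   densities g/mL (== pg/fL), volumes fL (== um^3), radii um, velocities um/s,
#   dynamic viscosity Pa.s, gravity m/s^2.  Physics is evaluated in SI
#   internally and converted at the boundary.

# unit conversion constants
.GML_TO_SI <- 1000      # g/mL -> kg/m^3
.UM_TO_M   <- 1e-6      # um -> m
.FL_TO_M3  <- 1e-18     # fL -> m^3
.MS_TO_UMS <- 1e6       # m/s -> um/s

.COMPONENTS <- c("water", "protein", "lipid", "carbohydrate", "other")

#' Molecular group densities
#'
#' Densities of the five molecular groups a cell is modelled as: water,
#' protein, lipid, carbohydrate and a lumped "other" group. Defaults are the
#' standard literature values for macromolecules (protein 1.35, lipid 0.92,
#' carbohydrate 1.50 g/mL), pure water at ~22 C (0.998 g/mL) and a
#' configurable 1.30 g/mL for the heterogeneous remainder.
#'
#' @param water,protein,lipid,carbohydrate,other densities in g/mL.
#' @return A named numeric vector of class `psk_densities`.
#' @export
#' @examples
#' component_densities()
component_densities <- function(water = 0.998, protein = 1.35, lipid = 0.92,
                                carbohydrate = 1.50, other = 1.30) {
  d <- c(water = water, protein = protein, lipid = lipid,
         carbohydrate = carbohydrate, other = other)
  if (any(!is.finite(d)) || any(d <= 0) || any(d >= 3)) {
    stop("component densities must be finite, positive and below 3 g/mL",
         call. = FALSE)
  }
  structure(d, class = "psk_densities")
}

#' Molecular composition of a cell
#'
#' Volume of each molecular group in a single (average) cell, in fL.
#' The cell volume is the sum of the group volumes and the cell density is
#' their volume-weighted mean density.
#'
#' @param water,protein,lipid,carbohydrate,other volumes in fL; each >= 0,
#'   total > 0.
#' @return Named numeric vector of class `psk_composition`.
#' @export
#' @examples
#' molecular_composition(water = 60, protein = 20, lipid = 5,
#'                       carbohydrate = 10, other = 5)
molecular_composition <- function(water = 0, protein = 0, lipid = 0,
                                  carbohydrate = 0, other = 0) {
  v <- c(water = water, protein = protein, lipid = lipid,
         carbohydrate = carbohydrate, other = other)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("component volumes must be finite and non-negative", call. = FALSE)
  }
  if (sum(v) <= 0) {
    stop("invalid composition: total volume must be positive", call. = FALSE)
  }
  structure(v, class = "psk_composition")
}

#' Fluid environment
#'
#' Physical properties of the medium the cells sink in. Defaults are surface
#' seawater: density 1.026 g/mL, dynamic viscosity 1.07e-3 Pa.s, g = 9.81
#' m/s^2. `water_density` is the density of the water making up the medium
#' (used by the synthetic generator to model full intracellular water
#' exchange); for plain seawater it is 0.998 g/mL.
#'
#' @param density fluid density, g/mL.
#' @param viscosity dynamic viscosity, Pa.s.
#' @param gravity gravitational acceleration, m/s^2.
#' @param water_density density of the medium's water fraction, g/mL.
#' @return List of class `psk_fluid`.
#' @export
fluid_environment <- function(density = 1.026, viscosity = 1.07e-3,
                              gravity = 9.81, water_density = 0.998) {
  vals <- c(density, viscosity, gravity, water_density)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("fluid properties must be finite and positive", call. = FALSE)
  }
  structure(list(density = density, viscosity = viscosity, gravity = gravity,
                 water_density = water_density),
            class = "psk_fluid")
}

#' Seawater with 90% of its water deuterated
#'
#' Convenience constructor for the heavy-water measurement medium used in
#' dual-fluid dry-content determination. The default solution density
#' (1.122 g/mL) corresponds to seawater whose water is 90% D2O; its water
#' fraction (1.094 g/mL) sits at the same salt offset (+0.028 g/mL) as the
#' plain medium, which is what full water exchange implies.
#'
#' @param density solution density, g/mL (a measured input in practice).
#' @param water_density density of the 90% D2O water itself, g/mL.
#' @inheritParams fluid_environment
#' @return List of class `psk_fluid`.
#' @export
fluid_d2o <- function(density = 1.122, water_density = 1.094,
                      viscosity = 1.07e-3, gravity = 9.81) {
  fluid_environment(density = density, viscosity = viscosity,
                    gravity = gravity, water_density = water_density)
}

#' Cell shape and its Stokes drag correction
#'
#' All species handled here are close enough to spheres, spheroids or
#' ellipsoids that the drag correction is a single multiplicative factor
#' `phi` on the Stokes velocity. A sphere has `phi = 1` exactly; corrections
#' further than 10% from a sphere trigger a warning because the model is not
#' meant for strongly elongated particles.
#'
#' @param kind one of "sphere", "spheroid", "ellipsoid".
#' @param phi shape correction factor (> 0). Forced to 1 for spheres.
#' @param aspect_ratios optional numeric vector of axis ratios (metadata
#'   only; no analytic drag formula is applied).
#' @return List of class `psk_shape`.
#' @export
cell_shape <- function(kind = c("sphere", "spheroid", "ellipsoid"),
                       phi = 1.0, aspect_ratios = NULL) {
  kind <- match.arg(kind)
  if (!is.finite(phi) || phi <= 0) {
    stop("shape correction factor phi must be positive", call. = FALSE)
  }
  if (kind == "sphere") {
    phi <- 1.0
  } else if (abs(phi - 1) > 0.1) {
    warning("shape correction |phi - 1| > 0.1; model intended for ",
            "near-spherical cells", call. = FALSE)
  }
  structure(list(kind = kind, phi = phi, aspect_ratios = aspect_ratios),
            class = "psk_shape")
}

#' Equivalent spherical radius from volume
#'
#' @param volume cell volume(s), fL.
#' @return radius in um, `(3 V / 4 pi)^(1/3)`.
#' @export
#' @examples
#' equivalent_radius(4 * pi / 3)  # 1 um
equivalent_radius <- function(volume) {
  if (any(!is.finite(volume)) || any(volume <= 0)) {
    stop("volume must be positive", call. = FALSE)
  }
  (3 * volume / (4 * pi))^(1 / 3)
}

#' Biophysical state of a cell
#'
#' Total volume, density and equivalent spherical radius, plus shape. Radius
#' is always derived from volume. Densities outside the plausible biological
#' range (0.85, 1.7) g/mL warn but are kept, so that simulation sweeps can
#' explore extremes.
#'
#' @param volume total cell volume, fL.
#' @param density cell density, g/mL.
#' @param shape a [cell_shape()].
#' @return List of class `psk_cell_state` with fields `volume`, `density`,
#'   `radius`, `shape`.
#' @export
cell_state <- function(volume, density, shape = cell_shape()) {
  if (!is.finite(density) || density <= 0) {
    stop("cell density must be positive", call. = FALSE)
  }
  r <- equivalent_radius(volume)
  if (density <= 0.85 || density >= 1.7) {
    warning(sprintf("cell density %.4g g/mL outside plausible (0.85, 1.7)",
                    density), call. = FALSE)
  }
  structure(list(volume = volume, density = density, radius = r,
                 shape = shape),
            class = "psk_cell_state")
}

#' @export
print.psk_cell_state <- function(x, ...) {
  cat(sprintf(
    "<cell state> V = %.4g fL, rho = %.4f g/mL, r = %.3f um, shape = %s (phi = %.3f)\n",
    x$volume, x$density, x$radius, x$shape$kind, x$shape$phi))
  invisible(x)
}

#' Cell state from molecular composition
#'
#' The cell volume is the sum of the molecular group volumes,
#' `V = sum(V_i)`, and the cell density is the volume-weighted mean of the
#' group densities, `rho = sum((V_i / V) * rho_i)`.
#'
#' @param comp a [molecular_composition()].
#' @param dens a [component_densities()].
#' @param shape a [cell_shape()].
#' @return A [cell_state()].
#' @export
#' @examples
#' comp <- molecular_composition(water = 50, protein = 50)
#' composition_to_cell_state(comp, component_densities())  # rho = 1.174
composition_to_cell_state <- function(comp, dens = component_densities(),
                                      shape = cell_shape()) {
  stopifnot(inherits(comp, "psk_composition"), inherits(dens, "psk_densities"))
  v <- sum(comp)
  rho <- sum(unclass(comp) * unclass(dens)[names(comp)]) / v
  cell_state(volume = v, density = rho, shape = shape)
}

#' Stokes-law gravitational sinking velocity
#'
#' `v = 2 (rho_cell - rho_fluid) g r^2 phi / (9 mu)`, returned in um/s.
#' Negative values mean the cell is positively buoyant and rises; they are
#' returned unclamped.
#'
#' @param state a [cell_state()], or a density in g/mL when `radius` is
#'   supplied directly.
#' @param fluid a [fluid_environment()].
#' @param radius optional radius in um; when given, `state` is interpreted
#'   as the cell density (scalar/vector g/mL) and `shape` supplies phi.
#' @param shape a [cell_shape()] used with the density/radius call form.
#' @return sinking velocity, um/s (vectorised over density/radius).
#' @export
#' @examples
#' s <- cell_state(volume = 33.51, density = 1.10)
#' sinking_velocity(s)  # ~0.603 um/s in default seawater
sinking_velocity <- function(state, fluid = fluid_environment(),
                             radius = NULL, shape = cell_shape()) {
  stopifnot(inherits(fluid, "psk_fluid"))
  if (inherits(state, "psk_cell_state")) {
    density <- state$density
    radius <- state$radius
    phi <- state$shape$phi
  } else {
    if (is.null(radius)) {
      stop("supply a psk_cell_state or density plus radius", call. = FALSE)
    }
    density <- state
    phi <- shape$phi
  }
  delta_rho_si <- (density - fluid$density) * .GML_TO_SI
  r_m <- radius * .UM_TO_M
  v_si <- 2 * delta_rho_si * fluid$gravity * r_m^2 * phi / (9 * fluid$viscosity)
  v_si * .MS_TO_UMS
}

#' Diffusivity presets for Peclet analysis
#'
#' um^2/s: 1700 for nitrate (a representative small nutrient), 10 for a
#' virus-sized particle.
#' @export
diffusivity_presets <- c(nitrate = 1700, virus = 10)

#' Peclet number
#'
#' `Pe = U L / D`: relative contribution of advection (cell sinking) and
#' diffusion to the encounter rate between the cell and an external particle.
#' `Pe >> 1` means the cell's motion dominates.
#'
#' @param velocity sinking speed U, um/s (magnitude is used).
#' @param length characteristic cell length L, um.
#' @param diffusivity particle diffusivity D, um^2/s; either a number or the
#'   name of a preset in [diffusivity_presets].
#' @return dimensionless Peclet number (vectorised).
#' @export
#' @examples
#' peclet_number(5, 4, "virus")  # 2
peclet_number <- function(velocity, length, diffusivity = "nitrate") {
  if (is.character(diffusivity)) {
    diffusivity <- diffusivity_presets[[match.arg(diffusivity,
                                                  names(diffusivity_presets))]]
  }
  if (any(!is.finite(diffusivity)) || any(diffusivity <= 0)) {
    stop("diffusivity must be positive", call. = FALSE)
  }
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("length must be positive", call. = FALSE)
  }
  abs(velocity) * length / diffusivity
}

#' Reynolds number
#'
#' `Re = rho_fluid U L / mu` in SI; for the micrometre scales and um/s
#' speeds here this is always far below 1, i.e. creeping (Stokes) flow.
#'
#' @param velocity speed U, um/s (magnitude used).
#' @param length characteristic length L, um.
#' @param fluid a [fluid_environment()].
#' @return dimensionless Reynolds number (vectorised).
#' @export
reynolds_number <- function(velocity, length, fluid = fluid_environment()) {
  stopifnot(inherits(fluid, "psk_fluid"))
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("length must be positive", call. = FALSE)
  }
  (fluid$density * .GML_TO_SI) * abs(velocity) * .UM_TO_M *
    (length * .UM_TO_M) / fluid$viscosity
}
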