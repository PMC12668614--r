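# Population-level biophysics inferred from single-cell measurements:
# resonator (SMR) buoyant masses in pg and impedance-counter volumes in fL.
# The two instruments measure different cells, so all inference is on
# population averages, never per-cell pairs.

#' A single instrument's measurement of one cell population
#'
#' @param values per-cell measurements: buoyant mass in pg (resonator; may
#'   be negative) or volume in fL (counter; must be positive).
#' @param species,condition,replicate_id labels identifying the culture.
#' @param instrument `"resonator"` or `"impedance_counter"`.
#' @param fluid_density density of the measurement medium, g/mL (required
#'   for resonator samples).
#' @return list of class `psk_sample` with an `n_cells` field.
#' @export
single_cell_sample <- function(values, species = "unknown",
                               condition = "high", replicate_id = "r1",
                               instrument = c("resonator",
                                              "impedance_counter"),
                               fluid_density = 1.026) {
  instrument <- match.arg(instrument)
  if (!length(values) || any(!is.finite(values))) {
    .psk_error("values must be non-empty and finite", "psk_domain")
  }
  if (instrument == "impedance_counter" && any(values <= 0)) {
    .psk_error("counter volumes must be positive", "psk_domain")
  }
  structure(list(values = as.numeric(values), species = species,
                 condition = condition, replicate_id = replicate_id,
                 instrument = instrument, fluid_density = fluid_density,
                 n_cells = length(values)),
            class = "psk_sample")
}

#' Remove particles too small to be viable cells
#'
#' Drops measurements below a per-species threshold (fL for counter
#' samples, pg for resonator samples). The number of removed particles is
#' reported via a message and stored in the result.
#'
#' @param sample a [single_cell_sample()].
#' @param min_value threshold; values strictly below it are removed.
#' @param quiet suppress the removal message.
#' @return the filtered `psk_sample` (with `n_removed` field).
#' @export
filter_small_particles <- function(sample, min_value, quiet = FALSE) {
  stopifnot(inherits(sample, "psk_sample"))
  if (!is.finite(min_value) || min_value < 0) {
    .psk_error("threshold must be non-negative", "psk_domain")
  }
  keep <- sample$values >= min_value
  if (!any(keep)) {
    .psk_error("all particles removed by size filter; empty population",
               "psk_empty_population")
  }
  n_removed <- sum(!keep)
  if (n_removed > 0 && !quiet) {
    message(sprintf("filter_small_particles: removed %d of %d particles",
                    n_removed, sample$n_cells))
  }
  sample$values <- sample$values[keep]
  sample$n_cells <- length(sample$values)
  sample$n_removed <- n_removed
  sample
}

#' Population biophysics from unpaired mass and volume samples
#'
#' Population average density is `rho_fluid + mean(BM) / mean(V)` (buoyant
#' mass definition `BM = V (rho_cell - rho_fluid)` applied to population
#' means); the equivalent radius comes from the mean volume and the sinking
#' velocity from Stokes' law on the resulting state.
#'
#' @param mass_sample resonator [single_cell_sample()] (pg).
#' @param volume_sample counter [single_cell_sample()] (fL).
#' @param fluid a [fluid_environment()]; its density must match the mass
#'   sample's measurement fluid.
#' @param shape a [cell_shape()].
#' @param statistic `"mean"` (default, matching population-average
#'   inference) or `"median"` for robustness.
#' @return list of class `psk_biophysics`: mean buoyant mass, mean volume,
#'   density, radius, sinking velocity, cell counts and metadata.
#' @export
population_biophysics <- function(mass_sample, volume_sample,
                                  fluid = fluid_environment(),
                                  shape = cell_shape(),
                                  statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(mass_sample, "psk_sample"),
            inherits(volume_sample, "psk_sample"))
  if (mass_sample$instrument != "resonator" ||
      volume_sample$instrument != "impedance_counter") {
    .psk_error("need one resonator sample and one impedance_counter sample",
               "psk_pairing")
  }
  meta_keys <- c("species", "condition", "replicate_id")
  if (!identical(mass_sample[meta_keys], volume_sample[meta_keys])) {
    .psk_error("samples are from different species/condition/replicate",
               "psk_pairing")
  }
  stat <- if (statistic == "mean") mean else stats::median
  bm <- stat(mass_sample$values)
  vol <- stat(volume_sample$values)
  rho_fluid <- mass_sample$fluid_density
  density <- rho_fluid + bm / vol
  state <- suppressWarnings(cell_state(vol, density, shape))
  structure(list(species = mass_sample$species,
                 condition = mass_sample$condition,
                 replicate_id = mass_sample$replicate_id,
                 mean_buoyant_mass = bm, mean_volume = vol,
                 density = density, equivalent_radius = state$radius,
                 sinking_velocity = sinking_velocity(state, fluid),
                 n_mass = mass_sample$n_cells,
                 n_volume = volume_sample$n_cells),
            class = "psk_biophysics")
}

#' Dry and water content from buoyant masses in two fluids
#'
#' With full, instantaneous exchange of intracellular water, water
#' contributes no buoyant mass in either fluid, so the population-average
#' buoyant mass in fluid k is `BM_k = Vdry (rho_dry - rho_k)`. Measuring in
#' plain seawater (`rho1`) and in medium whose water is 90% D2O (`rho2 >
#' rho1`) gives
#' `Vdry = (BM1 - BM2) / (rho2 - rho1)` and `rho_dry = rho1 + BM1 / Vdry`;
#' the water volume is the counter total volume minus `Vdry`.
#'
#' @param bm_h2o_mean,bm_d2o_mean population-average buoyant masses, pg.
#' @param rho1,rho2 densities of the two measurement fluids, g/mL
#'   (`rho2 > rho1`).
#' @param total_volume population-average total cell volume, fL (measured
#'   in the standard medium).
#' @param exchange_factor optional multiplicative correction on the
#'   heavy-water buoyant mass for incomplete labile-hydrogen exchange
#'   (default 1 = no correction).
#' @return list of class `psk_dry_content`: `water_volume`, `dry_volume`,
#'   `dry_density`, `water_fraction`.
#' @export
#' @examples
#' dual_fluid_dry_content(18.70, 13.90, 1.026, 1.122, 200)
dual_fluid_dry_content <- function(bm_h2o_mean, bm_d2o_mean,
                                   rho1 = 1.026, rho2 = 1.122,
                                   total_volume = NULL,
                                   exchange_factor = 1) {
  if (!(rho2 > rho1)) {
    .psk_error("rho2 (D2O medium) must exceed rho1 (H2O medium)",
               "psk_domain")
  }
  bm2 <- bm_d2o_mean * exchange_factor
  if (bm_h2o_mean <= bm2) {
    .psk_error(paste("buoyant mass must decrease in the denser fluid;",
                     "BM1 <= BM2 is inconsistent with the dry-content model"),
               "psk_inconsistent_measurement")
  }
  vdry <- (bm_h2o_mean - bm2) / (rho2 - rho1)
  rho_dry <- rho1 + bm_h2o_mean / vdry
  vwater <- NA_real_
  wf <- NA_real_
  if (!is.null(total_volume)) {
    if (vdry > total_volume) {
      .psk_error("inferred dry volume exceeds total cell volume",
                 "psk_inconsistent_measurement")
    }
    vwater <- total_volume - vdry
    wf <- vwater / total_volume
  }
  structure(list(water_volume = vwater, dry_volume = vdry,
                 dry_density = rho_dry, water_fraction = wf),
            class = "psk_dry_content")
}

#' Proliferation rate from multi-day cell counts
#'
#' Least-squares slope of log2(count) against time, in doublings/day;
#' exact for perfectly exponential growth.
#'
#' @param counts cell concentrations (cells/mL), all positive.
#' @param times measurement times in days.
#' @return list of class `psk_proliferation`: `rate` (doublings/day) and
#'   `window` (days spanned).
#' @export
#' @examples
#' proliferation_rate(c(1e5, 2e5, 4e5), c(0, 1, 2))  # 1 doubling/day
proliferation_rate <- function(counts, times) {
  if (length(counts) < 2 || length(counts) != length(times)) {
    .psk_error("need >= 2 counts with matching times", "psk_domain")
  }
  if (any(!is.finite(counts)) || any(counts <= 0)) {
    .psk_error("counts must be positive for exponential-growth fitting",
               "psk_domain")
  }
  fit <- stats::lm.fit(cbind(1, times), log2(counts))
  structure(list(rate = unname(fit$coefficients[2]),
                 window = diff(range(times))),
            class = "psk_proliferation")
}
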