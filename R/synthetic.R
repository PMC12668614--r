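# Synthetic measurement generator. Emulates the study's measurement
# structure with known ground truth: per-cell lognormal size variation,
# unpaired resonator/counter sampling, paired H2O / 90%-D2O buoyant-mass
# arms with full water exchange, between-culture replicate scatter applied
# at the composition level, multi-day cell counts, and condition effects
# injected as per-component volume fold changes.
#
# All random factors (size, instrument noise) are mean-1 lognormals with
# sdlog^2 = log(1 + cv^2), so expectations match the generating composition
# exactly and inference on synthetic data is unbiased by construction.

#' Species profile for the synthetic generator
#'
#' @param name species label.
#' @param composition baseline (high-nutrient) [molecular_composition()].
#' @param shape a [cell_shape()].
#' @param cell_size_cv coefficient of variation of the shared per-cell size
#'   factor (default 0.3, a typical width for a proliferating population).
#' @param peclet_length characteristic length for Peclet numbers, um;
#'   default NULL means "use the equivalent spherical diameter".
#' @return list of class `psk_species_profile`.
#' @export
species_profile <- function(name, composition, shape = cell_shape(),
                            cell_size_cv = 0.3, peclet_length = NULL) {
  stopifnot(inherits(composition, "psk_composition"), cell_size_cv >= 0)
  structure(list(name = name, composition = composition, shape = shape,
                 cell_size_cv = cell_size_cv, peclet_length = peclet_length),
            class = "psk_species_profile")
}

#' Condition effect: per-component fold changes plus culture-level scatter
#'
#' Encodes a starvation response as volume fold changes on each molecular
#' group (e.g. a starch-accumulating response is a carbohydrate fold > 1).
#' `replicate_sd` is the between-culture lognormal scatter (log scale)
#' applied independently to each component volume of each replicate culture
#' before cells are sampled; its small default reflects paired cultures
#' measured within an hour of each other and is the calibration under which
#' the documented recovery tolerances hold.
#'
#' @param condition condition label.
#' @param folds named numeric vector of volume fold changes (names among
#'   water, protein, lipid, carbohydrate, other; missing names mean 1).
#' @param replicate_sd between-culture scatter sd on the log scale.
#' @param growth_rate proliferation rate used for simulated day counts,
#'   doublings/day.
#' @return list of class `psk_condition_effect`.
#' @export
condition_effect <- function(condition, folds = numeric(0),
                             replicate_sd = 0.01, growth_rate = 1.0) {
  f <- stats::setNames(rep(1, length(.COMPONENTS)), .COMPONENTS)
  if (length(folds)) {
    bad <- setdiff(names(folds), .COMPONENTS)
    if (length(bad)) .psk_error(paste("unknown components:",
                                      paste(bad, collapse = ", ")),
                                "psk_validation")
    if (any(folds <= 0)) .psk_error("folds must be positive",
                                    "psk_validation")
    f[names(folds)] <- folds
  }
  structure(list(condition = condition, folds = f,
                 replicate_sd = replicate_sd, growth_rate = growth_rate),
            class = "psk_condition_effect")
}

# mean-1 lognormal factors with the requested coefficient of variation
.lognormal_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# documented substream derivation: one integer seed per simulated arm,
# kept below 2^31 - 1
.derive_seed <- function(seed, index) {
  (as.numeric(seed) %% 2147483647 + 7919 * index) %% 2147483647
}

#' Simulate one instrument's measurement of one cell population
#'
#' Each cell gets a shared mean-1 lognormal size factor (cv =
#' `profile$cell_size_cv`) scaling all component volumes. A counter
#' measurement is the cell's total volume times mean-1 lognormal
#' instrument noise (cv = `noise_cv`). A resonator measurement is the
#' cell's buoyant mass `sum_i V_i (rho_i - rho_fluid)` times the same kind
#' of noise, with the intracellular water density set to the measurement
#' fluid's `water_density` (full water exchange): in plain seawater this
#' reproduces `V (rho_cell - rho_fluid)` exactly, while in the D2O medium
#' the water term carries the same salt offset, so the expected buoyant-mass
#' difference between fluids is `Vdry (rho2 - rho1)`.
#'
#' @param profile a [species_profile()].
#' @param effect optional [condition_effect()] applied to the composition.
#' @param fluid a [fluid_environment()] ([fluid_d2o()] for the heavy arm).
#' @param instrument `"resonator"` or `"impedance_counter"`.
#' @param n number of cells.
#' @param seed integer seed (reproducible; same seed, same sample).
#' @param noise_cv instrument noise coefficient of variation.
#' @param dens a [component_densities()].
#' @param condition,replicate_id labels stored on the sample.
#' @param composition optional explicit composition overriding
#'   `profile$composition` (+ effect), used for replicate-level scatter.
#' @return a [single_cell_sample()].
#' @export
simulate_single_cells <- function(profile, effect = NULL,
                                  fluid = fluid_environment(),
                                  instrument = c("resonator",
                                                 "impedance_counter"),
                                  n = 300, seed = 1, noise_cv = 0.05,
                                  dens = component_densities(),
                                  condition = NULL, replicate_id = "r1",
                                  composition = NULL) {
  instrument <- match.arg(instrument)
  if (n < 1) .psk_error("n must be >= 1", "psk_domain")
  comp <- if (!is.null(composition)) unclass(composition) else {
    base <- unclass(profile$composition)
    if (!is.null(effect)) base * effect$folds[names(base)] else base
  }
  if (is.null(condition)) {
    condition <- if (!is.null(effect)) effect$condition else "high"
  }
  set.seed(seed)
  size <- .lognormal_factor(n, profile$cell_size_cv)
  noise <- .lognormal_factor(n, noise_cv)
  values <- if (instrument == "impedance_counter") {
    size * sum(comp) * noise
  } else {
    d <- unclass(dens)[names(comp)]
    d[["water"]] <- fluid$water_density  # full intracellular water exchange
    size * sum(comp * (d - fluid$density)) * noise
  }
  single_cell_sample(values, species = profile$name, condition = condition,
                     replicate_id = replicate_id, instrument = instrument,
                     fluid_density = fluid$density)
}

#' Study design for the synthetic generator
#'
#' @param species character vector of species names (must match profiles).
#' @param conditions condition labels; `"high"` is the reference and is
#'   always included.
#' @param n_replicates independent cultures per species x condition.
#' @param n_cells cells measured per instrument arm.
#' @param noise_cv instrument noise cv.
#' @param include_d2o simulate the heavy-water resonator arm.
#' @param include_counts simulate cell counts on three consecutive days.
#' @param count_days days of the count measurements.
#' @return list of class `psk_study_design`.
#' @export
study_design <- function(species, conditions = c("high", "low"),
                         n_replicates = 4, n_cells = 300, noise_cv = 0.05,
                         include_d2o = TRUE, include_counts = TRUE,
                         count_days = c(4, 5, 6)) {
  conditions <- union("high", conditions)
  structure(list(species = species, conditions = conditions,
                 n_replicates = n_replicates, n_cells = n_cells,
                 noise_cv = noise_cv, include_d2o = include_d2o,
                 include_counts = include_counts, count_days = count_days),
            class = "psk_study_design")
}

#' Simulate a full multi-species measurement study with ground truth
#'
#' For every species x condition x replicate, draws a replicate-level
#' composition (baseline x condition folds x per-component lognormal
#' scatter), then simulates unpaired resonator (H2O and optionally D2O) and
#' counter arms plus multi-day cell counts. Returns the tidy measurement
#' tables together with the generating truth.
#'
#' @param design a [study_design()].
#' @param profiles named list of [species_profile()]s.
#' @param effects nested named list `effects[[species]][[condition]]` of
#'   [condition_effect()]s; a missing entry means "no effect" (identity).
#' @param seed study-level integer seed; all arm seeds derive from it.
#' @param dens a [component_densities()].
#' @param fluid_h2o,fluid_d2o the two measurement media.
#' @return list of class `psk_study` with elements `measurements` (tidy
#'   data.frame: species, condition, replicate_id, instrument, fluid,
#'   fluid_density_g_ml, value, unit), `counts` (species, condition,
#'   replicate_id, day, count), and `ground_truth` (per-replicate true
#'   composition, volume, density, radius and sinking velocity).
#' @export
simulate_study <- function(design, profiles, effects = list(), seed = 1,
                           dens = component_densities(),
                           fluid_h2o = fluid_environment(),
                           fluid_d2o = planktosink::fluid_d2o()) {
  stopifnot(inherits(design, "psk_study_design"))
  missing_sp <- setdiff(design$species, names(profiles))
  if (length(missing_sp)) {
    .psk_error(paste("no profile for species:",
                     paste(missing_sp, collapse = ", ")), "psk_validation")
  }
  meas <- list(); truth <- list(); counts <- list()
  arm_index <- 0L
  for (sp in design$species) {
    prof <- profiles[[sp]]
    for (cond in design$conditions) {
      eff <- effects[[sp]][[cond]]
      if (is.null(eff)) eff <- condition_effect(cond)
      for (rep_i in seq_len(design$n_replicates)) {
        rep_id <- paste0("r", rep_i)
        arm_index <- arm_index + 1L
        # replicate-level composition scatter
        set.seed(.derive_seed(seed, arm_index))
        scatter <- if (eff$replicate_sd > 0) {
          exp(stats::rnorm(length(.COMPONENTS), 0, eff$replicate_sd))
        } else rep(1, length(.COMPONENTS))
        comp_v <- unclass(prof$composition) *
          eff$folds[.COMPONENTS] * scatter
        comp <- structure(comp_v, class = "psk_composition")
        st <- suppressWarnings(
          composition_to_cell_state(comp, dens, prof$shape))
        truth[[length(truth) + 1L]] <- data.frame(
          species = sp, condition = cond, replicate_id = rep_id,
          water_fl = comp_v[["water"]], protein_fl = comp_v[["protein"]],
          lipid_fl = comp_v[["lipid"]],
          carbohydrate_fl = comp_v[["carbohydrate"]],
          other_fl = comp_v[["other"]],
          volume_fl = st$volume, density_g_ml = st$density,
          radius_um = st$radius,
          velocity_um_s = sinking_velocity(st, fluid_h2o))

        arms <- list(list(instr = "resonator", fluid = fluid_h2o,
                          label = "h2o", unit = "pg"),
                     list(instr = "impedance_counter", fluid = fluid_h2o,
                          label = "h2o", unit = "fL"))
        if (design$include_d2o) {
          arms <- c(arms, list(list(instr = "resonator", fluid = fluid_d2o,
                                    label = "d2o", unit = "pg")))
        }
        for (arm in arms) {
          arm_index <- arm_index + 1L
          smp <- simulate_single_cells(
            prof, effect = NULL, fluid = arm$fluid,
            instrument = arm$instr, n = design$n_cells,
            seed = .derive_seed(seed, arm_index),
            noise_cv = design$noise_cv, dens = dens, condition = cond,
            replicate_id = rep_id, composition = comp)
          meas[[length(meas) + 1L]] <- data.frame(
            species = sp, condition = cond, replicate_id = rep_id,
            instrument = arm$instr, fluid = arm$label,
            fluid_density_g_ml = arm$fluid$density,
            value = smp$values, unit = arm$unit)
        }
        if (design$include_counts) {
          arm_index <- arm_index + 1L
          set.seed(.derive_seed(seed, arm_index))
          base_count <- 1e5
          mu <- base_count * 2^(eff$growth_rate *
                                  (design$count_days - design$count_days[1]))
          obs <- mu * .lognormal_factor(length(mu), 0.02)
          counts[[length(counts) + 1L]] <- data.frame(
            species = sp, condition = cond, replicate_id = rep_id,
            day = design$count_days, count = obs)
        }
      }
    }
  }
  structure(list(measurements = do.call(rbind, meas),
                 counts = if (length(counts)) do.call(rbind, counts) else NULL,
                 ground_truth = do.call(rbind, truth),
                 design = design, seed = seed),
            class = "psk_study")
}
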