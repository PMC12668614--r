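# Shared fixtures and independent numerical oracles.

# a mid-sized reference composition used across tests
ref_composition <- function() {
  molecular_composition(water = 60, protein = 20, lipid = 5,
                        carbohydrate = 10, other = 5)
}

# random valid biophysical states (density, radius) for property tests
rand_density_radius <- function(n, seed) {
  set.seed(seed)
  data.frame(density = runif(n, 1.03, 1.25), radius = runif(n, 0.8, 8))
}

# random valid (water_volume, dry_volume, dry_density) states
rand_water_dry <- function(n, seed) {
  set.seed(seed)
  data.frame(water_volume = runif(n, 20, 500),
             dry_volume = runif(n, 10, 300),
             dry_density = runif(n, 1.10, 1.55))
}

# central finite-difference oracle for the density/volume partials,
# differentiating sinking_velocity itself (independent of taylor_partials)
fd_partials_density_volume <- function(baseline, fluid = fluid_environment(),
                                       shape = cell_shape(),
                                       rel_step = 1e-6) {
  v_of <- function(rho, r) {
    sinking_velocity(rho, fluid = fluid, radius = r, shape = shape)
  }
  rho <- baseline[["density"]]; r <- baseline[["radius"]]
  h_rho <- rel_step * rho; h_r <- rel_step * r
  c(density = (v_of(rho + h_rho, r) - v_of(rho - h_rho, r)) / (2 * h_rho),
    radius = (v_of(rho, r + h_r) - v_of(rho, r - h_r)) / (2 * h_r))
}

# central finite-difference oracle for the water/dry partials, built on the
# composition route (molecular_composition -> cell state -> velocity)
fd_partials_water_dry <- function(baseline, fluid = fluid_environment(),
                                  water_density = 0.998,
                                  shape = cell_shape(), rel_step = 1e-6) {
  v_of <- function(vw, vd, rd) {
    v_tot <- vw + vd
    rho <- (vw * water_density + vd * rd) / v_tot
    st <- suppressWarnings(cell_state(v_tot, rho, shape))
    sinking_velocity(st, fluid)
  }
  b <- baseline
  out <- numeric(3)
  keys <- c("water_volume", "dry_volume", "dry_density")
  for (i in seq_along(keys)) {
    h <- rel_step * b[[keys[i]]]
    up <- b; up[[keys[i]]] <- b[[keys[i]]] + h
    dn <- b; dn[[keys[i]]] <- b[[keys[i]]] - h
    out[i] <- (v_of(up[[1]], up[[2]], up[[3]]) -
                 v_of(dn[[1]], dn[[2]], dn[[3]])) / (2 * h)
  }
  names(out) <- keys
  out
}

# compact two-species synthetic study for pipeline tests
small_study <- function(seed = 7, n_cells = 200, n_replicates = 3,
                        include_d2o = TRUE) {
  profiles <- default_species_profiles()[c("Chaetoceros calcitrans",
                                           "Emiliania huxleyi")]
  effects <- default_condition_effects()[names(profiles)]
  simulate_study(study_design(names(profiles), n_replicates = n_replicates,
                              n_cells = n_cells, include_d2o = include_d2o),
                 profiles, effects, seed = seed)
}
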