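# Synthetic measurement generator: determinism, unbiasedness, and
# generator/inference consistency.

test_that("degenerate generator (no noise, no size variation) is exact", {
  prof <- species_profile("test", ref_composition(), cell_size_cv = 0)
  st <- composition_to_cell_state(prof$composition)
  mass <- simulate_single_cells(prof, instrument = "resonator", n = 20,
                                seed = 1, noise_cv = 0)
  vol <- simulate_single_cells(prof, instrument = "impedance_counter",
                               n = 20, seed = 2, noise_cv = 0)
  expect_equal(unique(vol$values), st$volume)
  expect_equal(unique(mass$values), st$volume * (st$density - 1.026),
               tolerance = 1e-12)
  bp <- population_biophysics(mass, vol)
  expect_equal(bp$density, st$density, tolerance = 1e-12)
  expect_equal(bp$sinking_velocity, sinking_velocity(st), tolerance = 1e-12)
})

test_that("same seed reproduces identical samples and studies", {
  prof <- species_profile("test", ref_composition())
  a <- simulate_single_cells(prof, n = 50, seed = 42)
  b <- simulate_single_cells(prof, n = 50, seed = 42)
  expect_identical(a$values, b$values)
  c <- simulate_single_cells(prof, n = 50, seed = 43)
  expect_false(identical(a$values, c$values))

  s1 <- small_study(seed = 5, n_cells = 30, n_replicates = 2)
  s2 <- small_study(seed = 5, n_cells = 30, n_replicates = 2)
  expect_identical(s1$measurements, s2$measurements)
  expect_identical(s1$ground_truth, s2$ground_truth)
})

test_that("resonator expectation matches V (rho_cell - rho_fluid)", {
  prof <- species_profile("test", ref_composition(), cell_size_cv = 0.3)
  st <- composition_to_cell_state(prof$composition)
  smp <- simulate_single_cells(prof, instrument = "resonator", n = 20000,
                               seed = 99, noise_cv = 0.05)
  truth <- st$volume * (st$density - 1.026)
  # mean-1 noise model: Monte-Carlo tolerance ~3 SEM
  sem <- sd(smp$values) / sqrt(smp$n_cells)
  expect_lt(abs(mean(smp$values) - truth), 3 * sem)
})

test_that("D2O arm: expected BM difference equals Vdry (rho2 - rho1)", {
  prof <- species_profile("test", ref_composition(), cell_size_cv = 0)
  d2o <- fluid_d2o()
  m1 <- simulate_single_cells(prof, instrument = "resonator", n = 10,
                              seed = 1, noise_cv = 0)
  m2 <- simulate_single_cells(prof, fluid = d2o, instrument = "resonator",
                              n = 10, seed = 1, noise_cv = 0)
  vdry <- 40  # non-water volume of the reference composition
  expect_equal(mean(m1$values) - mean(m2$values),
               vdry * (d2o$density - 1.026), tolerance = 1e-9)
  # so the dual-fluid solver recovers the dry volume exactly
  dc <- dual_fluid_dry_content(mean(m1$values), mean(m2$values),
                               1.026, d2o$density, total_volume = 100)
  expect_equal(dc$dry_volume, vdry, tolerance = 1e-9)
  expect_equal(dc$water_volume, 60, tolerance = 1e-9)
})

test_that("generator/inference calibration: density within 0.005 g/mL", {
  # n = 300 cells, 30% size cv, 5% instrument noise: the recovered density
  # must land within 0.005 g/mL of truth in >= 95% of seeds
  prof <- species_profile("test", ref_composition(), cell_size_cv = 0.3)
  truth <- composition_to_cell_state(prof$composition)$density
  hits <- vapply(1:100, function(s) {
    m <- simulate_single_cells(prof, instrument = "resonator", n = 300,
                               seed = 1000 + s, noise_cv = 0.05)
    v <- simulate_single_cells(prof, instrument = "impedance_counter",
                               n = 300, seed = 2000 + s, noise_cv = 0.05)
    abs(population_biophysics(m, v)$density - truth) < 0.005
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("simulated studies carry a consistent tidy schema and truth table", {
  study <- small_study(seed = 3, n_cells = 25, n_replicates = 2)
  meas <- study$measurements
  expect_true(all(c("species", "condition", "replicate_id", "instrument",
                    "fluid", "fluid_density_g_ml", "value", "unit")
                  %in% names(meas)))
  expect_setequal(unique(meas$fluid), c("h2o", "d2o"))
  # arms: resonator h2o + counter h2o + resonator d2o, per repl x cond x sp
  expect_equal(nrow(meas), 2 * 2 * 2 * 3 * 25)
  expect_equal(nrow(study$ground_truth), 2 * 2 * 2)
  # counts: three days per culture
  expect_equal(nrow(study$counts), 2 * 2 * 2 * 3)
  # ground truth velocity is reproducible from its own density/radius
  gt <- study$ground_truth
  v <- sinking_velocity(gt$density_g_ml, fluid_environment(),
                        radius = gt$radius_um)
  expect_equal(v, gt$velocity_um_s, tolerance = 1e-12)
  expect_error(
    simulate_study(study_design("missing species"),
                   default_species_profiles()),
    class = "psk_validation")
})

test_that("null effect yields ratio ~1; carbohydrate injection is recovered", {
  profiles <- default_species_profiles()["Dunaliella tertiolecta"]
  base_effects <- list("Dunaliella tertiolecta" = list(
    high = condition_effect("high"),
    low = condition_effect("low", c(carbohydrate = 3))))
  study <- simulate_study(
    study_design(names(profiles), n_replicates = 4, n_cells = 200),
    profiles, base_effects, seed = 11)
  rep <- run_study(study)
  fc <- rep$fold_changes
  expect_gt(fc$mean_ratio, 1)
  # the molecular decomposition pins the change on dry content
  wd <- rep$influence_water_dry_summary
  i_dry <- wd$influence_mean[wd$factor == "dry"]
  expect_gt(i_dry, 0.5)

  # identity effect: the high/low ratio straddles 1
  null_effects <- list("Dunaliella tertiolecta" = list(
    high = condition_effect("high"), low = condition_effect("low")))
  study0 <- simulate_study(
    study_design(names(profiles), n_replicates = 4, n_cells = 200),
    profiles, null_effects, seed = 12)
  fc0 <- run_study(study0)$fold_changes
  expect_lt(abs(fc0$mean_ratio - 1), 0.1)
})
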