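# Study pipeline orchestration.

test_that("schema validation names missing columns and bad rows", {
  good <- small_study(seed = 2, n_cells = 10, n_replicates = 2)$measurements
  expect_silent(validate_measurements(good))
  expect_error(validate_measurements(good[, -7]), "missing columns: value",
               class = "psk_validation")
  bad <- good
  i <- which(bad$instrument == "impedance_counter")[1]
  bad$unit[i] <- "pg"  # a counter row labelled pg
  expect_error(validate_measurements(bad), class = "psk_validation")
  nonnum <- good
  nonnum$value[5] <- NA
  expect_error(validate_measurements(nonnum), "rows: 5",
               class = "psk_validation")
})

test_that("run_study recovers injected truth on a small synthetic study", {
  study <- small_study(seed = 21)
  rep <- run_study(study)

  # per-replicate biophysics close to the generating truth
  m <- merge(rep$biophysics, study$ground_truth,
             by = c("species", "condition", "replicate_id"))
  expect_lt(max(abs(m$density_g_ml.x - m$density_g_ml.y)), 0.02)
  expect_lt(max(abs(m$mean_vol_fl - m$volume_fl) / m$volume_fl), 0.05)
  # per-condition (replicate-averaged) densities land within 0.01 g/mL
  est <- aggregate(density_g_ml.x ~ species + condition, m, mean)
  tru <- aggregate(density_g_ml.y ~ species + condition, m, mean)
  expect_lt(max(abs(est$density_g_ml.x - tru$density_g_ml.y)), 0.01)

  # fold-change classification matches the injected effects
  fc <- rep$fold_changes
  expect_equal(
    fc$classification[fc$species == "Chaetoceros calcitrans"], "increased")
  expect_equal(
    fc$classification[fc$species == "Emiliania huxleyi"], "increased")

  # volume-driven species: density influence near 0; density-driven: near 1
  dv <- rep$influence_density_volume_summary
  i_eh <- dv$influence_mean[dv$species == "Emiliania huxleyi" &
                              dv$factor == "density"]
  i_cc <- dv$influence_mean[dv$species == "Chaetoceros calcitrans" &
                              dv$factor == "density"]
  expect_lt(abs(i_eh), 0.25)
  expect_gt(i_cc, 0.6)

  # every influence row sums to one within its replicate pair
  infl <- rep$influence_density_volume
  sums <- tapply(infl$influence[infl$factor %in% c("density", "volume")],
                 paste(infl$species, infl$condition,
                       infl$replicate_pair)[infl$factor %in%
                                              c("density", "volume")], sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  # velocities reproducible from stored density and radius
  v <- sinking_velocity(rep$biophysics$density_g_ml, fluid_environment(),
                       radius = rep$biophysics$radius_um)
  expect_equal(v, rep$biophysics$v_um_s, tolerance = 1e-12)

  # Peclet table uses the documented presets
  expect_equal(rep$peclet$pe_virus / rep$peclet$pe_nitrate,
               rep(170, nrow(rep$peclet)))

  # proliferation close to the injected growth rates
  pr <- rep$proliferation
  hi <- pr$doublings_per_day[pr$condition == "high"]
  expect_lt(max(abs(hi - 1.0)), 0.15)
})

test_that("per-condition density recovery: within 0.005 g/mL in >= 95% of runs", {
  # stated world: n = 300 cells/replicate, N = 4 replicates, 10%
  # instrument CV; 100 seeded runs on a two-species subset (including the
  # densest starved cells, the hardest case for the absolute tolerance)
  profiles <- default_species_profiles()[c("Chaetoceros calcitrans",
                                           "Emiliania huxleyi")]
  effects <- default_condition_effects()[names(profiles)]
  design <- study_design(names(profiles), n_replicates = 4, n_cells = 300,
                         noise_cv = 0.10, include_d2o = FALSE,
                         include_counts = FALSE)
  errs <- numeric(0)
  for (run in 1:100) {
    study <- simulate_study(design, profiles, effects, seed = 9000 + run)
    rep <- run_study(study)
    m <- merge(rep$biophysics, study$ground_truth,
               by = c("species", "condition", "replicate_id"))
    est <- aggregate(density_g_ml.x ~ species + condition, m, mean)
    tru <- aggregate(density_g_ml.y ~ species + condition, m, mean)
    errs <- c(errs, abs(est$density_g_ml.x - tru$density_g_ml.y))
  }
  expect_gte(mean(errs < 0.005), 0.95)
})

test_that("9-species default study reproduces the injected 7/1/1 pattern", {
  profiles <- default_species_profiles()
  study <- simulate_study(study_design(names(profiles)), profiles,
                          default_condition_effects(), seed = 17)
  rep <- run_study(study)
  cls <- table(rep$fold_changes$classification)
  expect_equal(unname(cls[["increased"]]), 7)
  expect_equal(unname(cls[["decreased"]]), 1)
  expect_equal(unname(cls[["unchanged"]]), 1)
  expect_equal(
    rep$fold_changes$classification[
      rep$fold_changes$species == "Phaeodactylum tricornutum"], "decreased")
  expect_equal(
    rep$fold_changes$classification[
      rep$fold_changes$species == "Isochrysis galbana"], "unchanged")
})

test_that("stages lacking inputs are skipped and flagged, not failed", {
  study <- small_study(seed = 4, n_cells = 15, n_replicates = 2,
                       include_d2o = FALSE)
  study$counts <- NULL
  rep <- run_study(study)
  expect_null(rep$influence_water_dry)
  expect_null(rep$proliferation)
  expect_true(any(grepl("D2O", rep$flags)))
  expect_true(any(grepl("counts", rep$flags)))
})

test_that("reports are deterministic and carry provenance", {
  study <- small_study(seed = 6, n_cells = 15, n_replicates = 2)
  r1 <- run_study(study)
  r2 <- run_study(study)
  p1 <- r1[setdiff(names(r1), "provenance")]
  p2 <- r2[setdiff(names(r2), "provenance")]
  expect_identical(p1, p2)
  expect_identical(r1$provenance$config_hash, r2$provenance$config_hash)
  expect_match(r1$provenance$config_hash, "^[0-9a-f]{32}$")

  out <- file.path(tempdir(), "psk-report-test")
  write_report(r1, out)
  expect_true(file.exists(file.path(out, "report.json")))
  expect_true(file.exists(file.path(out, "biophysics.csv")))
  unlink(out, recursive = TRUE)
})

test_that("config options change the analysis as documented", {
  study <- small_study(seed = 8, n_cells = 50, n_replicates = 3)
  # influence on condition means: one row per factor, labelled "means"
  rep_m <- run_study(study, study_config(influence_on = "means"))
  expect_true(all(rep_m$influence_density_volume$replicate_pair == "means"))
  # median statistic still yields a valid report
  rep_med <- run_study(study, study_config(statistic = "median"))
  expect_s3_class(rep_med, "psk_report")
  # FDR adds an adjusted column
  rep_fdr <- run_study(study, study_config(fdr = TRUE))
  expect_true("p_adjusted" %in% names(rep_fdr$fold_changes))
})
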