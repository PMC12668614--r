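# Study orchestration: from tidy single-cell measurement tables to
# per-replicate biophysics, fold-change tests, influence decompositions,
# Peclet tables and proliferation rates, assembled into a reproducible
# machine-readable report.

#' Analysis configuration for [run_study()]
#'
#' @param fluid the plain-seawater [fluid_environment()].
#' @param fluid_d2o the heavy-water [fluid_d2o()] medium.
#' @param dens [component_densities()] (used for water density in the
#'   molecular decomposition).
#' @param shape_phi named list/vector of per-species shape correction
#'   factors; species not listed get 1 (sphere).
#' @param peclet_length named list of per-species characteristic lengths
#'   (um); species not listed use the equivalent spherical diameter.
#' @param min_particle named list of per-species small-particle thresholds
#'   (fL, applied to counter samples; no filtering when not listed).
#' @param alpha significance threshold for classifying sinking changes.
#' @param statistic population statistic, `"mean"` or `"median"`.
#' @param influence_on `"pairs"` (decompose per replicate pair, then
#'   average) or `"means"` (decompose condition means).
#' @param reference_condition the control condition label.
#' @param fdr apply Benjamini-Hochberg across species per condition.
#' @return list of class `psk_config`.
#' @export
study_config <- function(fluid = fluid_environment(),
                         fluid_d2o = planktosink::fluid_d2o(),
                         dens = component_densities(),
                         shape_phi = list(), peclet_length = list(),
                         min_particle = list(), alpha = 0.05,
                         statistic = c("mean", "median"),
                         influence_on = c("pairs", "means"),
                         reference_condition = "high", fdr = FALSE) {
  structure(list(fluid = fluid, fluid_d2o = fluid_d2o, dens = dens,
                 shape_phi = shape_phi, peclet_length = peclet_length,
                 min_particle = min_particle, alpha = alpha,
                 statistic = match.arg(statistic),
                 influence_on = match.arg(influence_on),
                 reference_condition = reference_condition, fdr = fdr),
            class = "psk_config")
}

.species_shape <- function(config, species) {
  phi <- config$shape_phi[[species]]
  if (is.null(phi) || phi == 1) cell_shape("sphere") else
    suppressWarnings(cell_shape("spheroid", phi = phi))
}

.REQUIRED_COLS <- c("species", "condition", "replicate_id", "instrument",
                    "fluid", "fluid_density_g_ml", "value", "unit")

#' Validate a tidy measurement table
#'
#' Checks the schema of the single-cell measurement table: required
#' columns, numeric values, and unit consistency (resonator rows in pg,
#' counter rows in fL). Errors name the offending columns or row numbers.
#'
#' @param measurements data.frame to validate.
#' @return the validated data.frame, invisibly.
#' @export
validate_measurements <- function(measurements) {
  missing <- setdiff(.REQUIRED_COLS, names(measurements))
  if (length(missing)) {
    .psk_error(paste("missing columns:", paste(missing, collapse = ", ")),
               "psk_validation")
  }
  if (nrow(measurements) == 0) return(invisible(measurements))
  bad_num <- which(!is.finite(measurements$value))
  if (length(bad_num)) {
    .psk_error(paste("non-numeric or non-finite values in rows:",
                     paste(utils::head(bad_num, 10), collapse = ", ")),
               "psk_validation")
  }
  expected <- ifelse(measurements$instrument == "resonator", "pg", "fL")
  bad_unit <- which(measurements$unit != expected)
  if (length(bad_unit)) {
    .psk_error(paste("unit mismatch (resonator must be pg, counter fL) in rows:",
                     paste(utils::head(bad_unit, 10), collapse = ", ")),
               "psk_validation")
  }
  bad_instr <- which(!measurements$instrument %in%
                       c("resonator", "impedance_counter"))
  if (length(bad_instr)) {
    .psk_error(paste("unknown instrument in rows:",
                     paste(utils::head(bad_instr, 10), collapse = ", ")),
               "psk_validation")
  }
  invisible(measurements)
}

# build a psk_sample from the rows of one (species, condition, replicate,
# instrument, fluid) cell of the table
.sample_from_rows <- function(rows) {
  single_cell_sample(rows$value, species = rows$species[1],
                     condition = rows$condition[1],
                     replicate_id = rows$replicate_id[1],
                     instrument = rows$instrument[1],
                     fluid_density = rows$fluid_density_g_ml[1])
}

# mean/sem aggregation helper for influence tables
.aggregate_influences <- function(rows_df) {
  agg <- function(x) c(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)),
                       n = length(x))
  sp <- split(rows_df, rows_df[c("species", "condition", "factor")],
              drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(g) {
    a <- agg(g$influence)
    data.frame(species = g$species[1], condition = g$condition[1],
               factor = g$factor[1], influence_mean = a[["mean"]],
               influence_sem = a[["sem"]], n_pairs = a[["n"]])
  }))
  rownames(out) <- NULL
  out
}

#' Run the full starvation-sinking analysis
#'
#' Orchestrates the pipeline across species x conditions x replicates:
#' per-replicate population biophysics, dual-fluid dry/water content (when
#' a D2O arm is present), relative sinking fold changes with one-sample t
#' tests and a significance classification, density/volume and water/dry
#' influence decompositions (per replicate pair by default), Peclet numbers
#' for the nitrate and virus diffusivity presets, and proliferation rates
#' from day counts. Stages whose inputs are absent are skipped and flagged,
#' not failed. The result is deterministic given the dataset and config.
#'
#' @param study a `psk_study` from [simulate_study()], or a list with
#'   elements `measurements` (tidy table, see [validate_measurements()])
#'   and optionally `counts`.
#' @param config a [study_config()].
#' @return list of class `psk_report`; see the fields of the returned
#'   object (`biophysics`, `fold_changes`, `influence_density_volume`,
#'   `influence_water_dry`, `dry_content`, `peclet`, `proliferation`,
#'   `flags`, `provenance`).
#' @export
run_study <- function(study, config = study_config()) {
  if (is.data.frame(study)) study <- list(measurements = study)
  meas <- study$measurements
  validate_measurements(meas)
  flags <- character(0)
  ref <- config$reference_condition

  ## --- per-replicate biophysics (H2O arms) -------------------------------
  h2o <- meas[meas$fluid == "h2o", , drop = FALSE]
  key <- interaction(h2o$species, h2o$condition, h2o$replicate_id,
                     drop = TRUE)
  bio_rows <- list(); dry_rows <- list()
  for (cell in split(h2o, key)) {
    sp <- cell$species[1]
    mass_rows <- cell[cell$instrument == "resonator", , drop = FALSE]
    vol_rows <- cell[cell$instrument == "impedance_counter", , drop = FALSE]
    if (!nrow(mass_rows) || !nrow(vol_rows)) {
      flags <- c(flags, sprintf("missing instrument arm for %s/%s/%s",
                                sp, cell$condition[1], cell$replicate_id[1]))
      next
    }
    vs <- .sample_from_rows(vol_rows)
    thr <- config$min_particle[[sp]]
    if (!is.null(thr)) vs <- filter_small_particles(vs, thr, quiet = TRUE)
    bp <- population_biophysics(.sample_from_rows(mass_rows), vs,
                                fluid = config$fluid,
                                shape = .species_shape(config, sp),
                                statistic = config$statistic)
    bio_rows[[length(bio_rows) + 1L]] <- data.frame(
      species = bp$species, condition = bp$condition,
      replicate_id = bp$replicate_id, mean_bm_pg = bp$mean_buoyant_mass,
      mean_vol_fl = bp$mean_volume, density_g_ml = bp$density,
      radius_um = bp$equivalent_radius, v_um_s = bp$sinking_velocity,
      n_mass = bp$n_mass, n_volume = bp$n_volume)
  }
  if (!length(bio_rows)) .psk_error("no usable measurement arms",
                                    "psk_validation")
  biophysics <- do.call(rbind, bio_rows)
  rownames(biophysics) <- NULL

  ## --- dual-fluid dry content (needs the D2O arm) ------------------------
  d2o <- meas[meas$fluid == "d2o" & meas$instrument == "resonator", ,
              drop = FALSE]
  has_d2o <- nrow(d2o) > 0
  if (has_d2o) {
    stat <- if (config$statistic == "mean") mean else stats::median
    kd <- interaction(d2o$species, d2o$condition, d2o$replicate_id,
                      drop = TRUE)
    for (cell in split(d2o, kd)) {
      b <- biophysics[biophysics$species == cell$species[1] &
                        biophysics$condition == cell$condition[1] &
                        biophysics$replicate_id == cell$replicate_id[1], ,
                      drop = FALSE]
      if (!nrow(b)) next
      dc <- tryCatch(
        dual_fluid_dry_content(b$mean_bm_pg, stat(cell$value),
                               rho1 = config$fluid$density,
                               rho2 = cell$fluid_density_g_ml[1],
                               total_volume = b$mean_vol_fl),
        psk_error = function(e) NULL)
      if (is.null(dc)) {
        flags <- c(flags, sprintf("inconsistent dual-fluid data for %s/%s/%s",
                                  cell$species[1], cell$condition[1],
                                  cell$replicate_id[1]))
        next
      }
      dry_rows[[length(dry_rows) + 1L]] <- data.frame(
        species = cell$species[1], condition = cell$condition[1],
        replicate_id = cell$replicate_id[1],
        water_volume_fl = dc$water_volume, dry_volume_fl = dc$dry_volume,
        dry_density_g_ml = dc$dry_density, water_fraction = dc$water_fraction)
    }
  } else {
    flags <- c(flags, "no D2O arm: water/dry influence table skipped")
  }
  dry_content <- if (length(dry_rows)) do.call(rbind, dry_rows) else NULL
  if (!is.null(dry_content)) rownames(dry_content) <- NULL

  ## --- fold changes vs the reference condition ---------------------------
  conds <- setdiff(unique(biophysics$condition), ref)
  fc_rows <- list()
  for (sp in unique(biophysics$species)) {
    b_sp <- biophysics[biophysics$species == sp, , drop = FALSE]
    hi <- b_sp[b_sp$condition == ref, , drop = FALSE]
    if (!nrow(hi)) {
      flags <- c(flags, sprintf("no reference condition for %s", sp))
      next
    }
    hi_v <- stats::setNames(hi$v_um_s, hi$replicate_id)
    for (cond in conds) {
      lo <- b_sp[b_sp$condition == cond, , drop = FALSE]
      if (!nrow(lo)) next
      lo_v <- stats::setNames(lo$v_um_s, lo$replicate_id)
      fc <- tryCatch(relative_sinking_change(hi_v, lo_v),
                     psk_error = function(e) NULL)
      if (is.null(fc)) {
        flags <- c(flags, sprintf("fold change unavailable for %s/%s",
                                  sp, cond))
        next
      }
      fc_rows[[length(fc_rows) + 1L]] <- data.frame(
        species = sp, condition = cond, mean_ratio = fc$mean_ratio,
        sem = fc$sem, n_pairs = fc$n_pairs, t = fc$test$statistic,
        df = fc$test$df, p_value = fc$test$p_value)
    }
  }
  fold_changes <- if (length(fc_rows)) do.call(rbind, fc_rows) else NULL
  if (!is.null(fold_changes)) {
    rownames(fold_changes) <- NULL
    p_use <- fold_changes$p_value
    if (config$fdr) {
      for (cond in unique(fold_changes$condition)) {
        i <- fold_changes$condition == cond
        p_use[i] <- stats::p.adjust(fold_changes$p_value[i], "BH")
      }
      fold_changes$p_adjusted <- p_use
    }
    fold_changes$classification <- ifelse(
      p_use >= config$alpha, "unchanged",
      ifelse(fold_changes$mean_ratio > 1, "increased", "decreased"))
  }

  ## --- influence decompositions ------------------------------------------
  dv_rows <- list(); wd_rows <- list()
  pair_decompose <- function(sp, cond, b_hi, b_lo, kind) {
    if (config$influence_on == "means") {
      ids <- list(NULL)  # one decomposition on condition means
    } else {
      ids <- intersect(b_hi$replicate_id, b_lo$replicate_id)
      if (!length(ids)) return(NULL)
    }
    out <- list()
    for (id in ids) {
      if (is.null(id)) {
        hi <- lapply(b_hi[-(1:3)], mean); lo <- lapply(b_lo[-(1:3)], mean)
        pair_label <- "means"
      } else {
        hi <- as.list(b_hi[b_hi$replicate_id == id, ])
        lo <- as.list(b_lo[b_lo$replicate_id == id, ])
        pair_label <- id
      }
      res <- tryCatch({
        if (kind == "density_volume") {
          influence_density_volume(
            c(density = hi$density_g_ml, radius = hi$radius_um),
            c(density = lo$density_g_ml, radius = lo$radius_um),
            fluid = config$fluid, shape = .species_shape(config, sp))
        } else {
          influence_water_dry(
            c(water_volume = hi$water_volume_fl,
              dry_volume = hi$dry_volume_fl,
              dry_density = hi$dry_density_g_ml),
            c(water_volume = lo$water_volume_fl,
              dry_volume = lo$dry_volume_fl,
              dry_density = lo$dry_density_g_ml),
            fluid = config$fluid, water_density = config$dens[["water"]],
            shape = .species_shape(config, sp))
        }
      }, psk_error = function(e) NULL)
      if (is.null(res)) {
        warning(sprintf("degenerate decomposition excluded: %s/%s pair %s",
                        sp, cond, pair_label), call. = FALSE)
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        species = sp, condition = cond, replicate_pair = pair_label,
        mode = kind, factor = names(res$influences),
        term = c(res$terms, NA_real_)[seq_along(res$influences)],
        influence = unname(res$influences), valid = res$valid)
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  for (sp in unique(biophysics$species)) {
    b_sp <- biophysics[biophysics$species == sp, , drop = FALSE]
    b_hi <- b_sp[b_sp$condition == ref, , drop = FALSE]
    if (!nrow(b_hi)) next
    for (cond in conds) {
      b_lo <- b_sp[b_sp$condition == cond, , drop = FALSE]
      if (!nrow(b_lo)) next
      dv_rows[[length(dv_rows) + 1L]] <-
        pair_decompose(sp, cond, b_hi, b_lo, "density_volume")
      if (!is.null(dry_content)) {
        d_hi <- dry_content[dry_content$species == sp &
                              dry_content$condition == ref, , drop = FALSE]
        d_lo <- dry_content[dry_content$species == sp &
                              dry_content$condition == cond, , drop = FALSE]
        if (nrow(d_hi) && nrow(d_lo)) {
          wd_rows[[length(wd_rows) + 1L]] <-
            pair_decompose(sp, cond, d_hi, d_lo, "water_dry")
        }
      }
    }
  }
  infl_dv <- if (length(dv_rows)) do.call(rbind, dv_rows) else NULL
  infl_wd <- if (length(wd_rows)) do.call(rbind, wd_rows) else NULL

  ## --- Peclet table -------------------------------------------------------
  pe_len <- vapply(seq_len(nrow(biophysics)), function(i) {
    L <- config$peclet_length[[biophysics$species[i]]]
    if (is.null(L)) 2 * biophysics$radius_um[i] else L
  }, numeric(1))
  peclet <- data.frame(
    biophysics[c("species", "condition", "replicate_id", "v_um_s")],
    length_um = pe_len,
    pe_nitrate = peclet_number(biophysics$v_um_s, pe_len, "nitrate"),
    pe_virus = peclet_number(biophysics$v_um_s, pe_len, "virus"))

  ## --- proliferation ------------------------------------------------------
  prolif <- NULL
  if (!is.null(study$counts) && nrow(study$counts)) {
    kc <- interaction(study$counts$species, study$counts$condition,
                      study$counts$replicate_id, drop = TRUE)
    pr <- lapply(split(study$counts, kc), function(g) {
      est <- proliferation_rate(g$count, g$day)
      data.frame(species = g$species[1], condition = g$condition[1],
                 replicate_id = g$replicate_id[1],
                 doublings_per_day = est$rate, window_days = est$window)
    })
    prolif <- do.call(rbind, pr)
    rownames(prolif) <- NULL
  } else {
    flags <- c(flags, "no day counts: proliferation table skipped")
  }

  ## --- provenance ---------------------------------------------------------
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  saveRDS(config, tmp)
  provenance <- list(
    package_version = as.character(utils::packageVersion("planktosink")),
    config_hash = unname(tools::md5sum(tmp)),
    seed = study$seed %||% NA)

  structure(list(
    biophysics = biophysics,
    dry_content = dry_content,
    fold_changes = fold_changes,
    influence_density_volume = infl_dv,
    influence_density_volume_summary =
      if (!is.null(infl_dv)) .aggregate_influences(infl_dv) else NULL,
    influence_water_dry = infl_wd,
    influence_water_dry_summary =
      if (!is.null(infl_wd)) .aggregate_influences(infl_wd) else NULL,
    peclet = peclet,
    proliferation = prolif,
    flags = flags,
    provenance = provenance), class = "psk_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.psk_report <- function(x, ...) {
  cat("<planktosink study report>\n")
  cat(sprintf("  biophysics: %d replicate arms\n", nrow(x$biophysics)))
  if (!is.null(x$fold_changes)) {
    tab <- table(x$fold_changes$classification)
    cat("  fold-change classifications:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  if (length(x$flags)) cat("  flags:", length(x$flags), "\n")
  invisible(x)
}

#' Write a study report as JSON plus tidy CSV tables
#'
#' @param report a `psk_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- c("biophysics", "dry_content", "fold_changes",
              "influence_density_volume", "influence_water_dry",
              "influence_density_volume_summary",
              "influence_water_dry_summary", "peclet", "proliferation")
  for (nm in tables) {
    if (!is.null(report[[nm]])) {
      utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(
    list(flags = report$flags, provenance = report$provenance,
         tables = Filter(function(nm) !is.null(report[[nm]]), tables)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
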