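# Default species profiles and starvation effects for the synthetic study.
#
# SYNTHETIC STAND-INS: the compositions below are constructed from the
# standard molecular-group densities and typical literature ranges for
# marine pico/nanoplankton (water fraction ~0.65-0.75; dry matter mostly
# protein with smaller lipid, carbohydrate and "other" pools). They are not
# measured values for these strains; they exist so that the full pipeline
# can run and be tested against known ground truth. Velocities they imply
# are in the sub-um/s to ~10 um/s range typical of cells this size.

# helper: composition from total volume, water fraction, and dry fractions
.comp_from_fractions <- function(total, water_frac, protein, lipid,
                                 carbohydrate, other) {
  dry <- total * (1 - water_frac)
  molecular_composition(water = total * water_frac,
                        protein = dry * protein, lipid = dry * lipid,
                        carbohydrate = dry * carbohydrate,
                        other = dry * other)
}

#' Default synthetic species profiles
#'
#' Nine representative unicellular marine phytoplankton spanning diatoms,
#' green algae, haptophytes and a raphidophyte, with synthetic baseline
#' compositions (see file header in `R/profiles.R`). Total volumes range
#' from ~35 fL (small diatom) to ~1500 fL (the raphidophyte).
#'
#' @return named list of [species_profile()]s.
#' @export
default_species_profiles <- function() {
  p <- list(
    # species                 total  waterf  prot  lip  carb  other
    "Chaetoceros calcitrans"   = c(  35, 0.68, 0.55, 0.15, 0.20, 0.10),
    "Heterosigma akashiwo"     = c(1500, 0.72, 0.55, 0.15, 0.20, 0.10),
    "Chlamydomonas sp."        = c( 180, 0.70, 0.55, 0.15, 0.20, 0.10),
    "Tetraselmis sp."          = c( 300, 0.70, 0.50, 0.15, 0.25, 0.10),
    "Dunaliella tertiolecta"   = c( 250, 0.70, 0.50, 0.12, 0.28, 0.10),
    "Prymnesium parvum"        = c( 120, 0.71, 0.55, 0.18, 0.17, 0.10),
    "Emiliania huxleyi"        = c(  50, 0.70, 0.55, 0.15, 0.20, 0.10),
    "Phaeodactylum tricornutum" = c(100, 0.70, 0.55, 0.15, 0.20, 0.10),
    "Isochrysis galbana"       = c(  40, 0.71, 0.52, 0.20, 0.18, 0.10))
  out <- lapply(names(p), function(nm) {
    x <- p[[nm]]
    species_profile(nm, .comp_from_fractions(x[1], x[2], x[3], x[4], x[5],
                                             x[6]))
  })
  stats::setNames(out, names(p))
}

#' Default starvation effects emulating the observed response pattern
#'
#' Low-nutrient condition effects for the nine default species: seven
#' species sink faster when starved (mostly via carbohydrate/protein
#' accumulation, i.e. density; one purely via volume), one slows down (a
#' lipid accumulator / protein loser), and one does not respond. Fold
#' values are synthetic injections chosen to produce roughly 1.5-3x
#' velocity changes of the kinds described for these taxa.
#'
#' @param replicate_sd between-culture scatter passed to every effect.
#' @return nested list `effects[[species]][[condition]]`.
#' @export
default_condition_effects <- function(replicate_sd = 0.01) {
  eff <- function(folds, growth = 0.1) {
    condition_effect("low", folds, replicate_sd = replicate_sd,
                     growth_rate = growth)
  }
  high <- function() {
    condition_effect("high", replicate_sd = replicate_sd, growth_rate = 1.0)
  }
  low <- list(
    # density-driven accumulators of dense storage (starch/protein)
    "Chaetoceros calcitrans"   = eff(c(carbohydrate = 6, protein = 1.3)),
    "Heterosigma akashiwo"     = eff(c(carbohydrate = 5.5, protein = 1.35)),
    "Chlamydomonas sp."        = eff(c(carbohydrate = 6, protein = 1.2)),
    "Tetraselmis sp."          = eff(c(carbohydrate = 4, water = 0.95)),
    "Dunaliella tertiolecta"   = eff(c(carbohydrate = 4.2)),
    "Prymnesium parvum"        = eff(c(carbohydrate = 2.4, protein = 1.25,
                                       water = 1.08)),
    # volume-driven: everything scales, density constant
    "Emiliania huxleyi"        = eff(c(water = 1.9, protein = 1.9,
                                       lipid = 1.9, carbohydrate = 1.9,
                                       other = 1.9)),
    # lipid accumulation + protein loss: sinks slower
    "Phaeodactylum tricornutum" = eff(c(lipid = 4, protein = 0.8)),
    # non-responder
    "Isochrysis galbana"       = eff(numeric(0), growth = 0.1))
  lapply(low, function(e) list(high = high(), low = e))
}
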