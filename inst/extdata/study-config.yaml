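# Example planktosink study configuration.
# Load with read_study_config() or pass to the CLI via --config.
physics:
  fluid_density: 1.026        # g/mL, surface seawater
  viscosity: 1.07e-3          # Pa.s
  gravity: 9.81               # m/s^2
  water_density: 0.998        # g/mL
  d2o_density: 1.122          # g/mL, measured density of the 90% D2O medium
  d2o_water_density: 1.094    # g/mL
  component_densities:
    protein: 1.35
    lipid: 0.92
    carbohydrate: 1.50
    other: 1.30
species:
  "Chaetoceros calcitrans":
    phi: 1.0                  # sphere
    min_particle: 5           # fL, small-particle cutoff for this species
  "Phaeodactylum tricornutum":
    phi: 0.95                 # mild spheroid correction
    peclet_length: 20         # um, fusiform major axis instead of 2r
tests:
  alpha: 0.05
  statistic: mean
  influence_on: pairs
  reference_condition: high
  fdr: false
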