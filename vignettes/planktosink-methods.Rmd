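---
title: "planktosink: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{planktosink: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planktosink)
```

This vignette is the package's own account of its science: the model and
its assumptions, the parameters that matter, what the synthetic generator
does and does not emulate, the numerical choices, and the places where the
design was genuinely open. It states no empirical result that the test
suite does not itself compute.

## The physical model

A cell sinking at micrometre scales is deep in the creeping-flow regime
(Reynolds numbers around 10⁻⁶ for the sizes and speeds handled here), so
its terminal velocity follows Stokes' law,

$$ v = \frac{2\,(\rho_{cell} - \rho_{fluid})\, g\, r^2}{9\mu}\,\Phi, $$

where $r = (3V/4\pi)^{1/3}$ is the equivalent spherical radius and $\Phi$
a multiplicative shape correction. Negative $v$ (a cell less dense than
the medium) is returned unclamped: it is a rise velocity.

**Units.** All user-facing numbers use the laboratory convention:
densities in g/mL (≡ pg/fL), volumes in fL (≡ µm³), radii in µm,
velocities in µm/s, viscosity in Pa·s. Physics is evaluated in SI
internally and converted only at the boundary, so unit errors cannot
accumulate.

**Shape.** Nearly all pico- and nanoplankton handled here are spheres,
spheroids or mild ellipsoids whose drag correction is within 10% of a
sphere. $\Phi$ is therefore a user-supplied per-species scalar (default 1)
rather than an analytic spheroid drag formula; the constructor warns when
$|\Phi - 1| > 0.1$ because outside that range the single-factor
approximation is no longer appropriate.

**Composition.** The cell is the sum of five molecular pools — water,
protein, lipid, carbohydrate, other: $V = \sum_i V_i$ and $\rho_{cell} =
\sum_i (V_i/V)\,\rho_i$. Default pool densities are the standard
macromolecular values (protein 1.35, lipid 0.92, carbohydrate 1.50 g/mL),
pure water at laboratory temperature (0.998 g/mL) and 1.30 g/mL for the
heterogeneous "other" pool (nucleic acids, ions, small metabolites). The
water and "other" defaults are configurable: they are reasonable round
values, not measured constants, and "other" is assumed constant in
simulations because its composition is unresolved. Two consequences worth
knowing: the cell density is always a convex combination of pool
densities, and scaling all pools by $k$ leaves density unchanged while
scaling velocity by $k^{2/3}$.

**Environment.** Defaults are surface seawater: density 1.026 g/mL,
dynamic viscosity 1.07×10⁻³ Pa·s, g = 9.81 m/s². Temperature or salinity
dependence of these properties is out of scope; users model a different
water column by passing a different `fluid_environment()`.

**Transport numbers.** `peclet_number()` computes $Pe = UL/D$ with presets
D = 1700 µm²/s (nitrate, a representative dissolved nutrient) and
D = 10 µm²/s (a virus-sized particle). $Pe \gg 1$ means the cell's motion,
not the particle's diffusion, dominates their encounter rate. The
characteristic length L defaults to the equivalent spherical diameter
$2r$ and can be overridden per species with a measured major-axis length;
the choice matters only as a prefactor since Pe is linear in L.

## Influence decompositions

To say *why* sinking changed between a control (high-nutrient) state and a
perturbed (starved) state, velocity is written as a function of the
factors of interest and expanded to first order **at the control state** —
the expansion point is always the high-nutrient baseline, so influences
answer "of the change we observed, how much came from each factor as the
cell left its reference state".

*Biophysical level*: $v = f(\rho, r)$,

$$ I_{density} = \frac{\partial_\rho f \,\Delta\rho}
   {\partial_\rho f \,\Delta\rho + \partial_r f \,\Delta r},
   \qquad I_{volume} = 1 - I_{density}. $$

Volume changes enter through the equivalent radius. The two-factor split
is closed by construction ($I_{volume}$ is computed as $1 - I_{density}$
exactly).

*Molecular level*: $v = f(V_{water}, V_{dry}, \rho_{dry})$ with water
density held constant, $V = V_{water} + V_{dry}$, $\rho_{cell} =
(V_{water}\rho_w + V_{dry}\rho_{dry})/V$. Each of the three Taylor terms
is divided by their sum, and the dry-content influence is reported as
$I_{dry} = I_{dry\,volume} + I_{dry\,density}$.

Influences are signed and need not lie in [0, 1]: a negative influence
means that factor pushed velocity *against* the observed change. The
closed-form partials are exposed (`taylor_partials()`) and are verified in
the test suite against central finite differences on randomized states —
the finite-difference oracle is deliberately built on a different code
path (the composition route) than the analytic formulas it checks.

**Degeneracy.** When the Taylor terms cancel (denominator below 10⁻⁹ of
the largest term) the decomposition is undefined and a typed error is
raised; in the pipeline such replicate pairs are excluded from aggregation
with a warning rather than contaminating the mean. An identical baseline
and perturbed state is a separate "no change" error.

**Replicate handling.** The pipeline computes influences per paired
replicate (high and starved cultures sharing a replicate id) and averages
them (mean ± SEM). Whether the original analysis paired replicates or
decomposed condition means is not documented; both are supported
(`study_config(influence_on = "means")`), pairing is the default because
it propagates between-culture variability into the reported SEM.

## Composition sweeps and buoyancy thresholds

`sweep_component()` scales one pool (or all four dry pools together, the
"dry" sweep) across a fold grid, re-evaluating the full model at each
fold. The default grid is 48 log-spaced folds from 0.25 to 20 — wide
enough to cover multi-fold storage accumulation in either direction. Each
sweep row also carries the first-order density/volume split evaluated at
fold 1; rows where that first-order sum misses the exact velocity change
by more than 20% (relative) are flagged `taylor_valid = FALSE`. The 20%
cut-off is a package choice: large water accumulation bends the curve far
from its tangent and the split stops being meaningful, so those rows are
flagged for exclusion rather than silently reported.

`buoyancy_threshold()` finds the fold at which cell density equals fluid
density. Because density is monotone in the fold and tends to the scaled
pool's own density as the fold grows, reachability is decided analytically
first (accumulating a pool denser than seawater can never float the cell —
reported as `unreachable`, not an error), then the crossing is bracketed
geometrically and solved by bisection to a density residual below 10⁻⁶
g/mL. The procedure is deterministic.

`attribute_observed_change()` answers the complementary question: given
*measured* pool changes, what fraction of the *observed* velocity change
do they reproduce? It simulates the stated deltas and reports
$100 \cdot \Delta v_{sim} / \Delta v_{obs}$; values near 100% mean the
stated change suffices, values above it mean other compensating changes
must exist. Attribution against a zero observed change is undefined and
errors.

## Population inference

The two instruments measure **different cells** (a resonator measures
buoyant mass in pg; an impedance counter measures volume in fL), so all
inference is on population averages: $\rho = \rho_{fluid} +
\overline{BM}/\overline{V}$, radius from $\overline{V}$, velocity from
Stokes. The arithmetic mean is the default statistic (matching
population-average inference); a median option exists for robustness but
changes the estimand.

**Small particles.** Debris below a per-species size threshold can be
removed before averaging (`filter_small_particles()`); no universal
default is imposed because a sensible cutoff depends on the species'
size distribution — it is a per-species config entry.

**Dual-fluid dry content.** Measuring average buoyant mass in plain
seawater ($\rho_1$) and in medium whose water is 90% D₂O ($\rho_2$), with
intracellular water exchanging freely, water contributes no buoyant mass
in either fluid and

$$ V_{dry} = \frac{BM_1 - BM_2}{\rho_2 - \rho_1}, \qquad
   \rho_{dry} = \rho_1 + BM_1 / V_{dry}. $$

The solver is the exact inverse of its forward model $BM_k =
V_{dry}(\rho_{dry} - \rho_k)$ and rejects non-physical inputs ($BM_1 \le
BM_2$, or a dry volume exceeding the counter's total volume) as
inconsistent measurements. Assumptions to be aware of: complete and
instantaneous water exchange, and no correction for labile-hydrogen
deuterium exchange by default (an optional multiplicative factor on the
heavy-water arm is provided). The density of the D₂O medium is a
*measured user input* — the default 1.122 g/mL is only the nominal value
for 90%-heavy seawater and should be replaced by the solution density
actually measured.

**Proliferation.** Doublings/day is the least-squares slope of
log₂(count) against time — exact for exponential growth, and measured
over three consecutive days in the emulated design.

## The statistics layer

The replicate-level tests mirror the comparisons used in this kind of
study: per-pair velocity ratios (starved/control) tested against 1 with a
one-sample t test; Welch, Student and paired t tests; one-way ANOVA with
Tukey HSD; simple linear regression with R². They are thin wrappers over
base R's `t.test`, `aov`/`TukeyHSD` and `lm` behind a uniform result
shape, and the suite pins them to reference values computed independently
with scipy/statsmodels on the same fixtures. Choices worth stating:

* Fold changes are **ratios of velocities**, not log-ratios, tested
  against 1 — matching how relative sinking change is usually plotted.
  Pairs with non-positive control velocity have no meaningful ratio and
  are excluded with a warning.
* **No multiple-testing correction** is applied by default (per-species
  raw p-values are reported); Benjamini–Hochberg is available as a config
  switch.
* The significance threshold for classifying a species as having altered
  sinking defaults to **p < 0.05**; the threshold is exposed in config
  because the underlying choice is a convention, not a law.
* Degenerate inputs (zero-variance groups, all-identical ratios) raise
  typed errors instead of returning NaN statistics. One deliberate
  exception: a paired t test on *literally identical* paired groups
  returns t = 0, p = 1 (the difference is exactly zero everywhere, which
  is a defined, if extreme, outcome).

## The synthetic generator

The generator exists so every pipeline stage is testable against known
truth without any external data. It emulates, per species × condition ×
replicate culture:

1. a **replicate-level composition**: baseline pool volumes × condition
   fold changes × independent lognormal scatter per pool (between-culture
   variability applied before any cell is sampled);
2. **per-cell size variation**: one shared lognormal factor (default CV
   0.3) scaling all pools of that cell — sizes are strictly positive and
   right-skewed, as real volume histograms are;
3. **instrument sampling**: unpaired arms (different cells per
   instrument), counter values = total volume × multiplicative noise,
   resonator values = $\sum_i V_i(\rho_i - \rho_{fluid})$ × noise
   (default noise CV 0.05);
4. **the D₂O arm**: intracellular water takes the measurement fluid's
   water density (full exchange). The heavy medium's water density
   default (1.094 g/mL) sits at the same salt offset above its water as
   plain seawater does (1.026 − 0.998 = 0.028 g/mL), which makes the
   expected buoyant-mass difference between fluids exactly
   $V_{dry}(\rho_2 - \rho_1)$ — so dry-volume recovery is unbiased —
   while the plain-seawater arm still equals $V(\rho_{cell} -
   \rho_{fluid})$ exactly, so density inference recovers the generating
   state. The recovered dry *density* retains the small salt-offset bias
   ($-0.028\,V_{water}/V_{dry}$ g/mL at these defaults) that the real
   dual-fluid method carries under the same zero-water-buoyancy
   assumption;
5. **day counts** for proliferation, log-normal noise around exponential
   growth.

All random factors are **mean-one lognormals** (`meanlog = -sdlog²/2`).
A meanlog-zero parameterization was considered and rejected: it biases
every expectation upward by $e^{\sigma^2/2}$ and would contradict the
requirement that the expected resonator value equal
$V(\rho_{cell}-\rho_{fluid})$ of the generating composition.

Determinism: every arm's seed derives from the single study seed by a
documented affine map (`seed + 7919 × arm index`, mod 2³¹−1), so the same
seed reproduces the same dataset exactly, and different arms never share
a stream.

**Default replicate scatter** is 1% (log scale) per pool. This is the
calibration under which the documented recovery tolerances hold (N = 4
replicate cultures recovering fold changes within 5% and per-condition
densities within 0.005 g/mL in ≥95% of runs); it represents tightly
controlled paired cultures measured within an hour of each other. Real
between-culture variability in uncontrolled settings can be considerably
larger, in which case those tolerances scale accordingly — the parameter
is exposed on `condition_effect()`.

**Default species and effects.** `default_species_profiles()` ships nine
representative species with *synthetic stand-in* compositions (water
fraction ~0.7, dry matter mostly protein) spanning 35–1500 fL;
`default_condition_effects()` injects a response pattern of the kind
reported for these taxa: seven species sink faster when starved (mostly
dense-storage accumulation, one purely by volume growth), one lipid
accumulator sinks slower, one does not respond. These are modelling
choices, not measurements — the profiles file says so prominently — and
the resulting baselines land in the plausible sub-µm/s to ~10 µm/s range,
with water-accumulation buoyancy thresholds above 4-fold and lipid
thresholds above 10-fold on the diatom baseline.

**What a green test does not establish.** The generator shares one size
factor across all pools of a cell (true per-cell covariance between
composition and size is unknown); it does not simulate aggregation,
motility, death, calcified or silicified walls, or time-resolved
starvation kinetics (a single endpoint is emulated); instrument noise is
purely multiplicative with no calibration drift. Recovery results on
synthetic data therefore validate the *inference machinery*, not the
biological realism of any particular parameter value.

## Pattern-recovery criterion

The end-to-end acceptance test runs 100 seeded 9-species studies
(n = 300 cells/arm, N = 4 replicates) and requires (a) ≥95% of
per-species fold-change estimates within 5% of that run's injected truth
and (b) ≥95% of runs to recover the injected
7-increase/1-decrease/1-null pattern. The pattern is judged on the fold
*estimates* — every species on the injected side of 1, the null species
inside the same ±5% band used by (a). A p-value-based classifier was
considered for this criterion and rejected: with a size-0.05 test the
null species is misclassified in ~5% of runs by construction, so the
joint ≥95% bar would be a coin flip regardless of implementation quality;
the significance-based classification (which the report still produces,
and which a single-seed test does check) measures the test's size, not
the pipeline's recovery. Both clauses are computed in
`tests/testthat/test-acceptance.R`; nothing here asserts a number the
suite does not compute.

## Numerical choices, in one place

| Quantity | Value | Why |
|---|---|---|
| Cancelling-denominator guard (influences) | 10⁻⁹ relative | separates true degeneracy from rounding |
| Taylor-validity cut-off (sweeps) | 20% relative | beyond it the linear split is meaningless |
| Bisection residual (thresholds) | 10⁻⁶ g/mL | far below any measurable density difference |
| Partials vs finite differences (tests) | 10⁻⁶ relative, step 10⁻⁶ | standard central-difference accuracy floor |
| Density plausibility band | (0.85, 1.7) g/mL | warning only, sweeps may legitimately leave it |
| CSV serialization | 9 significant digits | idempotent round trips; far beyond instrument precision |
| Default fold grid | 48 log-spaced, 0.25–20 | covers multi-fold storage changes both ways |

## Known limitations

* Single-cell mass–volume pairing is impossible by design (different
  instruments measure different cells); all densities are population
  averages and within-population density variance is unidentifiable here.
* The Stokes model ignores turbulence, wall effects, and drag regimes
  beyond creeping flow; it applies to single cells, not aggregates.
* The shape correction is a scalar; strongly elongated cells need a
  proper drag model.
* The workbook importer maps sheets to the tidy schema by column
  inspection only; sheets with other layouts are listed unmapped and left
  for manual handling. Reading `.xlsx` requires the optional readxl
  package; the package's own exporter writes the equivalent
  sheet-per-CSV directory, which imports losslessly.
* Between-culture scatter, species compositions and condition effects in
  the synthetic world are stated choices; conclusions about real cultures
  require real measurements in the documented CSV schema.
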