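---
title: "Methods: boundary layer, flux and carbonate chemistry in cblflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: boundary layer, flux and carbonate chemistry in cblflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of the models it implements, the
assumptions behind them, the tunable parameters, and the design choices
made where the underlying methodology left the design open. Nothing here
states an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## The measurement being modelled

A dual microsensor (total-scale pH electrode and O₂ optode) is stepped
away from a coral's surface by a micromanipulator: from 0 µm (the surface)
in 100 µm steps to 2500 µm, then in 500 µm steps for a further 2000 µm of
tailing seawater. At each height it dwells and records ten replicate
readings. An independent external probe provides the bulk seawater value.
The package's data model (`micro_profile`) mirrors exactly this: strictly
increasing heights starting at 0, at least one replicate per height, pH in
(0, 14), O₂ ≥ 0.

Processing is a fixed chain, each stage exported on its own:

1. `average_heights()` — arithmetic mean of the replicates per height.
2. `standardize_to_bulk()` — one additive offset (in raw sensor units) so
   that the mean over the tailing region (heights ≥ `tail_from`, default
   2500 µm, the start of the coarse-stepped region) equals the external
   probe exactly. Sensor drift relative to a reference probe is
   offset-like on the timescale of one profile, which is why the
   correction is additive rather than multiplicative; the alternative
   would matter only if drift scaled with the reading itself, which
   typical electrode/optode drift does not.
3. `to_concentration()` — µmol L⁻¹ for both analytes. pH is converted via
   [H⁺] = 10^(−pH) mol (kg seawater)⁻¹ and a fixed density of
   1.025 kg L⁻¹ (overridable; density varies by under 0.3% across the
   temperature/salinity range of warm reef seawater, far below sensor
   noise). O₂ in mg L⁻¹ is divided by 31.998 g mol⁻¹.

A single internal concentration unit makes the flux unit conversion
explicit in exactly one place (see below) and keeps proton and oxygen
code paths identical.

## Boundary layer thickness

The concentration boundary layer (CBL) is the film in which concentration
transitions from its surface value to bulk. The package fits

log₁₀([X])(x) = α + βx

by ordinary least squares and extrapolates the height at which the fitted
line reaches the independently measured bulk concentration:

δ_CBL = (log₁₀([X]_bulk) − α) / β.

This is the unique inversion of the fitted model at the bulk threshold;
written without the parenthesis the expression is dimensionally
inconsistent, so the package implements the inversion. Choices and edge
cases:

- **Fit range.** Which points enter the fit is a genuinely open choice
  for field profiles. The default takes the surface up to the first
  height whose concentration is within 5% of bulk (`bulk_frac = 0.05`),
  always at least three points, and is user-overridable; the range used
  is reported in the result object so a manual override is auditable.
- **Degenerate slopes.** If |β| < `beta_tol` (default 10⁻⁶ log₁₀-units
  per µm — below what a sensor can resolve across a 4500 µm profile) the
  profile is indistinguishable from bulk and a typed condition
  (`cblflux_undefined_thickness`) is raised; the pipeline converts it to
  a flagged `NA` rather than a number.
- **Negative extrapolations** (fitted line meets bulk below the surface)
  are reported with a `negative_extrapolation` flag, never clipped:
  silently truncating to zero would bias group means of thickness.
- The log-linear form is *descriptive*. On exactly log-linear profiles
  the extrapolation is exact (the test suite checks machine precision);
  on other geometries (e.g. S-shaped) it returns an effective thickness.

## Flux from Fick's first law

Flux is the slope of *raw* concentration against height — not the log —
over the upper linear limb of the profile, times the diffusion
coefficient: J = −D·m. With m in µmol L⁻¹ µm⁻¹ and D in cm² s⁻¹,

J [µmol m⁻² s⁻¹] = −(D × 10⁻⁴) × (m × 10⁹),

since 1 µmol L⁻¹ µm⁻¹ = 10⁹ µmol m⁻⁴ and 1 cm² = 10⁻⁴ m². Positive J is
efflux from the coral. Defaults D_H⁺ = 9.31×10⁻⁵ and
D_O₂ = 2.20×10⁻⁵ cm² s⁻¹ refer to salinity 35 and 26.5 °C and are
overridable as a pair (`diffusion_constants()`). A convenience column
reports J × 10⁴, the conventional display scale for proton flux.

**Gradient-window selection.** Field profiles over rough coral surfaces
are frequently complex or S-shaped, and the "upper linear gradient" has
traditionally been chosen by eye. The package replaces that with a
deterministic rule: among all contiguous windows of at least `min_points`
(default 4) heights that contain the steepest surface-ward segment of the
profile, pick the one maximizing the linear-fit R²; ties (within 10⁻⁹,
which also absorbs floating-point noise on noiseless data) break toward
the window nearer the surface, then toward the longer window. A best
window with R² below `r2_floor` (default 0.8) is returned flagged
(`low_r2`), not rejected, and a profile with no resolvable gradient at
all is flagged `flat` with zero slope. The selected window is always part
of the result, so a manual override remains auditable.

The steady-state assumption means no advection correction, no
cylindrical-geometry correction and no time dependence; those are out of
scope by design.

## Seawater carbonate chemistry

`carb_solve()` computes the CO₂ system from (T, S, pH_T, A_T) on the
total pH scale at 0 dbar with zero nutrients. With pH known the solution
is closed-form: carbonate alkalinity is total alkalinity minus borate,
hydroxide and the minor acid–base terms (free H⁺, HSO₄⁻, HF), and DIC
follows algebraically. The constants are the conventional open-ocean
set — Lueker et al. (2000) K1/K2, Dickson (1990) KB and KS, Millero
(1995) KW, Perez & Fraga (1987) KF, Uppström (1974) total boron, Weiss
(1974) K0 and the CO₂ fugacity correction, Mucci (1983) aragonite
solubility, calcium proportional to salinity (Riley & Tongudai 1967).
pCO₂ is fCO₂ divided by the Weiss virial fugacity factor (a ~0.3%
correction at these temperatures).

The reverse direction, `carb_solve_dic()` (DIC, A_T → pH), is a damped
Newton iteration on [H⁺] with a numerically differenced Jacobian,
bracket maintenance over pH ∈ [2, 12] and a log-space bisection fallback,
converging to a relative tolerance of 10⁻¹² on [H⁺]. `roundtrip_check()`
drives a solved state through this reverse path and reports the pH and
pCO₂ discrepancies; the test suite additionally cross-checks the Newton
root against a deliberately naive 60-iteration bisection root-finder
written independently in the test helpers, and verifies the alkalinity
residual at every solution (below 10⁻³ µmol kg⁻¹).

Pressure corrections, pH-scale conversions and calcite saturation are out
of scope. One caveat worth stating: derived values are solved at the
*mean* of a bottle-sample series; when comparing against values that were
themselves averaged over per-sample solves from inputs printed at two
decimals of pH, discrepancies up to about one percent in the small
carbonate-ion pool arise from input quantization alone.

## Surface metrics, calcification and statistics

- `surface_record()` / `diel_delta()`: the surface value is the averaged,
  bulk-standardized reading at 0 µm; the diel oscillation is light minus
  dark for records matched on species, genotype and treatment (mismatches
  are errors, not NA).
- `calcification_rate()`: (final − initial buoyant weight) / days, in
  g CaCO₃ d⁻¹; the study design uses 19 days as the default exposure.
- `factorial_compare()`: ordinary least squares on fully crossed factors,
  Type II sums of squares by default (Type III with sum contrasts
  available; Type II is the conventional choice for balanced-ish
  factorial designs and is invariant to factor-level relabeling), cell
  estimated marginal means, and all pairwise cell contrasts with
  Bonferroni adjustment at α = 0.05. Random effects are deliberately not
  modelled — genotype effects in this design proved negligible and the
  final models drop them — but genotype is carried in the data so an
  external mixed-model check remains possible. An optional Yeo-Johnson
  transformation (maximum-likelihood λ over [−3, 3]) accommodates
  sign-mixed, skewed flux responses. Internally the response is rescaled
  to unit variance before fitting (F, t and p are invariant; estimates
  are rescaled back) so that µmol-scale proton fluxes (~10⁻⁵) do not trip
  numerical-rank checks. A perfectly constant response is reported as
  F = 0, p = 1 throughout rather than as 0/0.

## The synthetic-data generator

`synth_config()` + `make_profile()` produce profiles with *exact* ground
truth, emulating the instrument: the canonical 30-height scheme, ten
replicate readings per height, Gaussian per-reading noise in sensor units
(defaults 0.01 pH, 0.05 mg O₂ L⁻¹ — typical microelectrode/optode
precision), an optional constant sensor drift that the standardization
stage must remove, and an exact external bulk. Proton profiles are
generated in [H⁺] space and emitted as pH readings, so generator truth is
exact in flux units. Three geometries: `linear` (steady-state Fick:
constant gradient inside the boundary layer), `loglinear` (the CBL
fit's own model), and `s_shaped` (surface plateau, a linear limb carrying
the imposed gradient, then a half-cosine approach to bulk whose mean
slope is half the limb's, guaranteeing the limb is the steepest and
linear portion). Default bulk values are the measured morning control
seawater (pH_T 7.97, O₂ 6.99 mg L⁻¹); defaults are study conditions, not
assertions about new data. Each profile draws from an RNG stream derived
from `(seed, profile index)`, so datasets are byte-reproducible and
individual profiles can be regenerated in isolation.

`make_factorial_dataset()` builds the 2 species × 2 treatment × 2
light/dark design: cell mean flux = (species × condition baseline) ×
(cell multiplier, default 1). The proton baselines follow the observed
group means (dark efflux 2.5×10⁻⁴ for *P. acuta* and 0.29×10⁻⁴
µmol m⁻² s⁻¹ for *M. capitata*; light influxes −0.7×10⁻⁴ / −0.5×10⁻⁴,
magnitudes chosen so a linear [H⁺] profile to a pH 7.97 bulk stays
positive, implying light surface pH ≈ 8.3). The ocean-acidification
repression scenario multiplies the *P. acuta* × high-pCO₂ × dark cell by
0.16 (an 84% reduction). Three colonies per cell reproduce the reference
design's residual degrees of freedom (16). Between-colony biological
variation has two modes, chosen to match the question being asked:

- **proportional** (`bio_cv`, default 0.15): colony flux spread scales
  with the cell mean, the realistic structure for between-genotype
  physiological variation; used for effect-size recovery and power
  checks.
- **absolute** (`bio_sd`): one common additive σ in every cell — the
  exchangeable, homoscedastic null under which an OLS F-test is actually
  calibrated. Type-I-error simulations use this mode, because under the
  proportional mode a "null" dataset (all multipliers 1) still has cell
  variances differing by almost two orders of magnitude between the
  largest and smallest baselines, and smallish-n F-tests are known to be
  anticonservative under such heterogeneity; measuring that robustness
  gap is a different experiment from checking the test's calibration.

What the generator does **not** emulate: hydrodynamics and ciliary
vortices (profile shape is imposed, not simulated), treatment effects on
the bulk chemistry itself (one bulk per dataset), sensor calibration
error beyond constant drift, tissue-surface microtopography, or
time-dependence. Passing recovery tests on synthetic data therefore
demonstrates the estimators' correctness and calibration under the
instrument's sampling scheme and noise level, not robustness to every
pathology of field profiles.

## Problem sizes used in validation

The stochastic validation runs use 200 seeds each: boundary-layer
recovery on noisy log-linear profiles at the canonical sampling scheme,
effect-size recovery and interaction power on full 24-profile factorial
datasets run through the entire pipeline, and type-I calibration on
response-level datasets. Noiseless flux identity uses 20 configurations
with |J| spanning 10⁻⁵–10 µmol m⁻² s⁻¹ across both analytes and both
directions, with per-configuration bulk levels and signs chosen so
concentrations remain physical. These sizes give Monte-Carlo standard
errors comfortably below the tolerances being asserted.

## Known limitations

- The log-linear thickness model is descriptive; no piecewise or
  two-region CBL model is offered.
- Flux assumes molecular diffusion through a still film; advective
  contamination of the limb is flagged only indirectly (low R²).
- The carbonate solver is surface-pressure, total-scale, nutrient-free
  by construction.
- Statistical comparisons are fixed-effects OLS; genuinely clustered
  designs need an external mixed-model analysis (the data structures
  retain genotype for exactly that purpose).
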