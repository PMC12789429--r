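# cblflux

Microsensor profiles of pH and dissolved oxygen measured micrometre by
micrometre above a coral's surface resolve the **concentration boundary
layer (CBL)** — the thin, quiescent film of seawater in which diffusion,
not advection, carries material between the animal and the ocean. The
shape of those profiles encodes two quantities central to coral
ecophysiology under ocean acidification: the CBL thickness, and the
diffusive flux of protons and oxygen across it. Proton efflux from the
rapidly calcifying branch tips is how a coral exports the H⁺ generated by
calcification; its repression under elevated pCO₂ is a candidate mechanism
for species-specific calcification sensitivity.

`cblflux` is an R package for analysts working with such profiles. It
takes raw replicate sensor readings and produces:

- **CBL thickness** by log-linear fit and extrapolation: the profile is
  modelled as `log10([X])(x) = α + βx` and the thickness is the distance
  at which the fit reaches the independently measured bulk concentration,
  `δ_CBL = (log10([X]_bulk) − α) / β`.
- **Diffusive flux** by Fick's first law, `J = −D·m`, where `m` is the
  ordinary-least-squares concentration gradient (µmol L⁻¹ per µm) over the
  upper linear limb of the profile — selected automatically and
  deterministically for complex and S-shaped profiles — and
  `D_H⁺ = 9.31×10⁻⁵`, `D_O₂ = 2.20×10⁻⁵` cm² s⁻¹ (salinity 35, 26.5 °C).
  Positive `J` is efflux from the coral. Fluxes are reported in
  µmol m⁻² s⁻¹.
- **Seawater carbonate chemistry** from temperature, salinity, total-scale
  pH and total alkalinity: HCO₃⁻, CO₃²⁻, DIC, pCO₂ and the aragonite
  saturation state Ω_arag, on the total pH scale at surface pressure, with
  the conventional open-ocean constants (Lueker et al. 2000 K1/K2, Dickson
  1990 KB/KS, Perez & Fraga 1987 KF, Uppström 1974 boron, Mucci 1983
  aragonite solubility, Weiss 1974 CO₂ solubility and fugacity).
- **Physiological summaries and statistics**: diel surface oscillations
  (light − dark at 0 µm), buoyant-weight calcification rates, and
  factorial linear-model comparisons (species × treatment × light/dark)
  with Type II ANOVA, estimated marginal means and Bonferroni-adjusted
  pairwise contrasts, with an optional Yeo-Johnson transformation for
  sign-mixed flux responses.
- A **seeded synthetic-profile generator** with exact ground truth
  (imposed flux, imposed δ_CBL, imposed group effect sizes) emulating the
  instrument's sampling scheme — 10 readings per height, 100 µm steps to
  2500 µm, then 500 µm steps for a further 2000 µm — used throughout the
  test suite for parameter-recovery validation.

## Worked example

Simulate an S-shaped oxygen profile with a known influx of
−0.3 µmol m⁻² s⁻¹ carried by a linear limb at 100–600 µm, then run the
full pipeline (replicate averaging → bulk standardization → unit
conversion → CBL fit → gradient-window selection → flux):

```r
library(cblflux)

cfg <- synth_config("s_shaped", "oxygen", imposed_flux = -0.3,
                    delta_cbl_true = 900, limb = c(100, 600), seed = 42)
res <- profile_pipeline(make_profile(cfg)$profile)
res
#> CBL log-linear fit (oxygen, profile 'sim_ox_001')
#>   alpha = 2.10338, beta = 0.000298904 per um (R^2 = 0.9742, n = 9)
#>   delta_CBL = 789.5 um at bulk 218.5 umol/L  [ok]
#> Fick flux (oxygen, profile 'sim_ox_001')
#>   gradient m = 0.1413 umol/L/um over 100-500 um (R^2 = 0.9997297, n = 5)
#>   J = -0.3109 umol m-2 s-1 (influx; x1e4 scale: -3109)  [ok]
```

The window selector found the imposed limb and the recovered flux is
within 4% of the imposed −0.3 µmol m⁻² s⁻¹ at realistic sensor noise. The
boundary layer estimate (789.5 µm against the 218.5 µmol L⁻¹ ≈
6.99 mg L⁻¹ bulk probe) sits below the imposed 900 µm because the
log-linear extrapolation is a descriptive model: on a profile that is not
itself log-linear it recovers an effective thickness (on exactly
log-linear profiles it is exact to machine precision, and on noisy
log-linear profiles unbiased — see the test suite).

Carbonate chemistry from a bottle sample:

```r
carb_solve(temp = 26.80, salinity = 35.52, pH_T = 7.97, A_T = 2179)
#> Seawater CO2 system at T = 26.80 C, S = 35.52 (total scale, 0 dbar)
#>   pH_T = 7.970   A_T = 2179 umol/kg
#>   HCO3- = 1714  CO3-- = 187  CO2* = 12.4  DIC = 1914 umol/kg
#>   pCO2 = 461 uatm   Omega_arag = 2.98
#>   alkalinity residual = 0 umol/kg
```

A command-line wrapper over the same functions is installed at
`exec/cblflux` (subcommands `profile`, `carb`, `simulate`, `compare`,
`calcify`; every run writes a JSON manifest with input digests, flags,
package version and seed).

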