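---
title: "Modelling membrane-assisted solvent extraction in hollow-fibre contactors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling membrane-assisted solvent extraction in hollow-fibre contactors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pertraction)
```

## The process and the model

Membrane-assisted solvent extraction (pertraction) transfers a hydrophobic
solute from an aqueous donor stream into an organic acceptor stream across a
microporous membrane that immobilises the liquid–liquid interface. In a
hollow-fibre contactor one stream flows through the fibre lumen and the
other through the shell; with a hydrophobic (e.g. PTFE) membrane the organic
phase wets the pores, and the interface sits at the membrane surface facing
the aqueous side. The package models the laboratory-scale recovery of a
monoterpene — (S)-(+)-carvone from water into n-heptane — in a three-fibre
PTFE module, but every quantity is parameterised and none of the machinery
is specific to that system.

Three layers make up the model:

1. **Film coefficients.** The solute diffusivity `D` in each phase comes
   from the Wilke–Chang correlation,
   `D = 7.4e-8 (phi M)^0.5 T / (mu V^0.6)` (cm²/s with `mu` in cP, `V` in
   cm³/mol), with the solute molar volume `V` estimated by Le Bas additive
   increments when not supplied. The lumen-side film coefficient uses the
   Lévêque solution `Sh = 1.62 Gz^(1/3)` with the Graetz number
   `Gz = v d_i² / (L D)` built on the per-fibre mean velocity; the shell-side
   coefficient uses the parallel-flow correlation
   `k = beta (D/d_h)(1 - theta)(d_h/L) Re^0.6 Sc^0.33` with `beta = 5.8`
   for hydrophobic membranes, the packing fraction
   `theta = n d_o²/D_shell²` and the hydraulic diameter
   `d_h = (D_shell² - n d_o²)/(n d_o)`; the membrane term is
   `k_m = 2 eps D_org / (tau (d_o - d_i))` with the *organic*-phase
   diffusivity, since the organic phase wets the pores.

2. **Resistance in series.** On the aqueous basis,
   `1/(K_w d_basis) = 1/(P k_o d_other) + 1/(P k_m d_lm) + 1/(k_w d_basis)`,
   where `P = c_s/c_w` is the partition coefficient, `d_lm` the log-mean
   fibre diameter, and `d_basis` the diameter on the aqueous side of the
   membrane: `d_i` when the aqueous phase is in the lumen ("in-out" mode),
   `d_o` when it is in the shell ("out-in" mode). For strongly partitioning
   solutes (`P` of order 100 or more) the organic and membrane terms are
   negligible and the aqueous film controls.

3. **Recirculating dynamics.** Both streams loop between the module and
   stirred reservoirs, so no steady state exists. With the single-pass
   efficiency `Phi`, the flow factor `E = P Q_s/Q_w` and the reservoir
   factor `R = P V_s/V_w`, the aqueous reservoir obeys
   `dc_w/dt = -(Q_w Phi / V_w)(c_w (1 + 1/R) - c_w0/R)`, whose closed form
   `c_w(t) = c_w0 (1/R + e^{-kt})/(1 + 1/R)` with
   `k = (Q_w Phi/V_w)(1 + 1/R)` the package uses directly (the organic
   reservoir follows by exact conservation). The efficiency itself is
   `Phi = (1 - e^{-x a}) / (1 - (1/E) e^{-x a})` with `x = K_w A/Q_w` and
   `a = 1 - 1/E`, linking the measured dynamics to `K_w`.

Fitting inverts this chain: the transform
`y = ln[(1 + 1/R) c_w/c_w0 - 1/R]` is linear in time through the origin
with slope `-(Q_w Phi/V_w)(1 + 1/R)`, so a least-squares slope yields `Phi`
and then `K_w`.

## Parameters, defaults and provenance

The reference scenario (`synth_paper_fixture()`) encodes the study module:
3 PTFE fibres, 3 mm inner diameter, 20 cm length (inner area 56.5 cm², in
agreement with the module's nominal 56 cm²), 1 µm nominal pores, lumen flow
3 ml/min, shell flow 40 ml/min, aqueous:organic phase ratio 2:1, initial
aqueous carvone 0.15 mg/ml, 25 °C. Solvent bulk properties (molar mass,
viscosity, density, vapour pressure, ICH Q3C class) ship in
`inst/extdata/solvents.csv`.

Several quantities the module vendor or study did not report carry
**documented placeholder values**, chosen once on physical grounds and
clearly marked in `inst/extdata/module_memo3.conf`:

* fibre outer diameter `d_o = 3.3 mm` (0.15 mm wall, typical of thin-wall
  expanded-PTFE capillary membranes);
* membrane porosity 0.5 and tortuosity 2 (canonical stretched-PTFE values);
* shell bore 10 mm (three 3.3 mm fibres with clearance in a small glass
  housing);
* reservoir volumes `V_w = 100 ml`, `V_s = 50 ml` (only their 2:1 ratio is
  specified; every absolute-time prediction depends on this choice);
* carvone/n-heptane `logP = 2.778` (`P ≈ 600`) in the synthetic partition
  table — a representative value for this strongly hydrophobic solute; the
  shipped partition table is synthetic throughout and labelled as such.

With `P` this large the predicted `K_w` is insensitive to `P`, to the
membrane parameters and to the organic film: the aqueous film contributes
more than 99 % of the resistance in both modes.

Other defaults: Wilke–Chang association factors 2.6 (water) and 1.0
(non-associated organics); Le Bas increments C 14.8, H 3.7, carbonyl-O
7.4 cm³/mol (no ring corrections — see limitations); reference temperature
298.15 K; mass-balance closure band 0.85–1.15 on partition replicates
(motivated by the >90 % recoveries typical of this set-up); logP is base-10
throughout; all internal computation in SI, with mg/ml, ml/min, mm, cm²,
minutes accepted at the I/O boundary through unit-suffixed config keys and
explicit converters.

## Numerical choices

* `Phi(x, E)` is evaluated as `-expm1(-x a) / (-expm1(-x a) + a e^{-x a})`,
  which is exact at `E = 1` (`a = 0` gives `x/(1+x)` in the limit) and
  avoids cancellation for `E` near 1; `E = Inf` is accepted and gives the
  plug-extraction form `1 - e^{-x}`.
* The inverse `kw_from_phi()` is analytic: `e^{-x a} = (1 - Phi)/(1 - Phi/E)`,
  so `x = -ln[(1 - Phi)/(1 - Phi/E)]/a`. The attainable range is
  `0 < Phi < min(1, E)`; values outside it are rejected with the range in
  the message. Tests cross-check the inversion against an independent
  bisection of the forward formula and the `E -> Inf` closed form.
* The linearisation excludes points whose log argument is non-positive —
  measurements at or below the equilibrium floor `c_w0/(1 + R)` — and
  reports them with reasons; censored (`NA`) points are reported likewise.
  Near the floor the argument `(1 + 1/R) c_w/c_w0 - 1/R` is a difference of
  nearly equal numbers, so even exact model output loses all significant
  digits once `e^{-kt}` falls below about `1/R` times machine epsilon;
  sampling horizons in the tests are chosen so courses stay clear of that
  regime, which mirrors good experimental practice (points at equilibrium
  carry no kinetic information).
* Regression is through the origin by default because the model forces
  `y(0) = 0`; a free-intercept fit is available as a diagnostic.
* The bootstrap resamples time points with replacement (seeded, percentile
  intervals, 1000 resamples by default); resamples whose slope implies an
  unattainable `Phi` are dropped from the interval.
* `log_mean_diameter()` returns the continuous limit `d` at `d_o = d_i`.
* A lumen Graetz number below 4 triggers a warning (the Lévêque solution
  degrades there), never an error.

## The synthetic-data generator

`synth_partition_replicates()` emulates shake-flask equilibria: noiseless
concentrations from the dosed amount and the mass balance
(`c_w = c_total/(1 + r P)`, `c_s = P c_w`), then multiplicative Gaussian
noise (default sd 2 %, typical HPLC repeatability) or additive noise, in
triplicate. `synth_timecourse()` wraps the closed-form simulation, adds
module inlet/outlet stream concentrations from the single-pass balance
(`c_w,out = c_w (1 - Phi) + (Phi/P) c_s`), applies noise and
lower-limit-of-quantification censoring, and stores the generating
parameters as attributes so tests never re-derive truth from noisy data.
The default schedule (0, 15, 30, 60, 120, 240, 360, 480 min) mirrors an
8-hour bench run.

What the generator does **not** emulate — and what passing tests therefore
do not demonstrate about real data: solute adsorption to tubing and module
materials (real recoveries are 90–95 %, not 100 %), slow interfacial or
wetting transients, temperature drift, pump pulsation, analytical
calibration bias, and any departure of the true module physics from the
plug-flow single-pass balance. Parameter-recovery results certify the
estimator, not the correlations.

## Design decisions where the design was open

* The per-fibre interpretation of the lumen flow (total flow divided by the
  number of identical parallel fibres) is used in the Lévêque term.
* The shell Reynolds number uses the superficial velocity through the shell
  free cross-section and the hydraulic diameter above; with this
  correlation the explicit `d_h` cancels and `Re` is independent of the
  shell bore, so the predicted shell coefficient depends on geometry only
  through `(1 - theta)` and `d_o`.
* The interfacial area for efficiency/coefficient conversions defaults to
  the mode-consistent basis (inner area for aqueous-in-lumen, outer for
  aqueous-in-shell) and is overridable, since either convention appears in
  the contactor literature.
* Both directions of the efficiency–coefficient link are exposed
  (`module_efficiency_phi()` and `kw_from_phi()`), as either may be the
  measured quantity.
* The solvent-choice logic is formalised as an explicit, user-configurable
  lexicographic policy (ICH Q3C toxicity class, then logP, then vapour
  pressure) with a weighted-score alternative; neither is claimed to be
  *the* published procedure, which is narrative.
* Water-miscibility flags are input metadata (mutual-solubility prediction
  is out of scope); flagged solvents are annotated "polar-unreliable" in
  rankings rather than removed.

## Worked example

```{r example}
fx <- synth_paper_fixture()

# predicted overall coefficient, aqueous feed in the lumen
predict_kw(fx$module, fx$operating$in_out, fx$solute, fx$water,
           fx$heptane, fx$P)

# efficiency at a measured K_w, and back
phi <- module_efficiency_phi(2.2e-6, A = cm2_to_m2(56),
                             Q_w = ml_min_to_m3_s(3), E = 1e6)
phi
kw_from_phi(phi, A = cm2_to_m2(56), Q_w = ml_min_to_m3_s(3), E = 1e6)

# simulate, fit, recover
op <- fx$operating$in_out
course <- synth_timecourse(0.222, fx$P, op, sd = 0.02, seed = 42)
fit_phi_kw(course, op, fx$module, P = fx$P, nboot = 500, seed = 42)
```

## Validation scale

The shipped tests run the full chain at bench scale: parameter-recovery
grids over efficiency, partition coefficient and reservoir volume; 100
seeded noisy replicates for the median-error bound; 200 seeded replicates
with 400 bootstrap resamples each for interval-coverage sanity; 20 seeds by
4 logP levels for the partition round trip. These sizes keep the whole
suite under a few seconds while leaving Monte-Carlo margins wide relative
to the asserted bounds.

## Known limitations

* Le Bas volumes omit ring corrections; for cyclic solutes such as carvone
  this overestimates `V` somewhat and correspondingly underestimates `D`.
  The diffusivity-dependent predictions inherit roughly ±10 % uncertainty
  from the molar-volume convention alone.
* Shell-side mass transfer in sparse fibre bundles is notoriously
  geometry-sensitive, and the parallel-flow correlation used here is known
  to scatter widely between modules. With any physically admissible
  geometry for this three-fibre module the correlation caps the predicted
  shell-side (out-in) overall coefficient near 3×10⁻⁶ m/s, noticeably
  below values reported for comparable modules; the in-out (lumen-limited)
  prediction is far more trustworthy.
* The published Graetz-number value for this module's tube side (0.71) is
  not reproduced by the standard definition `Gz = Re Sc d/L` evaluated from
  the stated geometry and flows (which gives ≈ 153); the package reports
  the standard definition for diagnostics and pins no test to the published
  number.
* The recirculating model assumes lossless reservoirs, constant `P`,
  constant volumes and instantaneous mixing; adsorption losses and
  transmembrane-pressure effects (breakthrough) are outside its scope.
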