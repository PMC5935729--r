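---
title: "From litter phenols to lake methane: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From litter phenols to lake methane: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedimeth)
```

## The scientific problem

Littoral lake sediments are a dominant source of freshwater CH4, and the
kind of plant litter they receive changes how much methane they produce.
Water-soluble phenols leached from decomposing forest litter inhibit
methanogens, while emergent-macrophyte litter (*Typha latifolia*, "TYP")
leaves methanogenesis largely unimpeded. `sedimeth` implements the full
quantitative chain behind that argument for anaerobic jar incubations of
amended sediments:

1. **gas flux** — cumulative CH4/CO2 production per jar from periodic
   headspace measurements, with dilution bookkeeping;
2. **EEM/PARAFAC** — a relative phenol index from porewater fluorescence;
3. **qPCR** — methanogen (mcrA) abundance and treatment fold-differences;
4. **statistics** — the amendment-by-spike ANOVA and the log–log
   phenol–CH4 regression;
5. **upscaling** — a Boreal-Shield-wide CH4 projection from
   species-distribution-model occurrence probabilities;
6. **synthetic data** — seeded generators for every input, so the whole
   pipeline runs and is testable without any external data.

## Headspace accounting

Each jar holds headspace volume $V$ (default 122.65 mL: a 250 mL jar minus
4.5 cm of sediment over 28.3 cm²) at 20.5 °C and 101.325 kPa. At every
sampling event, 10 mL of N2 is homogenized into the headspace and a 10 mL
sample is withdrawn, so the recorded concentration $c_k$ (ppm by volume)
refers to the *mixed* state in $V + 10$ mL. Ideal-gas conversion gives the
headspace mass $m_k$; the withdrawal removes $r_k = m_k \cdot 10/(V+10)$.
Total production over the incubation is the mass left after the final
withdrawal plus all removed portions added back:

$$\text{total} = (m_K - r_K) + \sum_{k=1}^{K} r_k,$$

divided by the sediment area (28.3 cm²) for a per-area seasonal rate in
mg m⁻². The event model is exactly invertible: the synthetic generator
forward-simulates any cumulative production curve through the same
bookkeeping, and `cumulative_production()` recovers the stored truth to
machine precision — this round trip is asserted in the tests over hundreds
of random trajectories.

Two conventions are defensible for when the instrument reading happens;
`production_ledger(measure_state = "mixed")` (default) takes the reading
after N2 injection, `"pre"` before it. The generator uses the mixed
convention, so the pair is self-consistent and the choice is testable.

Assumptions: isothermal, isobaric ideal gas; no Henry's-law partitioning of
CH4/CO2 into porewater; concentration drops that would imply negative
production are flagged per jar rather than silently clamped, and excluded
from summaries only under `strict = TRUE`.

## Fluorescence, PARAFAC, and the phenol index

Porewater EEMs live on a 41-point excitation grid (250–450 nm, 5 nm) and a
151-point emission grid (300–600 nm, 2 nm). Inner-filter attenuation is
corrected multiplicatively with the measured absorbance (1 cm pathlength),
$I_\text{corr} = I \cdot 10^{(A_{ex}+A_{em})/2}$; samples with
$\max A > 1.5$ are outside the correction's validity and flagged.

`fit_parafac()` decomposes the sample × excitation × emission cube into
$F$ trilinear components with nonnegative scores and loadings, by
hierarchical alternating least squares: each factor column update solves
its nonnegative subproblem exactly, so the residual sum of squares cannot
increase (asserted per iteration in the tests). Identification of the model
rests on variation of the component scores across samples; the five
reference fluorophores here include a tyrosine-like (270/306 nm) and a
phenol-leachate-like (275/318 nm) component whose spectra overlap heavily
(concatenated-loading congruence ≈ 0.93), which makes the optimization
landscape genuinely hard.

Three numerical choices address that difficulty, and they matter:

* **Initialization.** Dense uniform-random starts almost always collapse
  the tyrosine/phenol pair into one component and waste a factor
  duplicating a humic peak (a local optimum ~0.02 %-points of variance
  below the global one). The first start therefore uses the singular
  vectors of the mode unfoldings, and the remaining starts draw random
  *localized Gaussian bumps* for the spectral modes — a shape prior that
  matches fluorophores. Initial scores come from an exact least-squares
  solve given the initial loadings.
* **Convergence.** The tolerance is on the change in fit
  ($1 - \text{SSE}/\text{SS}_\text{tot}$) between iterations; the default
  is $10^{-9}$ with up to 5000 iterations because collinear components
  produce long, shallow "swamps" in which a looser $10^{-8}$ stop leaves
  the phenol emission peak unsettled by a grid step or two.
* **Scale indeterminacy.** After fitting, spectral loading columns are
  rescaled to unit maximum and the magnitude is pushed into the scores;
  the reconstruction is invariant under this renormalization.

Split-half validation (`split_half_validate()`) fits random halves
independently and matches components by Tucker congruence of concatenated
excitation+emission loadings (greedy bijection, highest congruence first,
ties by component index); the default pass threshold is 0.95, standard for
this use. Overfactored models fail it because the surplus component fits
half-specific noise. Scatter bands are not simulated or excised by default
(`excise_scatter()` provides an optional ±10 nm first-order Rayleigh mask,
handled as missing data by expectation-style imputation).

`match_components()` labels fitted components against the Gaussian
reference spectra and reports grid-argmax peak positions. Note that a
fluorophore with a 25 nm emission width is almost flat across a 2 nm grid
step near its maximum, so even a fitted loading with congruence 0.9999 can
report an argmax one step from the truth; that resolution limit is
inherent to the grid, not to the fit.

The relative phenol concentration of a sample is the proportion of total
fitted score carried by the phenol component times the porewater DOC
concentration (mg L⁻¹); it is zero when a sample shows no phenol
fluorescence.

## qPCR quantification

`fit_standard_curve()` regresses mean Ct on log10 copies over a 10-fold
dilution series (≥3 points spanning ≥2 orders), reporting the slope,
intercept, R², and amplification efficiency $10^{-1/\text{slope}} - 1$.
The default synthetic assay uses slope −3.391 and intercept 38, i.e.
efficiency ≈ 97.2 %. `quantify_copies()` inverts the curve at the
triplicate-mean Ct and normalizes to copies per g dry sediment with
elution/template volumes, dry mass and extraction yield (defaults 100 µL,
2 µL, 0.25 g, 1.0 — configurable; they cancel from treatment ratios).
Ct values beyond the standard range extrapolate with a warning rather than
failing. Treatment contrasts (`fold_table()`) are geometric means across
the 10/20/40 % OM levels, with the SE computed on the log scale and
back-transformed, because abundances span orders of magnitude.

## Statistical layer

`anova_amendment_spike()` is a one-way ANOVA over the amendment × spike
cells at one OM level (8 cells × 4 replicates gives the design's
F with 7 and 24 degrees of freedom). It runs on log-transformed rates by
default: production spans nearly four orders of magnitude, so raw-scale
homoscedasticity is untenable; a raw-scale flag exists for comparison.
Group separation labels come from pooled-variance pairwise t tests on the
residual degrees of freedom (equivalent to re-levelling the model
intercept), merged transitively into numbered clusters ordered by group
mean.

`loglog_fit()` regresses log CH4 production on log phenol index and
returns slope/intercept with 95 % CIs and a mean-prediction band.
Zero-production or zero-phenol samples (the un-amended controls) are not
log-transformable and must be excluded — the relationship is defined
across amended sediments. Natural logs are used internally; the slope is
base-invariant. Simulation tests confirm ~95 % CI coverage of the slope at
n = 36 over 1000 replicates.

## Upscaling to the Boreal Shield

For each lake, suitable emergent-macrophyte habitat is capped at 28 % of
surface area; expected coverage is the occurrence probability times that
cap. Seasonal production is the incubation rate (mg m⁻² per 150 d) times
coverage, divided by 0.70 because the incubated 5 cm surficial layer
represents about 70 % of profile production, and reported in kg CH4 and in
CO2 equivalents (1 kg CH4 = 25 kg CO2). `ensemble_change()` propagates two
uncertainty sources per Monte Carlo draw: the rate (Normal with the
treatment mean and SE, truncated at zero) and the climate scenario (uniform
over the GCM × RCP columns). Because one rate multiplies every lake, the
percent change current→future is rate-free and depends only on the
occurrence fields — asserted per draw in the tests. "Lakes likely to be
colonized" has no unique definition, so both an expected count (sum of
probabilities, default) and a threshold count (p > 0.5) are available and
the per-scenario table reports the ensemble minimum percent change rather
than a single composite.

## What the generators emulate — and what they do not

* `gen_incubation()`: logistic cumulative production reaching the
  treatment mean exactly at day 150 (shape configurable; >99 % of the
  asymptote is reached before the final day), between-jar lognormal
  variation with CV 0.25 (the published error bars justify variation but
  not a value; this is a free knob), default treatment means 5.16 / 17.2 /
  2.63 / 7220 mg m⁻² (CTR/CON/DEC/TYP) spanning the printed 2.63–7220
  range with the reported ~400×, ~1400× and ~2800× contrasts, and spike
  multipliers (4, 1, 1, 2) reflecting that the methanogen spike raised
  production only in CTR and TYP. Instrument noise on concentrations is
  not simulated by default, so recovery tests measure the bookkeeping, not
  detector precision.
* `gen_eems()`: five Gaussian fluorophores (σ_ex 15 nm, σ_em 25 nm) at the
  reference peaks; phenol-component scores zero in CTR, lowest-amended in
  TYP, highest in DEC; lognormal per-sample score variation (sdlog 0.4);
  1 % multiplicative intensity noise; CDOM-like exponential absorbance
  tied to DOC for the optional inner-filter path. The tyrosine component's
  treatment pattern is deliberately non-collinear with the tryptophan
  component's so the trilinear model is well-conditioned — real porewater
  offers no such guarantee, which is one reason fits to real samples
  explain less variance than fits to these synthetic cubes. Scatter
  ridges, Raman bands and detector artefacts are not simulated.
* `gen_qpcr()`: exact log-linear Ct model with configurable replicate
  noise; true copy numbers constant across OM levels within treatment so
  the configured fold-deficits (172 CON, 1.33 × 10⁴ DEC vs TYP) are exact
  in truth. Inhibition, plateau effects and pipetting error are not
  modelled.
* `gen_lakes()`: log-normal areas (log10 ~ N(−0.5, 0.8), truncated to
  0.1–1000 km²) putting most mass at small lakes; Beta(0.8, 8) current
  occurrence; future columns are per-lake perturbations rescaled so each
  scenario's area-weighted future/current ratio is exactly the configured
  RCP target (1.73, 2.0, 2.5 for RCP 2.6/4.5/8.5) — chosen to reproduce
  the reported ≥73 % production increase and 1.7–2.5× colonization range
  as generator truth. Real MaxEnt surfaces have spatial structure these
  independent draws lack.

Passing tests on these cubes and tables therefore demonstrate the
*correctness of the computations* under the stated statistical structure,
not the field realism of any particular number.

## Problem sizes and runtime choices

The test suite and the acceptance script run at the scale of the study
design itself: 64 jars × 10 sampling events, 32-sample EEM cubes
(32 × 41 × 151), 7-point standard curves with 12 unknowns, 400–500 lakes ×
15 scenarios, 200–1000 Monte Carlo draws, and 1000-replicate coverage
simulations. A full 5-component fit with 10 starts takes tens of seconds;
unit tests use smaller coarse-grid cubes with well-separated components so
that properties (monotone objective, equivariance, split-half behaviour)
are exercised quickly.

## Known limitations

* Jar-level field measurements are not bundled, so published real-data F
  statistics cannot be re-derived here; the package checks the design
  structure (degrees of freedom, group separation) and statistical
  properties on synthetic data instead.
* The upscaling consumes a lake table; extracting areas and occurrence
  probabilities from GLWD and MaxEnt rasters is out of scope, as are
  aerenchyma transport, temperature response, sulfate dynamics and
  litterfall shifts.
* FT-ICR-MS confirmation of the phenol component and 16S/dsrA community
  analyses are outside the pipeline.
* The phenol index is relative (proportional fluorescence × DOC), not an
  absolute phenol concentration.
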