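# sedimeth

Litter phenols and methane production in lake sediments.

Littoral sediments dominate freshwater CH4 emissions, and the kind of plant
litter they receive controls how much methane they make: water-soluble
phenols leached from decomposing forest litter suppress methanogens, while
emergent-macrophyte litter (*Typha latifolia*) leaves methanogenesis
largely unimpeded. `sedimeth` implements the quantitative chain behind that
argument as a reusable, tested R pipeline for anaerobic jar-incubation
studies:

* **Gas-flux accounting** — cumulative CH4/CO2 production per jar from
  periodic headspace measurements, correcting for the N2 injected and the
  sample withdrawn at every event:
  `total = final headspace mass + Σ removed portions`, reported per m² of
  sediment over the 150-day season.
* **EEM / PARAFAC** — inner-filter correction (`I · 10^((A_ex+A_em)/2)`),
  a nonnegative trilinear decomposition
  `X[i,j,k] ≈ Σ_f a_if b_jf c_kf` fitted by multi-start alternating least
  squares with split-half validation, component labelling against
  reference fluorophores (humic-like 310/414 and 345/462 nm, tryptophan
  280/354, tyrosine 270/306, phenol-leachate 275/318), and a relative
  phenol index (proportional phenol fluorescence × DOC).
* **qPCR** — standard-curve fitting (`Ct = b0 + b1 · log10 copies`,
  efficiency `10^(−1/b1) − 1`), copies per g dry sediment, and geometric
  treatment fold-differences of the mcrA methanogen marker.
* **Statistics** — the 8-cell amendment × spike ANOVA with transitive
  group labelling, and the log–log regression of CH4 production on the
  phenol index with a 95 % confidence band.
* **Upscaling** — Boreal-Shield-wide CH4 projection:
  `kg CH4 = rate × p_occ × 0.28 × area / 0.70`, CO2 equivalents
  (1 kg CH4 = 25 kg CO2), and Monte Carlo propagation of rate and
  climate-ensemble (5 GCMs × 3 RCPs) uncertainty.
* **Synthetic data** — seeded generators for every input (headspace
  series, EEM cubes, qPCR plates, lake scenario tables) with stored
  truths, so the whole pipeline runs and is testable offline.

See `vignettes/phenol-methane-pipeline.Rmd` for the models, assumptions
and design choices.

## Worked example

```r
library(sedimeth)
cfg <- synth_config(seed = 1)

## 1. incubation -> per-jar production -> treatment summary
inc  <- gen_incubation(cfg)
est  <- cumulative_production(inc$headspace)
summ <- summarize_treatments(est)
subset(summ, om_pct == 20 & gas == "CH4" & !spike)
#>  treatment om_pct spike gas n mean_rate_mg_m2 se_rate_mg_m2
#>        CON     20 FALSE CH4 4          16.816        2.1424
#>        CTR     20 FALSE CH4 4           5.983        0.6401
#>        DEC     20 FALSE CH4 4           3.225        0.4864
#>        TYP     20 FALSE CH4 4        8164.625      742.6568
```

Macrophyte-amended sediments (TYP) produce three orders of magnitude more
CH4 than forest-litter treatments, mirroring the configured treatment
means (5.16 / 17.2 / 2.63 / 7220 mg m⁻² for CTR/CON/DEC/TYP) with
between-jar variation.

```r
## 2. porewater EEMs -> PARAFAC -> phenol index
cube <- gen_eems(cfg)                  # 32 samples, 1% noise
fit  <- fit_parafac(cube, ncomp = 5)   # ~20 s (10 starts)
fit
#> parafac_model: 5 components, 99.9904% variance explained
#>   converged after 1006 iterations (best of 10 starts)
#>   peaks (ex/em nm):  310/414, 345/462, 280/354, 270/306, 275/320
match_components(fit)
#>   component label       kind congruence ex_peak_fit em_peak_fit
#> 1         1    C1      humic  0.9999991         310         414
#> 2         2    C2      humic  0.9999997         345         462
#> 3         3    C3 tryptophan  0.9999603         280         354
#> 4         4    C4   tyrosine  0.9999977         270         306
#> 5         5    C5     phenol  0.9998315         275         320
idx <- phenol_index(fit, cube)         # proportion x DOC, per sample
```

All five fluorophores are recovered with congruence > 0.999; the
phenol-leachate component's emission maximum lands within one 2-nm grid
step of its true 318 nm.

```r
## 3. qPCR -> treatment fold-deficits of mcrA copies
pl    <- gen_qpcr(cfg)
std   <- subset(pl, well_type == "standard")
curve <- fit_standard_curve(std$true_copies, std$ct)
curve
#> standard_curve: Ct = 38.000 -3.3910 * log10(copies)
#>   R^2 = 1.0000, efficiency = 97.2%, range 10^1.0-10^7.0 copies
quant <- quantify_copies(curve, subset(pl, well_type == "unknown"))
fold_table(quant, reference = "TYP")
#>  treatment n_levels fold_vs_ref deficit log10_fold_se
#>        CON        3   6.384e-03   156.6       0.01632
#>        CTR        3   1.083e-03   923.0       0.01617
#>        DEC        3   8.158e-05 12258.3       0.03651
#>        TYP        3   1.000e+00     1.0       0.00000
```

The recovered deficits (157× CON, 1.23 × 10⁴× DEC, from Ct noise 0.2)
track the generator's true fold-deficits of 172 and 1.33 × 10⁴.

```r
## 4. amendment x spike ANOVA at 20% OM
anova_amendment_spike(est, om_level = 20)
#> anova_result: F(7, 24) = 1171.43, p = <2e-16 [log scale]
#>       group n     mean label
#> 1 TYP+spike 4 9.492397     1
#> 2       TYP 4 8.993811     2
#> 3 CON+spike 4 2.802937     3
#> 4       CON 4 2.797137     3
#> 5 CTR+spike 4 2.748698     3
#> 6       CTR 4 1.770129     4
#> 7       DEC 4 1.139425     5
#> 8 DEC+spike 4 1.022793     5
```

The design yields the expected (7, 24) degrees of freedom; spiking
separates TYP and CTR cells but not the phenol-suppressed CON/DEC cells.

```r
## 5. upscale to the Boreal Shield
lakes <- gen_lakes(cfg)
res   <- ensemble_change(lakes, upscale_params(), n_mc = 1000, seed = 1)
res
#> upscale_result: 15 lakes scenarios x 1000 draws
#>   current total: 2.41e+05 kg CH4 (6.04e+06 kg CO2-eq) at the mean rate
#>   pct change: median 100.0% [73.0, 150.0], ensemble minimum 73.0%
#>   colonized lakes (expected mode): 47.3 current
```

Even the most conservative scenario of the ensemble raises seasonal CH4
production by 73 %; the median across the GCM × RCP ensemble is ~100 %.

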