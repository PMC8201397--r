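# uavfield

Integrating dense UAV imagery with sparse hand-harvested samples in
agricultural field trials.

Field experiments measure treatments against a backdrop of smooth
fertility gradients and row/plot heterogeneity, with sample sizes
limited by the cost of hand harvesting. A UAV survey produces per-pixel
canopy indices — vegetation cover fraction, canopy height, NDVI — over
the whole field. `uavfield` turns the two into one analysis, for
agronomists and field ecologists running plot trials:

1. **Model development.** At each harvested 1-m² quadrat, per-index
   pixel means are regressed on the measured trait. Every subset of the
   m candidate indices is fitted by Gaussian identity-link least
   squares,

   ŷ_p = β₀ + Σ_{i∈S} β_i x_{i,p},

   and scored by AIC = −2ℓ + 2k with the full Gaussian log-likelihood
   ℓ = −(n/2)(log 2π + log RSS/n + 1) and k counting intercept, slopes
   and the residual variance (4 predictors ⇒ k = 6). The table carries
   Akaike differences Δᵢ and weights wᵢ = e^(−Δᵢ/2)/Σⱼe^(−Δⱼ/2).
2. **Gridding and prediction.** The best model predicts the trait at
   every pixel; predictions are averaged into 25-cm grid cells
   (ŷ_c = Σ_p ŷ_p / n_c) after eliminating cells that touch two plots
   or mix plot and corridor, so each retained cell maps to exactly one
   treatment.
3. **Statistical testing.** Cell predictions are analysed with a linear
   mixed model with nested random intercepts,
   y = Xβ + a_row + b_plot(row) + ε, likelihood-ratio tests (ML),
   Wald-z contrasts against the lowest-mean cultivar, and
   marginal-effect surfaces for plot traits and their pairwise
   interactions. The plot intercept is what prevents pseudo-replication
   from thousands of correlated cells.

A first-class synthetic-field generator (`generate_experiment()`)
produces layouts, index rasters, harvest samples and ground truth from
one seed, so the whole chain is testable without field data; a
file-based pipeline (`run_step()` / `run_pipeline()`, plus the
`inst/cli/uavfield-cli.R` wrapper) ties the stages together with
manifests and config hashes for byte-reproducible reruns.

## Worked example

```r
library(uavfield)
exp <- generate_experiment(synthetic_config(random_seed = 7L))
res <- analyze_experiment(exp)      # extract -> select -> predict -> grid
res$selection
```

```
All-subsets Gaussian model selection: ear_dry_weight_g ~ 7 candidates (128 models, n = 32)
Top of the selection table:
 rank                                                           spec r_squared df   aic delta_aic  weight
    1          C_Feb.15+C_Mar.14+C_Apr.12+H_Mar.14+H_Apr.12+N_Apr.12    0.9176  8 284.8     0.000 0.40806
    2 C_Feb.15+C_Mar.14+C_Apr.12+H_Mar.14+H_Apr.12+N_Mar.14+N_Apr.12    0.9186  9 286.4     1.597 0.18360
    3                   C_Mar.14+C_Apr.12+H_Mar.14+H_Apr.12+N_Apr.12    0.9052  7 287.3     2.463 0.11909
    4                   C_Feb.15+C_Mar.14+C_Apr.12+H_Mar.14+N_Apr.12    0.9037  7 287.8     2.981 0.09194
    5                            C_Mar.14+C_Apr.12+H_Mar.14+N_Apr.12    0.8961  6 288.2     3.413 0.07406
```

Layer names encode index kind and survey date (`C` cover, `H` height,
`N` NDVI). The generating subset here is
`C_Mar.14 + H_Mar.14 + C_Apr.12 + N_Apr.12`; at this deliberately small
sample (n = 32 quadrats) AIC keeps two spurious indices — the ranked
table, not just the winner, is the honest output. `df` is the parameter
count (rank-1 model: 6 predictors + intercept + residual variance = 8),
and `weight` the model's share of e^(−Δ/2) mass over all 128 models.

```r
res$summary                         # per-plot predicted IQR vs manual value
```

```
Manual value outside the predicted IQR in 25.0% of plots (5 of 20)
  below q25: 2, above q75: 3
```

```r
cultivar_analysis(res$observations) # LMM on 2,816 retained cells
```

```
Cultivar effects on predicted cell yields
  LRT cultivar: chisq = 9.51, df = 4, p = 0.04964
  LRT sowing date: chisq = 3.15, df = 1, p = 0.07597
  reference (lowest marginal mean): v01
  contrasts vs reference (Wald z, uncorrected):
 cultivar estimate    se     z p.value signif
      v02    88.17 35.71 2.469 0.01354      *
      v03    71.59 36.26 1.974 0.04836      *
      v04    84.28 37.87 2.226 0.02605      *
      v05    90.41 37.87 2.387 0.01698      *
```

The chi-square LRT (df = 4, one per non-reference cultivar) tests the
cultivar term as a whole; contrasts are differences from the
estimated-lowest cultivar in yield units (g per quadrat-equivalent).
With only 4 plots per cultivar the contrast SEs (~36 g) are honest
about how little a 20-plot trial can resolve — the detection-scale
preset (`synthetic_config_detection_preset()`, 80 plots) is the one
sized for power studies.

See `vignettes/uav-field-analysis.Rmd` for the model conventions
(AIC parameter counting, degenerate exact fits, cell elimination rules,
quantile definition, simulation design sizes) and the generator's
assumptions and limits.

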