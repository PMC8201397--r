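---
title: "Predicting and testing field-trial traits from UAV imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting and testing field-trial traits from UAV imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

Field experiments on crops suffer from two chronic limitations: hand
harvesting is so expensive that sample sizes stay small, and fields carry
smooth fertility gradients plus row- and plot-level heterogeneity that
inflate error variance. UAV surveys invert the economics — they produce
dense per-pixel canopy descriptors (vegetation cover, canopy height,
NDVI) across the whole field for a few flight hours — but those
descriptors are not the trait of interest. `uavfield` implements the
bridge in three stages:

1. **Model development.** At each harvested quadrat, the per-index pixel
   means are regressed against the measured trait (here: wheat ear dry
   weight, g per 1-m² quadrat) with an exhaustive all-subsets Gaussian
   identity-link search scored by AIC.
2. **Gridding and prediction.** The winning model is applied per pixel
   over the field; predictions are averaged into 25-cm grid cells after
   eliminating cells that mix treatments (two plots) or mix plot and
   corridor.
3. **Statistical testing.** The dense cell-level predictions are
   analysed with a linear mixed model carrying nested random intercepts
   (field row, and plot within row), likelihood-ratio tests,
   reference-cultivar contrasts, and marginal-effect surfaces for plot
   traits.

The payoff of stage 3 is statistical: thousands of spatially indexed
predictions replace a few dozen quadrats, and the random-effect
structure absorbs the field's systematic error instead of leaving it in
the residual.

## The prediction model and its selection

For quadrat (or pixel) $p$ with index values $x_{1,p},\dots,x_{m,p}$,

$$\hat y_p = \beta_0 + \sum_{i \in S} \beta_i x_{i,p},$$

fitted by least squares for every subset $S$ of the $m$ candidates
($2^m$ models, intercept-only included). Models are scored with the full
Gaussian log-likelihood,

$$\ell = -\tfrac{n}{2}\left(\log 2\pi + \log \mathrm{RSS}/n + 1\right),
\qquad \mathrm{AIC} = -2\ell + 2k,$$

where $k$ counts the intercept, the slopes **and the residual
variance** — so a 4-predictor model has $k = 6$. This convention is
deliberate: it is the one under which the degrees-of-freedom column of a
selection table lists 6 for a 4-index model, and it matches `logLik()`
on a Gaussian `glm`. Akaike differences $\Delta_i$ and weights
$w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$ are attached; weights
are normalized over the enumerated set, so absolute weights depend on
that set while the ratios $w_i/w_j$ do not.

Numerical corner cases are handled explicitly:

* An exact fit (RSS numerically zero, i.e. below
  $\max(10^{-10}\,\mathrm{TSS}, 10^{-12})$) has unbounded likelihood.
  Such fits are flagged *degenerate*; `model_aic()` refuses them, and
  `rank_models()` places them ahead of all scored fits, breaking ties by
  smaller $k$ then lexicographic spec. The smaller-$k$ tie-break is what
  makes noiseless recovery exact: the true subset and all its supersets
  reach RSS = 0, and the true subset is the smallest of them.
* Rank-deficient subsets (e.g. containing a constant index layer) are
  dropped from the ranking and reported, not silently scored.
* AIC ties between scored fits break toward fewer parameters, then
  lexicographic spec, so ranking is deterministic.

## Imagery operations

The candidate layers come from three primitive operations on
co-registered rasters: reflectance calibration against a panel of known
reflectance photographed before and after each flight (gain
$g = r_\mathrm{known} / \overline{r}_\mathrm{observed}$, output clipped
to $[0,1]$); $\mathrm{NDVI} = (\mathrm{NIR} - \mathrm{Red}) /
(\mathrm{NIR} + \mathrm{Red})$; canopy height as
$\max(\mathrm{DSM} - \mathrm{ground}, 0)$ (negative differences are
sensor noise, clamped rather than masked); and vegetation cover by
excess-green thresholding, $\mathrm{ExG} = 2G - R - B$, with the
threshold either fixed at 0 or chosen by a bimodal histogram split
(Otsu's criterion on 256 bins). Cover is a per-pixel 0/1 layer whose
quadrat or cell mean is the cover *fraction*. The segmentation criterion
is a pluggable choice — the published description of cover area does not
pin one down, and ExG at $t = 0$ is the simplest defensible default for
RGB orthomosaics.

Masks are monotone through every operation: a masked input pixel can
never become an unmasked output pixel.

All geometry lives in a local projected Cartesian frame in meters.
There is deliberately no support for geographic coordinates or
re-projection; inputs must arrive pre-projected. Rasters are exchanged
as plain-text ESRI ASCII grids (with optional TIFF + world-file
export), layouts and sample points as GeoJSON with a `crs_note` member.

## Gridding rules

The grid is anchored at the field bounding box's minimum corner with
half-open square cells $[x, x+s) \times [y, y+s)$, $s = 0.25$ m by
default (about one wheat plant's footprint). Classification is strict:

* a cell intersecting two or more plot polygons is eliminated
  (`eliminated_two_plots`) — it would mix treatments;
* a cell intersecting exactly one plot but not fully contained in it is
  eliminated (`eliminated_corridor_mix`) — it would mix plot and
  corridor soil;
* a cell fully inside exactly one plot is retained and owns that plot's
  treatment metadata;
* all other cells are outside.

Because plot dimensions (2.4 m × 4.2 m) are not integer multiples of
0.25 m, plot-edge cells are removed by the containment rule rather than
by snapping plots to the grid; a 2.4 × 4.2 plot therefore retains
between 120 and 144 cells depending on its phase relative to the grid.
Pixel membership in cells and quadrats is by pixel center with the same
half-open convention, which prevents double counting; intersection
tests carry a $10^{-9}$ m tolerance so exactly touching rectangles do
not register as overlapping.

Cell aggregation is a plain average of unmasked pixel predictions,
$\hat y_{c} = \sum_{p \in c} \hat y_p / n_c$, which conserves the
retained-pixel total $\sum_c \hat y_c n_c$ exactly up to floating-point
rounding (the test suite checks relative agreement to $10^{-9}$; the
sums are of order $10^7$ g, where an absolute $10^{-9}$ tolerance would
be below double-precision rounding of the summation itself).

Per-plot comparison of predicted distributions against the manual
sample uses the linear-interpolation quantile definition
(`stats::quantile` type 7) — the published box plots do not state their
quartile rule, so the common statistical default is used — and flags a
plot when the manual value falls outside $[q_{25}, q_{75}]$.

## Mixed-model inference

"Gaussian GLMM with identity link" is a linear mixed model, and it is
fitted as one (via `lme4`): for cell $i$ in plot $j$ nested in row $r$,

$$y_{ijr} = \mathbf{x}_{ij}^\top\boldsymbol\beta + a_r + b_{jr} +
\varepsilon_{ijr}, \qquad a_r \sim N(0, \sigma^2_\mathrm{row}),\;
b_{jr} \sim N(0, \sigma^2_\mathrm{plot}),\;
\varepsilon \sim N(0, \sigma^2_e).$$

The plot intercept is what prevents pseudo-replication: cells of one
plot share $b_{jr}$, so the effective replication for treatment
contrasts is the number of plots, not the number of cells. The package
exposes `include_plot = FALSE` solely so users can reproduce the
inflation this causes (the type-I error of the cultivar test roughly
decuples in the packaged simulation).

Conventions, all of which are standard practice and configurable where
sensible:

* Likelihood-ratio tests compare ML fits (REML likelihoods are not
  comparable across fixed structures); reported coefficient tables use
  REML. The LRT statistic is clamped at 0 and referred to
  $\chi^2_{\Delta\#\text{coef}}$.
* The cultivar analysis fits `yield ~ sowing_date + cultivar`, runs
  LRTs for both terms, then re-levels the cultivar factor so the level
  with the lowest estimated marginal mean (predictions averaged over
  sowing dates with equal weight, random effects at zero) is the
  reference, and reports Wald $z$ contrasts of every other level
  against it, uncorrected (`*` $p<0.05$, `**` $p<0.01$). No
  multiple-testing correction is applied by default because the
  asterisk convention being mirrored is raw; `stats::p.adjust` composes
  trivially if wanted.
* Sowing date enters as a two-level factor.
* The trait analysis fits the four plot-level soybean traits (stem,
  seed, above-ground dry weight, 100-seed weight) and all six pairwise
  interactions — 11 coefficients with the intercept — and tests each
  term by single-term deletion under ML. Marginal-effect surfaces
  evaluate the fixed part on a focal × moderator grid with other
  covariates at their data means and random effects at zero; with an
  interaction present the focal slope at moderator value $m$ is
  $\beta_f + \beta_{f:m} m$.
* Denominator-degree-of-freedom corrections (Satterthwaite,
  Kenward-Roger) are intentionally out of scope; the chi-square
  reference is accurate when plot replication is adequate, and the
  packaged simulation designs are sized accordingly (see below).

## The synthetic field generator

No public dataset accompanies the study design this package serves, so
the generator is first-class, tested code with known ground truth. Its
latent yield surface at a pixel is

$$y = \mu + T(x, y) + a_{\mathrm{row}} + b_{\mathrm{plot}} +
\text{treatment} + \text{trait terms} + \varepsilon_{\mathrm{pixel}},$$

with $T$ a sum of a linear gradient and a fixed-wavelength (12.5 m)
sinusoid — smooth, reproducible, parameter-light systematic error — and
row/plot effects drawn from independent child streams of one root seed,
so adding a generation stage never perturbs earlier stages.

The candidate index layers are constructed so that the latent surface
is *exactly* linear in the true-subset indices: each true index carries
an equal share of the design surface scaled by the inverse of its true
coefficient, plus an index-specific smooth pattern that keeps the true
indices from being collinear, plus per-pixel noise. Decoy candidates
are pure noise. Consequences worth knowing:

* With all noise and random-effect parameters at zero
  (`synthetic_config_noiseless()`), sample observations equal quadrat
  means of the deterministic latent surface, model selection returns
  exactly the true subset (decoys become constant layers, so subsets
  containing them are rank-deficient and are dropped), and pixel
  prediction error is zero to floating point.
* Trait tables draw the four soybean traits per plot around
  cultivar-specific means with above-ground weight built as
  stem + seed + residual biomass, so `above_dw >= stem_dw` holds by
  construction; trait effects act on centered traits (and centered
  products for interactions), so a trait spec never shifts the field
  mean.
* Harvest samples are quadrat means of the latent surface plus
  measurement noise, at one point per plot plus a configurable number
  of points placed in the corridor/adjacent area by seeded rejection
  sampling.

Default scales: the default configuration is a quarter-scale trial
(20 m × 25 m, 20 plots, 0.0625-m pixels) that keeps a full pipeline run
under two seconds; `synthetic_config_field_preset()` reproduces the
full trial geometry (40 m × 50 m, 70 plots of 2.4 m × 4.2 m in 7 rows,
14 cultivars on 56 plots plus weedy/sheet/destructive plots, 154 sample
points of 1 m²). Yield magnitudes (mean 500 g per quadrat, trend
amplitude 40 g, row/plot SDs 10 g, sample noise 25 g) are round numbers
of the order a winter-wheat quadrat harvest produces; no published
variance figures exist for the emulated field, so parameter *recovery*,
not matching any published $R^2$, is the test target.

**What the generator does not emulate.** Indices are statistical
surrogates linked linearly to yield, not biophysical canopy models;
there is no radiative transfer, no canopy growth curve, no
georeferencing error, no orthomosaic stitching artefacts, and spatial
error beyond the smooth trend + row/plot structure (e.g. short-range
autocorrelated residuals) is absent. Passing tests therefore show the
*pipeline machinery* is correct and calibrated under its stated model;
they do not certify performance on real imagery, where index-trait
relations are nonlinear and residuals are spatially correlated.

## Simulation study sizes

Three packaged studies exercise the inference stage; their sizes are
design choices made once:

* **Parameter recovery and type-I error** use a reduced-scale direct
  cell simulation: 8 rows × 10 plots × 10 cells, 5 cultivars (16 plots
  each). The plot count is kept near the full trial's because the
  chi-square LRT reference needs plot-level replication — at a
  12-plot scale the cultivar LRT rejects a true null ~30% of the time,
  which is a property of the asymptotics, not a code defect. At the
  chosen scale the rejection rate is ≈ 0.06 (2,000-replicate
  estimate), and the same simulation with the plot intercept removed
  rejects at ≈ 0.3–0.5, the pseudo-replication demonstration.
* **End-to-end detection** uses `synthetic_config_detection_preset()`:
  80 plots, 5 cultivars, 0.125-m pixels, per-pixel index noise 0.08 and
  gentle spatial structure. After cell averaging the model's residual
  SD is ≈ 25–30 g while plot-level nuisance stays below it, so an
  elevation of one cultivar by 2 residual SDs (calibrated at run time
  from a null fit, not hard-coded) is comfortably detectable, while
  the all-null preset stays non-significant in ≈ 95% of runs.

## Known limitations

* Axis-aligned rectangular plots only; arbitrary polygons would need a
  point-in-polygon core the current layouts do not require.
* No spatially correlated residual models (kriging, AR errors); the
  random-effect structure is rows + plots only.
* No cross-validation or regularized alternatives to the exhaustive
  AIC search (guarded at 20 candidates).
* The 154 → 143 sample reduction seen in the emulated study has no
  recorded mechanism; it is exposed as an explicit, logged exclusion-id
  list (default empty) rather than a heuristic.
* Quadrat means are midpoint-rule integrals over pixel centers, so for
  smoothly varying surfaces they carry $O(h^2)$ discretization error;
  resolution-invariance of sampling holds exactly only for surfaces
  constant within each quadrat (the form the invariance test uses).
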