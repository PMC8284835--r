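# seedscape

Multi-scale landscape analysis of tree-seedling diversity in fragmented
landscapes.

Forest patches embedded in agricultural mosaics retain much of a region's
plant diversity, and the seedling layer decides what those patches will
look like in thirty years. Whether a patch's seedling community is rich or
homogenised depends on the surrounding landscape — how much forest is
left, how aggregated it is, how harsh the matrix at the patch edge is —
and each of those influences acts at its own characteristic distance (the
*scale of effect*). seedscape is for ecologists who sample communities in
plots inside patches and want to ask, rigorously: **which landscape
metrics drive α- and β-diversity, and at which spatial scales?**

## What it computes

**Diversity** in effective numbers of species (Hill numbers). With
$p_{ij}$ the relative abundance of species $i$ in plot $j$ and
$\bar p_i$ its mean over the $N$ plots of a patch:

$$ {}^q\!D_\gamma = \Big(\textstyle\sum_i \bar p_i^{\,q}\Big)^{1/(1-q)},
\qquad
{}^q\!D_\alpha = \Big(\tfrac1N \textstyle\sum_j \sum_i p_{ij}^{\,q}\Big)^{1/(1-q)},
\qquad
{}^q\beta = {}^q\!D_\gamma / {}^q\!D_\alpha \in [1, N], $$

for orders $q = 0, 1, 2$ (all / typical / dominant species), with the
exponential-Shannon forms at $q = 1$, plus Chao–Shen sample coverage per
patch.

**Landscape structure** as six class-level metrics inside 13 circular
buffers (300–1500 m) around each patch centre: old-growth and
secondary-forest cover (FC, SF), patch density (PD), aggregation index
(AI), patch isolation (PI) and a quality-ranked edge-contrast index (EC).

**Scale of effect** per response × metric: 13 single-predictor linear
models scored by the leave-two-out cross-validated
$R^2_{CV} = 1 - \overline{SS}_{cv} / \big(\tfrac1n\sum_i (y_i-\bar y)^2\big)$,
with the selected radius's uncertainty quantified by bootstrap
reselection over patches.

**Multimodel inference**: all subsets of the global model (predictors at
their selected scales, VIF-screened) plus the null, ranked by AICc;
Akaike weights, the 95% confidence set, full model-averaged coefficients
with unconditional standard errors, and per-term importances
($\sum w_i$).

A neutral-landscape + community simulator with a *planted* scale of
effect generates complete synthetic studies (16 patches × ten 1-m² plots
by default), so the whole chain is validated against known ground truth.

## Worked example

Simulate a study in which forest cover measured at 800 m drives
typical-species diversity, then recover that structure:

```r
library(seedscape)

cfg <- simulation_config(seed = 7)   # 16 patches, FC @ 800 m, effect 1.0
study <- make_study(cfg)
#> seedscape_study: 16 patches, 10 plots each; focal FC at 800 m
#> (effect 1.00, noise 0.25), seed 7

blocks <- lapply(study$blocks, filter_animal_dispersed)
div <- diversity_table(blocks)
head(div, 3)
#>   patch_id q    alpha     beta     gamma n_plots
#> 1      P01 0 3.100000 4.838710 15.000000      10
#> 2      P01 1 2.259795 3.494462  7.896769      10
#> 3      P01 2 1.837739 2.993348  5.500993      10
round(mean(coverage_table(blocks)$coverage) * 100, 1)
#> [1] 83.4
```

Patch P01 holds 15 seedling species; its plots average 3.1 species each,
and the patch behaves like ~4.8 completely distinct assemblages at
$q = 0$ — high within-patch turnover. Coverage ≈ 83% says the 10-m²
sample catches most individuals' species. Now the scale analysis:

```r
metrics <- metric_table(study$raster, study$centres)  # 16 x 13 x 6 = 1248 rows
responses <- diversity_responses(div)
rv <- data.frame(patch_id = responses$patch_id, value = log(responses$gamma_q1))

prof <- scale_profile(rv, metrics, "FC", response = "log_gamma_q1")
prof
#> scale_profile log_gamma_q1 ~ FC: scale of effect 800 m (R2_CV = 0.895)

boot <- bootstrap_scale(rv, metrics, "FC", B = 1000, seed = 7)
boot
#> bootstrap_scale: B = 1000, modal radius 800 m, mean 741.50 +/- 116.19 m
```

The cross-validated profile peaks at the planted 800 m radius
($R^2_{CV} = 0.90$), and the bootstrap mode agrees, with ~120 m of
selection uncertainty. Multimodel inference then separates the true
driver from idle predictors:

```r
responses$log_gamma_q1 <- log(responses$gamma_q1)
infer <- run_inference(
  list(log_gamma_q1 = c(FC = prof$selected_radius, SF = 600, PD = 800)),
  responses, metrics)
infer$log_gamma_q1$averaged
#>     term  coefficient        use importance influential
#> 1 FC_800  0.270099234 0.02197701  1.0000000        TRUE
#> 2 SF_600 -0.000207517 0.00215380  0.1232437       FALSE
#> 3 PD_800 -0.064379177 1.08824469  0.1226943       FALSE
```

Forest cover at 800 m carries all the Akaike weight (importance 1.0) and
its averaged coefficient excludes zero; the non-drivers shrink toward
zero and are not influential. `run_pipeline(cfg, out_dir = "...")` runs
this whole chain — simulation or file inputs, diversity, metrics,
diagnostics (Shapiro–Wilk, Clark–Evans, Mantel screens), the full
6-response × 6-predictor sweep (468 models), bootstraps and inference —
and writes every table as CSV.

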