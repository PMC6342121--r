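# sstindex

A taxonomy-free, OTU-based water-quality index for diatom meta-barcoding,
evaluated across OTU clustering resolutions.

## The problem

River bioassessment with benthic diatoms traditionally scores a sample as
an abundance-weighted average of species' ecological values — which
requires identifying species. Meta-barcoding replaces microscopy with
amplicon sequencing, but a large fraction of the resulting operational
taxonomic units (OTUs) cannot be assigned a name against incomplete
reference libraries, and the sequence similarity threshold (SST) used to
cluster reads into OTUs is an arbitrary knob whose effect on the final
index is rarely measured.

`sstindex` implements and evaluates an index that skips taxonomy
entirely. A reference pressure gradient is built as the first principal
component (PC1) of ten log-transformed water-chemistry variables
(turbidity, TSS, DOC, TOC, TN, TP, NO2, NO3, PO4, NH4), oriented from
high to poor quality. Each OTU *j* gets an ecological **optimum** and
**tolerance** by weighted averaging of its relative abundances
*a<sub>ij</sub>* along the gradient scores *x<sub>i</sub>*:

```
s_j = Σ_i a_ij x_i / Σ_i a_ij        v_j = max(v_floor, sqrt(Σ_i a_ij (x_i − s_j)² / Σ_i a_ij))
```

and a sample is scored with the adapted Zelinka–Marvan weighted average
over the OTUs it shares with the profile database:

```
Idx = Σ_j a_j s_j w_j / Σ_j a_j w_j ,   w_j = 1/v_j  (default dialect)  or  w_j = v_j
```

The evaluation engine sweeps the SST grid (80–99%) with repeated
stratified 75/25 train/test randomizations (profiles from training
samples only, index scored on held-out samples) and reports three
performance surfaces per SST: fit to the gradient (R² of test index vs
PC1), discrimination power (SD of index values within a randomization),
and stability (SD of the discrimination across randomizations). A
synthetic community generator — Gaussian niche responses on a latent
pollution gradient, lognormal abundances with many rare taxa, multinomial
read sampling, and an ultrametric merge tree emulating SST coarsening
with tunable phylogenetic niche signal — provides ground truth for every
stage.

## Worked example

```r
library(sstindex)

sc  <- otu_scenario(n_samples = 36, n_species = 120, depth = 5000, seed = 42)
sim <- simulate_dataset(sc, sst_grid = c(80, 85, 90, 95, 99))

pg <- compute_gradient(log_transform(sim$chemistry))
glance(pg)
#> # A tibble: 1 × 4
#>   n_samples n_variables var_explained flipped
#>       <int>       <int>         <dbl> <lgl>
#> 1        36          10         0.760 FALSE

tabs   <- lapply(sim$tables, \(t) filter_rare(to_relative(t))$table)
splits <- make_splits(pg$scores, reps = 20, seed = 43)
sw     <- run_sweep(tabs, pg, splits)
sw$summary
#> # A tibble: 5 × 6
#>     sst n_valid mean_r2 median_r2 discrimination stability_sd
#>   <dbl>   <int>   <dbl>     <dbl>          <dbl>        <dbl>
#> 1    80      20   0.776     0.804          0.124       0.0688
#> 2    85      20   0.773     0.784          0.215       0.0400
#> 3    90      20   0.813     0.807          1.37        0.157
#> 4    95      20   0.967     0.967          2.19        0.204
#> 5    99      20   0.968     0.970          2.32        0.241

compare_sst_groups(sw, low = c(80, 85), high = c(90, 99))
#> # A tibble: 1 × 8
#>   mean_low mean_high n_low n_high     t    df       p_value zero_variance
#>      <dbl>     <dbl> <int>  <int> <dbl> <dbl>         <dbl> <lgl>
#> 1    0.774     0.916    40     60 -6.61    98 0.00000000200 FALSE
```

Reading the output: PC1 captures 76% of the chemistry variance and is the
reference quality scale. Moving from coarse (SST 80) to fine (SST 99)
clustering, the test-set fit to the gradient rises (mean R² 0.78 → 0.97),
the index separates samples more sharply (discrimination 0.12 → 2.3), but
it becomes less reproducible across train/test draws (stability SD
0.069 → 0.24) — the resolution trade-off the package is built to expose.
The group comparison confirms the fit difference between the low- and
high-SST ranges (pooled t, p ≈ 2e-9).

Plot helpers: `autoplot(sw)` (R² boxplots per SST), `plot_tradeoff(sw)`
(normalized discrimination/stability curves), `plot_sample_stability(sw)`
(per-sample SD heat map). `run_pipeline(config)` orchestrates the whole
procedure from a config list or YAML file and writes all result tables
plus a reproducibility manifest.

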