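# coversad

Analysis tools for gridded **point-intercept vegetation surveys** —
the 1 ha, 10-transect × 101-point design used for standardised
rangelands monitoring — aimed at one ecological question: *do species
relative-abundance patterns vary predictably along rainfall
gradients?*

The package is for community ecologists and monitoring programs who
have (or want to simulate) point-intercept data and need the full
chain from raw intercept records to gradient inference:

1. **Cover metrics** — per-species Foliage Projective Cover
   (FPC = 100 × points with a direct hit / 1010, excluding
   within-canopy sky), Opaque Canopy Cover (sky gaps counted toward
   the canopy species), fractional cover, and plot × species cover
   matrices with explicit zeros.
2. **Sampling diagnostics** — rarefied species-accumulation curves
   (random permutations of the point set) and cumulative cover
   trajectories in field (zigzag) collection order.
3. **Diversity** — point-intercept vs voucher richness, Shannon H′
   (nats), and the Gini–Simpson index 1 − Σpᵢ².
4. **Species abundance distributions** — per-plot maximum-likelihood
   fits of the Pareto (power-law) model, α̂ = n / Σ ln(xᵢ/xmin), and
   the lognormal (μ̂, σ̂), compared by AIC (k = 1 vs 2), with
   rank-abundance (Whittaker plot) prediction from fitted quantiles.
   Plots with fewer than six species are excluded.
5. **Gradient regression** — per vegetation group, robust Huber
   M-estimation (IRLS, c = 1.345, MAD scale) of SAD shape on mean
   annual precipitation (MAP), weighted R²_WLS from the final robust
   weights, and 90% percentile bootstrap CIs from 1000 pairs
   resamples; slopes are flagged robust when the CI excludes zero.
6. **A synthetic survey generator** — full forward model of the
   instrument (multi-layer hits, canopy sky records, substrates,
   vouchers) on a landscape whose Pareto shape follows a known linear
   MAP link, so every stage can be validated against ground truth.

## Worked example

Simulate a two-group landscape (grasslands carry a −4×10⁻⁴ α–MAP
link, woodlands none) and run the whole pipeline:

```r
library(coversad)

sim <- simulate_landscape(landscape_config(
  n_plots_per_group = 20,
  groups = c("Tussock Grasslands", "Eucalypt Woodlands"),
  seed = 2026))

res <- run_pipeline(sim$hits, sim$sites, sim$vouchers,
                    n_boot = 1000, seed = 1)
res
#> Survey pipeline result: 40 plot-visits, 537 species, 40 SAD fits (0 excluded)
#>                group        response n_obs         slope ...       r2_wls
#> 1 Eucalypt Woodlands    pareto_alpha    20  2.153704e-05     0.0008724889
#> 2 Eucalypt Woodlands lognormal_sigma    20  9.639767e-05     0.0191034813
#> 3 Tussock Grasslands    pareto_alpha    20 -2.782602e-04     0.2361936738
#> 4 Tussock Grasslands lognormal_sigma    20  4.231827e-04     0.2398059433
#> 5           Combined    pareto_alpha    40 -1.675815e-04     0.0746179719
#> 6           Combined lognormal_sigma    40  2.499892e-04     0.1076270256
#>        ci_lower      ci_upper ci_excludes_zero
#> 1 -1.832425e-04  4.244568e-04            FALSE
#> 3 -5.658554e-04 -9.097035e-05             TRUE
#> ...
```

Reading the gradient table: in the grassland group the Pareto shape
declines with rainfall (slope −2.8×10⁻⁴ per mm, bootstrap 90% CI
entirely below zero — a robust link), while the woodland slope is
near zero with a CI straddling it; the lognormal σ moves in the
opposite direction, as expected for a spread parameter. The per-plot
products look like:

```r
head(res$diversity, 3)
#>    plot_id visit_id richness_pi richness_voucher shannon simpson
#> 1 PLOT0001       V1          18               36    2.22   0.855
#> 2 PLOT0002       V1          19               38    2.39   0.873
#> 3 PLOT0003       V1          15               36    1.37   0.612

head(res$sad_fits[, c("plot_id", "n_species", "pareto_alpha",
                      "lognormal_sigma", "best_model")], 3)
#>    plot_id n_species pareto_alpha lognormal_sigma best_model
#> 1 PLOT0001        18        0.352            1.39  lognormal
#> 2 PLOT0002        19        0.684            1.12     pareto
#> 3 PLOT0003        15        0.631            1.71     pareto
```

`run_pipeline(..., out_dir = "out")` additionally writes every product
as CSV (site-by-species flat file, diversity table, fit and exclusion
tables, the gradient table with ×10⁻⁴ display columns) plus JSON
schema sidecars and a run log. A thin command-line front-end over the
same functions is in `inst/scripts/coversad-cli.R`.

Note that recovered slope magnitudes sit below the generating
−4×10⁻⁴: estimating α from 1010 binomially-sampled, quantised
intercepts attenuates the latent gradient (regression dilution). The
methods vignette (`vignettes/point-intercept-sad-gradients.Rmd`)
quantifies this instrument property.

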