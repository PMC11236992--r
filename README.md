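# thermoshift

Quantify **thermophilization** — the directional shift of tree communities
towards species affiliated with warmer climates — from repeated forest
inventory censuses, occurrence records and a gridded climatology.

The package is aimed at ecologists working with permanent-plot networks
(montane transects in particular) who need the full measurement chain in
one tested place:

- **Species climate optima.** Clean Darwin-Core-style occurrence tables
  (provider flags, year cutoff, nodata/water cells), deduplicate to one
  record per species per ~30 arc-second grid cell, and estimate each
  species' thermal optimum as the mean of mean annual temperature (MAT) at
  its locations, with niche breadth (95th − 5th MAT percentile) and
  subsampling curves of optimum error versus record count.
- **Community indices.** The community temperature index
  `CTI = Σ w_i T_opt(s(i)) / Σ w_i` over live stems, stem-weighted
  (`CTI_Stem`) or basal-area-weighted (`CTI_BA`); the same machinery for
  precipitation (CPI) or wood density. Annual rates of change from
  endpoint censuses, plus per-interval changes.
- **Demographic partition.** An exactly additive decomposition of index
  change into mortality, growth (basal-area weighting) and recruitment
  from the Alive_F / Alive_L / Survive_F / Survive_L stem sets, and
  jackknife per-species contributions to the cross-plot trend.
- **Carbon dynamics.** Plot-level Weibull / log-log height-diameter
  models, taxonomic-fallback wood-density matching, the pantropical
  allometry `AGB = 0.0673 (ρ D² H)^0.976` with AGC = 45.6% of AGB, and
  census-interval-corrected gain/loss fluxes whose ledger identity
  (net = gains − losses) holds exactly.
- **Inference.** One-sample Wilcoxon signed-rank tests on per-plot rates,
  percentile bootstrap CIs, Spearman and Kruskal-Wallis tests, OLS climate
  trends and the cross-sectional CTI-on-MAT regression with a climatic-lag
  flag.
- **Synthetic data.** A stem-level demographic simulator with known
  thermal recruitment/mortality biases, Gaussian species niches, synthetic
  occurrence clouds and deterministic climate grids, so the entire
  pipeline is validated by parameter recovery — no downloads needed.

## Worked example

```r
library(thermoshift)

res <- run_pipeline(list(seed = 1), out_dir = "run1")
#> simulate: 17 plots, 30153 stem records, 5400 occurrence records
#> optima: 60 species scored, 60 included at threshold 10
#> cti: 34 plot x weighting trajectories
#> carbon: 17 plot ledgers
#> report: mean dCTI_stem +0.00487 C/y (V = 138, p = 0.00209)
```

The report says the simulated 17-plot network warmed compositionally at
+0.0049 °C y⁻¹ in the stem-weighted index, significantly different from
zero (Wilcoxon V = 138, p = 0.002, bootstrap 95% CI 0.0026–0.0074), with
the partition attributing +0.0031 °C y⁻¹ to recruitment and
+0.0018 °C y⁻¹ to mortality, and the plots acting as a carbon sink
(net +0.75 Mg C ha⁻¹ y⁻¹ = growth 2.00 + recruitment 0.29 − mortality
1.54). `run1/` holds the per-plot tables (`trajectory.csv`,
`partition.csv`, `carbon_ledger.csv`, `affiliations.csv`), `report.json`
and `manifest.json`.

Individual stages are plain functions — e.g.

```r
aff <- build_affiliation_table(occ, mat_grid, map_grid, threshold = 10)
tr  <- index_trajectory(series, aff, weighting = "stem")
pr  <- partition_change(series, aff, weighting = "ba", annualize = TRUE)
led <- carbon_ledger(series, traits)
```

See `vignettes/thermophilization.Rmd` for the model, conventions and
design choices, and the roxygen help pages for every function.

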