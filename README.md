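# melaniche

Phenotype-stratified niche analysis of coat-colour melanism across a
species' range.

Many mammals carry discrete colour polymorphisms — the melanistic "black
panther" form of the leopard is the iconic case — whose geographic structure
bears directly on classical hypotheses of adaptive coloration (Gloger's
rule: darker animals in humid, densely vegetated habitats). Testing whether
a morph occurs randomly across a range or tracks particular habitats takes a
chain of spatial biostatistics, and this package implements that chain
end-to-end for researchers in macroecology and evolutionary biology:

* **Record curation** — validation, camera-trap deduplication within a
  25-km buffer, filtering by record age, exact coordinate duplicates and
  landscape modification (|ΔNDVI| ≥ 0.7), with a count-reconciled report.
* **Biome association** — the full biome × phenotype contingency analysis:
  observed/expected counts, percentage blocks, adjusted standardised
  residuals `(O − E)/√(E(1 − nᵢ./N)(1 − n.ⱼ/N))`, Pearson χ², likelihood
  ratio G, linear-by-linear trend.
* **Spatial randomness** — a Monte Carlo CSR test of each phenotype's point
  pattern against an inhomogeneous null guided by a multivariate kernel
  estimate of sampling effort over the merged 200-km record buffers, using
  the nearest-neighbour G-function.
* **Maximum-entropy niche models** — a from-scratch presence-background
  Maxent: Gibbs distribution over background cells maximising the
  L1-penalised presence log-likelihood, with the classic feature classes,
  regularisation schedules, 70/30 replicate protocol, background AUC and
  permutation variable importance.
* **Niche comparison** — Schoener's D, Hellinger-based I and relative rank
  between suitability maps, a pooled-resampling equivalency null
  (100 × 100 cross comparisons), and a paired suitability t-test.
* **Driver contrasts** — per-variable, per-scale comparisons between
  phenotype models with Bonferroni correction, suitability-vs-driver
  regressions, a barrier moisture-contrast test (600 points split 50/50
  across a barrier within one biome class), and leave-region-out
  robustness refits.
* **Synthetic landscapes** — a generator with known niche structure
  (correlated autocorrelated gradients, biome map, NDVI-change layer,
  phenotype-labelled records) so the whole pipeline is testable offline.

## Worked example

```r
library(melaniche)

cfg   <- synthetic_config(seed = 42)      # the default stated world
truth <- generate_records(cfg)
truth
#> <synthetic_truth> 600 records (melanistic=68, non_melanistic=532)
#>   on a 100 x 100 landscape, 4 biomes

rec <- read_records(truth$records)
fr  <- filter_records(dedup_camera_traps(rec, 25), reference_year = 2013,
                      ndvi_change = truth$ndvi_change,
                      ndvi_grid = truth$env$grid)
fr$report
#> <filter_report> 426 in -> 409 out (age 0, duplicate 0, ndvi 17)

contingency_table(fr$records)
#> <contingency_result> 4 x 2, N = 409
#>   chi-square = 73.255 (dof 3), G = 74.250, linear-by-linear = 55.687
#>         n_non_melanistic n_melanistic E_non_melanistic E_melanistic ...
#> biome_4               84           45            111.3         17.7
#>         ar_non_melanistic ar_melanistic
#> biome_4              -8.5           8.5

phenotype_frequency(fr$records)$frequency_pct
#> [1] 13.69193
```

The melanistic morph concentrates in the wettest biome (adjusted residual
+8.5, far beyond the ±2 significance guide), exactly the structure the
generator was told to produce — dedup collapsed 174 camera-trap repeats and
the NDVI rule removed 17 records on heavily modified cells. Downstream:
`csr_test()` for the spatial-randomness p-value, `run_replicates()` for the
per-phenotype suitability maps and AUCs, `equivalency_test()` for D/I/RR
against the resampled null, `driver_contrast()` / `barrier_contrast()` for
environmental drivers, or `run_pipeline(pipeline_config(synthetic = TRUE,
seed = 7), "out_dir")` for the whole chain with a reproducible manifest.

A thin CLI wraps the pipeline:

```sh
Rscript inst/cli/melaniche.R all --synthetic --seed 7 --out run1
Rscript inst/cli/melaniche.R synth --seed 3 --out truthdir
```

## Documentation

`vignettes/melaniche-methods.Rmd` documents the model and every open
methodological choice: the maximum-entropy objective and optimiser, the
kernel-guided CSR null and its exchangeable p-value, the two equivalency
null schemes and their measured size/power, what the synthetic generator
does and does not emulate, and known limitations.
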