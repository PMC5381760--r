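---
title: "Methods: phenotype-stratified niche analysis of coat-colour melanism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype-stratified niche analysis of coat-colour melanism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Melanism — a darkened coat phenotype, in leopards a recessive ASIP variant —
is a classic polymorphism whose habitat associations bear on long-standing
hypotheses of adaptive coloration (Gloger's rule: darker animals in humid,
densely vegetated environments). `melaniche` implements a complete analysis
chain for asking whether a colour morph is distributed randomly across a
species' range or tracks particular habitats: occurrence-record curation,
biome-association statistics, a spatial-randomness test, per-phenotype
maximum-entropy niche models, niche-overlap/equivalency testing, and
environmental driver contrasts. Every stage runs on synthetic landscapes with
known ground truth, so the statistical machinery is testable without
gigabytes of climate rasters.

## Spatial infrastructure

The package carries its own minimal raster layer (`env_grid`, `env_stack`)
backed by plain matrices, with ESRI ASCII grid text I/O. This is deliberate:
the analysis needs only aligned-grid arithmetic, point-in-cell lookup and
value extraction, and depending on a heavyweight GIS stack would buy nothing
testable here. Polygonal objects (the merged record buffers, spatial scales,
barrier sides) are represented as raster masks on a working grid; areas come
from cell counting. The buffer-union mask converges on the true polygon area
as the working resolution grows — at the default ~220 cells along the long
side, a single 200-km disc's area is recovered to well under 1%.

Geodesic distances use the haversine formula on the WGS84 mean radius;
point-pattern work projects to a local equirectangular km system centred on
the data. At subcontinental spans the distortion of these choices is far
below every tolerance used in the analysis.

## Record curation

Records carry phenotype (`melanistic`, `non_melanistic`,
`unconfirmed_melanistic`), source and year. Unconfirmed-melanism records are
flagged ineligible for modelling — conservatively treating melanism as absent
where it was reported but never documented. Camera-trap deduplication
collapses same-phenotype detections within a 25-km-diameter buffer (the
species' maximum reported home-range extent) unless records are identified
as distinct individuals. Filtering applies, in a fixed order: age (records
≥ 20 years before the reference year), exact coordinate duplicates, and
landscape modification (|NDVI change| ≥ 0.7). The order is a package
decision — the source protocol does not state one — chosen so a record
failing several rules is attributed deterministically to the first, making
the `FilterReport` reconcile exactly: input = output + removals. When exact
duplicates conflict in phenotype, the melanistic record is kept (the rarer
class; conservative for frequency estimation) and the conflict is logged.

## Biome association

`contingency_table()` computes the full association table between biome
classes and the two confirmed phenotypes: observed and expected counts, the
three percentage blocks, adjusted standardised residuals
$(O-E)/\sqrt{E(1-n_{i\cdot}/N)(1-n_{\cdot j}/N)}$, Pearson's $\chi^2$, the
likelihood-ratio $G$, and a linear-by-linear trend statistic $(N-1)r^2$ on
user-supplied ordinal scores. Everything is computed from raw counts, never
from rounded intermediate tables: the published footnote statistics only
reproduce that way. The trend scores are configurable because any biome
ordering is a modelling choice; the default is table row order against
phenotype 0/1. No continuity correction is applied.

## Complete spatial randomness with a kernel-guided null

Sampling effort is never uniform, so raw clustering of records is
uninformative. The CSR test therefore simulates from an inhomogeneous null:
a Gaussian product-kernel estimate of sampling intensity over the
"effectively sampled area" (the union of 200-km buffers around records),
normalised to integrate to the observed count. Choices the source protocol
leaves open, each overridable:

* **Bandwidth** — Scott's plug-in rule per coordinate, $\hat\sigma\,n^{-1/6}$.
* **Summary statistic** — Kolmogorov-type maximum absolute deviation of the
  nearest-neighbour G-function from the pooled null mean over a 512-point
  distance grid.
* **Edge correction** — none; the identical uncorrected estimator is applied
  to observed and simulated patterns, so the comparison is fair.
* **Conditioning** — simulated patterns have exactly the observed n.

Deviations are computed leave-one-out over the exchangeable pool of the
observed pattern plus the `n_sim` simulations, giving
$p = (1 + \#\{d_{sim} \ge d_{obs}\})/(n_{sim}+1)$, exactly uniform under the
null. The acceptance experiment confirms this: over 200 trials of patterns
simulated from the fitted intensity, the rejection rate at $\alpha = 0.05$
sits inside the exact binomial interval, while tight clusters under a broad
effort kernel are rejected essentially always.

## The maximum-entropy model

The niche model is the Gibbs distribution over background cells
$q_\lambda(x) \propto e^{\lambda\cdot f(x)}$ whose weights maximise the
L1-penalised presence log-likelihood

$$\frac{1}{m}\sum_i \lambda\cdot f(x_i) - \log Z_\lambda
  - \sum_j \beta_j|\lambda_j|.$$

Features (linear, quadratic, pairwise product, two-sided hinge with 50 knots
per layer) are standardised to $[0,1]$ over the training extent and clamped
to those bounds at prediction. The auto-feature schedule follows the classic
presence-count thresholds (linear below 10; +quadratic from 10; +hinge from
15; +product from 80), and $\beta_j$ follows the published per-class
schedules scaled by $\sqrt{s^2_j/m}$. The optimiser is FISTA-style
accelerated proximal gradient with backtracking and restart on the convex
objective — the objective, not any particular sequential-update algorithm,
defines the model — with the 1e-5 convergence threshold applied to relative
objective change and a 500-iteration cap. The logistic output
$e^H q/(1+e^H q)$ uses the entropy $H$ of the fitted raw distribution
(implied prevalence 0.5).

Parameter recovery holds when the generator is inside the family: presences
drawn $\propto e^{2x}$ on one layer return $\hat\lambda = 2$ within a few
percent at $m = 2000$. Replicated runs use random 70/30 presence splits
("bootstrap" in the classic tool's sense of repeated random partitions),
AUC against the background sample via the rank (Mann-Whitney) estimator
with tie correction, and permutation variable importance — the mean AUC drop
when one layer is shuffled across evaluation points, floored at zero and
normalised to percentages. Permutation importance replaces the classic
internal "contribution" metric, which is optimiser-path-dependent and not
reproducible. Published AUCs (0.948/0.982) and mean suitabilities
(0.594/0.192) require the real climate layers and record set and are
deliberately out of desk scope; the property checks (recovery, null AUC
0.5 ± 0.05, informative AUC > 0.8) stand in for them.

## Niche overlap and the equivalency null

Suitability maps are normalised to sum 1 over shared valid cells before
computing Schoener's $D = 1-\frac12\sum|p-q|$, the Hellinger-derived
$I = 1-\frac12\sum(\sqrt p-\sqrt q)^2$, and the relative rank RR — the
probability that a random cell pair is ordered identically by the two maps,
with ties counted as agreement, exhaustive below 2·10^6 pairs and seeded
sampling of 10^6 pairs above. (A worked 3-cell example in the tests pins the
estimator: maps ordering all pairs oppositely have RR = 0.)

The equivalency test compares the observed D/I/RR between the two
phenotypes' mean suitability maps against a resampled null at the observed
class imbalance: 100 pseudo-minor models of size
$0.1\,n_{major}$ and 100 pseudo-major models of size $0.9\,n_{minor}$, with
D/I/RR over all 100×100 cross pairs, and
$p = (1+\#\{null \le obs\})/(n_{null}+1)$, one-sided because the hypothesis
is reduced overlap.

Two resampling schemes are implemented, and the difference matters. The
written description of the source protocol draws pseudo-minor records from
the *opposite* (majority) group and pseudo-major records from the minority
group ("reciprocal"). Measured on synthetic ground truth, that null is
itself a cross-niche comparison: under a true niche difference its
distribution tracks the observed statistic (rejection ≈ 40–45% at the
600-record scale) and under no difference it can reject wildly (65% at a
260-record scale) whenever pseudo and observed models carry different
information — it responds to sample-size asymmetry, not to niche
difference. The tool the protocol names, however, implements the classic
niche-identity null: pseudo records of both directions drawn from the
*pooled* record set. Under label exchangeability the pooled null reproduces
the observed comparison (measured size: 0–5% false rejection), and under a
real difference the pooled models converge on the mixture niche, leaving
the observed overlap in the far left tail (measured power: 100% on
disjoint-niche worlds). `null_scheme = "pooled"` is therefore the default;
`"reciprocal"` remains available for protocol comparison.

The paired suitability test extracts both models' suitability at every
record (dropping nodata pairwise, with a count) and applies a paired t-test;
identical maps give t = 0, p = 1 by convention.

## Driver contrasts, the barrier test, leave-region-out

For each spatial scale and variable, `driver_contrast()` reports each
model's suitability-weighted mean of the variable over the shared record
set and tests the difference with a record-level paired t-test: the pair for
record $i$ is $v_i s_i/\bar s$ under each model, whose mean is exactly the
suitability-weighted mean. The pairing unit is a package decision — the
source protocol states "paired t-test" without one — chosen so both models
are interrogated at identical points. Significance uses a Bonferroni
threshold $\alpha/(\text{variables}\times\text{scales})$. Per-phenotype
least-squares slope and Pearson R of suitability against each variable (and
an NDVI layer) mirror the classic suitability-versus-driver panels.

The barrier contrast samples equal numbers of random cells on each side of a
latitudinal barrier within one biome class (default 600 points, 300 per
side) and compares the target variable with a two-sample t-test. One caveat
is documented rather than hidden: with strongly autocorrelated fields the
iid assumption fails and the naive t-test over-rejects badly (measured 73%
at α = 0.05 on smoothed null landscapes, versus 4–7% on independent-noise
landscapes). The calibration experiment therefore runs on independent-noise
moisture fields — the regime where the test's assumptions hold — and
analyses of autocorrelated data should read the p-value as descriptive, a
limitation shared with the original point-sampling design.

`leave_region_out()` refits a model excluding all presences inside a region
and reports mean within-region suitability before versus after; a ratio
near 1 indicates the regional signal is shared with records elsewhere. With
a region disjoint from all records the refit is bit-identical under the
same seed.

## The synthetic world

`synthetic_config()` states the world the tests live in; its defaults are
fixed and were chosen once to mirror the study system's published structure:

* ~600 records with ~11% melanistic overall (the published global frequency
  is ca. 11%), with the wettest biome holding roughly a third of records and
  a 0.30 melanism frequency, open/dry classes near zero
  (`melanism_freq_by_biome = c(0, 0.02, 0.06, 0.30)`).
* Three standardised environmental gradients with pairwise correlation 0.5
  between the first two, built by smoothing white noise with a Gaussian
  kernel (range 5 cells), empirically orthogonalising, and mixing through
  the Cholesky factor of the target matrix — so realised correlations equal
  the target to numerical precision, not merely in expectation.
* Four biome classes cut from a field that tracks the moisture gradient, so
  biome and climate are confounded the way real landscapes are.
* An NDVI-change layer scaled so |Δ| rarely crosses the 0.7 filter cutoff.
* Records at cell centres with sub-cell jitter (so exact-duplicate filtering
  stays exercisable), camera-trap-dominated sources, years 2001–2013.

Labels are drawn per-biome from the stated frequencies; for power
experiments an explicit per-phenotype coefficient set switches the generator
to sampling each phenotype from its own surface. What the generator does
*not* emulate: real bioclim covariance structure, range geometry,
observation bias gradients, or spatial clustering of survey effort. A green
test therefore establishes that the statistical machinery is correct and
calibrated in a known world — not that any particular field dataset will
behave.

## Numerical choices and degenerate inputs

* Correlation matrices must be symmetric PSD (checked by eigenvalue).
* All-zero suitability surfaces, all-identical kernel points, empty
  contingency tables, odd barrier point counts and undersized minority
  groups are rejected with explanatory errors; biomes with zero totals are
  dropped with a warning.
* Monte Carlo p-values are never below $1/(n_{sim}+1)$ and never zero.
* A single global seed derives per-stage seeds by name hashing, so pipeline
  stages can be rerun in isolation and full runs are byte-reproducible
  (manifests carry no timestamps).
* Replicate counts default to desk scale (10 SDM replicates) and are
  configurable up to the classic 500; the acceptance experiments state
  their reduced scales explicitly (10×10 equivalency nulls, 39–99 CSR
  simulations at 200 trials).

## Known limitations

* The raster layer is deliberately minimal: no projections beyond the local
  equirectangular, no GeoTIFF (text ASCII grids only), no polygon geometry
  beyond raster masks.
* Presence-background AUC is a relative, not absolute, discrimination
  measure; with 10,000 background points it is bounded away from 1.
* The barrier t-test's size under strong spatial autocorrelation is
  anticonservative (above).
* The reciprocal equivalency null is retained for fidelity to the written
  protocol but should not be used for inference; see the measured behaviour
  above.
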