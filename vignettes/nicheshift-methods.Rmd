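---
title: "Methods: maximum-entropy niche models, scenario projection, and the vulnerability assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maximum-entropy niche models, scenario projection, and the vulnerability assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nicheshift)
```

## The problem

`nicheshift` estimates habitat suitability for a pair of interacting
species from presence-only occurrence records and gridded environmental
predictors, projects the fitted models onto past and future climate-layer
sets, and summarizes the consequences with two families of statistics:
abiotic niche-overlap metrics (Schoener's *D*, Warren's *I*) and a
threshold-free *vulnerability assessment* — the percent change in summed
suitability per species and over the geographic intersection of the two
ranges. Every stage is driven by a synthetic-data generator with known
ground truth, so the whole analysis is verifiable at desk scale without
any external data download.

## The estimator

The core model is a maximum-entropy (Gibbs) density over background
cells. With features $f_j(x) \in [0,1]$ built from the environmental
variables and coefficients $\lambda_j$, the model is

$$ p_\lambda(x) \;=\; \frac{e^{\eta(x)}}{Z(\lambda)}, \qquad
   \eta(x) = \sum_j \lambda_j f_j(x), \qquad
   Z(\lambda) = \sum_{x \in \text{background}} e^{\eta(x)}, $$

fitted by minimizing the penalized negative log-likelihood

$$ J(\lambda) \;=\; -\frac{1}{m}\sum_{i=1}^{m} \eta(x_i) + \log Z(\lambda)
   \;+\; \sum_j \beta_j\,\mathrm{rm}\,|\lambda_j| $$

over the $m$ presences. The per-feature penalty $\beta_j$ is a
class-level constant (interpolated by presence sample size, 0.5 for hinge
features) times the feature's presence standard deviation over
$\sqrt{m}$; the global regularization multiplier rm scales all of them,
with rm = 0 accepted as a fully unpenalized fit (a warning notes the
overfitting risk). Feature classes default to linear + quadratic + hinge;
products are available but off by default.

Optimization is cyclic coordinate descent: each coordinate takes a Newton
step soft-thresholded for the L1 term, guarded by a halving line search
on the true objective so the penalized objective is monotonically
non-increasing — an invariant the tests assert. $\lambda$ starts at 0,
there is no random initialization, and convergence is declared when the
largest KKT violation drops below $10^{-6}$ (cap: 10,000 sweeps), so fits
are bit-reproducible. Raw outputs over the training background sum to 1
by construction; the bounded display scale is the cloglog transform
$1 - \exp(-e^{\eta(x) - r})$ with the entropy-based offset
$r = \log Z - H$ fixed at training time.

Two output scales are carried through the package deliberately: the
**raw** scale (a probability distribution over cells — the natural input
to the overlap metrics, which require normalized surfaces) and the
**cloglog** scale (bounded relative suitability — the natural scale to
*sum* in the vulnerability assessment, since raw sums are 1 by
definition). Both choices are config flags; these defaults are the
package's own reading, since presence-background toolchains rarely state
which scale their overlap and summation conveniences use.

### Regularization-multiplier selection

Candidate multipliers (default grid 0.5–3 in steps of 0.5) are scored by
AICc with $k$ = the number of nonzero coefficients, $n$ = the presence
count, and the log-likelihood summed over presences on the raw scale:
$\mathrm{AICc} = 2k - 2\ln L + 2k(k+1)/(n-k-1)$, reported non-finite when
$n \le k+1$. Candidates are fitted as a warm-started path from the
strongest penalty down (`maxent_rm_path()`), the standard way to sweep an
L1 penalty: faster than independent fits and numerically stable. One
caveat worth stating plainly: the exact L1 active set is not
mathematically guaranteed to shrink monotonically in the penalty when the
basis contains near-duplicate columns (adjacent hinge knots correlate at
$|r| \approx 0.98$), and on some datasets an independent-fit sweep shows
a transient increase of one coefficient. On the smooth linear+quadratic
basis the monotone-sparsity property holds robustly and is asserted in
the tests.

### Evaluation and diagnostics

AUC is computed in its Mann–Whitney form (ties count one half), making
it invariant under any monotone transform of the scores — raw and
cloglog outputs give identical AUC, which the tests check. Five-fold
cross-validation partitions presences into seeded folds, trains each
replicate against the full background, and reports held-out AUC; the
final projection maps are the cell-wise mean of the replicate
predictions (a "refit on all data" model is what `select_rm()` returns if
preferred). Percent contribution allocates the objective improvements
accumulated during coordinate descent to each feature's source variable,
normalized to 100; the jackknife refits with only / without each
variable; marginal response curves sweep one variable over its training
range with the others held at background means.

## Occurrences, bias, and background

Cleaning applies exactly three filters — missing coordinates, subspecies
rank, exact (species, lon, lat) duplicates — preserving survivor order.
Thinning lays a 5 km grid (converted to degrees at the study-area
mid-latitude, anchored at the raster origin) and keeps one record per
occupied cell, chosen uniformly at random under a seed rather than "first
in file", so results do not depend on input ordering. Sampling effort is
modeled by a target-group bias surface: per-cell counts of records of
similarly surveyed taxa, optionally Gaussian-smoothed with the total mass
renormalized. Pseudo-absences (default 10,000) are drawn cell-wise
multinomially proportional to that effort, with replacement, and placed
uniformly within cells; cells with no target-group records get zero
weight by default (an `floor_eps` escape hatch exists for sparse
fixtures). A datum-transform hook on `clean_records()` is where a
standard NAD27→WGS84 conversion would plug in; the package does not
re-derive datum mathematics.

## Rasters

The raster containers are deliberately small: a `raster_grid` (extent,
square cells, CRS, nodata sentinel) plus named layer matrices, with ESRI
ASCII grid text files as the interchange format and GeoJSON for
polygons. Range masking keeps cells whose *centers* are inside the range
polygon or within the species' dispersal buffer of its boundary, with
distances evaluated in a local equirectangular metric frame — equivalent
to buffering the polygon, without polygon offsetting. The terrain
ruggedness index is the Riley root-sum-of-squares of the eight neighbor
differences (a mean-absolute-difference variant sits behind a flag);
edge cells use available neighbors and nodata propagates. Predictor
pruning computes pairwise Pearson correlations over jointly valid cells
and greedily drops the lower-priority member of the worst pair at or
above the threshold (default 0.8) until no pair remains — an explicit,
user-supplied priority order replaces the expert's ecological choice so
the result is deterministic. Coarser scenario layers are bilinearly
resampled onto the model grid (nearest-neighbor for categorical layers);
identical grids short-circuit bit-identically.

## Scenarios, projection, and averaging

A scenario carries one climate stack per GCM plus static layers (terrain
and soil stand-ins) held constant across periods. Projection merges each
GCM's climate with the static layers, predicts with clamping (variables
truncated to their training range) and averages the per-GCM maps
cell-wise, with a strict-intersection nodata rule so sums are never taken
over unequal footprints. Averaging model *outputs* across GCMs, rather
than averaging climate *inputs* first, is the package default (the
conservative reading of ensemble averaging); input-space averaging can be
assembled from the same pieces if wanted.

## Overlap and vulnerability

With both current maps normalized over the shared valid-cell mask,

$$ D = 1 - \tfrac12 \sum_i |p_{X,i} - p_{Y,i}|, \qquad
   I = 1 - \tfrac12 \sum_i (\sqrt{p_{X,i}} - \sqrt{p_{Y,i}})^2 . $$

$I \ge D$ always (cell-wise $(\sqrt p - \sqrt q)^2 \le |p - q|$), both
lie in $[0,1]$, equal 1 only for identical surfaces, and are invariant to
positive rescaling of the inputs — all asserted over random surface pairs
against brute-force summation oracles.

The vulnerability assessment applies no suitability threshold anywhere.
For each species, with $H$ the sum of suitability over the masked map,
future scenarios report $100\,(H_f - H_c)/H_c$ and past periods report
the change *from past to current*, $100\,(H_c - H_p)/H_p$; negative
means loss. The combined statistic pools both species' sums over the
geometric intersection of their ranges:
$100\,((H^P_{new} + H^O_{new}) - (H^P_{ref} + H^O_{ref})) /
(H^P_{ref} + H^O_{ref})$. All $H$ values are retained in the report for
audit, and the table is recomputable from them exactly. Percentages are
printed to two decimals. (One presentation note: in analyses of this
design the sign of small overlap-area changes is easy to mis-transcribe
between prose and tables; this package always reports the signed value
the formula yields.)

## The synthetic generator

Environmental layers are white noise convolved with a Gaussian kernel
(bandwidth in cells, default 2) and standardized — cheap, controllable
spatial autocorrelation — plus a deterministic latitudinal-gradient
layer standing in for static terrain. Correlated pairs are built by
mixing, $B = \rho A + \sqrt{1-\rho^2}\,\varepsilon$, giving a closed-form
target correlation for the pruning stage to find. Note that smoothing
shrinks the fields' effective sample size, so empirical correlations of
*independent* layers scatter more widely the wider the kernel; fixtures
that assert near-zero correlation use a bandwidth of 1.

The true niche is log-linear in the standardized layers with optional
quadratic terms (so an optimum can be placed at or away from current
conditions), normalized to sum to 1. Presences are drawn cell-wise
proportional to truth × sampling effort and jittered uniformly within
cells; 5% dirty rows (missing coordinates, exact duplicates,
subspecies-tagged records) are appended so the cleaning stage is
exercised deterministically. What the generator does *not* emulate:
real bioclimatic covariance structure, GCM physics, spatially structured
observation error, or taxonomic noise beyond the rank tag — passing
tests demonstrate correctness of the machinery, not realism of any
ecological conclusion.

The default two-species configuration encodes the predator–prey contrast
the assessment is designed to expose: species A (ectotherm-analogue) has
its thermal optimum *at* current conditions (pure negative quadratic on
the temperature-like layer), so any warming shift costs it habitat;
species B (endotherm-analogue) is driven by a different layer with a weak
positive linear response to temperature, so warming leaves it
flat-to-gaining. A strictly temperature-indifferent species B would make
the *sign* of its small change a coin flip at finite sample size, so the
default gives B a weak positive coefficient — the qualitative pattern
(A loses, B does not) is then robust across seeds.

## Determinism and problem sizes

One master seed fans out through a hash into named per-stage sub-seeds
(`derive_seed()`), so no stage reuses another's stream and a full
pipeline re-run is bit-identical — the test suite compares output files
byte for byte. The bundled configurations run on a 30×30 grid with 6
random layers (one correlated pair each), 500–600 presences per species,
2,000 background points, 8 hinge knots, the 0.5–3 rm grid and 5-fold
cross-validation: sizes chosen so a full two-species run completes in a
few seconds while every statistic retains enough signal to test sharply.
The function-level defaults keep the field-standard values (10,000
background points, 20 hinge knots, 5-km thinning, |r| ≥ 0.8 pruning).

## Worked example

```{r example, eval = FALSE}
library(nicheshift)
cfg <- run_config(seed = 42, out_dir = "run42")
res <- run_pipeline(cfg)
res$overlap          # Schoener's D, Warren's I
res$report           # vulnerability table (percent change per scenario)
render_report("run42")
```

## Known limitations

* Polygon intersection requires one convex operand (rectangular synthetic
  ranges always qualify); holes and non-convex/non-convex pairs are
  rejected rather than approximated.
* Reprojection between arbitrary CRSs is out of scope; all geometry runs
  in lon/lat with a local-metric buffer frame.
* The estimator re-implements the published maximum-entropy core, not any
  particular historical implementation byte-for-byte; per-feature penalty
  constants follow the published class defaults but small numerical
  differences from other implementations are expected.
* Binary thresholded range maps are deliberately absent: the vulnerability
  design is threshold-free.
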