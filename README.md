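# nicheshift

Presence-background ecological niche modeling for interacting species
pairs, with climate-scenario projection, niche-overlap metrics, and a
threshold-free vulnerability assessment — built for ecologists who want
the whole analysis chain (occurrence cleaning through the final percent-
change table) reproducible, testable, and free of external data
dependencies.

## What it does

Given occurrence records and gridded environmental predictors for two
sympatric species (say, an ectotherm predator and its endotherm prey),
`nicheshift`:

1. **cleans and thins occurrences** — drops incomplete, subspecies, and
   duplicate records, then keeps one record per 5-km grid cell;
2. **replicates sampling bias in the background** — builds a target-group
   sampling-effort surface and draws 10,000 pseudo-absences weighted by
   it;
3. **prunes correlated predictors** at Pearson |r| ≥ 0.8 under an
   explicit priority order;
4. **fits a maximum-entropy suitability model** — a Gibbs log-linear
   density over background cells,

   p(x) ∝ exp( Σⱼ λⱼ fⱼ(x) ),

   with linear/quadratic/hinge features and an L1 penalty per feature,
   fitted by monotone coordinate descent; the regularization multiplier
   is selected by AICc over a 0.5–3 grid (warm-started path), and models
   are evaluated by 5-fold cross-validated AUC;
5. **projects** the fitted model onto past/future scenario layer stacks,
   averaging across GCMs per scenario with static terrain layers held
   constant;
6. **quantifies overlap and change** — Schoener's
   D = 1 − ½Σ|pₓ − p_y| and Warren's I = 1 − ½Σ(√pₓ − √p_y)² on
   normalized surfaces, and a vulnerability table of percent changes in
   summed suitability, 100·(H_f − H_c)/H_c per species and over the
   geometric intersection of the two ranges, with no suitability
   threshold anywhere.

A first-class synthetic-data generator (smoothed Gaussian random fields,
a known log-linear truth with optional quadratic optima, biased sampling,
scenario perturbations with known-direction effects) stands in for the
usual occurrence-database and climate-archive downloads, so every stage
has verifiable ground truth.

## Worked example

```r
library(nicheshift)
cfg <- run_config(seed = 42, out_dir = "run42")   # two synthetic species,
res <- run_pipeline(cfg)                          # 3 warming + 2 paleo scenarios
render_report("run42")
```

`summary.txt` from that exact run:

```
nicheshift run run42 (seed 42, config 5eb9dbf0)
layers kept after |r| filter: env01, env03, env05, lat_gradient

  species_A: mean cross-validated AUC = 0.738 (rm = 0.5)
  species_B: mean cross-validated AUC = 0.729 (rm = 1.5)

  niche overlap: Schoener's D = 0.603, Warren's I = 0.866

  vulnerability (percent change in summed suitability):
    species_A      warm_low=-5.82%  warm_mid=-22.94%  warm_high=-46.77%  glacial=+426.59%  mid_holocene=+2.58%
    species_B      warm_low=+6.45%  warm_mid=+8.51%  warm_high=+6.72%  glacial=+171.24%  mid_holocene=+6.22%
    Overlap area   warm_low=+4.59%  warm_mid=-1.16%  warm_high=-14.74%  glacial=+330.17%  mid_holocene=+7.90%
```

Reading it: one of six correlated layer pairs survives per pair after the
|r| filter; both models discriminate presences from background well above
chance (AUC ≈ 0.73); the two species share most of their abiotic niche
(D = 0.60, I = 0.87); species A — whose thermal optimum sits at current
conditions — loses suitable habitat monotonically as warming strengthens
(−5.8% → −46.8%), while species B, weakly warming-favored, gains
(+6.5% → +6.7%); both species have expanded enormously since the
glacial-like past period (+427%, +171%), and the co-occurrence area
tracks a compromise of the two single-species signals. Full
machine-readable outputs (per-fold AUCs, percent-contribution tables,
suitability and difference rasters as ASCII grids, the report as
CSV/JSON, a manifest with per-stage seeds and a config hash) land in the
run directory, and a re-run under the same seed reproduces every file
byte for byte.

A minimal command-line wrapper ships in `inst/cli/nicheshift.R`
(`generate | run | report`, each accepting `--seed` and `--out`).

## Package layout

| Where | What |
|---|---|
| `R/grid.R`, `R/rasters.R`, `R/geometry.R` | raster grid/stack containers, ASCII-grid and GeoJSON I/O, range masking with metric buffers, TRI, correlation pruning, resampling |
| `R/occurrences.R` | cleaning, grid thinning, bias surfaces, background sampling |
| `R/synthetic.R` | the ground-truth generator (layers, truths, effort, scenarios, ranges) |
| `R/features.R`, `R/maxent.R`, `R/evaluate.R` | feature expansion, the maximum-entropy estimator, AUC/CV/AICc/importance/response curves |
| `R/projection.R`, `R/metrics.R` | scenario projection, GCM averaging, D/I, range intersection, vulnerability report |
| `R/pipeline.R` | configuration-driven orchestration and reporting |
| `vignettes/nicheshift-methods.Rmd` | the model, its assumptions, numerical choices and limitations |
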