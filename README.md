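# etaxis

Quantitative analysis of single-cell **electrotaxis** (galvanotaxis)
experiments: directed cell migration under direct-current electric
fields, as studied in multi-field microfluidic chips with time-lapse
phase-contrast microscopy and automated single-cell tracking.

The package is for experimentalists and analysts who have per-cell track
tables (and optionally labelled segmentation masks) and need the field's
standard migration statistics, the directional tests used to compare
conditions, and a way to validate the whole pipeline on synthetic data
with known ground truth.

## What it computes

For a cohort of N tracked cells under a field applied anode→cathode:

- **Directedness** — mean of cos Φᵢ, where Φᵢ is the angle between cell
  i's net (first-to-last frame) displacement and the field vector:
  +1 for cathodal cohorts, −1 anodal, 0 random.
- **Speed** — mean of d_net/t_elapsed (μm/h), the net Euclidean distance
  over elapsed time (total path length is an auxiliary column).
- **Orientation index** — mean of cos 2θᵢ, θᵢ the angle between the cell
  long axis and the field: +1 parallel, −1 perpendicular, 0 random.
- **Area** — mean mask area (μm²), with centroid and long-axis angle
  measured from integer label masks by second-moment analysis.
- **Directional statistics** — displacement angles, mean resultant
  (r-)vectors, rose histograms, and the non-parametric
  **Mardia–Watson–Wheeler** uniform-scores test
  (W asymptotically χ²₂; p = exp(−W/2), plus permutation p-values).
- **Chip field model** — lumped resistor-network (Kirchhoff) solution of
  multi-field chip channels, section field strengths from current
  density, and ratio scaling (e.g. 5.25 : 2.5 : 1 : 0 → 300, 142.9,
  57.1, 0 V/m).
- **Synthetic data** — biased persistent random walks (von Mises
  headings, gamma step speeds) and rasterized elliptical label masks
  with analytic ground truth, for end-to-end validation.

The pipeline applies the conventional filters and reporting rules:
only cells tracked through every frame are analyzed, cohorts under 100
cells are flagged, and group values are reported as mean ± 1.96·SEM.

## Worked example

Two simulated conditions — field on (biased walks) vs field off
(isotropic walks), 150 cells each, 6 h at 10-min frames:

```r
library(etaxis)
cfg <- list(
  frame_interval = 10,
  filters = list(completeness = TRUE, min_cells = 100),
  statistics = list(ci_multiplier = 1.96, seed = 7),
  conditions = list(
    list(label = "EF_300Vm", field = list(direction = c(1, 0), strength = 300),
         simulate = list(n_cells = 150, kappa_bias = 1.2, mix_weight = 1)),
    list(label = "no_EF", field = list(direction = c(1, 0), strength = 0),
         simulate = list(n_cells = 150, kappa_bias = 0))))
res <- run_experiment(cfg)
print(res$summary, digits = 3)
#>      label n_cells efs directedness directedness_ci speed speed_ci      r
#> 1 EF_300Vm     150 300       0.9604         0.00904  7.74    0.312 0.9604
#> 2    no_EF     150   0       0.0253         0.11410  2.72    0.241 0.0254
#>   mean_angle low_n
#> 1   -0.00523 FALSE
#> 2    0.01327 FALSE
print(res$comparisons, digits = 3)
#>    group_a group_b mww_W   mww_p mww_p_perm directedness_t_p
#> 1 EF_300Vm   no_EF   165 1.5e-36         NA          2.4e-34
```

The field-on cohort is strongly directed (0.96 ± 0.01, r = 0.96 with
mean angle ≈ 0, i.e. along the field) and faster in net terms
(7.7 vs 2.7 μm/h — straighter paths cover more net distance at the same
step speed); the field-off cohort is consistent with random migration
(0.03 ± 0.11). The Mardia–Watson–Wheeler test rejects equality of the
two direction distributions (W = 165, p ≈ 10⁻³⁶). `run_experiment(cfg,
out_dir = "out")` additionally writes per-cell CSVs, rose-histogram
tables, and a JSON report with provenance (config hash, seed, version).

A thin command-line front end is installed at
`inst/cli/etaxis.R` (`Rscript etaxis.R run|simulate|field --config ...
--out ... --seed ...`).

## Documentation

See the methods vignette
(`vignettes/electrotaxis-analysis.Rmd`) for the models, conventions,
default parameters and their rationale, and known limitations.
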