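---
title: "Quantifying single-cell electrotaxis: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-cell electrotaxis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etaxis)
```

## The problem

Electrotaxis (galvanotaxis) is directed cell migration along a
direct-current electric field. Experiments expose cells — here the
motivating system is glioblastoma cell lines in multi-field microfluidic
chips — to field strengths of order 100–300 V/m, image them by time-lapse
microscopy at ~10-min intervals over ~6 h, and track each cell. The
analysis question is always the same: *do cells move and align
differently under the field, and by how much?* `etaxis` implements the
standard quantitative answer: per-cell migration indices, group summaries
with confidence intervals, and directional statistics for comparing
groups, together with a synthetic-data generator and a lumped electrical
model of the chip so that every stage can be validated without access to
raw microscopy data.

## The metrics

All metrics are defined relative to the applied field vector, taken
anode→cathode, so cathodal migration is "positive".

* **Directedness** $\frac{1}{N}\sum_i \cos\Phi_i$, where $\Phi_i$ is the
  angle between cell $i$'s *net* (first-to-last frame, Euclidean)
  displacement and the field vector. A cohort moving cathodally scores
  +1, anodally −1, and randomly 0.
* **Speed** $\frac{1}{N}\sum_i d_{\mathrm{net},i}/t_{\mathrm{elapsed},i}$
  in μm/h, the net Euclidean distance over elapsed time. The total path
  length and path speed are emitted as auxiliary columns only — net speed
  is the headline statistic.
* **Orientation index** $\frac{1}{N}\sum_i \cos 2\theta_i$, where
  $\theta_i$ is the angle between cell $i$'s long axis and the field.
  Doubling the angle respects the head/tail ambiguity of an axis:
  parallel alignment gives +1, perpendicular −1, random 0.
* **Area** $\frac{1}{N}\sum_i A_i$ in μm², integrated from label masks.

Cells with zero net displacement carry no direction: they are excluded
from directedness and displacement angles with a logged count, never
imputed. Likewise near-circular regions (flagged by the mask measurer)
are excluded from orientation statistics.

Time-resolved variants exist for figures: directedness at frame $t$ uses
the *cumulative* displacement from frame 0 to $t$ (the per-interval
alternative measures instantaneous wiggle, not progress, and frame 0 is
undefined and omitted); orientation at frame $t$ averages $\cos 2\theta$
over the regions measured in that frame.

## Filtering and reporting rules

Only cells tracked through *every* frame of their viewfield's range are
analyzed (`filter_complete_tracks`); cells that appear, disappear,
divide or die would otherwise bias endpoint statistics. The frame range
defaults to the [min, max] frame observed in the viewfield. Cohorts
below 100 cells are flagged (`min_cells`), mirroring common practice for
these indices. Group values are reported as mean ± 1.96·SEM — the
normal-approximation 95% interval, applied at every n rather than
switching to t-quantiles, because that is the convention the reported
index values in this field follow; at the cohort sizes the filter
enforces (≥100) the difference is negligible.

## Directional statistics

Displacement angles are computed by two-argument arctangent relative to
the field vector and summarized by the mean resultant vector (length
$r \in [0,1]$, mean angle) and rose histograms (frequency per bin, first
bin centred on the field direction). Axial data (cell long axes on
$[0,\pi)$) are doubled before any circular operation and never mixed
with directional sets.

Two groups are compared with the **Mardia–Watson–Wheeler uniform-scores
test**: pool both samples, rank them around the circle, replace angle
$k$ by its uniform score $\beta_k = 2\pi\,\mathrm{rank}_k/N$, and form

$$W = 2\sum_{j=1,2}\frac{C_j^2 + S_j^2}{n_j},\qquad
C_j = \sum_{k\in j}\cos\beta_k,\; S_j = \sum_{k\in j}\sin\beta_k.$$

Under the null of identical distributions $W$ is asymptotically
$\chi^2_2$, so the asymptotic p-value has the closed form $e^{-W/2}$.
Because the test is rank-based, $W$ is exactly invariant under a common
rotation of both samples. Ties are broken by infinitesimal random jitter
under a recorded seed (the standard device for uniform-scores tests);
the asymptotic p is flagged unreliable below $\min(n_1,n_2) = 10$, and a
permutation p-value — reported as $(b+1)/(B+1)$ over $B$ random
relabellings, default 10 000 — is available for small samples or as a
cross-check. Whether a given historical analysis used asymptotic or
exact p-values is rarely stated; providing both makes either
reproducible. Routine scalar comparisons are delegated to standard
routines: Welch t-tests for two groups, one-way ANOVA with Tukey's
post-hoc for several; no additional multiplicity correction is layered
on top.

## The synthetic-data generator

No deposited raw data exist for the motivating experiments, so the
generator stands in for them, and its defaults *are* the study
conditions: 36 steps of 10 min (6 h), per-step speeds gamma-distributed
with mean 15 μm/h and shape 2 (positive, right-skewed; net speeds of the
resulting walks fall in the ~2–20 μm/h range reported for glioblastoma
electrotaxis — per-step speeds of real cells are not recoverable from
published net speeds, so this is an order-of-magnitude choice).

The walk model is a biased persistent random walk with von Mises
headings: step $t$'s heading is one von Mises draw centred on the
circular weighted mean of the target angle (weight $w$, concentration
$\kappa_b$) and the previous heading (weight $1-w$, concentration
$\kappa_p$), the two weighted concentration vectors added vectorially.
A single draw about a combined centre (rather than a mixture) was chosen
because it has closed-form checks: with $w=1$ headings are i.i.d.
von Mises($\kappa_b$), whose mean resultant length is the Bessel ratio
$I_1(\kappa)/I_0(\kappa)$ — the parameter-recovery oracle in the test
suite, computed independently by numerical quadrature. The initial
reference heading is the target angle plus a uniform deviate, which
keeps zero-bias ensembles exactly isotropic while making rotation of the
target angle an exact symmetry at matched seeds. One root seed yields
deterministic per-cell substreams. The von Mises sampler itself is
Best–Fisher (1979) rejection sampling.

Cell shapes are generated as non-overlapping filled ellipses
(gamma-distributed areas and aspect ratios, axial orientations with
$2\theta \sim$ von Mises$(2\theta_0, \kappa_{\mathrm{axial}})$),
rasterized with the same y-up pixel-centre convention the measurement
code assumes, alongside an analytic ground-truth table. Overlap is
resolved by rejection sampling on bounding circles; a bounded number of
retries (200) guards against infeasible densities, raising a placement
error rather than looping forever.

**What the generator does *not* emulate:** cell division, death, and
track fragmentation (the complete-track filter's real-world targets);
shape change over time; spatially varying fields; camera noise and
segmentation errors; mechanistic electro-sensing. Passing tests
therefore validate the *analysis arithmetic and statistical calibration*,
not the biology of any particular experiment.

## Mask measurement conventions

Region properties come from pixel-coordinate moments: area = pixel count
× (effective pixel size)², centroid from coordinate means, long-axis
angle from the principal eigenvector of the second central moment
matrix, mapped to $[0,\pi)$. The image row axis is negated so angles
live in the mathematical y-up frame — segmentation tools differ on this,
and the sign of directedness and orientation must not depend on imaging
orientation, so the package fixes one convention at ingestion.
Degenerate regions (<3 pixels) report area but an undefined axis;
isotropic regions (equal principal moments) report 0 and are flagged,
keeping output deterministic. The effective pixel size follows the
optical train: pitch × binning / (objective × intermediate
magnification); e.g. a 6.5 μm sCMOS pixel, 2×2 binning, 10× objective
and 1.5× intermediate magnification give 0.867 ≈ 0.87 μm/pixel.

## The lumped chip model

Multi-field chips create several field strengths in one device by
routing current through an R-2R-style resistor ladder of medium-filled
channels. `etaxis` models the chip as a lumped resistor network:
segment resistance $L/(\sigma w h)$ with medium conductivity 1.536 S/m
by default, nodal (Kirchhoff) analysis via a conductance Laplacian, and
section field strength $I/(\sigma w h)$. An ideal-return R-2R ladder
halves successive rung currents exactly; `scale_to_max` converts a
section ratio such as 5.25 : 2.5 : 1 : 0 into absolute values — scaled
to a 300 V/m maximum this gives 300, 142.9, 57.1, 0 V/m. A
finite-element continuum simulation of the same chip reports a slightly
different ratio (4.99 : 2.45 : 1 : 0); the discrepancy is expected of a
lumped approximation and is documented, not chased. The hydraulic
resistance of a shallow rectangular duct, $12\mu L/(wh^3(1-0.63h/w))$
for $h \le w$, quantifies why tall main channels exchange fluid freely
while shallow interconnects (10 μm × 0.84 mm vs 100 μm × 2 mm mains)
suppress convective cross-talk by >1000×.

## Numerical choices and problem sizes

* Zero-net-displacement exclusion and degenerate-axis exclusion are
  logged, never silent.
* MWW tie jitter is $\le 10^{-9}$ rad, below any physically meaningful
  angular resolution.
* The statistical test-suite sizes were chosen as the smallest that make
  the checks sharp: 2000 cells for "index ≈ 0" checks (SE ≈ 0.016 for
  directedness), 5000 replicates for type-I error calibration
  (binomial SE ≈ 0.003 at α = 0.05), ~10⁵ headings per concentration for
  Bessel-ratio recovery (tolerance 0.02), 100 seeded runs for the
  end-to-end biased-vs-unbiased separation check.
* Pipeline outputs are written with fixed 10-significant-digit
  formatting so repeated runs under one config + seed are byte-identical.

## Known limitations

* The time-resolved directedness definition (cumulative displacement) is
  one of two defensible choices; per-interval directedness is not
  provided.
* The permutation MWW p-value is Monte Carlo, not exact enumeration.
* The lumped network cannot reproduce continuum effects (fringing at
  section boundaries, electrode electrochemistry); it models ratios and
  orders of magnitude.
* Orientation statistics assume the upstream segmentation yields
  meaningful long axes; for nearly round cells the index is noise, which
  the degenerate-region exclusion only partly mitigates.
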