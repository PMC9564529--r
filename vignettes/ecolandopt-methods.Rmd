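---
title: "Methods: scenario optimization and patch-growing allocation of ecological land"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scenario optimization and patch-growing allocation of ecological land}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecolandopt)
```

# Overview

`ecolandopt` couples two stages. The *quantity* stage decides how many km²
each of six land-use classes (arable, forest, grass, water, residential,
industrial-mining-transport — always in this canonical order, codes 1–6,
nodata −1) a region should hold under a chosen human-needs priority. The
*spatial* stage places those areas on a raster landscape with a
patch-growing cellular automaton whose conversion pressure comes from
random-forest growth probabilities calibrated on an observed two-epoch
transition. The region of reference is a forest-dominated karst prefecture
(regional total 33,481.23 km²), whose published coefficient and constraint
tables are the package defaults; every number is overridable
configuration.

Grids are row-major with origin at top-left and carry no geodesy: areas are
cell counts times a stated `cellArea` (km²), never projection arithmetic,
so two grids are comparable only when shapes and cell areas match exactly.
This keeps the method projection-agnostic and the synthetic tests CRS-free.

# Quantity stage

## Objectives

Three linear objectives express the needs levels:

* **Security** (ecological footprint supply):
  $f_1(x) = 0.02x_1 + 0.08x_2 + 0.45x_3 + 0.16x_4$. The demand side of the
  footprint is $ef=\sum_j\sum_i r_j c_i/p_i$ (hm²/cap) with equilibrium
  factors $r$ fixed at 1.74 / 0.44 / 1.41 / 0.35 for arable / grass /
  forest / water, and $EF = N\,ef$. The algebra connecting the equilibrium
  factors to the printed $f_1$ coefficients is not derivable from the
  published material, so all objective coefficients are taken as printed
  defaults rather than recomputed — they are configuration, and the printed
  values are the interface to the published scenario table.
* **Spiritual** (green equivalent):
  $f_2(x) = (0.33x_1 + x_2 + 0.34x_3 + 0.83x_4)/S$, the forest-equivalent
  green share of the regional total $S$. The biannual-cropping growth
  factor (0.67) is already folded into the printed $g_1 = 0.33$ and is not
  re-applied. Built classes have zero green equivalent.
* **Material** (economic benefit): $f_3(x) = \sum_i E_i x_i$ with per-km²
  benefits (362.33, 13.56, 168.47, 235.78, 45,783.88, 67,582.55 — the
  published scale). In the original workflow the $E_i$ come from GM(1,1)
  forecasts of yearbook value series; `gm11Fit`/`gm11Forecast` provide
  that step.

Units: areas are km² everywhere inside the package; footprint quantities in
hm² convert at 1 km² = 100 hm² only at the constraint boundary, since the
source material mixes the two without stating conversions.

## Constraints and solving

The shared constraint system (`constraintSet()`) holds the regional total
as an equality, a population-capacity bracket
$4{,}523{,}100 \le 120(x_1+x_2+x_3) + 3000(x_5+x_6) \le 4{,}618{,}000$
(transcribed literally — water is excluded from the capacity term), an
arable floor 3919.27, a residential bracket [136.49, 143.27], a water floor
311.17, and a footprint bracket $[32{,}527.23,\ 32{,}787.82]$ on
$x_1+\dots+x_4$. Each family can be toggled off, because audits must be
runnable independently of solving: the published optimal solutions
themselves violate parts of the published system (the security column
exceeds the footprint upper bound; the material column's residential area
exceeds its bracket), so reproducing the published optima by re-solving is
explicitly a non-goal. The published table ships as a CSV fixture and all
scenario-change accounting is computed from it; the solver is validated by
exhaustive vertex enumeration on random LPs instead.

LPs are solved with the two-phase simplex method (Dantzig pivoting, as
implemented in `boot::simplex`), which is deterministic: repeated solves
agree bit-wise. Infeasibility and non-convergence are reported in the
`status` slot, never silently.

The **comprehensive** scenario scalarizes the three objectives. The source
states only that all three are maximized; the package's design choice is
ideal-point normalization: solve the three single-objective LPs for
$f_m^*$, then maximize $\sum_m w_m f_m(x)/f_m^*$ with default equal
weights. This is standard, reproducible, and makes each objective
contribute its achievement ratio; it errors if any ideal value is
non-positive.

The **LD** baseline is not an LP: per class, an OLS line through the
historical areas is evaluated at the target year, negative extrapolations
are floored at zero, and the vector is closed proportionally to the fixed
regional total (the published LD column sums to the regional total, so
closure is implied).

## GM(1,1) numerical behavior

The grey model uses the conventional first-order accumulation with
trapezoidal background $z(k)=\tfrac12(x^1(k)+x^1(k-1))$ and least squares
for $(a, b)$. On an exact exponential $c\,e^{g(k-1)}$ the regression has
zero residuals and recovers $\hat a = -2\tanh(g/2) = -(g - g^3/12 + \dots)$:
the model is exact on exponentials *up to this $O(g^3)$ background bias*.
Consequently coefficient recovery is at the $10^{-7}$ level for $g = 0.01$
and forecasts at horizon 3 are within 0.03% at $g = 0.05$ but only within
about 0.14% at $g = 0.1$. The tests therefore exercise recovery in the
small-coefficient regime and forecasting at a yearbook-typical 5% growth
rate; the closed form above serves as the independent oracle. A constant
series is handled analytically ($a = 0$, forecasts equal the mean), and
non-positive observations are rejected.

# Spatial stage

## Land-expansion analysis

For class $k$, a cell is a positive example when it converted *to* $k$
between the two calibration epochs; cells already $k$ at the first epoch
are excluded from positives and from negative sampling. Balanced sampling
(equal positives and negatives without replacement, default cap 5000 per
class) is the default because expansion cells are rare. One one-vs-rest
classification forest per class (default $M = 50$ trees,
$\lfloor\sqrt{p}\rfloor$ features per split) yields the growth probability
as the vote ratio (trees voting "converts")/M — by definition in $[0,1]$
and invariant to driver ordering. Ensemble hyperparameters are unstated in
the source and are documented configuration. Driver importances are
impurity-based, normalized to sum one; needs-group contributions sum the
drivers of each group, with drivers listed in two groups (population
density, slope) split 50/50 since the published grouping lists them twice
without weights.

## Patch-growing allocation

Demands are converted to integer cell targets by largest-remainder
rounding. Each iteration:

1. **Adaptive coefficient.** $D_k$ is unchanged while the absolute gap
   $|demand_k - area_k|$ shrinks (or the demand is met); when the gap
   grows, $D_k$ is scaled by the gap ratio (in magnitude on sign flips)
   and clipped to $[0.1, 10]$. The source names the coefficient but gives
   no update formula; this bounded gap-ratio inertia rule is the package's
   documented choice.
2. **Overall probability.** $OP = P \cdot \Omega \cdot D$, where
   $\Omega$ is the share of the (default 3×3, never stated in the source)
   window occupied by the class, center excluded, with clipped windows at
   edges. Where $\Omega = 0$, a cell passing the expansion-coefficient
   gate (default 0.1, the probability of random patch seeding) and drawing
   $r < P$ seeds a new patch with $OP = P\,r\,\mu_k D$; the patch
   threshold $\mu$ defaults to 0.5 for every class (per-class values are
   allowed, one shared default).
3. **Roulette competition.** Convertible cells of surplus classes draw a
   candidate deficit class with probability proportional to $OP$,
   restricted to allowed transitions. A conversion is accepted if its $OP$
   clears the competition threshold $\tau$ (initialized at 1); accepted
   conversions apply in decreasing $OP$, capped so no class overshoots its
   target and no donor is pushed into deficit. Ties in the shedding phase
   break by class code order for determinism.
4. **Decreasing threshold.** If an iteration changes no cell, $\tau$
   decays by $\delta = 0.5$. If $\tau$ bottoms out without convergence,
   surplus classes shed their lowest-retention cells (lowest own-class
   $P$) directly to the most probable deficit class — the source describes
   only growth, but published demands require class shrinkage, so surplus
   shedding is a necessary and documented extension.

Transition rules always allow self-transition; built classes (residential,
industrial-mining-transport) neither leave nor receive by default,
mirroring the zero transfer probability of built land in the source
workflow — demands for built classes must then equal their base areas, and
growth into them can be re-enabled through the `allowed` matrix. Frozen
cells (e.g. arable protection areas) are never touched. Total cell count
is conserved exactly at every iteration by construction, and the whole
loop runs under a locally seeded RNG, so runs are bit-reproducible and
never disturb the caller's RNG state.

**Convergence tolerance.** The default demand tolerance is 0.1% of the
total landscape area. Cell granularity bounds what per-class closeness can
mean: on a 100×100 grid with 1 km² cells, a class demanding ~1% of the
landscape cannot be matched to 0.1% *of its own demand* (that is sub-cell),
so tolerances are stated and tested against the total-area scale; with the
tolerance set to zero the loop runs to the exact integer cell targets.

# Synthetic landscape generator

The generator is first-class, tested code that defines the package's study
conditions. It emulates: (a) a clustered categorical map — a smoothed
random cosine field thresholded at the cumulative class fractions, so
empirical fractions match the request exactly up to rounding (patch
structure keeps the neighborhood term non-degenerate); (b) seven smooth
driver surfaces named dem, slope (the gradient magnitude of dem),
dist_rail, dist_road, dist_river (distances to random straight routes),
pop_density and gdp (exponentiated smooth fields), standardized, with the
standard needs grouping; (c) a second epoch in which a chosen fraction of
cells (default 0.1 over the two decades the calibration represents)
converts, with per-class conversion propensity logistic in a known 6×7
weight matrix on the drivers — so the true driver ranking is known and
recovery is testable; (d) a red-line mask as the top ~40% of a smoothed
forest/water indicator. With the region-like class fractions
(0.117/0.744/0.125/0.009/0.004/0.001) forest and water alone cover ~75% of
cells, so a literal dilated union would overshoot; thresholding the
smoothed indicator is the dilation that keeps the mask at ~40%,
forest-dominated and effectively contiguous. One global RNG stream per
call, restored on exit, makes every output bit-identical under a seed.

What it does *not* emulate: real geography (the actual karst relief,
population or GDP magnitudes), multi-date epoch stacks, classification
noise, or the real red-line geometry. Passing tests on these landscapes
show the algorithms are implemented correctly and recover known structure;
they do not certify accuracy on the real rasters, whose results (map
figures, real driver importances, the real-data kappa, red-line areas)
are out of scope and replaced by the same computations on synthetic
hold-outs.

# Problem sizes and test design

The test and acceptance runs use 200×200 landscapes for driver-recovery
checks (10 seeds, dominant driver weighted 3× the others, 50-tree
ensembles, 5000-cell samples), 100×100 landscapes for allocation checks
(10 seeds, demands proportioned like the published comprehensive column
over the ecological classes with built classes at base areas, frozen
arable inside the red line), and 40–60 cell grids for unit fixtures —
sizes at which every property of interest is already expressed and the
whole suite runs in well under a minute. The LP oracle enumerates all
vertices of random 6-variable programs with 9 explicit rows plus
non-negativity; the simplex solution must agree to 1e−8.

# Known limitations

* The published optimal solutions are not reproducible from the published
  objective/constraint system (documented inconsistencies); the package
  flags them in audits rather than guessing unpublished constraints.
* The published 2020 status-quo column totals 33,481.35 km², 0.12 above
  the stated regional total; the fixture transcribes it verbatim, and the
  consistency check over that column reports the discrepancy honestly.
* Single-horizon allocation only (one target year); no multi-epoch
  dynamics, no GPU, and no attempt to reproduce the reference software's
  internal scheduling, which is unspecified.
* The GM(1,1) background bias makes long-horizon forecasts of fast
  exponential growth (≥10%/yr) drift at the 0.1% level per step.
* Raster I/O covers ESRI ASCII grids and single-band TIFF; reprojection,
  resampling and vector geometry are out of scope.
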