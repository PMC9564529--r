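# ecolandopt

Scenario-based optimal allocation of ecological land: coupled
quantity-structure optimization (multi-objective linear programming) and
spatial allocation (patch-generating cellular automaton driven by
random-forest growth probabilities), with ecological-red-line auditing.

## Who this is for

Landscape ecologists and land-use planners who need to (a) decide **how
much** of each land-use class a region should hold under different
human-needs priorities, and (b) decide **where** on the raster landscape
those areas should go. The package works with six classes in a fixed
canonical order — arable, forest, grass, water, residential,
industrial-mining-transport — on projection-agnostic grids whose areas come
from a stated km² per cell.

## The models

**Quantity structure.** Each scenario maximizes a linear objective over the
class areas x₁…x₆ subject to a shared constraint system (fixed regional
total, a population-capacity bracket 120·(x₁+x₂+x₃) + 3000·(x₅+x₆), an
arable floor, a residential bracket, a water floor, and an
ecological-footprint bracket on x₁+…+x₄):

- *security* — ecological-footprint supply, f₁ = 0.02x₁ + 0.08x₂ + 0.45x₃ + 0.16x₄;
- *spiritual* — green-equivalent share, f₂ = (0.33x₁ + x₂ + 0.34x₃ + 0.83x₄)/S;
- *material* — economic benefit, f₃ = Σ Eᵢxᵢ with per-km² benefits
  estimated by GM(1,1) grey forecasting of yearbook series;
- *comprehensive* — the ideal-point normalized weighted sum Σ wₘ fₘ(x)/fₘ*;
- *LD* — a no-intervention baseline: per-class ordinary-least-squares
  extrapolation of historical areas, closed proportionally to the regional
  total.

The per-capita ecological footprint itself is ef = Σⱼ Σᵢ rⱼ·cᵢ/pᵢ over
consumption items, with the published equilibrium factors (arable 1.74,
grass 0.44, forest 1.41, water 0.35).

**Spatial allocation.** A land-expansion analysis fits, per class, a
random-forest vote model P(cell) = (trees voting "converts to k")/M on
driver values (DEM, slope, distances to rail/road/river, population
density, GDP) at cells that expanded between two calibration epochs. The
cellular automaton then iterates: overall probability OP = P·Ω·D (Ω the
windowed neighborhood share of the class, D an adaptive coefficient
tracking the gap to demand), random patch seeding OP = P·r·μ·D on
zero-neighborhood cells, roulette-wheel competition among deficit classes,
and a decreasing acceptance threshold τ — until every class area meets its
demand. Transition rules freeze built land and any frozen mask (e.g. an
arable-protection red line); results are audited inside an ecological
red-line mask.

A synthetic landscape generator (clustered class maps, smooth driver
surfaces, logistic driver-dependent transitions with a known truth)
provides every input, so the whole pipeline is testable without any
downloads.

## Worked example

```r
library(ecolandopt)

# quantity structure: published coefficients and constraints
d <- solveLp(buildLp("security"))
d
#> ScenarioDemand 'security' [optimal], objective 9,693.709
#>      arable      forest       grass       water residential  industrial
#>     3919.27        0.00    17228.81    11639.74      136.49      556.92
auditConstraints(demandAreas(d))$satisfied
#> [1] TRUE TRUE TRUE TRUE TRUE TRUE TRUE

# published scenario table: change accounting
ct <- changeTable(scenarioAreas("security"), scenarioAreas("y2020"))
ct[ct$class == "forest", ]
#>    class   area_a   area_b delta
#> 2 forest 25176.17 24887.55 288.62

# synthetic end-to-end run: generate, fit expansion models, allocate
out <- runPipeline(list(seed = 5, synth = list(rows = 50, cols = 50)))
head(out$areas, 3)
#>   scenario  class area_km2
#> 1 security arable      280
#> 2 security forest     1802
#> 3 security  grass      280
```

The solved security optimum differs from the published one — the published
constraint system does not uniquely reproduce the published solutions (its
own security column violates the printed footprint bound), so the published
table ships as a fixture for accounting while the solver is validated
against an exhaustive vertex-enumeration oracle. The change table shows the
published forest gain of 288.62 km² under the security scenario relative
to 2020, computed from the fixture, not hard-coded.

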