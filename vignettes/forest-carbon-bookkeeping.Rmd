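---
title: "Methods: long-term forest carbon bookkeeping with wildfire, harvest and grazing removals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: long-term forest carbon bookkeeping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firecarbon)
library(dplyr)
```

## The problem

Forest inventories observe carbon *stocks* at widely spaced points in time,
while the processes that move carbon — growth, fire, wood harvest, livestock
grazing in forests — act every year and are recorded by different agencies,
in different units, over different periods, with gaps and discontinued
series. `firecarbon` implements a bookkeeping pipeline that turns this
mosaic into decadal-interval carbon balances for the contiguous United
States and its four broad regions (Northeast, Southeast, Rocky Mountains,
Pacific Coast), and quantifies how sensitive the result is to the most
uncertain inputs.

The accounting identity is

$$\mathrm{NEP} = \Delta C + R_{fire} + R_{harvest} + R_{grazing},$$

all in tC per hectare of total forest per year. $\Delta C$ is the observed
change in biomass carbon stock density between two inventories divided by
the interval length; each removal term is the mean annual per-area flux
over the years of the interval (an interval $[t_0, t_1]$ contains the flux
years $t_0{+}1, \dots, t_1$). Their sum is a proxy for net ecosystem
productivity: every unit of net production either accumulated in the forest
or left it through a quantified removal. Negative $\Delta C$ is allowed and
indicates mortality beyond the quantified removals (insects, windthrow,
drought); such disturbances are deliberately *not* separate terms — they
surface as reduced NEP-attributable stock change.

## Burned-area reconstruction

No single source covers the whole study span (1926–2017 nationally,
1941–2017 regionally). The reconstruction combines:

1. **A national statistical series** (census-style compilations, published
   in acres) for the early decades. Areas are converted with the exact
   definition 1 acre = 0.40468564224 ha.
2. **State-level agency reports** by forest category — commercial *state &
   private* timberland, *federal* forests, and sparse *other forest*
   (wood-, shrub-, scrubland) — aggregated to the four regions.
   State-to-region membership is configuration data, never code.
3. **A regional-totals compilation** of burned area in total forest
   ecosystems. After 1960 the agency reports stop covering state & private
   forests; subtracting the still-covered categories from the regional
   totals recovers the missing component. Small negative residuals are
   treated as reporting noise: clamped to zero and logged as diagnostics,
   because burned area cannot be negative and the sources agree to
   96–100% over their overlaps.
4. **Satellite land-cover class summaries** from 1985 on. Tree-covered
   classes take their category from intersected ownership; shrub/scrub maps
   to other forest; herbaceous classes are excluded and logged.

The national series splices the historical record with the satellite
record at a configurable switch year (default 1985); the satellite source
is authoritative from that year on, and overlapping historical values are
logged, never averaged. Years no source reports — including the configured
regional exclusion window 1980–1984 and the listed missing federal/other
years — are kept as explicit `NA` gaps. Gaps are never interpolated and
never silently zero-filled: balance computations skip them, which matters
because the sources distinguish "no data reported" from "no burning".

## Burned biomass

Burned area becomes carbon via compartment-resolved fuels:

$$B(y) = BA(y) \sum_c FL_c(y)\, CC_c(y) \times f_C,$$

with seven fuel compartments $c$ (duff/litter; dead wood in the 1, 10, 100
and 1000-hour moisture time-lag classes; herbaceous fuels; canopy), fuel
loads $FL_c$ in t dry matter/ha, combustion completeness $CC_c \in [0,1]$,
and carbon fraction $f_C = 0.5$ by default (the standard average carbon
content of dry woody biomass; configurable). Completeness is applied *per
compartment* before summation — not as one aggregate factor — because the
severity sub-variants of the sensitivity design are defined per
compartment.

Category allocation: productive forests (state & private, federal) carry
all seven compartments; sparse other forest carries only duff/litter,
1-hour dead fuels and herbs. Absent compartments are structurally removed,
not zeroed.

Fuel loads are anchored to contemporary field measurements (reference
period 2003–2015 by default) and scaled through time by yearly
multiplicative change coefficients from a fire-enabled vegetation model —
consumed here strictly as inputs. The coefficients are normalised so the
reference-period mean of the resulting timeline equals the base load in
every compartment. Years before the first modeled year (1941) reuse that
year's loads and completeness unchanged (constant back-extrapolation); a
1941-era average would be an alternative, but the first modeled year is
used because it is the only value that requires no further assumption.
Completeness is modeled at the region level and applied to all categories;
this is configurable, as category-specific completeness is plausible but
not separately constrained.

When only the national burned-area record exists (before the regional
span), national burned biomass uses region-area-weighted mean fuel
consumption with a configured category mix; once regional estimates exist
the national series is their sum.

## Removals and stocks

Harvest statistics report extracted stem volume. Whole-tree biomass
destroyed is `stem × (1 + bark + crown) × (1 + root_shoot)`, applied
separately to fuelwood and industrial wood and mixed by the annual
fuelwood share. Central, minimum and maximum factor sets are provided and
ordered per ratio. Grazing is consumed as a prepared flux series. All
fluxes are normalised per hectare of total forest; the denominator is the
*mean* of the interval's two endpoint inventory areas (start-only and
end-only are available switches), a choice that matters only when forest
area changes within an interval.

Interval breaks are configuration data; the defaults are decades with two
irregular intervals (1926–1930 nationally, 1970–1977 everywhere) that
follow inventory timing. Period averages are duration-weighted, which
preserves the balance identity exactly by linearity. Cumulative offsets
integrate each component over time and express it as a share of cumulative
NEP; the removal shares plus the stock-change share sum to 100% by
construction.

## Factorial sensitivity design

Burned-biomass uncertainty is explored factorially, not probabilistically:
two fuel sources (field-measured vs. modeled) × two fuel dynamics (static
reference-period mean vs. dynamic coefficient-scaled) × three static
severity completeness sets (low/moderate/high, ordered per compartment) ×
four regions = 48 regional series. The envelope is the pointwise min/max
over variants. The central estimate (modeled-dynamic fuels with modeled
completeness) is reported alongside the envelope and *not* clipped into
it: the extreme severity sets are understood as unrealistic bounds rather
than a credible interval, so nothing guarantees the central series lies
inside them. Additional toggles (excluding duff, average vs.
category-specific loads) can be expressed by editing the input tables; the
canonical design is the 48.

## The synthetic-world generator

Because the historical inputs cannot be redistributed, every pipeline
stage is validated against seeded synthetic worlds with known ground
truth:

* **Fire truth**: per state × category, a declining exponential trend
  (default rate 0.05/yr over the first five decades, with a small post-2000
  increase) times lognormal year-to-year shocks — burned areas are positive
  and heavy-tailed, so multiplicative lognormal variation is the natural
  noise family.
* **Coverage model**: the generator renders the truth into the four source
  families with configurable spans, discontinued categories (state &
  private after 1960), missing-year lists, an exclusion window, per-category
  underreporting, and per-source reporting noise. Reporting noise is
  multiplicative lognormal with *unit mean* (`meanlog = -sd²/2`), so
  reported values are unbiased on average; this makes the
  noise-vs-recovery-bias question well-posed.
* **Constructive balance**: the per-region NEP trajectory is prescribed
  (linear between configured endpoints); stock densities are then built
  forward as `density(y) = density(y−1) + nep(y) − removals(y)`, so the
  truth satisfies the balance identity exactly before any observation
  noise. Forest area is held constant per region by default, which keeps
  the per-area bookkeeping exact under the mean-denominator convention; an
  area trend would re-introduce a (real, documented) discretisation choice.
* **Determinism**: all draws derive from the single seed through fixed
  per-component sub-seeds, so changing, say, the harvest parameters leaves
  the fire draws untouched, and identical configurations render
  byte-identical files.

What the generator does *not* emulate: spatial structure (no gridded
fires, no polygon intersection), climate forcing, reporting biases that
are correlated across sources, age-structured forest dynamics, and
harvested-wood-product pools. Passing recovery tests therefore shows the
*bookkeeping* is faithful — sources are spliced, subtracted, allocated and
integrated correctly — not that the historical inputs themselves are
accurate.

## Numerical choices and problem sizes

* Gap semantics: a regional year is a gap iff every member state lacks a
  report; removal means skip gap years rather than zero-filling; moving
  averages (default 5-year, centered) shrink their window at series edges
  and skip interior gaps.
* Clamping: negative subtraction residuals are clamped to 0 and logged;
  the count of such events is part of the run manifest.
* Tolerances asserted in the test suite: 1e-9 ha for burned-area recovery
  and conservation, 1e-12 relative for oracle equivalence of the numeric
  kernels, 1e-9 tC/ha/yr for the balance identity, 1e-6 tC/ha/yr for
  noise-free NEP recovery.
* Validation studies in the tests and acceptance script use 31–51-year
  worlds with two states per region and decadal inventories; replicate
  counts are 100 worlds for the identity and noise-bias studies and 200
  randomized cases per numeric kernel. These sizes were chosen as the
  smallest at which every mechanism (splice seam, subtraction era,
  satellite era, irregular intervals) is exercised.

## Limitations

* The pipeline consumes pre-aggregated tables; it performs no GIS and
  cannot detect georeferencing errors in its inputs.
* Other disturbances are not separated from NEP; regions with large
  insect/drought mortality will show depressed NEP rather than an
  attributed loss term.
* The min/max envelope has no probabilistic interpretation.
* Fuel-dynamics coefficients and modeled completeness are trusted inputs;
  errors in them propagate linearly into burned biomass.
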