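---
title: "Methods: realized niche limits and position indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: realized niche limits and position indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichePosition)
```

## The model

A species' *realized* climatic niche is described here by monthly lower and
upper limits of two variables: monthly maximum temperature (degrees C) and
the aridity index, AI = monthly precipitation / monthly potential
evapotranspiration (dimensionless; low values are arid). An environmental
observation `N_i` for that species is rescaled linearly between the limits:

$$PI = \frac{1}{t}\sum_{i=1}^{t}\frac{N_i - N_{min}}{N_{max} - N_{min}}$$

averaged over `t` units (12 when computed over the months of a year).
PI = 0 at the lower (cold/dry) limit and 1 at the upper (hot/wet) limit.
Values outside [0, 1] are meaningful — they mark conditions beyond the
realized niche — so they are reported as-is and flagged `out_of_range`,
never clipped or dropped. Because the index is a ratio of differences it is
invariant under any affine transform applied to value and limits together,
which is why Fahrenheit or Kelvin observations (converted internally via
`toCelsius()`) give bit-identical indices to their Celsius equivalents up
to floating-point rounding.

### Estimating the limits

`estimateLimits()` derives limits from a `ClimateCube` (a
`SummarizedExperiment` of cells x monthly time steps) and a
`SpeciesGeometry`:

1. **Cell selection.** Polygon ranges select every cell whose *center*
   falls inside any polygon (boundary inclusive); occurrence points select
   the unique cells containing each point. An empty selection is an error,
   never an empty table — a silently empty range would propagate as
   missing limits.
2. **Pooling.** For each calendar month, values are pooled over all
   selected cells *and* all years of the reference period. Pooling before
   taking extremes is the simplest rule consistent with a realized
   tolerance limit — the most extreme conditions the species is observed
   to persist through anywhere in its range, any year of the period.
   Cells are not area-weighted (a poleward cell counts as much as an
   equatorial one); this is a documented simplification.
3. **Extremes or quantiles.** The lower/upper limits are the `q` and
   `1 - q` quantiles of the pool. The default `q = 0` gives the absolute
   pooled minimum and maximum. Because absolute extremes are sensitive to
   single outlying cell-years, `q` is exposed (valid range [0, 0.5)) so
   users can trim the tails; quantiles use linear interpolation between
   order statistics (R type 7), stated here so results are stable across
   dialects. Trimmed intervals are always nested inside wider-`q`
   intervals on the same pool.

The reference period defaults to 1961–1975, a pre-warming baseline; any
span inside the cube's years is accepted, and the period, quantile rule
and source are recorded in the table's provenance so limits are never
detached from how they were made.

### Aridity-index guards

AI blows up where PET is very small and is undefined where PET = 0. The
contract is flag-don't-silently-alter: PET = 0 yields a missing AI with
flag `"undefined"` (never an infinity or an exception); an optional
`extreme` threshold flags large ratios without changing them; an optional
`cap` clamps and flags. No cap is applied by default because any cap value
would be arbitrary and silently capped values would bias upper aridity
limits downward.

### Scoring and validity flags

`tpi()`/`api()` join each observation to its species x month x variable
limit row. The join key is the *canonical* binomial (whitespace collapsed,
genus capitalized, epithet lower-cased); when a `SynonymMap` is supplied,
names are resolved to accepted names *before* the join, mirroring a
workflow where name verification precedes scoring. Rows that cannot be
scored get exactly one kind of blocking flag: `bad_binomial` (species
absent from the limits), `bad_month` (month token invalid, or no usable
limit row for that month), `bad_value` (missing measurement; negative AI
is impossible and also flagged), `degenerate_limits` (upper = lower, the
ratio is undefined — a flag, not an infinity, so downstream statistics
never ingest `Inf` silently). `out_of_range` is informative, not blocking.
With flags enabled, output rows equal input rows and every row carries
either an index or a blocking flag. With flags disabled the flag columns
are dropped and unscorable rows are excluded, since without the columns
there is no way to tell a missing index from a meaningful one.

When several measurement columns per row are supplied (`tmp_var`/`ar_var`
as character vectors), a per-column index is computed and the row's index
is the mean over non-missing columns — the same averaging as the
`1/t` sum above, applied across measurements instead of months. `NULL`
(the default) means single-column mode.

## Tunable parameters

| parameter | where | default | units | rationale |
|---|---|---|---|---|
| `period` | `estimateLimits` | 1961–1975 | years | pre-warming baseline period |
| `q` | `estimateLimits` | 0 | — | absolute extremes; raise to trim outlier cell-years |
| `ai_cap` / `extreme` | aridity functions | none | — | flag extremes rather than alter them |
| `tmp_unit` | `tpi` | `"C"` | — | accepts `"F"`, `"K"`; conversion precedes the join |
| `pet_floor` | `synthesizeCube` | 0.1 | mm/month | keeps synthetic AI defined unless a test requests PET = 0 |
| `cell_size` | grids | 1 | degrees | regular lon/lat lattice, cell-center convention |

## The synthetic world

`makeWorld(worldSpec())` builds the test world all validation runs on. Its
defaults are the study conditions: 20 species, 12 months, years 1961–1975,
each species on its own disjoint 3 x 3 block of 1-degree cells, species
envelopes drawn once per species (annual-mean temperature 8–24 °C,
envelope width 6–12 °C, seasonal amplitude 2–6 °C; aridity lower limit
0.2–0.6 with width 0.3–0.8 and a 0.05 seasonal swing) — ranges a
mid-latitude terrestrial vertebrate assemblage would plausibly span. 80%
of regular observations are sampled inside the species' true envelope and
20% are planted outside it.

Two construction choices make validation deterministic rather than
asymptotic:

* **Planted extremes.** Within each species x month, one cell-year is
  assigned exactly the true lower limit and one exactly the true upper
  limit, so `q = 0` recovery is an exact-equality test against ground
  truth, not a statistical one.
* **Power-of-two PET.** Inside species blocks PET is the constant 64
  mm/month and precipitation is `AI * 64`, so the recomputed ratio
  `ppt/pet` is bit-exact and planted aridity extremes survive the round
  trip through the climate cube.

The world also plants one observation per failure mode (a bare-genus
binomial, month 13, a missing temperature, a negative AI, a zero-width
limit row, a value beyond the upper limits, a synonym-submitted name) and
records every intended flag in a ground-truth table; the recorded flags
assume the scoring pipeline is run with the world's synonym map, since
name resolution is part of the intended workflow. The submitted-names
scenario degrades one of the 20 binomials to its bare genus, so exactly 19
match.

What the world does **not** emulate: spatially autocorrelated or
topography-driven climate, range shapes more complex than rectangles,
overlapping ranges, observation error in the climate itself, or real
taxonomy. Passing tests therefore demonstrate correctness of the
*computation* (selection, pooling, scaling, flag logic), not skill of the
realized-limit approach on real range maps — that is an empirical question
outside a synthetic fixture's reach.

## Numerical and design choices

* **Canonical binomials.** Matching is exact on canonical forms; there is
  deliberately no fuzzy matching or spelling correction, so an unmatched
  name is a signal to the user, not a guess. Inputs without exactly two
  tokens are reported unmatched instead of raising, because a bare genus
  in a batch of names is routine and should not abort the batch.
* **Synonym maps are pre-flattened.** A synonym pointing at two accepted
  names, or at a name that is itself a synonym, is rejected at load time;
  this keeps resolution single-step and idempotent, which the tests assert.
* **Month tokens.** Integers 1–12 or case-insensitive 3-letter
  abbreviations only; full month names error with the accepted forms
  listed, rather than being half-supported.
* **Year-average rows.** `yr_avg = TRUE` appends one row per species x
  variable whose lower/upper are arithmetic means over the 12 monthly
  rows (months with missing limits skipped with a warning). Internally the
  month marker is the integer 0, rendered and serialized as `"ALL"`, so
  the month column stays numeric and joinable.
* **Plain-text cube serialization.** Cubes round-trip through one long
  CSV per variable plus a JSON sidecar. Reading validates that all
  variables share one grid and time axis and that PET is present, failing
  at read time with the offending variable named instead of mid-pipeline.
* **Degenerate inputs.** Empty geometry selections, periods outside the
  cube, all-missing months and zero-width limits each have a defined
  outcome (error, error, warn-and-missing, flag) chosen so that failures
  surface where the cause is, not downstream.

Problem sizes used in the shipped tests and acceptance script — a 180-cell
x 15-year world, 1000-replicate property checks — were chosen as the
smallest sizes at which every property is exercised across all species,
months and flag kinds.

## Known limitations

* Limits are realized, not physiological; a species absent from suitable
  climate for non-climatic reasons will look narrower than it is.
* No area-weighting of cells and no handling of coordinate systems other
  than geographic lon/lat on a regular lattice; reprojection and
  downscaling are out of scope.
* `checkBinomials`/`resolveSynonyms` correct formatting, not spelling.
* The pooling rule (cells and years pooled before quantiles) is one
  defensible choice among several — per-cell climatologies first, or
  per-year extremes first, would give different tails; the `q` parameter
  and the provenance record exist so the choice is explicit and
  adjustable rather than silent.
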