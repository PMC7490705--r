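---
title: "Methods: propagule pressure estimation and establishment simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: propagule pressure estimation and establishment simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedflux)
```

## The problem

Refrigerated shipping containers carry hitchhiking plant seeds on their
air-intake grilles. At a busy container terminal, a single commodity route
can deliver nearly two thousand containers over an August–February
season, of which a surveillance team can vacuum-sample only a fraction
during biweekly on-port visits. Three questions follow:

1. How many seeds of a given taxon entered on *all* containers, given
   counts from the sampled ones?
2. How viable are those seeds (germination, seedling survival)?
3. If some fraction escapes onto port greenspace, does a population
   establish?

`seedflux` implements one self-contained analysis for each, plus a
synthetic-data generator that provides ground truth for validating them.

## Estimating total influx

Seeds-per-container varies strongly and non-monotonically over the season
(peaks in mid-autumn, sometimes more than one), so a parametric trend is
unattractive. We use K-nearest-neighbours regression over *sampling
dates*: the predicted rate for any arrival date is the unweighted mean of
the observed per-date rates at the `k` nearest visit dates, with distance
measured in calendar days.

Choices a user should know about:

* **Training points are per-date aggregates**, not individual containers:
  the observed rate for a visit is (total seeds of the taxon) / (number of
  containers sampled that visit), with zero-seed containers counted in the
  denominator. Dropping the zeros would bias every rate upward.
* **`k = 2` by default.** With ~15 visits per season, `k = 2` tracks the
  sharp seasonal peaks; larger `k` flattens them toward the global mean
  (at `k = n` every prediction *is* the global mean).
* **Tie-breaking.** At equal day-distance the earlier date wins, and the
  neighbour list is truncated to exactly `k` after sorting by
  (distance, date). This makes predictions deterministic; with `k = 2`
  and an equidistant pair, both neighbours are averaged, so the rule only
  matters for odd `k` or clustered ties.
* **Extrapolation.** Arrival dates before the first or after the last
  visit use the `k` nearest dates one-sided. Every prediction is a mean
  of observed values, hence bounded by the observed range.

The season total is the exact identity `N = sum(s_hat * containers)` over
all arrival dates; `N` is reported both real-valued and rounded to the
nearest integer.

## Germination and survivorship

Trials plate seeds in dishes of 10 (the last dish may be partial).
Germination is germinated/plated over a 14-day chamber trial;
survivorship is seedlings surviving to transplant into 4″ pots divided by
the number *germinated*, not plated. Taxon-level rates pool raw counts
across dishes — a mean of per-dish percentages would weight a 3-seed dish
like a 10-seed dish. Printed percentages round half away from zero, the
convention consistent with every published pair we tabulate (e.g. 149/164
= 90.85 → 91; 75/160 = 46.875 → 47). Taxa with zero germination get an
`NA` survivorship and a `no_germination` flag rather than an error.

## The establishment model

The simulator tracks *invaded sites* — 1-m² areas holding at least one
reproductive individual — among `S` equally susceptible sites (the
mean-field assumption: no spatial heterogeneity, no competition). Four
processes act multiplicatively:

| parameter | meaning | default / range |
|---|---|---|
| `N` | container-borne seed influx, one season | per-taxon estimate |
| `e` | escape rate from containers (year 1 only) | swept 10⁻⁴–10⁻¹ |
| `g` | germination probability per seed | empirical per taxon |
| `v` | survival probability per seedling | empirical is an upper bound; lower values swept |
| `f` | seeds per established individual per year | lowest literature value per taxon |
| `S` | available sites (carrying capacity) | 1,000 (alternative 100) |
| `T` | horizon, years | 10 |

Year 1: the seed pool is `N * e`. Later years: the pool is
`invaded * f` — local reproduction faces only `g` and `v`, no escape
filter. Established sites never revert (rhizomatous persistence), so
trajectories are non-decreasing and capped at `S`. There is no seed bank:
seeds that fail to germinate in their year are gone. We count the influx
year as year 1, so "invaded sites after four years" is the fourth
trajectory entry.

**Deterministic mode** replaces every transition with its expectation and
carries fractional counts. This is deliberate: the headline regime has
about one expected founder (`N*e*g*v ≈ 1`), and rounding to integers would
extinguish it by fiat. New sites are `min(S - invaded, survivors)`; a
collision-corrected alternative `empty * (1 - (1 - 1/S)^survivors)` is
available behind `collision_correction = TRUE`. The two differ only near
saturation, where both hit the cap within a year of each other.

**Stochastic mode** draws escapes binomially, lands each surviving seed on
a uniformly random site (seeds landing on occupied sites are wasted), and
invades any site with ≥ 1 survivor. Sites are exchangeable, so the
implementation tracks only the invaded count and exploits symmetry rather
than site labels. Two numerical guards: survivors are drawn as a single
binomial thinning (distributionally identical to per-seed Bernoulli
chains), and when expected survivors exceed `50 * S` the year
short-circuits to full occupancy — the probability that any site escapes
being hit is below `S * exp(-50)`, far under floating-point resolution.

The deterministic and stochastic modes agree in expectation while
collisions are negligible (expected escaped seeds ≪ `S`), and the
stochastic extinction fraction at small founder numbers λ = `N*e*g*v`
follows the thinning prediction `(1 - e*g*v)^N ≈ exp(-λ)`; both are
checked in the test suite. They *diverge by design* for tiny fractional
founder numbers combined with enormous fecundity: a deterministic 0.006 of
a founder still multiplies to carrying capacity, whereas most stochastic
replicates never get a founder at all. Sweeps therefore default to
deterministic (the canonical expectation surface) but can take the median
of stochastic replicates, which is the right summary when λ < 1.

Sweeps run one simulation per (taxon, season, `e`, `v`, `S`) cell. The
empirical survivorship is appended to the survival grid as an upper bound
and cells above it are flagged `v_above_observed`, since greenhouse
survivorship likely overstates field survivorship. Per-cell RNG substreams
are derived by hashing the cell key against the master seed, so a sweep is
reproducible cell-by-cell and independent of iteration order.

## What the synthetic generator does and does not emulate

`generate_season()` produces: steady weekly arrivals (default 59
containers × 32 weeks ≈ 1,900 — arrivals in this system are roughly
constant while seed deposition is not), per-container counts from a
negative binomial with variance `m + dispersion * m²` (default
`dispersion = 1`, i.e. variance `m(1+m)`, reflecting strongly
heterogeneous counts; `0` gives Poisson) whose mean follows one or more
Gaussian bumps (default peak around day 100 ≈ mid-November for an August
start, SD 20 days), and biweekly sampling visits. A visit samples each
container that arrived since the previous visit with probability
`sampled_fraction` (default 0.16) and records its counts under the visit
date — this is how a real team samples the containers accumulated on-port
between visits, and it yields season-wide coverage near the nominal
fraction. Explicit zero counts are recorded: they carry information and
enter the rate denominators.

Known departures from real data: container access is uniform rather than
opportunistic; the sampling date proxies the arrival dates of the window
it closes (a ≤ interval/2 timing blur that slightly smooths the estimated
curve); no transit damage, no vacuum-efficiency loss, no multi-port
routing. Recovery tests on this generator therefore show the estimator is
consistent under its own assumptions — unmodelled access bias in real
collections would propagate into `N` undetected.

Validation sizes used by the test suite (chosen as reasonable Monte-Carlo
resolution for the properties asserted): 200 seeded study-scale seasons
for influx recovery (the estimate lands within 25% of truth in ≥ 90% of
them), 500 replicates each for the extinction-probability and
stochastic-vs-deterministic agreement checks at 3 Monte-Carlo-SE
tolerance.

## Degenerate inputs and edge rules

* A sampling date with zero sampled containers never reaches the rate
  series (no division by zero); a date where the taxon is absent is a
  legitimate zero observation and is retained.
* `knn_predict` errors when the series has fewer than `k` points;
  `estimate_total_influx` warns and returns `N = 0` on an empty arrival
  schedule.
* Zero plated seeds is an error for germination; zero germinated seeds is
  an error for the single-taxon survivorship helper and a flag in the
  table-level `tabulate_rates`.
* `N = 0` or `e = 0` gives an identically zero trajectory in both modes.

## Limitations

The model is single-season influx only (no accumulation across seasons),
has no competition, density dependence beyond site saturation, dispersal
kernel, or seed dormancy, and treats one invaded site as one reproducing
unit regardless of how many survivors landed there. The influx estimator
provides no uncertainty interval; a bootstrap over sampling dates would be
the natural extension.
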