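---
title: "Detecting sustained reductions in organizational opioid prescribing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sustained reductions in organizational opioid prescribing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opioidtrends)
```

## The problem

English primary-care dispensing is published monthly by the NHS Business
Services Authority as one row per product, per prescribing organization, per
month, with the number of items (prescriptions issued) and the quantity of
units dispensed. Public-health teams want to find general practices and
their regional groupings (clinical commissioning groups, CCGs) whose opioid
prescribing shows a *sustained, substantial reduction*: such organizations
are candidates for qualitative follow-up, because they may have implemented
an intervention worth copying.

`opioidtrends` implements that surveillance pipeline end to end: three
monthly opioid prescribing measures, a broken-linear-trend change detector
that locates and sizes reductions, a screening cascade for organizations
whose series cannot be interpreted, a peer-relative starting-level filter, a
ranking by proportional reduction, and monthly decile charts. Because the
national dispensing files are large and external, the package also contains
a first-class synthetic panel generator with known injected changes, so
every stage is testable offline and the detector's operating characteristics
can be measured by simulation.

## The three measures

For every organization and month the package computes, from product-level
records and a product reference table:

1. **Total OME per 1000 patients** — the oral morphine equivalence (mg) of
   all opioid prescriptions, divided by the registered list size, times
   1000. Each product carries an OME-per-unit conversion factor
   (`ome_reference()` ships a table of common products).
2. **High-dose opioids as a percentage of regular opioids** — items of
   high-dose regular opioids as a share of items of all regular
   (long-acting) opioids. *Regular* excludes breakthrough-pain preparations
   and injections; *high dose* means an expected intake of at least 120 mg
   OME per day when taken as directed (boundary inclusive).
3. **High-dose opioids per 1000 patients** — the same high-dose item count
   per 1000 registered patients.

Region-level series sum member practices' numerators and denominators
before dividing, as population rates aggregate; averaging practice ratios
would weight a 1500-patient practice like a 15,000-patient one. A month
with a zero denominator yields a *missing* value, never zero: 0/0 carries
no information, and the screening stage counts exactly those months.

## The change detector

Each organization's monthly series $y_t$ over its $T$ observed (non-missing)
months is modelled as a broken linear trend,

$$y_t = \mu + \beta t + \sum_{j} \gamma_j\,(t-j+1)\,\mathbf 1[t \ge j] + \varepsilon_t,$$

with a candidate trend-break indicator at every observed month at least
three months from either end of the series (a break closer to the edge
leaves the baseline trend essentially unidentified, so candidates are
trimmed, as is standard in structural-break estimation). Each indicator
bends the slope from month $j$ onward; a *pair of adjacent* indicators with
offsetting coefficients is a level step. The saturated basis therefore
represents both steep, sudden drops and gradual, smooth declines over many
months.

Model selection proceeds in two stages:

* **Block screening.** Candidates are split into `n_blocks` (default 4)
  contiguous blocks; within each block, backward elimination removes the
  least significant indicator until all retained indicators have two-sided
  $p <$ `alpha` (default 0.01). The partition is applied twice, the second
  time with boundaries shifted by half a block, so an adjacent step pair is
  never split between blocks in both passes. Survivors are pooled.
* **Final selection by event-penalized BIC.** Candidate models are: the
  backward-deletion path from the pooled survivors down to the no-break
  model; all small subsets of the survivors; and every *one-event* model
  over the full candidate range. A *change event* is a run of adjacent
  indicators — one indicator is a slope change, two adjacent indicators a
  step; longer runs are inadmissible because their extra flexibility mostly
  fits one- or two-month noise blips. The selected model minimizes
  $$n\log(\mathrm{RSS}/n) \;+\; 2\log n \;+\; E\,(\log n + 2\log m),$$
  where $E$ is the number of events and $m$ the number of candidate months,
  among models whose indicators are all individually significant at
  `alpha`. The $2\log m$ term is the extreme-value scaling of the best
  chance break over $m$ candidate positions: a spurious indicator, or a
  mutually offsetting cluster of them, explains too little variance to pay
  the penalty, while a genuine break — even a step whose collinear
  indicator pair has only moderate partial $t$-values — pays it easily.
  On noise-free input the residual term collapses and the sparsest exactly
  interpolating model wins, so noiseless piecewise-linear series are
  reproduced exactly; on short series the selection agrees with exhaustive
  best-subset search under BIC, which the test suite checks against a
  brute-force oracle.

Plain backward elimination alone, without the event-penalized comparison,
retains individually "significant" offsetting indicator clusters on most
pure-noise series — a classic stepwise-selection pathology — which is why
the final stage compares whole models rather than single coefficients.

### From fitted path to reported reduction

`extract_reduction()` scans the *break-induced component* of the fitted
path — the path minus its estimated baseline linear trend. On that
component, a reduction episode is a maximal run of declining months; with
no retained breaks the component is constant, so a chance tilt of the base
trend is never reported as a change. Three numerical details matter:

* Slopes smaller than 5% of the steepest fitted slope are treated as flat,
  so a statistically negligible tilt between two distinct break events
  cannot chain them into one long episode.
* A declining run spanning several events is split at each interior event
  start: the drift between events stays with the earlier episode, and a
  later event's episode begins at its own month.
* Episode length is counted in calendar months spanned (pre-drop month to
  end-drop month inclusive), so the default `min_episode_months = 2`
  admits a one-month step, which spans two calendar months.

The **pre-drop value** is the fitted (not raw) level immediately before the
first declining month — robust to single-month spikes — and the **end-drop
value** the fitted level where the decline ends. The reported quantities are
the absolute change (pre-drop minus end-drop) and the proportional change
(as a percentage of the pre-drop value). If several episodes qualify, the
largest absolute change wins, the earlier episode breaking ties; increases
are never reported, and an episode with a non-positive pre-drop level is
discarded because its proportional change is undefined.

### Measured operating characteristics

The detector's operating point under the generator's default noise
(practice-level total OME series with roughly 13% monthly coefficient of
variation) is measured by simulation in the test suite and the acceptance
script: a 30% step at month 30 of a 60-month window is detected with its
start month within ±2 months in about 92% of 200 replicates, and about
4–5% of 500 flat-noise series yield any detected reduction at the default
`alpha = 0.01`. Detected magnitudes of noisy gradual ramps are mildly
conservative, because a short step event can be a more parsimonious fit
than the full ramp.

## Screening, starting-level filter, ranking, summary

Screening removes, in a fixed order: (1) closed or dormant practices; (2)
practices with a list size below 2000 at the latest available month
(configurable to the minimum or mean over the window — the evaluation month
is a design choice, since a single administrative reference month is what a
register would provide); (3) organizations whose measure denominator is
zero in *strictly more than* half the months (30 zero months out of 60 is
retained, 31 removed). Regions are exempt from the first two stages, which
are practice-level administrative facts. Every organization gets exactly
one disposition, so stage counts always sum to the input count and can be
audited from the per-organization report.

The starting-level filter keeps a detected reduction only if the
organization's level immediately before the drop was in the top 20% of its
peers, removing consistently low prescribers from the results. The
reference distribution is the cross-section of all analyzable
organizations' observed values in the candidate's pre-drop month — a
starting level is high or low *relative to peers at that time*. The cutoff
is the $k$-th largest cross-sectional value with $k = \lfloor 0.2 N
\rfloor$ (38 of 191 regions), ties at the cutoff all retained; with every
organization identical, everyone qualifies.

Ranking sorts by proportional change, breaking ties by absolute change and
then organization id, so the table is invariant to input order. Summary
statistics (count, median, quartile-based IQR, range of the proportional
reductions) are computed over *all* detected reductions among analyzable
organizations, before the starting-level filter, which only shapes the
ranking tables.

Decile reports compute the nine monthly deciles (linear-interpolation
quantiles) across organizations with a defined value that month; months
with fewer than two defined values are missing. The highlighted
organization is included in its own decile computation by default (the peer
comparison includes everyone), and charts are emitted together with a CSV
of the plotted arrays so checks can assert on data rather than pixels.

## The synthetic panel generator

`generate_panel()` emulates the published panel shape: practices nested in
regions over a 60-month window (December 2014 – November 2019 by default),
lognormal list sizes, and four synthetic products — a standard regular
opioid, a high-dose regular opioid (180 mg OME/day), a breakthrough opioid
and a non-opioid. Item counts are negative binomial around a deterministic
trajectory; quantities are items times a fixed pack size; and the standard
product's OME factor is solved so the noiseless total OME per 1000 patients
equals the configured baseline exactly. With `noise_dispersion = 0` the
trajectory is returned exactly (counts may then be non-integer — exactness
of the closed-form curve takes precedence in the noiseless limit).

Key generator choices, fixed once as the study conditions:

* **Noise.** `noise_dispersion = 0.02` (negative-binomial size 50). The
  source data's monthly noise is not characterized anywhere authoritative,
  so this is the package's calibration: practice-level monthly totals with
  a coefficient of variation around 13%, the stability a practice of ~7000
  patients with a few hundred opioid items a month plausibly shows.
* **Injected changes** multiply *all* opioid products uniformly, so the
  OME-per-1000 and high-dose-per-1000 measures fall by exactly the injected
  proportional reduction, while the high-dose-percentage measure stays
  flat under a uniform reduction. Ground-truth levels refer to the
  OME-per-1000 measure. A step completes within one month; a ramp
  interpolates linearly over its duration.
* **Special practices.** Closed or dormant practices emit zero items and
  zero list size after a closure month drawn from the middle of the
  window; zero-denominator practices get a zero list size in 60% of
  months (safely more than half, with the final month kept nonzero so the
  list-size screen reads a real value); small practices draw a list size
  uniformly between 800 and 1999. The bulk list-size distribution is a
  lognormal truncated below at 2000, so composition counts (for example
  7458 practices with 678 closed and 237 small leaving 6543 analyzable)
  are exact by construction.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: seasonality, secular national trends, BNF product
granularity, practice list-size drift and mergers, region reassignment over
time, and any correlation of noise across months or neighboring practices.
Simulation results bound the detector's behavior under idealized
independent overdispersed noise only.

## Pipeline, determinism, problem sizes

`run_pipeline()` executes generate (or load a CSV fixture) → measures →
screening → detection → summary → starting-level filter → ranking →
deciles (→ charts) for each requested measure and level, staging outputs
and moving them into the output directory only when every stage succeeds.
All thresholds (2000-patient list size, 0.5 zero-denominator fraction, 0.2
top fraction, 120 mg/day high-dose cutoff, `alpha`) are configuration with
the defaults above, never constants buried in stage logic. A manifest
records configuration, seed, package version and per-stage counts; reruns
with the same configuration and seed are byte-identical. A thin command
line (`inst/scripts/opioid-pipeline.R`) wraps `simulate` and `run` for
shell use.

The simulation sizes used by the test suite and `scripts/acceptance.R` —
200 replicates for break-timing recovery, 500 for the false-positive share,
a single 7458-practice noiseless panel for the screening-cascade
composition — are the package's chosen compromise between Monte-Carlo error
(about ±2 percentage points on a 90% rate at 200 replicates) and runtime.

## Known limitations

* The detector's break-event grammar (slope changes and one-month steps)
  under-represents compound shapes such as a step immediately followed by
  a ramp; these are approximated by nearby admissible events.
* Magnitudes of gradual ramps under noise are mildly underestimated when a
  shorter event is the more parsimonious fit.
* A genuinely linear decline spanning the whole window is absorbed by the
  baseline trend and not reported as a change — by design, since it has no
  locatable start.
* The starting-level filter compares a fitted pre-drop level against
  observed peer values; in noiseless degenerate panels this is exact, in
  noisy data it mixes smoothed and raw quantities.
* Screening evaluates the list size at a single reference month; a
  practice shrinking through the threshold mid-window is kept or dropped
  wholesale.
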