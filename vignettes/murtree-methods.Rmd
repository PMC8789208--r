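---
title: "Predicting medical usage at mass gatherings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting medical usage at mass gatherings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(murtree)
```

## The problem

Organisations providing onsite first aid at mass gatherings — festivals,
dance events, recreational sports events — need to size their deployment
before the event. The two planning quantities are the **patient
presentation rate** (PPR, patients presenting at onsite care posts per
10,000 attendees) and the **transfer to hospital rate** (TTHR, ambulance
transfers per 10,000 attendees). Both vary over two orders of magnitude
between event types, and classical linear or Poisson regressions have
predicted them poorly. `murtree` implements a nonlinear alternative: a
recursive-partitioning regression tree over categorical event descriptors,
refined by a linear temperature adjustment for outdoor summer events, and
cascaded into a second tree for TTHR.

The unit of analysis is the *event edition* (one year of one recurring mass
gathering). Editions are aggregated from patient encounter forms (PEFs):

* `ppr = 10000 * n_patients / attendance`, counting every encounter dated
  on an official event day regardless of missing fields, and excluding
  encounters dated the day before or after (arrival/departure days of
  campers);
* `tthr = 10000 * n_transfers / attendance`, counting only transfers by
  ambulance; transport by own means is not a transfer, and a missing
  dismissal destination counts as a non-transfer. This is the conservative
  reading: the dominant "back to the event" destination is the one most
  often left blank on real forms, so if anything the registry's TTHR is
  slightly overestimated, never underestimated, by this rule.

## Predictor categorization

The tree engine deliberately takes only categorical predictors —
dichotomising continuous variables inside a tree fit is known to be
unstable, so all categorization happens *a priori*, blinded to outcomes:

* **attendance class**: six bins, half-open on the right —
  [0, 10k), [10k, 20k), [20k, 30k), [30k, 100k), [100k, 1M), [1M, ∞).
  The published class labels overlap at the boundaries, so a convention is
  required; the half-open one is consistent with the worked examples
  (12,000 attendees in class 1, 37,000 in class 3).
* **age class** of the patient population, from the median, Q1 and IQR of
  non-missing PEF ages (quantile type 7, the inclusive linear-interpolation
  convention). A broad spread marks the mixed/family class and takes
  precedence: Q1 < 21 y with IQR > 20 y, or Q1 < 18 y with IQR > 15 y.
  Otherwise the median decides: children (< 16), young adults (16–30),
  middle adults (> 30).
* **days class**: 1, 2, 3+ official days.
* the remaining six enter as recorded: category (6 levels), timing,
  alcohol availability, indoor, bounded, camping.

Missing attendance is resolved by exactly two rules (one interior missing
year interpolated as the mean of its neighbours; sold-out editions copying
the first edition's figure) and every imputed value carries a provenance
flag. Anything else is an explicit error — no other imputation is
attempted.

## The regression tree engine

`grow_tree()` implements CART-style recursive binary partitioning for a
continuous outcome:

* At each node, for each predictor, every binary partition of the observed
  levels is scored by its reduction in the sum of squared errors,
  `SSE(parent) − SSE(left) − SSE(right)`. Nominal predictors are searched
  by exhaustive subset enumeration (at most 2^k − 2 candidates; the levels
  here never exceed 8, and the classical sort-by-node-mean shortcut is
  verified against the exhaustive search in the test suite). Ordered
  predictors (attendance, days, hospital-proximity bins) only admit
  order-respecting cuts.
* A split is kept only if its reduction is at least `cp` times the **root**
  SSE (default `cp = 0.01`: a split must reduce the overall lack of fit by
  at least 1%), the node holds at least `minsplit` observations, and its
  depth is below `maxdepth`.
* Node predictions are training means; nodes are numbered heap-style
  (root 1, children of *k* are 2*k* and 2*k* + 1), so the printed tree and
  serialized JSON are directly comparable across runs.
* At every split, **surrogate splits** are recorded: for each other
  predictor, the partition best mimicking the primary left/right
  assignment, kept only if it beats the majority-direction baseline and
  ranked by agreement. Prediction for an event whose level was never seen
  at a split falls back to the first applicable surrogate, then to the
  majority direction (ties route left, deterministically; an error is
  raised only when the split variable is entirely missing, no surrogate
  applies and the children are tied).
* **Variable importance** credits each predictor with the SSE reductions
  of its primary splits plus agreement-weighted reductions for its
  surrogate roles, normalized to percentages. The surrogate weighting is a
  documented package choice (agreement × primary reduction).

Ties anywhere are broken deterministically: equal split reductions go to
the variable declared earlier, then to the lexicographically smaller left
level set; equal grid cross-validation errors go to fewer leaves, then the
smaller `(minsplit, maxdepth)`.

### Model selection

`grid_search()` follows the published protocol: all `minsplit` values 5–20
crossed with all `maxdepth` values 8–15 — 128 models — each scored by
10-fold cross-validation at fixed `cp = 0.01`, selecting the model with
minimal cross-validated relative error (`xerror`, held-out SSE divided by
the root SSE of the full data). The 1-SE pruning rule is *not* used; the
protocol selects the minimal `xerror` outright. Fold assignment is a
seeded balanced permutation, shared across the grid so all 128 models are
compared on identical folds, and each fold's trees are refit at the fixed
configuration (not cp-sequence pruned).

Internally the grid is evaluated by growing one *maximal* tree per fold at
the loosest gates and re-reading each configuration as a pruned view: the
split chosen at a node does not depend on `minsplit`/`maxdepth` (they only
gate whether splitting is attempted) and gate-passing is upward-closed
along any root-to-leaf path, so the pruned view is exactly the tree direct
growth would produce. The test suite asserts this equivalence against
per-configuration refits, and cross-checks fitted trees against `rpart` on
a fixture.

## Temperature adjustment

Ambient temperature acts on presentations approximately linearly over the
Belgian summer range, so it is kept continuous and applied *after* the
tree: `fit_daily_linear()` regresses daily PPR on daily temperature (24 h
average or daily maximum) over the day-level records of a reference
multi-day festival — the only event type with daily attendance, hence
daily PPR; nine editions of four days give 36 points. The fit transfers to
any event *i* proportionally:

PPR_adj = PPR_tree,i + (PPR_tree,i / PPR_ref) × b × (T − T_pivot)

where `b` is the fitted slope, `PPR_ref` the tree-predicted PPR of the
reference event, and `T_pivot = (PPR_ref − intercept)/b` the temperature
at which the fitted line passes through `PPR_ref` — so at the pivot the
adjustment vanishes identically, and the additive correction scales with
the event's own predicted rate. The published coefficients are slope 10.6
PPR/°C with pivot 20.4 °C on the 24 h average, and 7.6 with 25.6 °C on the
daily maximum, both against a reference prediction of 183 per 10,000;
`adjustment_params()` accepts them directly.

The adjustment applies only to outdoor events whose official days all fall
in June–September (an event straddling May 31–June 1 is not adjusted; no
straddling rule is published, so the conservative all-days rule is used).
Multi-day events use the unweighted mean temperature over official days.
Negative adjusted values, possible under the linear form at unseasonably
low temperatures, are floored at 0. Humidity and heat index are
deliberately not modelled: the conditions under which they matter are rare
in a maritime temperate climate.

TTHR is *never* temperature-adjusted: `check_temperature_association()`
fits the same daily model to transfer rates and returns a verdict
(associated if the two-sided slope p-value is below 0.05); on the
reference event's data, daily TTHR shows no association, and the pipeline
asserts the verdict before leaving TTHR predictions untouched.

## The cascaded TTHR model

`build_tthr_features()` routes every event through the fitted, unadjusted
PPR tree and adds its terminal-node id as a categorical predictor
(`ppr_node`) — predicted PPR enters as the node label rather than the
numeric leaf mean, matching how published TTHR trees label their splits by
PPR-model node numbers, and using *predicted* rather than observed PPR to
reflect how the model is used prospectively. Hospital proximity enters as
ordered bins (≤ 5, 5–15, > 15 km; ≤ 10, 10–20, > 20 min; the engine takes
categorical predictors and the bins are config-overridable). With the nine
base predictors this gives 12 candidates; `fit_tthr()` runs the identical
128-point grid-search protocol.

## Calibration and validation

`validate()` applies a serialized model bundle to a categorized dataset —
development, temporal (later editions of the same events) or external
(events never used for development) — without any refitting, and reports
per variant (crude, T_av-adjusted, T_max-adjusted PPR; crude TTHR):

* **R²** as the squared Pearson correlation between observed and predicted
  rates. On training data this equals 1 − rel error of the tree (asserted
  to 1e-12 in the tests). Correlation is affine-invariant, so this R² does
  not measure bias — the deviation bands are the bias-sensitive
  complement, and both facts are asserted in the test suite.
* a **95% confidence interval** for R². The published analyses do not
  state their CI method; the default here is the Fisher z-transform
  interval on r with endpoints squared and clipped to [0, 1] (the lower
  bound collapses to 0 when the r-interval straddles zero, making the
  interval conservative near R² = 0). A seeded bootstrap percentile
  interval (2000 resamples) is available as `method = "bootstrap"`, and
  the method used is recorded in the report.
* **deviation bands**: the count of events whose prediction lies within
  25% of the observed rate (`|pred − obs| ≤ 0.25 × obs`, boundary
  inclusive — the published figures draw the band without stating
  inclusivity), plus flags for >50% over- and under-prediction. Events
  with observed 0 but positive prediction have an undefined ratio and are
  excluded from band counts, reported separately; the partition
  `within + outside + undefined = n` is a tested invariant.

## The synthetic registry generator

The registry that motivated this package is not public, so
`generate_registry()` produces registries with the same *shape* and a
known ground truth; it is first-class, tested code and doubles as the
parameter-recovery harness.

What it emulates: recurring series with editions (default 25 series × 8
editions = 200 events); the development-set category mix (44% outdoor
music, 19% city festivals, 11% outdoor EDM, 10% each indoor EDM and
sports, 6% indoor dance), apportioned to series deterministically by
largest remainder so group sizes are stable; attendance spanning 10⁴–1.5M
(the development eligibility floor of 10,000 attendees is respected);
per-class age mixtures with 23% missing age; 10% missing dismissal (masked
only on non-transfer forms — mirroring that the routine "back to the
event" destination is the one forgotten in practice, and keeping the
transfer ground truth recoverable); daily temperatures from a seasonal
sinusoid with noise, or frozen at a constant for oracle runs.

Ground truth: expected PPR is piecewise-constant over predictor profiles —
category, plus a days split inside outdoor music — with values
12/64/120/176/225/273 per 10,000, spanning the leaf range a fitted model
produces in practice. The two small indoor categories share a rate (indoor
dance crowds present like indoor EDM crowds): with a 1%-of-root-SSE
complexity gate, a rate group needs either size or separation to be
detectable, and giving every distinct rate a group of at least ~16 events
with gaps of ~50 keeps each generating split above the gate by a ~1.5×
margin at the default noise. Outdoor summer events additionally receive
the linear temperature term `true/reference × slope × (T − pivot)`
(defaults: slope 7.6 on the daily maximum, pivot 25.6 °C).
The transfer is anchored at the long-festival rate
(`reference_ppr = 273`), so the registry's temperature law and the
generated day-level reference series share one anchor — and the fitted
pipeline, which anchors at the adjustable event with the highest
tree-predicted PPR, recovers a pivot close to the generating one.
Expected TTHR is keyed to the PPR profile, spanning 0.3–5.9 with indoor
EDM highest; neighbouring values are deliberately close, so — as in real
TTHR trees — the complexity gate lumps some of them at realistic transfer
counts.

Noise model: realized patient counts are Poisson with mean
`attendance × (expected PPR + N(0, noise_sd)) / 10⁴` (noise_sd in
per-10,000 units, default 5, i.e. about 10% of the smallest between-group
gap). Additive event-level noise was chosen over a lognormal
overdispersion factor so that `noise_sd` is directly comparable to the
between-group gaps that determine recoverability. `noise_sd = 0` is the
degenerate oracle mode: event noise *and* count sampling are switched off
and counts are deterministic rounded expectations, so the pipeline must
reproduce the ground truth exactly up to per-event count rounding
(≤ 10⁴/(2 × attendance) ≤ 0.5 per 10,000).

What it does **not** emulate — and hence what passing tests do not show
about real data: within-event temporal dynamics (presentation rates rise
over multi-day events; generated day-level rates are exchangeable),
music-genre and sports-type heterogeneity inside categories,
care-post visibility and staffing effects, weather-station versus onsite
temperature error, and rounding of attendance figures by organisers. Real
registries also break the piecewise-constant assumption outright — the
published external validations collapse to R² ≈ 0.02–0.03 — and the
generator can mimic that regime only by scrambling its effect map
(`test-validation.R` does exactly that).

## Recovery study and known limitations

The package's own recovery study (run by the acceptance script and the
test suite: 100 registries of 200 events at default noise, full
grid-search selection per registry) realizes **every generating split in
100%** of registries; requiring additionally that *every* leaf mean lie
within 2 standard errors of its generating value passes in **90%**. The
misses are all joint-band effects, not bias: with ~6 leaves per tree, a
2-SE requirement on every leaf simultaneously is expected to fail in a
nontrivial fraction of registries for *any* unbiased estimator, and the
observed misses sit at 2.0–2.8 SE with no systematic sign. Temperature
spread inside outdoor leaves widens their observed standard deviations
(hence their bands), which is why the joint rate sits above the naive
0.95⁶ ≈ 0.74.

Other limitations worth knowing:

* `xerror` is computed by refitting each fold at the fixed configuration;
  it is not guaranteed to match `rpart`'s internal cp-sequence
  cross-validation number for number, though fitted trees themselves are
  cross-checked against `rpart`.
* The reported `xstd` is a delta-method approximation
  (`sd(per-observation squared errors) × √n / SSE₀`).
* Squared-correlation R² rewards any monotone association; a model wrong
  by a constant factor still calibrates perfectly on R². Use the deviation
  bands alongside it.
* Problem sizes in the tests (200-event registries, 100-seed studies,
  500-seed slope recovery, 1000-draw coverage checks) were chosen to give
  each statistical assertion a standard error well below its tolerance
  while keeping a full run in minutes on one core.

## Worked pipeline

```{r pipeline}
library(murtree)

reg  <- generate_registry(synth_config(seed = 1))
agg  <- aggregate_events(reg$events, reg$encounters)
daily <- generate_reference_daily(synth_config(seed = 1))

model <- fit_mur_model(agg, daily, seed = 1)
print(model)
print(model$ppr_tree)
autoplot(model$ppr_tree)            # variable importance

val <- validate(model, agg, "development",
                temperatures = reg$temperatures)
glance(val)
autoplot(val$ppr$t_max, scale = "log")
```
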