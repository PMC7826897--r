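---
title: "Modular welfare grading: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular welfare grading: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishwelfare)
```

## The model

`fishwelfare` grades fish welfare on a farm from a single visit's
measurements.  Its theoretical frame is allostatic load: every stressor
acting on a fish incurs a physiological cost, costs accumulate across
stressors, and more severe stressors cost more.  The model therefore
(1) discretises every measured parameter into intervals with a
*parameter score* `PS` between 0 (no or positive influence on welfare)
and −1 (negative influence), (2) weights each interval by a *score
weight* `SW` from 1 (low or no stress) to 5 (strong, long or frequent
stress), (3) weights each parameter by a *parameter weight* `PW` from 1
to 5 expressing its relative importance, and (4) sums the weighted
scores within each of five modules — farm management (M), water quality
(W), fish group behaviour (FG), fish external appearance (FE) and fish
internal appearance (FI).  The module grade is

$$MG \;=\; 1 + \frac{\sum_i PS_i \, SW_i^{SWE} \, PW_i^{PWE}}
                    {\sum_i SW_i^{SWE} \, PW_i^{PWE}},$$

with *weight exponents* `SWE = PWE = 1.7` for W, FG, FE and FI and
`SWE = 0` for M, where interval severity acts on welfare only
indirectly and a dynamic score weight is not needed.  Grades map onto
four categories: critical `[0, 0.25)`, poor `[0.25, 0.5)`, acceptable
`[0.5, 0.75)`, good `[0.75, 1]`.  There is deliberately **no** overall
index across modules: five separate grades preserve the resolution
needed to locate a problem.

### Why the exponents appear in the denominator

One rendering of the grade equation normalises by
$\sum_i SW_i \, PW_i$ *without* exponents.  That form is not
range-safe: a single parameter at `PS = −1`, `SW = PW = 5` contributes
$-5^{3.4} \approx -239$ against a denominator of 25, driving the
"grade" far below zero, which contradicts the model's stated `[0, 1]`
range and its category brackets.  This package therefore applies the
same exponent-weighted terms in numerator and denominator, making `MG`
a weighted mean of `1 + PS`.  The guarantees follow immediately:
`MG ∈ [0, 1]`, `MG = 1` exactly when all scores are 0, `MG = 0` exactly
when all scores are −1, and `MG` is invariant under duplicating the
scored set.  The tests pin all four properties, plus equivalence with an
independently coded direct summation at a relative tolerance of 1e−12.

### Missing data

A parameter that was not measured or does not apply (predator
protection indoors, ambient light outdoors, several water parameters in
flow-through systems) is recorded `NA` and excluded from numerator *and*
denominator.  Grades therefore remain comparable across farms with
different applicable parameter sets.  A module with no measured
parameter at all is omitted from the result with a notice rather than
graded 1.0: absence of evidence is not good welfare.

### Per-fish sampling

External- and internal-appearance parameters are scored on individual
fish; their per-fish `PS` and `SW` are averaged arithmetically per
parameter before grading, so effective weights may be non-integer.
Fewer than three fish trigger a warning (unreliable); ten is a practical
upper bound because sampling dominates assessment time.  Alternative
aggregation readings (median interval, grade-then-average) were
considered; the arithmetic mean of scores is the default because it is
the only reading that commutes with the equation's linearity in `PS`
and keeps effective scores inside `[−1, 0]`.

## The registry and what is (not) calibrated

The shipped default configuration (`default_model_config()`) carries 80
parameters: 18 in M (three intervals each — diverse management facts
need coarse, easily judged states), 14 in W (nominally four intervals;
two-sided parameters such as pH or temperature use extra intervals so
that each side of the optimum is covered), 20 in FG (six intervals,
encoding severity together with abundance), 18 in FE and 10 in FI (four
intervals).  Interval index 0 is always the optimal interval with
`PS = 0`, `SW = 1`; indices increase with severity.

Two provenance layers must be distinguished.  The *structure* —
module layout, parameter names, interval counts, the exponents, the
index-0 convention — follows the published model.  The *per-interval
numbers* are a reconstruction, because the original per-parameter score
tables and the expert-survey weight medians are not redistributable
here: parameter scores are spaced linearly from 0 to −1 over each
parameter's severity ranks (the documented default for newly authored
parameters), score weights scale linearly from 1 to 5 over the ranks,
every `PW` is 3 (the documented default absent evidence for more or
less relevance), and numeric water-quality boundaries follow common
freshwater grow-out guidance (e.g. temperature optimal in 8–26 °C
across the covered species, dissolved oxygen optimal at ≥ 8 mg/L).
Consequently the packaged six-farm fixtures reproduce the original
campaign's grades exactly where the structure forces it (an all-optimal
column grades 1.00 regardless of weights) and track the remaining
grades closely but not to two decimals.  Users with a calibrated
registry load it with `load_model_config()`; nothing in the engine is
specific to the shipped numbers.

Numeric intervals are half-open `[lower, upper)`.  This makes
assignment at printed thresholds deterministic ("10–16 °C" puts exactly
16 into the next interval) and is flagged in the configuration's
provenance because printed boundaries rarely state their inclusivity.
Open outer ranges use `±Inf` sentinels.  Regulatory overrides
(`apply_overrides()`) swap a parameter's interval table for a
jurisdiction-specific one and are validated like any other intervals.

## Derived measures

Three parameters are calculated, not measured:

* **Unionized ammonia** uses the freshwater Emerson equilibrium,
  `pKa = 0.09018 + 2729.92/T(K)`, `NH3‑N = TAN/(1 + 10^{pKa − pH})`.
  This formulation reproduces both recorded farm values (0.001 and
  0.005 mg/L) at the reported precision; salinity corrections are out
  of scope for the freshwater systems covered.
* **Oxygen saturation** divides measured dissolved oxygen by the
  Benson–Krause equilibrium concentration, with an optional barometric
  pressure argument (default 1 atm).  The recorded farm saturations are
  only consistent with sub-sea-level site pressures, so they ship as
  fixture inputs and are not asserted against this function; the
  solubility itself is tested against standard freshwater tables to
  0.5 %.
* **Fulton's condition factor** is `100·W/L³` with *standard* length:
  verified against all six recorded farm values, which total length
  does not reproduce.

Display rounding matches the campaign tables (grades to two decimals,
ammonia to three, condition factor to two significant figures) and
rounds half away from zero; internal computation is never rounded, and
categories are always derived from the unrounded grade.

## The exponent-calibration harness

`calibrate_exponents()` reproduces the original calibration procedure
in miniature: candidate exponents (with `SWE = PWE` to keep the two
weights balanced) are applied to scored data sets whose intended
category is known, and the candidate minimising misclassifications
wins, ties breaking toward the smallest exponent.  The tests construct
boundary data sets by inverting the grade equation around the 0.25
category boundary — with scores `(0, −1)` and score weights `(1, s)`,
the grade crosses 0.25 exactly at exponent `log 3 / log s` — and verify
that only 1.7 on a 1.0–2.5 grid classifies both sets correctly.

## The synthetic-assessment generator

`generate_assessment()` emulates a single farm visit against any valid
configuration: a severity profile (`optimal`, `worst`, `mixed`,
`random`), a per-parameter missing probability, and 1–10 fish for
per-fish parameters.  Numeric values are drawn uniformly inside the
chosen interval (infinite bounds clipped by the parameter's largest
finite interval width) so drawn values provably resolve back to their
interval.  Output is a pure function of the seed, and the caller's RNG
state is restored.  What it does **not** emulate: correlation between
parameters (low oxygen co-occurring with high ventilation rates),
temporal dynamics, measurement error, or inter-observer variation in
ordinal judgements — so passing property tests demonstrate engine
correctness, not field validity of the registry.

## Numerical choices and degenerate inputs

* Worst-profile generation picks the lowest-`PS` interval, ties broken
  toward the highest index (most severe).
* `resolve_interval()` never returns a silent `NA`: values outside the
  covered range and unknown ordinal labels are errors naming the
  parameter, because they indicate a configuration/measurement
  mismatch.
* Validation collects *all* configuration violations in one error
  message, each naming the offending parameter and rule.
* Reports embed a checksum of the configuration; comparing reports
  graded under different configurations is refused, not silently
  merged.  Report timestamps come from the assessment, so identical
  inputs give byte-identical reports.
* An assessment with duplicate `(parameter, fish)` measurements is
  rejected at construction.

## Known limitations

* **Local non-monotonicity.**  Because severity raises the score weight
  and the grade is a weighted mean, degrading one previously optimal
  parameter by a small step can *raise* the grade of a module whose
  other parameters are much worse: the new, heavier term sits above the
  old mean.  The effect is confined to extreme mixtures; degradation is
  provably strictly grade-decreasing whenever the weight is unchanged
  or the new score does not exceed the mean of the remaining
  parameters, and the property tests cover exactly those regimes.  The
  same caveat applies to the non-exponent denominator rendering, so it
  is a property of severity-weighted means, not of this package's
  denominator choice.
* **Species breadth.**  The reconstructed water-quality intervals span
  salmonid and percid grow-out jointly; a species-specific registry
  (e.g. narrower thermal optima) should be supplied via
  `load_model_config()` for serious use.
* **Ontology excerpt.**  The packaged ontology carries the full needs
  list and the model parameters, but only an illustrative excerpt of
  the correlation network around respiration and nutrition; the full
  published network is hundreds of parameters dense.

## Problem sizes used by the test suite

Property suites run 500 random scored sets against the independent
equation oracle, 200 single-parameter degradation perturbations, 100
seed pairs for generator entropy, and 40–60 random resolutions per
numeric parameter against a linear-scan oracle; all suites complete in
well under a minute on one CPU.
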