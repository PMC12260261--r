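---
title: "Leaf-open-time attainment: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leaf-open-time attainment: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lotqa)
```

## The delivery model

A helical tomotherapy delivery is a sequence of projections — 51 angular
segments per gantry rotation — during each of which any of the 64 binary
MLC leaves may open for a prescribed **leaf open time** (LOT). A plan is
therefore a projection × leaf matrix of LOTs in milliseconds, the
*sinogram*. The projection duration is `gantry_period_s / 51` (e.g.
650.6 ms for a 33.18 s SBRT rotation), and the number of projections is
`round(beam_on_time_s / projection_duration)`. An in-head optical sensor
reports the delivered LOTs at roughly 3 ms resolution, which makes a
purely timing-based delivery audit possible.

## The attainment statistic

For every planned opening (planned LOT > 0) we pair the measured LOT at
the same (projection, leaf) cell and form the signed difference
Δ = measured − planned. Binning the Δ values with width *w* gives the
difference histogram ΔLOT(t); the **attainment rate** is its zero bin
divided by its integral:

η = ΔLOT(0) / ∑ₜ ΔLOT(t)

Three reading rules matter and are fixed in code:

* **Event-level pairing.** The statistic counts *instances* of zero
  difference, so Δ is computed per event, not by subtracting two marginal
  LOT histograms. The denominator is the planned-opening count.
* **Failed openings stay in the denominator.** A planned opening the MLC
  never executed contributes Δ = −planned (usually the negative overflow
  bin). Conversely, measured openings where the plan is closed are
  reported in a side channel (`extra_measured`) and never enter η — the
  denominator is defined by the plan.
* **Zero-LOT exclusion.** Closed leaves (LOT = 0 in the plan) are not
  events; LOT histograms likewise exclude zeros.

The default bin width is 5 ms, so "attained" means |Δ| ≤ 2.5 ms; boundary
ties resolve toward the zero bin. Δ is kept signed (latency can be early
or late); an absolute-difference variant would only merge symmetric bins
and cannot change η. η is reported as a percentage rounded to three
decimals.

```{r worked}
attainment_rate(11736, 12160)
```

## The synthetic delivery generator

No public telemetry from clinical deliveries exists, so the package ships
a generator whose defaults emulate a realistic clinical cohort. What it
reproduces, and how:

* **Site archetypes** (`site_archetypes()`): per-site field width, pitch,
  modulation factor, beam-on time and gantry period for prostate, pelvis,
  head, chest, H&N and lung SBRT plans, at cohort-mean values typical of
  clinical practice on this platform.
* **Planned LOTs**: leaves in the central half of the bank open with
  probability 0.7 per projection; nonzero LOTs are drawn from a
  long-tailed beta(0.8, 3) shape scaled to the projection duration and
  affinely rescaled so the realized modulation factor (max/mean of
  nonzero LOTs) matches the requested one exactly, capped at 95% of the
  projection duration. The per-site LOT *distributions* are a modeling
  choice — only their aggregate parameters are constrained — so plans are
  plausible stand-ins, not reconstructions of any clinical plan.
* **Error model**: measured = planned + latency + jitter, clamped to
  [0, projection duration], quantized to the sensor grid; openings drop
  (measure 0) with a small probability. Latency is drawn once per
  fraction — it models plan-level delay, which is systematic within a
  session — while jitter is per event. Defaults (latency 0.5 ± 0.3 ms,
  jitter 0.8 ms, drops 0.2%, 3 ms quantization) were chosen so cohort
  attainment lands in the low-to-mid 90s regime reported for clinical
  deliveries; they are study conditions, not tuning knobs.
* **Synthetic gamma pass rates**: `100 − a·(100 − η%) + noise`, clamped
  to [0, 100]. This is plumbing to exercise the correlation machinery —
  no claim is made that gamma analysis is generatively linked to η.
* **Detector trend**: baseline exit-detector signal 1.0 with 0.01 noise
  SD; anomalous fractions are depressed multiplicatively and
  simultaneously receive extra jitter of 60·depth ms, so a 10% signal dip
  comes with ~6 ms extra jitter and η collapses on the same fractions.
  The factor 60 makes the attainment dip unambiguous relative to the
  ±2.5 ms zero bin; only the *co-decline*, not its magnitude, is the
  modeled phenomenon.

What the generator does **not** emulate: dose, beam output, couch/gantry
kinematics, anatomy-driven modulation structure, intra-fraction motion,
or any correlation between neighbouring leaves or projections (events are
independent). Tests passing on this generator therefore validate the
statistic and its plumbing, not machine-specific behavior of real MLCs.

## Numerical choices

* **Clamp before quantize.** Raw measured times are clamped to
  [0, projection duration] first, then quantized (ties half away from
  zero), then capped at the largest grid multiple inside the projection.
  The order is fixed for bit-reproducibility.
* **Quantization never breaks attainment by itself**: the 3 ms grid
  perturbs an event by at most 1.5 ms, inside the 2.5 ms zero bin — so a
  zero-noise delivery attains 100.000% even when planned LOTs are off the
  grid.
* **Binning.** Bin index is `sign(Δ)·ceiling(|Δ|/w − 0.5)`: nearest
  center, half-width ties toward zero. The grid spans ±20 bins by
  default with two overflow bins, so counts always sum to the planned
  event total.
* **Seeding.** Every stochastic function takes an explicit seed;
  per-fraction streams are derived with a fixed integer mix, and draws
  use fixed-count standard-normal/uniform streams so different error
  scales share common random numbers (this is what makes the
  jitter-monotonicity property testable without Monte Carlo slack).
* **Degenerate inputs.** An all-zero plan makes η undefined and raises a
  typed error; constant sequences are undefined for Spearman; two
  zero-variance samples are undefined for Welch; IQR screening requires
  at least 4 values.

## Statistical conventions

* **Aggregation** pools *sessions* within a group (plan, site, or all);
  per-plan-mean pooling is available via `aggregation = "plan"`. Sample
  SD uses n − 1.
* **Quartiles** are linear-interpolation order statistics
  (`stats::quantile` type 7); the IQR fence multiplier is the standard
  box-plot 1.5. Both are surfaced as options because outlier sets depend
  on them. Outliers are values *strictly* outside the fences; low-side
  outliers mark attainment-degrading sessions.
* **Spearman** ρ is the rank Pearson with average ties. The two-sided
  p-value enumerates all n! permutations for n ≤ 9 (exact under ties)
  and uses the t-approximation on n − 2 df otherwise. Strength labels
  follow the five-level |ρ| cutpoints 0.2/0.4/0.6/0.8, right-open.
* **Welch's t-test** (unequal variances, Welch–Satterthwaite df,
  two-sided) compares each site's sessions against the pooled cohort;
  significance level 0.05; no multiple-testing correction by default
  (Holm available) since each site-metric cell is reported individually.
* **Trend screening** uses median − z·MAD (z = 3 by default) on both the
  detector signal and η, flagging only fractions failing *both* — the
  conjunction is what distinguishes a machine-side anomaly from
  statistical noise in either series. Median/MAD rather than mean/SD
  because courses have ≤ 10–40 fractions and the anomalies themselves
  would inflate a mean-based threshold.

## Problem sizes

The test suite and the acceptance script run full-geometry plans where it
matters (the chest archetype's ~22 000 openings for the monotonicity
property; ~10 000 for prostate) and shortened beam-on times (10–60 s)
where only correctness of plumbing is at stake. The cohort driver
simulates 6 sites × 2 plans × 5 fractions — 60 sessions — which is enough
for stable means/SDs and IQR screening while keeping every run under a
minute on one core.

## Known limitations

* Synthetic plans share one error model per cohort; real machines drift
  over months and differ by leaf, which the model's leaf-independent
  draws cannot express.
* η is a timing-fidelity statistic; the package deliberately makes no
  claim about delivered dose, and the synthetic gamma columns must not be
  read as dosimetric predictions.
* With few distinct fractions the MAD can collapse to zero, making the
  trend screen overly eager for any dip below the median; the z
  thresholds are configurable for such series.
* Exact permutation p-values are limited to n ≤ 9 (9! rows); above that
  the t-approximation is used, which is slightly anti-conservative for
  very small n but standard at n ≥ 10.
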