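---
title: "Thermal death time modelling of fish heat tolerance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal death time modelling of fish heat tolerance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermotol)
```

## The problem

Small tropical fish living in geothermally heated streams experience water
that warms every day toward — and occasionally past — the temperatures at
which they lose motor control. Laboratory ramping assays measure a critical
thermal maximum (CTmax): fish are heated at a fixed rate (around
0.42 °C/min) until knockdown. But habitat heating is a hundred times slower
(0.003–0.066 °C/min, dawn to afternoon peak), and a CTmax measured at one
ramp rate does not transfer to another. `thermotol` provides the machinery
to move between these regimes: it fits a thermal death time (TDT) model to
ramping trials, predicts knockdown temperatures under habitat heating
rates, converts temperature-logger records into daily heat doses, and asks
whether observed exposure exceeds what the tolerance curve allows.

## The model

The TDT curve assumes a log-linear trade-off between stress temperature and
endurance. With a reference duration $t_{ref}$ (1 minute by default), the
tolerable duration at constant temperature $T$ is

$$t(T) = t_{ref}\,10^{(T_{static} - T)/z},$$

where $T_{static}$ is the static limit — the constant temperature endured
for exactly $t_{ref}$ — and $z$ (°C per decade of time) is the heat
sensitivity coefficient: warming by $z$ divides endurance by ten. Typical
fish values of $z$ lie between 2 and 8; small $z$ means endurance collapses
quickly with warming.

Dynamic assays are connected to this curve by cumulative injury: along a
temperature trajectory $T(t)$, injury accrues at rate $1/t(T(t))$ and
knockdown occurs when the integral reaches 1. For a linear ramp from
$T_0$ at rate $r$, the integral has a closed form, giving the knockdown
temperature

$$T_k = T_{static} + z \log_{10}\!\left(\frac{r\,\ln 10\,t_{ref}}{z}
  + 10^{(T_0 - T_{static})/z}\right).$$

`injury_integral()` evaluates the damage integral exactly per linear
segment of an arbitrary trajectory (with a Simpson fallback at 0.01-min
resolution for cross-checking), and `dynamic_knockdown()` implements the
closed form. The start-temperature term is retained: at habitat rates the
ramp begins only a few degrees below the limit and the term is not
negligible. Two consequences of the model are worth keeping in mind when
reading outputs: faster ramps always produce higher CTmax, and the fitted
$T_{static}$ sits several degrees *above* the CTmax measured at
laboratory rates — at 0.42 °C/min a fish spends roughly
$z/(r \ln 10) \approx 5$ minutes near its end temperature, so the 1-minute
static limit must be higher.

## Fitting

Trials, not fish, are the unit of fitting: all fish in a ramp share one
heating rate, so replicates within a trial are averaged
(`trial_summaries()`) and `fit_tdt()` minimises the squared difference
between each trial's mean knockdown and the closed-form prediction at that
trial's rate and start temperature. $z$ is identified only by variation in
heating rate across trials; identical rates are an error, and a spread
below 0.05 °C/min is flagged as ill-conditioned. Least squares on the
closed form is used because (rate, mean knockdown) pairs are the only data
the design provides; nothing about within-trial spread enters the fit.

The optimiser is a deterministic direct search: Nelder–Mead on
$(\log z, T_{static})$, restarted from $z \in \{3, 5, 7\}$ and polished
from the best point, relative tolerance $10^{-14}$. The log transform
enforces $z > 0$ without box constraints, and the fixed start grid makes
fits reproducible without seeds. Noiseless synthetic trials are recovered
to well below $10^{-4}$ in both parameters. Expect large sampling variance
from real designs, though: with four trials spanning 0.32–0.46 °C/min and
realistic between-fish spread, replicate simulated experiments return
$\hat z$ anywhere from near 0 (a degenerate flat fit in which every trial
is explained by $T_k \approx T_{static}$) to twice the truth. The
acceptance script therefore reports the median of 20 replicate simulated
experiments, and `fit_tdt()` flags $\hat z > 20$ as suspicious.

## Field analytics

Logger series are tibbles of (site, timestamp, °C) in the input's own
local clock; no timezone arithmetic is applied. Between readings the
temperature is taken as linear, which makes every derived quantity exact
and resolution-invariant on piecewise-linear data:

* `daily_summaries()` — per civil day: mean, extremes and their clock
  times; days with fewer than 75% of the readings expected at the site's
  nominal interval are flagged partial and should be excluded from
  cross-day means; single-reading days are dropped.
* `heating_rates()` — the habitat ramp: temperature rise from a sunrise
  anchor to the daily maximum over the elapsed minutes, reported to three
  decimals. True sunrise is not in the data, so the default anchor is the
  dawn minimum (coolest reading before noon), with a fixed-clock
  alternative (default 06:00) for sensitivity checks.
* `exposure_durations()` — minutes per day inside half-open bands
  $[lo, hi)$, default 32–36 °C in 1 °C steps; band crossings are solved
  exactly per linear segment and segments spanning midnight are split at
  the boundary.
* `detect_spikes()` — transient events: a reading is anomalous when it
  exceeds the site's median temperature at that hour on *other* days by at
  least `delta` (default 1.0 °C, the magnitude of the river-heating event
  the detector is designed around). The leave-one-day-out hourly median
  needs at least three days of data; `delta = 0` is rejected because it
  would flag ordinary noise.

## The interaction test

Whether hypoxia depresses CTmax differently in the two species is a 2×2
interaction with fish nested in trials. Rather than a mixed model — which
the data sizes here cannot support reliably — the package uses a
randomisation test on the trial-blocked interaction contrast
$(\bar y_{1,\mathrm{hyp}} - \bar y_{1,\mathrm{norm}}) -
 (\bar y_{2,\mathrm{hyp}} - \bar y_{2,\mathrm{norm}})$,
where each cell mean is an unweighted mean of trial means. The null is
built by shuffling each species' fish across its fixed trial-by-oxygen
design slots and recomputing the contrast; p-values use the add-one rule.

A design note: permuting *whole-trial* labels instead would be the more
conservative blocked scheme, but with three trials per cell it admits only
$\binom{6}{3}^2 = 400$ arrangements and — because an interaction
concentrated in one species leaves that species' permuted contrast at full
magnitude only for the identity and complement arrangements — its
two-sided p-value cannot fall much below 0.1. Fish-level shuffling restores
resolution and power; its cost is the assumption that fish are
exchangeable across a species' trials under the null, i.e. that there is no
large tank effect beyond the treatment. Under the generator used in the
tests (no extra between-trial variance) the measured type-I error at
$\alpha = 0.05$ is 0.041 (1000 simulations), and power against a 2 °C
interaction at 3 trials/cell with 0.8 °C between-fish spread is ~1.

## Margins, breadths, rounding

`safety_margin()` is CTmax minus the maximum habitat temperature over the
sampling period; `tolerance_breadth()` is mean CTmax minus mean CTmin.
Both round to one decimal **half away from zero** (11.45 → 11.5), matching
how such margins are conventionally printed; base R's `round()` would give
11.4. Negative margins are legitimate output — they mean habitat maxima
already overlap the tolerance limit.

## What the generators emulate

`simulate_assay()` runs the TDT model forwards: each fish draws an
individual static limit $\sim N(T_{static}, \sigma)$ (default
$\sigma = 0.5$ °C; heterogeneity is placed on the limit, not on $z$,
because individual CTmax spread is observable but individual $z$ is not
identifiable), and per-trial ramp rates are jittered (sd 0.06 °C/min,
truncated at 0.05) around the 0.42 °C/min laboratory target. Defaults give
around 16 fish per trial from a 30 °C start — a warm-season hypoxic
experiment.

`simulate_logger()` produces a single-harmonic diel cycle; the defaults
(mean 31.7 °C, amplitude 3.5 °C, afternoon peak at 15:00, hourly readings)
give a daily range of 28.2–35.2 °C, a warm-season pool profile, with an
optional transient spike (e.g. +1 °C for 60 min) and Gaussian observation
noise. Real logger data differ in ways the generator deliberately omits:
asymmetric heating/cooling limbs, weather-driven day-to-day drift,
multi-day autocorrelation, and gaps. Tests passing on generated data
therefore establish the correctness of the *computations* (round-trips,
conservation, invariance under resampling), not robustness to every field
artefact.

`t_static_for_ctmax()` inverts the ramp solution so generator
configurations can be anchored to published dynamic CTmax values: the
static limit itself is rarely printed, but the (rate, start, CTmax) triple
pins it down exactly.

## Numerical choices and degenerate inputs

* Injury per linear segment uses the exact exponential closed form; the
  flat-segment branch triggers below $10^{-12}$ °C of change. Additivity
  over concatenated trajectories holds to $10^{-12}$.
* The closed-form ramp solution agrees with an independent fine-grid
  numeric integration of the injury integral to better than $10^{-6}$ °C
  across $z \in [2, 8]$, rates 0.001–1 °C/min, starts 20–35 °C.
* Spike detection compares the excess against `delta` with a $10^{-9}$
  tolerance so an injected excess exactly equal to the threshold is not
  lost to floating-point representation.
* Exposure ties at band boundaries follow the half-open convention; flat
  segments exactly at a boundary belong to the band whose lower edge they
  sit on.
* Exceedance verdicts (`run_compare()`) use strict inequality: observed
  exposure equal to the tolerable duration is "within tolerance",
  conservative toward the null.
* Warnings rather than errors for implausible-but-possible values:
  $T_{static}$ outside 20–50 °C, $z > 20$, ramp starts close enough to the
  static limit that injury accrues before heating begins.

## Problem sizes in the test-suite and acceptance script

Simulation-based checks use sizes chosen to make Monte-Carlo error small
relative to the bands being checked: 1000 simulations × 999 permutations
for type-I calibration, 200 for power, 100 replicate fits for noisy
recovery, 75-point parameter grids for the oracle equivalence, and
14-day hourly logger series. The full synthetic pipeline
(`run_pipeline()`) runs end-to-end in a few seconds.

## Known limitations

* The TDT curve is assumed log-linear over the few degrees spanned by the
  data; curvature at extreme temperatures is not modelled.
* All-or-none knockdown only; no survival fractions or repair/recovery
  dynamics, so long, mild exposures may be treated more pessimistically
  than physiology warrants.
* Cold-side limits (CTmin) are summarised descriptively; no cold-injury
  TDT curve is fitted.
* The interaction test's fish-level permutation is anti-conservative if
  trials carry large non-treatment variance; with many trials per cell a
  trial-level permutation becomes preferable.
* Sunrise anchoring by dawn minimum is a proxy; heavily shaded or
  spring-fed sites with flat mornings can anchor late and bias rates low.
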