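---
title: "Quantifying glucose and glycemic variability from CGM data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying glucose and glycemic variability from CGM data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgmetrics)
```

## The problem

A continuous glucose monitor (CGM) reports interstitial glucose every 5
minutes (Dexcom-style sensors) or ~15 minutes (Abbott FreeStyle Libre's
historic log), producing thousands of readings per week of wear.
Clinical research cares not only about the average glucose level — which
maps onto hemoglobin A1c — but about *glycemic variability*: the
dispersion and excursion structure of the trace, an established risk
factor for hypoglycemia and for diabetes complications. Dozens of
variability metrics circulate in the literature, each with its own
parameters and conventions, which makes results hard to compare across
studies. cgmetrics implements a canonical roster of 28 clinically
validated metrics behind a surface of 25 metric functions, together with
device-export ingestion, standard longitudinal visualizations, and a
seeded synthetic CGM simulator so the whole pipeline is testable without
patient data.

## The canonical series and its assumptions

Everything operates on a tidy `cgm_series`: a tibble of `(time,
glucose)` readings in mg/dL, sorted, deduplicated (first occurrence
wins), with a declared nominal sampling interval and a device label.
Three assumptions are made once, at ingestion, and hold everywhere:

* **Timestamps are naive local wall-clock.** Device exports carry no
  time-zone information; we store timestamps as-is (internally UTC) and
  never apply daylight-saving arithmetic. A DST transition during wear
  will shift one day's alignment by an hour — a documented limitation
  rather than a silent correction.
* **Days break at local midnight.** Every intraday metric, ADRR, and the
  by-day plot need a day definition; midnight is the convention. A day
  with fewer than two readings is "thin" and is skipped by per-day
  dispersion metrics (a within-day SD of one point is undefined).
* **No imputation, ever.** Gaps are located and reported
  (`find_gaps()`), but metrics operate on observed readings only. For
  the lagged metrics this means gaps reduce the pair count rather than
  being bridged by fabricated values.

Parse-time sanity bounds are [10, 1000] mg/dL — deliberately wider than
any sensor's reportable range (40–400/500), so genuine exports always
pass while corrupted rows fail loudly, listing the offending rows.

## The metric roster

`cgm_metrics()` returns a 28-row report: mean, median, min, max,
quartiles (linear interpolation between order statistics), interday SD
(sample, n−1) and CV; intraday SD and CV, each aggregated across days as
mean/median/SD (six entries); band-based time in range (TIR), time
outside range (TOR) and percent outside range (POR); MGE and MGN (mean
glucose outside/inside the band); MAGE; J-index; LBGI, HBGI and ADRR;
MODD and CONGA; GMI and eA1c. The roster lives in one config table, so
it can be revised without touching the computation. `percent_in_range()`
is exported as the complement of POR but not double-counted in the
roster — the report counts one member of each complementary percent
pair.

Parameter conventions, with defaults and why:

* **k (SD multiplier), default 1.** The dispersion band is
  `mean ± k·SD`; it parameterizes TIR/TOR/POR, MGE/MGN and the MAGE
  threshold. k = 1 is the classical choice for MAGE and the common
  band convention.
* **Clinical thresholds, 70 and 180 mg/dL.** The standard consensus cut
  points for hypo- and hyperglycemia; `clinical_range_times()` and the
  threshold plot accept personalized values. Comparisons are strict
  (<70, >180) for the out-of-range sides, inclusive for in-range.
* **sr (minutes per reading), default the nominal interval.** Durations
  are reading counts × sr, so TIR + TOR always equals observed wear
  time.
* **CONGA lag, default 24 h.** CONGA(n) is the sample SD of differences
  between readings n hours apart; 24 h is this package's default lag.
* **Pairing tolerance, default half the nominal interval.** MODD and
  CONGA pair by timestamp, not by index: the partner of a reading at t
  is the reading nearest t − lag within the tolerance, ties resolved to
  the earlier candidate. Index-shift pairing silently corrupts both
  metrics on records with gaps; timestamp pairing degrades gracefully
  (fewer pairs) and is deterministic.

### MAGE

MAGE (mean amplitude of glycemic excursions) is reported everywhere and
specified nowhere; variants differ in smoothing, in turning-point rules,
and in which legs are averaged. The variant here is the classical
Service-style procedure, stated precisely in `?mage` so it can be
reimplemented independently:

1. Smooth with a centered moving average (default 9 readings ≈ 45 min at
   5-min cadence), shrinking the window symmetrically at the edges.
2. Collapse plateau runs of the smoothed trace to their midpoints; take
   direction-change points as turning points, plus the record's first
   and last points as boundary turning points.
3. Refine each turning point to the raw extremum within half a window,
   and measure amplitudes on the **raw** readings. Smoothing exists to
   locate excursions; measuring amplitudes on the smoothed trace would
   attenuate every excursion by an amount that depends on the sampling
   cadence and pulse shape (for a meal-like pulse at 5-min cadence the
   9-point average clips >10 mg/dL off the peak), which is a bias, not a
   convention.
4. Keep amplitudes > k·SD of the raw trace; average the qualifying
   amplitudes whose direction (nadir→peak vs peak→nadir) matches the
   first qualifying swing, counting each excursion once.

Including the boundary points means a record that starts at a nadir and
ends mid-excursion still counts its leading and trailing swings; on a
flat record there are no turning points and MAGE is undefined (returned
as a typed undefined value with its reason, like every undefined metric
here — never a silent `NaN`).

### The risk family

LBGI, HBGI and ADRR share the Kovatchev symmetrizing transform
`f(G) = 1.509·((ln G)^1.084 − 5.381)`, whose constants — along with the
GMI and eA1c coefficients — live in one table with their literature
citations. Per reading, risk is `10·f²`, split into a low side (f < 0)
and high side (f > 0); LBGI and HBGI are the means of the two sides,
and ADRR averages across days the sum of each day's maximal low and
high risk. The transform's root is ≈112.5 mg/dL, which gives the sign
structure the tests exercise: a trace entirely above ~113 mg/dL has
LBGI exactly 0.

## The simulator

`simulate_cgm()` generates
`G(t) = baseline + A·sin(2π·tod/24h) + Σ meal pulses + AR(1) noise`,
clipped to the sensor-reportable [40, 400] mg/dL and quantized to
0.1 mg/dL as real sensors report. Design choices:

* **Meal pulses are functions of time of day** (linear rise over
  `rise_min`, exponential decay with time constant `decay_min`), so a
  noiseless profile is exactly 24-h periodic. That makes MODD and
  CONGA(24) identically zero on it — a sharp calibration point for the
  pairing logic.
* **AR(1) noise** (default innovation SD 5 mg/dL, coefficient 0.7) is
  the simplest autocorrelated model consistent with CGM sensor error;
  white noise would understate run lengths, and the stationary initial
  state keeps the first readings statistically identical to the rest.
* **Defaults** sketch a realistic, reasonably controlled week: baseline
  120 mg/dL, circadian amplitude 20 mg/dL, three meals (+45/+55/+60
  mg/dL at 08:00/13:00/19:00), 5-min cadence, 7 days.
* **Gaps** are removal windows, mirroring sensor dropouts; gap windows
  never trigger imputation downstream.

Two analytic recoveries anchor the simulator to the metrics: a pure
sine of amplitude A sampled over whole days has interday SD = A/√2
(observed within 0.05% at 5-min cadence over 7 days), and a single
daily +80 mg/dL meal pulse on a flat baseline yields MAGE = 80 exactly,
because peaks land on samples and amplitudes are read from raw values.

What the simulator does *not* emulate: glucose–insulin dynamics,
calibration-event artifacts, pressure-induced sensor attenuation, or
device quantization quirks beyond 0.1 mg/dL rounding. Tests passing on
simulated traces therefore validate the *computation* of the metrics
and the ingestion/plotting pipeline, not the clinical interpretation of
any metric on real patients.

## Numerical choices and degenerate inputs

* Sample (n−1) SD everywhere, the clinical-literature convention.
* Quantiles by linear interpolation (R type 7).
* A constant series has SD = CV = 0, a degenerate band equal to its
  mean, all time in range, MGN equal to the constant, and MGE/MAGE
  undefined (no excursions).
* Duplicate timestamps keep the first occurrence and are counted in the
  parse log; exact-tie lag pairs resolve to the earlier reading; plateau
  runs collapse to their midpoint (floor of the midpoint index for
  even-length runs). Every tie-break is deterministic, so identical
  inputs give identical reports.
* LOWESS (tricube weights, default span 0.1, 2 robustness iterations)
  is delegated to `stats::lowess`, evaluated at every observation time
  with no interpolation shortcut (`delta = 0`). It reproduces a linear
  trace to machine precision and suppresses isolated outliers at 2+
  robustness passes. The span for the smoothed figure is a free choice;
  0.1 keeps meal excursions visible on multi-day records.

## Problem sizes in the test suite

The oracle-equivalence suite compares every metric against naive
brute-force reimplementations (explicit loops, exhaustive pair search)
on twenty randomized 2-day fixtures of at most 600 readings each, to
1e-9 relative tolerance; recovery checks use 7-day noiseless
simulations (2016 readings) and the reference report a 14-day noisy one
(4032 readings). These sizes were chosen to exercise day boundaries,
both cadences and gap handling while keeping each suite run in seconds.

## Limitations

* No time-zone or DST handling (by design, above).
* mmol/L inputs must be converted by the caller before the generic
  reader; the device readers assume mg/dL exports.
* Medtronic and other manufacturers' dialects are not parsed; their
  data enters through `read_generic_csv()`.
* The MAGE variant is one defensible member of a family; comparisons
  with other software should state the variant and parameters (`k`,
  `smooth_window`), which the report echoes for exactly that reason.
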