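---
title: "Optimizing moving-average QC procedures: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing moving-average QC procedures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbrtqc)
```

# The model

Patient-based real-time QC follows a moving average of patient results as a
continuous control signal. `pbrtqc` implements the two standard formulas:

* **Simple MA.** At each accepted result, the unweighted mean of the last
  $n$ accepted results: $z_t = \frac{1}{n}\sum_{i=0}^{n-1} x_{t-i}$. The value
  is undefined until $n$ accepted results exist — the formula has no meaning
  for a partial window, so no warm-up value is emitted.
* **EWMA.** $z_t = \lambda x_t + (1-\lambda) z_{t-1}$ with $0 < \lambda < 1$,
  defined from the first accepted result onward. $z_0$ is the arithmetic mean
  of the truncation-accepted values of the whole historical stream (the same
  filtered population that defines the rest of the procedure); a numeric
  $z_0$ can be given instead. At $\lambda = 1$ the series reproduces the raw
  accepted values; as $\lambda \to 0$ it stays at $z_0$.

**Truncation.** Results outside the configured concentration range are
excluded from the calculation. Limits are *inclusive*: a result exactly equal
to a limit is accepted, matching the usual "$\le$ limit" phrasing of
inclusion criteria. At an excluded result the MA carries its previous value
forward and no alarm evaluation takes place — the alarm state can only change
when the MA changes.

**Control limits.** The lower/upper control limits are the minimum and
maximum of the defined MA values on unbiased historical data. An alarm
requires *strict* exceedance. This pairing is deliberate: the limits are
themselves attained by the limit-defining series, so a non-strict comparison
would alarm on the very data the procedure was trained on, while strict
comparison gives zero false alarms on it by construction. Whether a non-strict
rule was intended by existing software is unknowable from published material;
strictness is the assumption made here and tested as an exact invariant.

# Bias detection simulation

A systematic error is emulated as a persistent proportional shift: from the
injection point on, every result is multiplied by $1 + b/100$. The bias is
applied *before* truncation — a +50 % shift can push results beyond an upper
truncation limit, in which case they are excluded and the MA stops moving.
This ordering is what makes the well-known trade-off reproducible: an upper
truncation limit delays or entirely blocks the detection of large positive
biases (and a lower limit, of large negative ones).

**Injection design.** The stream is cut into consecutive non-overlapping
blocks of 400 results. Bias is injected at the first result of each block
from the second block onward, so every run starts from an MA state warmed by
at least 400 unbiased results, and runs never overlap. This reading of
"simulation for every 400 consecutive results" maximizes the number of
independent runs; injecting at every position within a block would give
correlated runs without adding information. Each run replays the unbiased
stream deterministically up to its injection point — no state leaks between
runs.

**Counting.** `n_to_detection` counts *all* results presented after injection
(accepted and rejected) up to and including the first alarming one, because it
measures patient-result exposure to the error; `n_accepted_to_detection`
counts accepted results only, and is always $\le$ the former, with equality
when nothing is truncated. A run with no alarm within the 400-result window is
*censored*; censored runs are reported via the detected fraction and excluded
from the median/min/max (the alternative — scoring them as 400 — would make
the summary depend on an arbitrary window). The median of an even number of
runs is the mean of the central pair.

The per-bias summaries feed two displays: the **bias detection curve**
(median results-to-detection vs bias size) and the **validation chart**
(median bar with min/max error bars per bias size).

# Optimization criteria

The allowable total error (TEa) of the analyte is treated as the clinically
significant bias; it is rounded to the nearest integer percent, halves away
from zero, because biases are simulated on an integer grid (17.97 % → 18 %,
3.57 % → 4 %). A candidate procedure is **feasible** when

1. a bias of ±TEa is detected in *every* injection run, with worst-case
   (maximum) results-to-detection within the analyte's daily volume, and
2. the same holds for every bias larger than the TEa.

Feasibility is judged on the maximum, not the median: the point of the
exercise is that a clinically significant error will *certainly* be caught
within a day's production. Medians are used only to rank feasible candidates:
ascending median at +TEa, then at −TEa, then the worst median over all biases
≥ TEa, then simplicity (fewer truncation limits, larger $\lambda$ / smaller
$n$), then the identifier. Published selections of this kind blend the two
criteria with visual judgement of the curves; the tie-break chain here is an
explicit, deterministic formalization of that practice and is documented as
such rather than claimed to be canonical.

# The synthetic stream generator

Real LIS extracts cannot be shipped, so streams are generated from
**profiles**: the summary statistics a laboratory can publish (median,
quartiles, extremes, daily volume) plus a skew family and an outlier rate.

**Core distributions.** Only three quantiles are available, so families are
chosen by the quantile asymmetry and matched exactly where possible:

* *symmetric* (sodium, potassium): a normal with mean = median and
  sd = IQR$/(2\,\Phi^{-1}(0.75))$, truncated to the observed range and
  sampled by inverse CDF. For these narrow analytes the truncation sits many
  sd away and is numerically irrelevant.
* *right-tailed* (creatinine, maximum 971 vs median 70 µmol/L): a shifted
  log-normal. The three quantile equations solve in closed form:
  shift $= (q_1 q_3 - m^2)/(q_1 + q_3 - 2m)$, then meanlog and sdlog from the
  median and quartile ratios. Q1, median and Q3 are matched exactly.
* *left-tailed* (albumin, minimum 20 vs median 43 g/L): the mirror image of
  the shifted log-normal solution on the negated quantiles. A truncated
  normal cannot reproduce albumin's quantile asymmetry (median − Q1 = 2 vs
  Q3 − median = 1 g/L) without implausibly extreme truncation, so the
  mirrored skew family is used instead; it also reaches toward the low
  pathological values actually observed.

If the quantiles carry no skew the skewed families fall back to the truncated
normal. A degenerate profile (zero IQR) is valid only as a point mass.

**Pathological tail.** A fraction `outlier_rate` of results (default 0.01 —
roughly the share of grossly pathological samples a primary-care outpatient
population produces) is drawn uniformly from $[\min, Q_1]$ and $[Q_3, \max]$,
half each, so the observed extremes remain reachable. Generated values are
clipped to $[0.9\cdot\min,\ 1.1\cdot\max]$.

**Day structure.** Daily counts are Poisson around the profile's daily
volume; timestamps fall within 07:00–15:00 (an outpatient collection
pattern) at second resolution. There is no weekend gap by default (the target
population shows none; a `skip_weekends` switch exists), no autocorrelation,
and an optional slow sinusoidal day-level drift whose amplitude defaults
to 0 — published summary statistics quantify neither autocorrelation nor
analyser drift, so none is assumed. Each stream is produced by a single
explicitly seeded RNG and is byte-identical under the same inputs; the seed
is recorded in the stream's metadata.

**What passing tests do and do not show.** The generator reproduces the
marginal distribution and volume of each analyte, not the serial structure of
a real analyser (calibration jumps, reagent-lot drift, haemolysis episodes,
duplicate patients). Results obtained on synthetic streams therefore validate
the *machinery* — formulas, limits, simulation, ranking — and the qualitative
behaviour of procedures, not the specific control limits a laboratory should
deploy, which must always be derived from its own data.

# Numerical choices

* MA values are kept at full double precision; no rounding to reporting
  precision (an explicit design choice — rounding would make alarms depend on
  the analyte's reporting convention).
* The zero-false-alarm property is maintained *exactly*: the simple-MA window
  mean is computed as a moving convolution with weights $1/n$ both when
  deriving limits and when replaying a stream during simulation, so the same
  window of doubles yields bit-identical means (a prefix-sum formulation
  differs by an ulp and can produce spurious alarms at bias 0). The EWMA
  recursion is sequential in both paths and is exact as-is.
* Detection-delay closed forms on constant streams,
  $k_{\text{simple}} = \min\{k: |cb/100|\min(k,n)/n > d\}$ and
  $k_{\text{EWMA}} = \min\{k: |cb/100|(1-(1-\lambda)^k) > d\}$ with $d$ the
  distance from the starting MA to the relevant limit, are used as analytic
  oracles in the tests.

# Known limitations

* **Truncation vs small negative biases.** For the potassium comparison
  (EWMA $\lambda=0.1$, with vs without an upper truncation limit of
  6 mmol/L), negative-bias detection medians coincide exactly at clinically
  significant bias sizes but can differ by one or two results at small biases
  (±1–5 %). The stream's rare values above 6 mmol/L are ingested by the
  untruncated procedure and not by the truncated one, so the two EWMA states
  differ slightly near injection points that follow such a value, and the
  min/max control limits can differ marginally. Exact coincidence across the
  whole negative grid would require a stream with no value above the
  truncation limit, which contradicts the population it emulates. The
  clinically relevant conclusion — an upper limit costs nothing for negative
  biases but delays large positive ones — holds.
* Censoring conventions of existing MA software (whether undetected runs
  enter the reported min/max) are not published; the choice here (exclude,
  report the detected fraction) is explicit but unverifiable against it.
* Only persistent proportional bias is simulated; random-error increase,
  intermittent error and drifting bias are out of scope, as are Bull's
  algorithm and multi-analyte rules.

# Problem sizes

The shipped tests exercise streams of roughly 2,000–7,500 results (15–270
generated days depending on the analyte's volume), 400-result blocks, the
full formula grid (batch sizes 5–100, weighting factors 0.02–0.2) and the
per-analyte truncation variants; the oracle-equivalence checks use 100 random
streams of 500 results. The acceptance script runs the four optimal
procedures on 121-day streams — about the volume of six months of routine
work in a small laboratory.
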