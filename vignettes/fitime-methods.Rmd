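---
title: "Models and methods behind fitime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fitime}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fitime)
```

# The experiment fitime analyses

fitime targets 12-s fixed-interval (FI12) operant experiments in rodents:
a houselight marks trial onset (t = 0), the first lever press after 12 s is
rewarded, earlier presses have no programmed consequence, and trials are
separated by intertrial intervals drawn from {6, 8, 10, 12} s across
60-minute sessions.  The designs it supports cross a reversible
pharmacological manipulation of medial frontal cortex (bilateral saline or
muscimol infusion, one session per drug) with optogenetic stimulation of
corticostriatal axon terminals (no stimulation, 2 Hz, or 20 Hz,
pseudo-randomly interleaved so per-condition trial counts differ by at most
one), while single units are recorded in dorsomedial striatum.

# Behavioural quantities

## Curvature of the cumulative response record

Temporal control of responding is summarised by a curvature index on the
cumulative response record $R(t)$ over $[0, T]$.  The discrete form splits
the interval into $n$ equal segments with cumulative counts $R_i$:

$$C = \frac{(n-1)\,R_n - 2\sum_{i=1}^{n-1} R_i}{n\,R_n},$$

bounded by $\pm(n-1)/n$; 0 corresponds to a constant response rate,
positive values to responding concentrated late (the scalloped records of
timed behaviour), negative values to early responding.  The continuous
variant reports $(A_{line}-A_{record})/A_{line}$, where $A_{line}=T R_n/2$
and $A_{record}$ is the trapezoidal area under the polyline through the
record's vertices $(0,0),(t_{(i)},i),(T,R_n)$.  The polyline (rather than
the exact step-function integral) was chosen deliberately: it makes the
two variants agree *exactly* on a perfectly regular record (one press at
the end of each of $n$ segments gives 0 by both routes), which is the
analytic anchor of the whole index.  The cost is that duplication
invariance is exact only for the discrete form; duplicating every response
shifts the polyline value by exactly $t_N/(2TN)$, which vanishes in the
response count $N$.  The two variants share their large-$n$ limit
$2\bar t/T - 1$ and agree within 0.01 once records hold a few hundred
responses.  The package default is the discrete form with $n = 1000$: the
index is binning-resistant, and at that granularity the discrete value is
within $10^{-3}$ of the continuous one; $n = 4$ is retained because its
extreme values ($\pm 3/4$) are convenient hand-checks.  Only responses in
$[0, T]$ (the pre-reward interval) enter the index.

## Single-trial start times

Per-trial start times use the two-rate special case of the three-state
single-trial analysis developed for peak-interval procedures: a fixed
interval has no stop, so only the low-to-high transition is sought.  For a
trial with $N$ responses and overall rate $r = N/T$, the detector
exhaustively evaluates

$$D(s) = s\,(r - r_1) + (T - s)\,(r_2 - r)$$

at every candidate breakpoint (each response time plus 0 and $T$), where
$r_1$ and $r_2$ are the response rates on $[0,s)$ and $[s,T)$, and keeps
the earliest maximiser; candidates whose objective lies within $10^{-9}$
of the maximum are treated as exact ties, because repeated response times
produce mathematically equal objectives that differ only by float noise.
Trials with fewer than 2 responses are flagged invalid and excluded from
start-time summaries, with exclusion counts reported.

Because candidates are press times, the estimate lands on the first press
after the true transition, giving a structural positive bias of about
$1/\text{rate}_{high}$ (0.5 s at 2 presses/s, shrinking at brisker press
rates).  The recovery tests assert exactly this derived behaviour rather
than pretending the estimator is unbiased.

## Time-response histograms

For display, pooled response times are smoothed with a Gaussian kernel
(bandwidth 1 s) on a 0.1-s grid, normalised to each animal's maximum
before averaging across animals, with raw binned press rates returned
alongside.  No boundary correction is applied, matching the kernel
procedure the field uses.

# Unit-level quantities

**Waveform features and classification.**  Units are classified from two
scalar waveform features — peak-to-trough duration and half-peak width,
both in ms — extracted with polarity detection on the largest-magnitude
extremum and linear interpolation at half amplitude.  A full-covariance
Gaussian mixture (via mclust, with its deterministic hierarchical
initialisation, BIC choosing between one and two components) assigns
classes; the broader-waveform component is labelled MSN (medium spiny
neuron), the narrower FSI (fast-spiking interneuron).  Units firing at or
below 0.1 Hz over the session are excluded (the threshold is strict), and
headline analyses keep MSNs only, since FSIs are roughly half as numerous
in such recordings.

**Ramping.**  Per neuron and per (drug, stim) cell, firing rate is binned
at 10 ms over the 12-s interval (unsmoothed, unnormalised) and regressed
on bin-centre time by ordinary least squares.  A neuron with time
coefficient p < 0.05 is flagged as time-ramping; no multiple-testing
correction is applied, matching field practice for this per-neuron screen.
A Poisson log-link count regression is available as an option, since the
per-neuron model family is a genuinely open choice; OLS on rates is the
default because the population model is also an identity-link Gaussian
model and the two should agree in kind.  With zero residual variance
(noiseless input) the p-value is set to 0 or 1 according to whether the
slope is non-zero.

**PETH matrices.**  For display, trial-averaged rates in 100-ms bins are
z-scored across bins per unit, Gaussian-smoothed (bandwidth 0.5 s;
z-scoring precedes smoothing, and smoothing never feeds any regression),
and sorted by loading on the first principal component, whose sign is
fixed by its correlation with time so that upward-ramping units gather at
one edge of the heat map.

# Mixed-effects models

Response times are modelled as `RT ~ Stim * Drug + (1 | Animal)` and
population firing as `FR ~ Time * Stim * Drug + (1 | Neuron)`, both
identity-link Gaussian fits (lme4), with type-III F tests on sum-to-zero
contrasts and Satterthwaite denominator degrees of freedom (lmerTest) —
the denominator-df method is a documented choice, as the field's tools do
not state one.  Likelihood-ratio tests compare maximum-likelihood refits
against the intercept-plus-random-intercept null, and both marginal and
conditional R² (fixed-effect variance over total, with and without the
random component) are reported because the convention is ambiguous.  Time
enters the firing model as a continuous bin-centre covariate.  RT
granularity defaults to per-press (all presses within the interval), with
per-trial reward latency available; the calibration caveat this carries is
discussed under Limitations.  With a single animal or neuron the random
intercept is degenerate and the fit falls back to a fixed-effects model
with a loud warning.  Paired condition contrasts report the paired t,
two-sided p, group means ± SEM, and Cohen's d computed on the paired
differences; zero-variance non-zero differences yield a signed infinite t
flagged explicitly.

# The synthetic-session generator

The generator is first-class, tested code: it defines the study conditions
under which every downstream claim is checked.

* **Behaviour.**  Each trial draws a start time from a truncated Normal
  (lognormal optional) with mean `startMu[drug, stim]` and SD
  `startCv * mean` — the scalar-timing property — then presses as a
  homogeneous Poisson process at `rateLow` before the start and
  `rateHigh` after.  The trial ends at the first press after 12 s
  (rewarded) or at a 24-s timeout (2 × interval) when no such press
  occurs; the timeout is a free design parameter because the protocol does
  not state what happened on pressless trials.  Defaults place mean starts
  at 8.4 s under saline, 7.8 s under muscimol, and 8.8 s under muscimol
  with 20-Hz stimulation — the printed condition means of the experiment
  the package emulates — with `startCv` = 0.15 and animal-level offsets of
  SD 0.3 s, typical scalar-timing values for rodent fixed-interval work,
  and press rates of 0.1/2 presses/s.  Control (non-opsin) animals ignore
  the stimulation label, as opsin-free tissue should.
* **Spikes.**  Each unit belongs to one session (recordings on separate
  days sample different neurons).  Ramping units (half, by default) fire
  as an inhomogeneous Poisson process with
  $\lambda(t) = \max(0, a + b\,t)$ across the interval, sampled by exact
  thinning; elsewhere, and for non-ramping units, the rate is the
  lognormally heterogeneous baseline $a$ (mean 3 spikes/s).  Default
  slopes are 0.4 spikes/s per s under saline, attenuated to 0.15 under
  muscimol and restored to 0.4 by 20-Hz stimulation — encoding the
  directions of the frontal-inactivation and stimulation-rescue effects.
* **Waveforms.**  Biphasic difference-of-Gaussians templates at 40 kHz
  whose two scalar features are drawn per class (MSN 0.60 ± 0.05 ms
  peak-to-trough, 0.25 ± 0.03 ms half-width; FSI 0.20 ± 0.03 and
  0.10 ± 0.02), more than five within-class SDs apart, so classification
  accuracy against generator truth is essentially an identity check;
  overlapping settings are permitted but flagged.

What the generator does **not** emulate — and what passing tests therefore
cannot certify about real data: within-trial response acceleration beyond
a single rate switch (real scallops curve, so real curvature values sit
lower than the two-state model's at matched start times), stop-free
post-reward behaviour, bursting/refractory spike statistics,
condition-dependent press *rates* (only start times shift between
conditions), D1/D2 subtypes, and any electrode-level artifacts.

# Determinism and problem sizes

All randomness descends from one root seed, split deterministically into
per-module streams; the same configuration and seed reproduce
byte-identical bundles and pipeline reports.  The shipped analyses run at
desk scale by choice: the population firing model defaults to 100-ms bins
(10-ms mode behind a flag reproduces the headline design structurally at
~100× the rows), per-neuron ramping uses 10-ms bins, calibration suites
use 400 replicates at 6-animal/8-minute scale for the response-time null
and 10-unit/6-minute scale for the firing null, power runs use 50 and 12
replicates at ~9000-press and 50-unit/60-trial scale respectively, and the
directional end-to-end check uses 20 seeds of the full 12-animal,
60-minute, 50-unit configuration.

# Known limitations

* Under the generator, presses within a trial share that trial's random
  start time, so per-press RT observations are intra-trial correlated; the
  RT model's formula has no trial-level random effect, which makes its
  interaction F test mildly anticonservative at per-press granularity and
  dilutes its power relative to the effect sizes the start-time shifts
  imply.  The calibration suite measures and reports this honestly rather
  than papering over it; per-trial granularity is calibrated but carries
  less signal under this generator.
* The start-time detector's press-time candidate set gives it the
  $1/\text{rate}_{high}$ positive bias derived above.
* Ramping is linear by construction; real striatal ramps can be convex or
  delayed, and the OLS slope then summarises, not reconstructs, them.
* Stop times, peak-interval probe trials, and response-rate asymptote
  modelling are out of scope.
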