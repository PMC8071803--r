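---
title: "Model-free multiscale idealization of patchclamp recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-free multiscale idealization of patchclamp recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchseg)
```

## The observation model

A patchclamp recording measures the conductance of a single transmembrane
channel over time. The channel gates between conformations, so the underlying
conductance is piecewise constant,

$$ f(t) = \sum_{j=0}^{K} c_j\, 1_{[\tau_j, \tau_{j+1})}(t), $$

with unknown number of gating events $K$, event times $\tau_j$ and levels
$c_j$ (in nS). The measurement device low-pass filters the signal in hardware
(typically an analogue Bessel filter with an even number of poles), so the
recorded samples at rate $f_s$ are

$$ Y_i = \big(F_m * (f + \sigma \eta)\big)(i/f_s), $$

where $F_m$ is the filter kernel truncated after $m$ sampling steps, $\eta$ is
Gaussian white noise and $\sigma$ the noise level. Filtering has two
consequences that any idealization method must address: the noise is coloured
(correlated over $m$ lags), and abrupt conductance changes become smooth ramps
of roughly one filter length $m/f_s$. Methods that ignore this either detect
spurious changes (the colour is misread as signal) or split each true change
into a staircase of small increments. Under *heterogeneous* noise — e.g.
open-channel noise, where high-conductance segments are noisier — $\sigma(t)$
is itself piecewise constant with jumps only at the $\tau_j$.

## The filter module

`lowpass_filter()` builds the analogue Bessel kernel from the pole set of the
Bessel polynomial, scaled so that the −3 dB frequency equals
`cutoff * sample_rate` (the hardware convention: a normalized cutoff of 0.1 at
50 kHz is a 5 kHz filter). Because the kernel is a finite sum of complex
exponentials, its step response and all autocovariance overlap integrals have
closed forms; no numerical quadrature is involved, and the unit tests verify
the closed forms against an independent oversampled quadrature oracle.

The truncation length $m$ is chosen as the smallest integer such that the
autocorrelation of the *untruncated* kernel stays below `acf_threshold`
(default $10^{-3}$) at every lag of $m$ samples or more; for the 4-pole filter
with normalized cutoff 0.1 this gives $m = 11$. The truncated kernel is
renormalized to unit integral so that constant signals are preserved exactly
by convolution — the paperless convention choice here keeps the standard
visual check "idealization convolved with the kernel overlays the data" exact
for constant stretches. `convolve_step_signal()` evaluates the convolution of
a step signal as a finite sum of step-response differences over its jumps,
exactly, at arbitrary (continuous) times.

## Synthetic traces

`simulate_trace()` draws from the observation model. The coloured noise is a
moving average of white noise whose weights come from an exact spectral
factorization of the truncated-kernel autocorrelation, so the simulated noise
matches the model ACF exactly up to lag $m$ (not merely asymptotically). The
noise level is parameterized as the *post-filter marginal standard deviation*,
because that is what a user estimates from quiet stretches of an (already
filtered) recording; the continuous-time scaling is absorbed into the
normalization $\rho(0) = 1$. Under heterogeneous noise the level of a sample
is the level of the segment containing its time stamp, so the few samples in
a transition inherit the right segment's level — the model is silent about
the transition region and this matches the half-open segment convention.

What the generator deliberately does not emulate: $1/f$ (pink) and $f^2$
(violet) noise components, baseline drift, and measurement artifacts. Passing
tests therefore certify correctness *under the model*; on real recordings
these violations are the main caveat, and the robust (median-based) noise
estimator plus the locality of the methods are the only mitigations built in.

## Multiscale detection with error control

All three detectors fit the step function with the **minimal number of
changes** such that, inside every fitted segment, local averages over a system
of test intervals stay within a calibrated band around the segment level:

* **jsmurf** uses intervals with lengths on a dyadic grid starting at $m + 2$
  and drops the first $m$ samples of every interval — exactly the samples a
  transition can occupy — so genuine changes at segment boundaries do not
  contaminate the tests. Means are standardized by the noise level and by the
  exact variance of a mean of correlated samples (from the kernel ACF), and
  penalized by the scale term $\sqrt{2\log(en/\ell)}$ before taking the
  maximum.
* **jules** extends the interval system down to single samples without
  dropping, which resolves events below the filter length but initially
  splits each filtered ramp into a monotone staircase; a postfilter collapses
  every run of two or more same-direction changes whose intermediate segments
  are shorter than $m$ samples into a single change. "Same direction" is
  enforced up to counter-movements of 2% of the run's net change: the 4-pole
  Bessel step response overshoots by about 0.8%, so a noise-free ramp ends in
  a small settling step that would otherwise survive as a spurious change.
* **hilde** runs jsmurf at level $\alpha_1$ and then, inside each fitted
  segment, scans windows with a whitened matched filter for peaks of each
  length $\ell \le \ell_{\max}$ (default $\ell_{\max} = m$): the test
  statistic is the Gaussian score $\,g^\top (y - c)\,$ with
  $g \propto \Sigma^{-1} r_\ell$, where $r_\ell$ is the filtered response of a
  unit peak of length $\ell$ and $\Sigma$ the noise correlation. Per-scale
  critical values are calibrated at the equal split $\alpha_2 / |\mathcal{L}|$
  (a Bonferroni allocation). A design note: a plain windowed-mean local test
  was evaluated first and rejected, because under coloured noise its power is
  essentially that of the stage-1 criterion itself — the response of a short
  peak is smeared over $\ell + m$ samples, and only the whitened matched
  statistic (the likelihood-ratio score for the peak shape) gains the factor
  1.7–2.6 in signal-to-noise ratio that makes the second stage worthwhile.
  The matched score divided by its scale is also an unbiased,
  attenuation-corrected estimate of the peak amplitude, which seeds the
  inserted segment's level.

**Calibration.** Critical values come from Monte-Carlo simulation of pure
noise (`simulate_null()`): for each trace the *smallest* critical value that
admits a 0-change fit is recorded, and the $(1-\alpha)$ empirical quantile
("higher" interpolation, conservative) of these $r$ statistics is the critical
value. Detection on model-conform constant data is then exactly the event
"statistic exceeds its quantile", so the family-wise error equals $\alpha$ up
to Monte-Carlo error by construction. Simulations run at unit noise with
scale-equivariant standardization, so one simulation serves all noise levels,
and results are cached on disk as self-describing JSON keyed by
(statistic family, $n$, filter fingerprint, scales, $r$); reloading is
bit-identical. Default repetitions are $r = 10{,}000$ for jsmurf/jules and
$r = 1{,}000$ for hilde; a few hundred suffice for screening.

**Search.** Because the interval system is start-anchored and dyadic,
feasibility of a constant fit on $[a, b]$ is down-closed in $b$; a greedy
sweep with binary search is therefore provably minimal in the number of
changes, and forward/backward sweeps bracket every boundary of every
minimal-$K$ fit. A dynamic program over these brackets picks the
least-squares-optimal boundaries among minimal-$K$ fits (the tie-break rule);
levels are segment means projected into the feasible band. The tests verify
exact agreement with brute-force enumeration over all step functions on
instances with $n \le 40$. The interval system itself is a design choice:
intervals spanning exactly a candidate segment are not added to the dyadic
system, which keeps feasibility down-closed (exact greedy minimality) and the
calibration statistic reducible to per-scale extrema, at a negligible cost in
power on segment-length scales; the calibration runs on the same system, so
the error-control contract is unaffected.

**Degenerate inputs.** Noise-free traces give a zero noise estimate; a
floor of $10^{-7}$ times the data range is added to every feasibility band so
that exact-equality fitting remains well-posed in floating point. For
heterogeneous noise, segments are studentized by their own
median-absolute-deviation estimate (lag-$(m{+}1)$ differences with the first
$m$ samples of the segment dropped); segments too short to estimate inherit
the mean of their neighbours and are flagged. Under segment-local
studentization feasibility is no longer exactly down-closed; the search is
unchanged and the forward sweep is used as a fallback, so the minimal-$K$
guarantee is exact in the homogeneous case and approximate in the
heterogeneous case.

## Local deconvolution

Detection leaves change times on the sampling grid and short-event levels
attenuated. `deconvolve_locally()` refines both using the known kernel:
isolated single changes by least squares over $(\tau, c_L, c_R)$ against the
convolved two-level step (linear in the levels given $\tau$), isolated pairs
jointly over $(\tau_1, \tau_2, c_L, c_M, c_R)$. The time search is a
deterministic three-level nested grid with final resolution $1/(100 f_s)$;
the objective is piecewise smooth in $\tau$, and on noise-free forward
simulations the recovery is exact to the grid (tested for peaks down to
$0.3\,m/f_s$, where the grid fit underestimates the amplitude by >20% and the
deconvolved fit is within 1%). Isolation means neighbours at least $3\,m/f_s$
away under homogeneous noise and $5\,m/f_s$ under heterogeneous noise.
Clusters of three or more close changes are left at grid resolution and
flagged (`mark_no_deconvolution()`, exportable as `NA`); deconvolving them is
deliberately out of scope. The fitting window extends to the neighbouring
events with a buffer of $m$ samples past each transition and at most $6m$
samples per side — a window-size engineering choice validated by the recovery
oracle, not a statement from the underlying theory. Under heterogeneous noise
residuals are inverse-variance weighted with transition samples weighted by
the right segment's level, consistent with the simulator's convention.

## Conductance-level analysis

`idealization_histograms()` returns the three standard views: raw values
(point-amplitude), one value per segment (event), and consecutive level
differences (amplitude). Because dwell times are not represented in the event
histogram and levels are deconvolved, event-histogram peaks are much narrower
than point-amplitude peaks; the tests assert this on simulated two-state
traces. Conductance levels are read off with the `half_sample_mode()` (keep
the contiguous half of the sorted sample with the smallest range until at
most three points remain; with three points, the mean of the closer pair,
midpoint on ties; with two or fewer, the mean) — robust against the skewed
tails that filtered short events produce. `assign_levels()` maps segment
levels into disjoint user intervals, marks outliers unassigned (they
typically stem from artifacts) and merges consecutive same-state segments,
and `dwell_times()` extracts per-state dwell times with a left-truncated
exponential maximum-likelihood rate ($\hat\lambda = 1/(\bar d - t_0)$ over
dwells $\ge t_0$) plus the lag-1 correlation of consecutive dwells as a quick
Markov-model diagnostic. The truncation limit is a crude guard against missed
short events, a stand-in for exact missed-event corrections, which are out of
scope; its default in the command-line tool is 3 samples.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `poles`, `cutoff` | 4, 0.1 | hardware Bessel filter; cutoff as fraction of $f_s$ |
| `acf_threshold` | $10^{-3}$ | kernel truncation rule; gives $m = 11$ at cutoff 0.1 |
| `alpha` | 0.05 | bound on P(any false-positive change) |
| `alpha1`, `alpha2` | 0.01, 0.04 | hilde split: large scales vs. local tests |
| `r` | 10,000 / 1,000 | Monte-Carlo repetitions (jsmurf, jules / hilde) |
| `l_max`, `scales` | $m$, $1{:}l_{\max}$ | local-test peak lengths (samples) |
| `resolution_limit` | 0 s | dwell-time left truncation |

## Problem sizes used in the checks

The packaged checks calibrate with $r = 1{,}000$ repetitions at $n = 2{,}048$
samples and evaluate false-positive rates on 1,000 fresh pure-noise traces;
module tests use $r$ between 150 and 400 and $n$ between 40 and $10^5$
depending on what they measure. These sizes were chosen so the full suite
documents the statistical contracts at useful precision (binomial standard
errors below 0.01 for error rates) while remaining quick to run; power
statements use fixed seeds and are exactly reproducible.

## Known limitations

* Error control is exact-by-construction only against the model (filtered
  piecewise-constant signal, Gaussian noise, correct filter specification);
  pink/violet noise and artifacts are outside the guarantee.
* The heterogeneous variant's minimal-jump property is approximate (see
  above); its error control is still Monte-Carlo calibrated.
* Clusters of ≥3 changes within an isolation window are flagged, not
  idealized; data dominated by such extreme flickering need
  conductance-distribution methods instead.
* Only Bessel filters are supported, and recordings must be equidistantly
  sampled; ABF files must be exported to CSV by an external reader.
* Hidden-Markov machinery (Baum–Welch, Viterbi, Q-matrix missed-event
  estimators) is intentionally not included; the outputs here (assigned
  levels, dwell times) are designed to feed such tools.
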