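---
title: "Recovering instantaneous gas-exchange signals from flow-through respirometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering instantaneous gas-exchange signals from flow-through respirometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respdeconv)
```

## The problem

A flow-through respirometry chamber holds an animal in a stream of air; a
downstream analyzer records the concentration change $c(t)$ the animal
causes. Washout of the chamber, tubing and analyzer cell low-pass filters
the emitted signal $u(t)$ (the gas exchange rate divided by the flow rate,
$u = \dot V_X / F$): a short CO~2~ burst arrives smeared over seconds to
minutes, and successive bursts overlap. Recovering $u$ from $c$ is a
deconvolution problem, and because deconvolution is a high-pass operation
it is inherently noise-amplifying and ill conditioned.

`respdeconv` treats the measurement chain as a linear time-invariant (LTI)
system, $c(t) = \int_0^t u(\tau)\, h(t - \tau)\, d\tau$, and provides three
recovery methods of increasing generality, the forward simulator used to
benchmark them, and the supporting noise, evaluation and spiracle-phase
machinery.

## Models and methods

### Perfectly mixed chamber and the Z-transform inverse

If mixing is instantaneous and uniform, mass balance gives the first-order
ODE $\dot c = (F/V)(u - c)$, i.e. an exponential impulse response
$h(t) = (F/V) e^{-(F/V)t}$ with time constant $\tau = V/F$. Discretized at
sampling period $T$ with $Z = 1 - e^{-(F/V)T}$, the exact inverse is

$$u(k) = \frac{c(k+1)}{Z} - \frac{1-Z}{Z}\,c(k),$$

implemented by `recover_zt_discrete()`. `simulate_well_mixed()` uses the
matching exponential-integrator update, so the discrete pair
simulate-then-recover is an algebraic identity for piecewise-constant
inputs with an empty chamber — the package's headline exactness test. The
continuous form $u = c + \tau \dot c$ (`recover_zt_continuous()`) accepts
an experimentally tuned $\tau$ and shares the derivative machinery below.

### Gamma-shaped impulse response and the derivative recovery

Measured impulse responses of real chambers are not exponential: they rise
from zero, peak, and decay, and they arrive after a pure transport delay
$\delta$. The package models them as

$$h(t) = \alpha\,(t-\delta)^m e^{-\beta (t-\delta)}, \qquad
  \alpha = \frac{\beta^{m+1}}{\Gamma(m+1)},$$

a unit-area gamma density with shape $m$, rate $\beta$, shifted by
$\delta$. $\Gamma(m+1)$ continues the integer factorial to real $m$, which
the free-shape fitting mode uses; $m = 0$, $\delta = 0$, $\beta = F/V$
recovers the perfectly mixed model exactly.

For integer $m$ the LTI system with this kernel is governed by an
order-$(m{+}1)$ linear ODE, and the input is an exact weighted sum of the
recorded trace and its derivatives:

$$u(t) = \sum_{k=0}^{m+1} a_k\, c^{(k)}(t), \qquad
  a_k = \frac{1}{\beta^k}\binom{m+1}{k}.$$

`compute_ezt_coefficients()` evaluates the weights (a binomial-theorem
self-check $\sum_k a_k \beta^k = 2^{m+1}$ is cheap and is asserted in the
tests) and `recover_ezt()` applies them after removing the delay. For the
28 mL benchmark chamber the integer-shape fits give $(a_1, a_2)$ =
(8.03 s, 16.13 s²) at 250 mL/min ($\beta$ = 0.249 1/s) and (4.36 s,
4.75 s²) at 500 mL/min ($\beta$ = 0.459 1/s); these are the
desk-reproducible numbers `scripts/acceptance.R` recomputes.

### Calibrated FIR inverse

The generalized method drops the parametric kernel entirely: the input at
sample $k$ is a linear combination of the next $N+1$ recorded samples,
$u(k) = \sum_{j=0}^{N} a_j c(k+j)$, with coefficients fit by least squares
on one recording of a known injected input (`calibrate_gzt()`). Each row
of the design matrix is a sliding window of the recorded trace;
mathematically the solution is $(C^\top C)^{-1} C^\top u$, but the package
solves via SVD because the windows of a washout trace are nearly
collinear — the literal normal-equations inverse is kept only as a test
oracle. Rank deficiency falls back to the pseudo-inverse with a
condition-number warning.

Two properties found while validating this method are worth knowing:

* **The transport delay is load-bearing.** For an $m = 1$ kernel with no
  delay, the exact discrete inverse needs one *past* sample
  ($u(k) \propto c(k+1) - 2r\,c(k) + r^2 c(k-1)$ with $r = e^{-\beta T}$),
  which a future-only filter cannot represent; the filter then only
  approximates the inverse. A real chamber's delay shifts the record so
  that the early taps carry the needed past context, and calibration
  becomes essentially exact on noiseless data.
* **Periodic calibration inputs are degenerate.** If the known input is
  strictly periodic, sliding windows longer than the period are linearly
  dependent and the least-squares problem becomes rank deficient; filters
  larger than the period then behave badly off the calibration record. An
  aperiodic (telegraph-like) injection pattern avoids this.

Filter order selection (`select_n()`) calibrates on the first half of the
pair and scores normalized ITAE on the second half. Scoring held-out data
deviates deliberately from scoring the calibration stretch itself, which
cannot penalize overfitting; if the held-out half contains no signal the
score falls back to absolute ITAE. Ties prefer the smaller $N$.

## Noise handling

Recovery is a high-pass operation, so the package mirrors the standard
filtering pipeline: a centered moving average of span 10 samples on the
recorded trace before recovery, another span-10 pass after *each*
differentiation, and an adaptive weak-signal stage. For the last, the
recovery is applied to a stretch of recording known to contain no gas
release; the root-mean-square of that output is the method's noise floor,
and twice the floor (configurable) is the threshold below which recovered
samples are replaced by a strong span-50 moving average
(`estimate_noise_floor()`, `adaptive_filter()`). The threshold comparison
uses the absolute value: undershoot below minus the threshold is treated
as signal, since clipping it would bias the error integral. Spans are
total window lengths; even spans are decremented to stay centered, and the
end windows shrink symmetrically (1, 3, 5, ... samples). Baseline offsets
are removed by subtracting the mean of a user-designated quiet segment,
because the recovery equations assume $c$ measures the change caused by
the animal.

Derivatives are central finite differences (one-sided at the record ends)
followed by the smoothing pass — differentiate first, then filter. The
delay is removed by shifting whole samples; sub-sample delays are rounded
with a warning rather than interpolated.

## Impulse-response fitting

`fit_impulse_response()` minimizes the discrete integral of absolute error
(ITAE, $\sum |h_{\text{model}} - h_{\text{data}}|\,T$) between the model
curve and a unit-area measured response; since the data area is 1 the
objective is directly the error fraction. The delay is initialized at the
5%-of-peak crossing and then refined jointly with $(m, \beta)$ — a
threshold alone is noise-sensitive, and joint refinement is what "minimize
the ITAE" implies. The optimizer is a derivative-free Nelder–Mead simplex
with five restarts from a fixed table of jitter multipliers (deterministic
on purpose: fitting neither consumes nor perturbs the global RNG stream).
Moment matching supplies the starting values ($\text{mean} - \delta =
(m+1)/\beta$, $\text{var} = (m+1)/\beta^2$). Four modes: free real shape;
integer shape (exhaustive search $m = 0..20$); smallest integer shape
within a 10% ITAE budget (fewer derivatives downstream means less noise
amplification); and shape pinned at 0, the best-fit exponential.

## The forward simulator

`simulate_well_mixed()` is step-wise exact for piecewise-constant input at
any sampling period. `simulate_convolution()` samples the delay-free
kernel pointwise on the grid, truncates it where the density falls below
10^-6^ of its peak, convolves (FFT) scaled by $T$, and shifts by the
rounded delay. Pointwise sampling makes the response to a discrete unit
impulse exactly the sampled kernel and conserves signal area to
$O((\beta T)^2)$ for $m \ge 1$ kernels; for $m = 0$ kernels, whose density
steps at the origin, both the area and the agreement with the ODE
integrator carry an $O(\beta T)$ error that vanishes under grid
refinement — the ODE-equivalence test runs at $T = 0.25$ ms for this
reason.

`generate_pulse_train()` produces the benchmark inputs: rectangular pulse
trains as produced by switching the inlet between scrubbed air and a
100 ppm CO~2~ source. The standard calibration input is three 200 ms
pulses two seconds apart; the evaluation inputs are three pulses at 50%
duty at switching frequencies 0.1, 0.167, 0.25, 0.5 and 1 Hz, sampled at
10 Hz through the 28 mL benchmark chamber (integer-shape kernel $m = 1$,
$\beta = 0.249$ 1/s, $\delta = 5.82$ s at 250 mL/min). Sensor noise is
i.i.d. Gaussian, seed-deterministic, with the fixture default
$\sigma = 0.5\%$ of the pulse amplitude (0.5 ppm) — instrument noise for
such analyzers is not standardized, so this is a single fixed choice, made
once.

What the simulator does *not* emulate: flow-rate perturbation by the
injection itself (which would break the LTI assumption), temperature and
pressure corrections, analyzer drift, and non-Gaussian or correlated
instrument noise. Passing benchmarks on synthetic data therefore
demonstrates correctness of the inverse computations under the stated
model, not performance on any particular instrument.

## Evaluation and what the benchmark shows

`itae()` integrates $|\hat u - u|$ trapezoidally over the common support
(a recovery output shorter than the truth is scored on its own support);
`normalized_itae()` divides by the truth's area on that support, so a
recovery that misses everything scores exactly 1.
`run_frequency_sweep()` assembles the full benchmark: simulate each pulse
train, add noise, recover with each method, average normalized ITAE over
seeds. The pulse-train records include a washout-length quiet tail (the
truth grid extends until the chamber has emptied), and all methods share
the adaptive weak-signal filtering, with the noise floor estimated on the
pre-pulse quiet region.

On noiseless data the sweep reproduces the expected structure cleanly: the
calibrated FIR is best, the derivative recovery second, the exponential
inverse worst, at every frequency, and every method degrades monotonically
as the switching frequency rises. With noise at the fixture level the
monotonic degradation persists, but the ranking partially inverts at the
extremes: the quiet-tail portion of the error integral is proportional to
each method's recovered-noise floor, and those floors order ZT < GZT < EZT
(one smoothed derivative, versus a 231-tap filter calibrated on a noisy
pair, versus two smoothed derivatives with weights up to 16 s²). At low
frequency the signal area dominates and the derivative recovery wins; at
high frequency the noise floor dominates and the exponential inverse's
small floor wins. This trade-off is a real property of the stated noise
level and scoring window, not of the inverse computations; the noiseless
ordering is asserted in the test suite, and the noisy-case behaviour is
reported as measured.

Problem sizes throughout the tests and benchmark — records of roughly
10^3^–10^5^ samples, five noise seeds, filter orders up to a few hundred —
were chosen as representative of a 10 Hz gas analyzer workflow while
keeping every computation a desk-scale exercise.

## Spiracle phase classification

`vco2_from_u()` converts the recovered dimensionless input to a release
rate, $\dot V_{CO_2} = F \cdot u$, reported in µL/min. The open/closed
threshold comes from a hyperoxic recording, during which spiracles stay
closed for long stretches: the mean of the contiguous two-minute window
with the lowest mean, times four (`hyperoxia_threshold()`). "Lowest
continuous values" is read as a contiguous window — the alternative
(below-quantile samples scattered through the trace) discards the
contiguity the wording implies; ties resolve to the earliest window.
Samples strictly above the threshold count as open; equality counts as
closed (`classify_phases()`). Because washout smears bursts above the
threshold for longer than the emission itself lasted, the raw recorded
trace overstates the open fraction, and sharper recoveries reduce it —
the package's tests assert exactly this direction of effect on synthetic
bursty traces.

## Known limitations

* The gamma kernel is an empirical shape family, not a transport model;
  chambers with multi-modal or heavy-tailed responses need the calibrated
  FIR route.
* The derivative recovery requires integer shape; free-shape fits must be
  re-fit in an integer mode first (fractional-order differentiation is out
  of scope).
* Delays are whole-sample; sub-sample alignment error of up to half a
  sampling period is accepted and scored as part of the recovery error.
* FIR coefficients are specific to the sampling period they were
  calibrated at; applying them to a differently sampled record is refused
  rather than resampled.
* The CSV interface assumes strictly uniform sampling and rejects
  anything else at read time.
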