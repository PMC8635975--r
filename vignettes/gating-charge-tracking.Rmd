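---
title: "Tracking a gating charge optically: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking a gating charge optically: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsdtrack)
```

## The physical picture

A voltage-sensing domain (VSD) responds to membrane potential through its
S4 arginines. Substituting one arginine with a cysteine conjugated to a
small cationic bimane dye (qBBr) preserves the charge while making the
residue fluorescent, and a tryptophan placed in or near the charge's path
quenches that fluorescence in a steeply distance-dependent way. The
recorded fluorescence then reports where along its trajectory the charge
sits, in real time, while the gating current reports the summed charge
displacement of all sensors. `vsdtrack` models this measurement end to end.

## The kinetic model and its assumptions

The VSD is a continuous-time Markov chain over `n >= 2` conformational
states. The model assumes:

* **Discrete states, memoryless transitions.** The trajectory is a set of
  metastable positions `x_i` (Å, scalar 1-D coordinate) separated by
  barriers; dynamics within a well are not modelled.
* **Single-barrier voltage dependence.** Each directed transition has
  `k_ij(V) = k0_ij exp(z_ij V / kT)` with `k0_ij` in 1/ms and `z_ij` in
  elementary charges. `kT/e0` defaults to 25.4 mV (about 22 °C,
  room-temperature recordings). No other temperature dependence exists in
  the model. Rates that overflow to non-finite values (extreme `V × z`)
  are an error, never silently clamped.
* **Piecewise-constant command voltage.** Protocols are ordered
  `(duration, voltage)` segments, left-closed/right-open, with an
  indefinite holding potential before `t = 0`. Ramps are not supported.
* **Non-conducting constructs.** There is no pore model and no ionic
  current; gating current is purely the rate of change of the mean
  cumulative gating charge, `I_g = n_ch d<q>/dt`.

Occupancies obey `dP/dt = P Q(v(t))` and are propagated exactly within
each segment by the matrix exponential of `Q · dt` (cached per segment for
the regular sampling step; partial steps at segment boundaries are
evaluated directly). Output is sampled on the protocol grid. Probability
round-off is renormalized when the row sum drifts beyond 1e-12 and treated
as an error beyond 1e-6.

## The quenching observable

The classical Stern–Volmer concentration dependence becomes a distance law
through `d ∝ C^(-1/3)`: the surviving emission fraction at separation `d`
is `g(d) = 1/(1 + (λ/d)^3)`. Two conventions are fixed here:

* `g(0) = 0` (complete quenching) rather than an error, so a state may sit
  exactly at the quencher's coordinate.
* `λ` (default 6 Å, configurable) is the distance at which half the
  emission is quenched. The default makes quenching near-complete at
  van-der-Waals contact and pushes it below ~20% beyond 10 Å, the
  documented range of bimane–tryptophan photoinduced electron transfer.
  Whether `λ` should be read center-to-center or side-chain-adjusted is
  left to the user: it is a parameter, nothing in the code assumes either
  framing.

The deterministic ensemble observable is `F(t) = F0 Σ_i P_i(t) g(|x_i −
x_w|)`. Two of its properties anchor the test suite: for two states the
normalized time course equals `P0(t)` independently of `x_w`, `x0`, `x_f`
and `λ` (whenever the amplitude is nonzero), and with three or more states
the trace carries `n − 1` exponential components and can be biphasic when
the intermediate state dwells near the quencher. The shipped configs
`three_state_biphasic.yaml` (dwell comparable to the pulse, quencher at
4.5 Å next to the 5 Å intermediate) and `three_state_brief_dwell.yaml`
(20× faster exit, quencher at 2 Å) realize the two regimes; their rate
values are synthetic demonstration parameters.

Orientation/rotamer dependence of quenching and fluorophore photophysics
(blinking, shot noise, single-molecule bleaching) are deliberately outside
the model.

## Stochastic single-molecule simulation

`simulate_path()` draws exact trajectories: within a segment, exponential
waiting times at the current state's total exit rate; when a segment
boundary arrives first, the waiting time is re-drawn under the new rates.
By memorylessness of the exponential distribution this boundary handling
is exact, not an approximation. Determinism is guaranteed per seed, and
ensemble members use seeds `seed + molecule index`, so any molecule can be
re-simulated in isolation. Single-molecule output is an intensity level
(piecewise-constant, right-continuous); photon statistics are not
emulated.

A design point worth making explicit: stochastic/deterministic agreement
is verified at a half-activating test potential (−40 mV for the default
two-state sensor). There both states stay populated at every grid time, so
the per-point standard error is estimated from well-resolved counts. At
strongly saturating potentials the minority state's expected count at
10,000 molecules falls below one per grid point and the empirical standard
error collapses to zero while the true deviation stays finite — a
small-count artifact of the estimator, not a model discrepancy.

## The analysis pipeline

The pipeline mirrors standard cut-open-oocyte fluorimetry practice, with
each ambiguity resolved explicitly:

* **Filtering**: a 4-pole low-pass Bessel response, applied causally
  (mimicking acquisition hardware), with DC gain exactly 1. The analog
  prototype poles come from the reversed Bessel polynomial, scaled to put
  the −3 dB point at the requested cutoff, then discretized by the
  bilinear transform with prewarping. A zero-phase forward–backward
  variant exists behind a flag, off by default. Filtering precedes
  baseline subtraction when both are used.
* **ΔF/F₀**: a least-squares line fitted over a pre-pulse baseline window
  (default: the period 6000–1500 ms before the pulse onset, shrunk
  proportionally for shorter sweeps), extrapolated and subtracted across
  the sweep. `F0` is the extrapolated line at pulse onset — the
  subtraction window itself says nothing about where `F0` is evaluated,
  so this is fixed by convention here. The response window defaults to
  the last 20% of the test pulse (steady state). Windows are half-open
  `[start, end)` in ms; `t = 0` is sweep start and the pulse onset is
  derived from the protocol, never detected from data. The returned 95%
  confidence interval combines the response-mean standard error with the
  baseline-extrapolation uncertainty.
* **Charge**: linear baseline over user-defined windows (defaults mirror
  the "current returned to zero" convention: the tails of the holding
  periods), then trapezoidal integration.
* **Exponential fits**: Levenberg–Marquardt on `offset + Σ A_k
  exp(−t/τ_k)` with `τ > 0` enforced, initial values from the trace range
  and a log-linear estimate (capped at half the window: a slower
  relaxation is unidentifiable within the window), and a documented
  restart ladder (τ × 1, 1/10, 1/3, 3, 10) with the best converged fit
  kept. The optimizer is used through its residual-function interface so
  that a vanishing second component (a perfectly single-exponential
  trace fitted at order 2) degrades gracefully instead of failing on a
  singular model matrix. The *weighted* τ of a double fit is the
  amplitude-weighted mean `Σ|A_k|τ_k / Σ|A_k|` — the conventional
  reading, stated here because "weighted" alone underdetermines it.
* **Voltage curves**: QV normalized to [0, 1] by min/max and FV by the
  maximum absolute value, *per recording* (as done per oocyte), with
  mean ± SEM pooled per voltage afterwards.
* **Cole–Moore analysis**: per prepulse condition, sweeps are averaged,
  baseline-corrected over the pre-prepulse holding period, and the test
  pulse fitted with a weighted double exponential; conditions must share
  an identical test pulse.

## The synthetic-recording generator

`generate_sweep()` emulates what the acquisition chain would hand the
analyst:

* sampling at 50 kHz by default (protocol `sample_interval = 0.02` ms),
  with four consecutively-seeded sweeps per condition for averaging;
* a recorded intensity `F0 (b + (1 − b) Σ P_i g_i)`: the channel-coupled
  signal diluted by a dominant uncoupled background fraction `b`. For
  each construct preset keyed to a published fractional change, `b` is solved analytically from the
  steady-state occupancies at the holding (−120 mV) and test (+80 mV)
  potentials so that the noiseless steady-state ΔF/F₀ equals the
  construct's published value exactly — presets are self-consistent by
  construction, and the resulting `b ≈ 0.99` reproduces why sub-1%
  fractional changes ride on a large background;
* per-sweep additive Gaussian noise (default SD 10% of the pulse-response
  amplitude, halved by 4-sweep averaging), linear drift (1e-4 F₀/s) and
  slow multiplicative photobleaching (0.01/s);
* gating current from the same occupancy solution (default 1e9 channels,
  giving sub-µA currents).

"No effect" constructs are modelled phenomenologically as a small, fast
(τ = 0.5 ms), voltage-independent additive step whose amplitude is the
published value; the mechanism of that residual signal is not modelled.
The kinetic rate constants attached to preset labels are tuning choices
targeting millisecond-scale activation (forward `0.05/ms·e^{V/25.4}`,
backward `0.00214/ms·e^{−V/25.4}`, midpoint −40 mV, z = 2 e₀); no
published rate table exists for these constructs and the rates should not
be read as measured values. The extra `"deep-closed"` preset adds a third
state entered only at very negative potentials (entry τ ≈ 0.7 s at
−160 mV, exit τ ≈ 10 ms at +80 mV, cumulative charge −0.5 e₀) for
Cole–Moore simulations; it is synthetic and labelled as such.

What the generator does **not** emulate: capacitive transients and leak
(recordings are assumed leak-subtracted), oocyte-to-oocyte variability
beyond per-recording scale factors, photon shot noise, and absolute
photodiode units. Passing tests therefore demonstrate correctness of the
model and pipeline under these idealizations, not robustness to every
artifact of real recordings.

## Problem sizes

The defaults used by the test suite and the acceptance script are chosen
as a balance between statistical resolution and run time, and are the
package's own choices: 600 ms pre-pulse baselines (with the baseline
window scaled proportionally from the 6000–1500 ms convention), 100 ms
test pulses at 50 kHz for ΔF/F₀ recovery, 10,000 molecules for ensemble
convergence, 200 seeded repetitions for confidence-interval coverage, and
0.2 ms sampling for the multi-second Cole–Moore protocols. The
fine-step explicit-Euler oracle used to cross-check the matrix-exponential
propagator runs at 1e-5 ms steps on schemes with rates of order 0.1/ms,
where the first-order method's global error sits safely below the 1e-6
comparison tolerance.

## Known limitations

* The trajectory coordinate is scalar; a 3-D position mode (Euclidean
  distances) would be a straightforward extension but is not implemented.
* Quenching is static and isotropic: one λ, no rotamer or orientation
  effects, no distinction between tryptophan and tyrosine efficiency
  beyond the λ value chosen.
* The background fraction is a single per-construct constant; real
  background fluorescence varies between oocytes and over time beyond the
  linear drift and exponential bleach modelled here.
* Markov schemes with degenerate (defective) generators are handled by
  the segment-stepping propagator, but pathological inputs such as
  disconnected schemes are rejected rather than analysed per component.
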