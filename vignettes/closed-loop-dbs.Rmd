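---
title: "Model-based closed-loop control of thalamic DBS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based closed-loop control of thalamic DBS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dbsloop` simulates the pathway from thalamic (Vim) deep brain stimulation to
surface EMG in essential tremor, fits a fast polynomial biomarker that stands
in for the full simulation, and closes the loop with a PID controller that
adjusts the stimulation frequency until the EMG power reaches a target. This
vignette is the package's account of the model, the numerical choices, and
the places where the design was genuinely open.

## The pathway model

The simulator has four stages, all sharing a 0.1-ms step (`dt` in
`dbs_config()`; the 1-ms cortical refractory period is the shortest timescale
and is resolved ten-fold).

**Short-term synaptic plasticity.** Every input pathway passes through a
Tsodyks–Markram (TM) synapse. Between presynaptic events the release variable
`u` relaxes to its resting point with `tau_fac` (0 disables facilitation),
resources `r` recover to 1 with `tau_dep`, and the post-synaptic current
decays with `tau_syn`. At an event the synapse facilitates, releases `u r`,
and depletes; the PSC jumps by `gain * u * r`. State updates between events
are exact exponentials, so per-event amplitudes do not depend on the
integration step. The canonical event ordering (facilitate, release, deplete)
makes the first event from rest release exactly `U * gain`, and for a purely
depressing synapse the pre-pulse resources converge to
`(1 - exp(-D/tau_dep)) / (1 - (1-U) exp(-D/tau_dep))` at pulse interval `D` —
the oracle the tests check against. All shipped synapse parameters are
*uncalibrated placeholders*: the source fits are unpublished, so values were
chosen once against the qualitative behaviour described below and are not
revisited.

**Vim rate network.** Three populations (DBS-targeted Vim, an external
excitatory group, an inhibitory group) follow Wilson–Cowan-style dynamics
`tau dr/dt = -r + F(W r + drive + I_dbs)` with a saturating rectified sigmoid
`F(x) = max / (1 + exp(-(x - theta)/slope))`, integrated by exponential
Euler. The DBS current enters the Vim population (couplings to the other
populations are configurable and default to zero). Calibration targets, fixed
before any downstream fitting: a DBS-OFF operating point of 25 Hz (clinical
baseline range 10–40 Hz), a high-amplitude onset transient followed by
partial adaptation under high-frequency stimulation (driven by the depressing
DBS synapse, `tau_dep` = 250 ms), and pulse-locked rate modulation whose
amplitude falls smoothly with stimulation frequency. The simulation starts at
the analytic DBS-OFF fixed point (found by damped iteration), so DBS-OFF
traces are flat from the first sample.

**Corticospinal stage.** Each of the `N_c = 150` M1 neurons is a leaky
integrate-and-fire unit, `tau_V dV/dt = -(V - EL) + R Isyn` with threshold
−35 mV, reset −90 mV and a 1-ms refractory period. The published form of the
membrane equation is typographically ambiguous; the standard sign convention
is used, since the alternative (excitation hyperpolarizing) is unphysical.
Inputs are the shared DBS axonal TM current (stimulation activates the axons
synapsing onto M1, identically across the population) plus one independent
Poisson realization each of the Vim rate and of the tremor background
(reading "Poisson spike trains" as one effective afferent per pathway per
neuron, with the synaptic gain absorbing the afferent count). Poisson
generation is per-bin thinning with `p = rate * dt / 1000`, rejected if any
bin exceeds 0.3. Motoneurons (`N_m = 120`) each receive 70 randomly chosen M1
inputs through a delayed exponential PSC (`C exp(-(t - td_cm - k)/tau_i)`,
static weights — the cited plasticity rule describes the kernel, not ongoing
weight changes) and follow a spike-response membrane: a reset transient
`V0 exp(-(t-t_sp)/tau_p)` plus a recovery-gated convolution
`(Rm/tau_m)(1 - exp(-(t-t_sp)/tau_r)) * int exp(-s/tau_m) I(t-s) ds`,
evaluated by the exact exponential recursion and cleared at each spike.
Motoneuron voltages are relative-to-rest (thresholds drawn uniformly from
[5, 15] mV, reset −22 mV), a deliberately different convention from the
absolute-scale M1 membrane; both are kept as published.

**Tremor background.** A 6-Hz burst waveform: each 166.7-ms period opens with
three full 20-ms sinusoid cycles riding on a low baseline (4 Hz) with a large
amplitude (70 Hz), rectified at zero. The rectification lifts the mean rate
during a burst, which is what makes the burst rate dominate the 2–20 Hz band
downstream. Note that the raw waveform, being 6-Hz periodic with three
intra-burst cycles, necessarily has its largest Fourier line near the
48–54 Hz harmonics; the 6-Hz line dominates after the synaptic and membrane
low-pass stages, and the simulated DBS-OFF EMG peaks at 6 Hz.

**EMG synthesis.** Each motoneuron spike elicits a motor-unit action
potential `A (t - tau) exp(-((t - tau)/lambda)^2)` after a 10-ms conduction
delay; the published exponent is ambiguous and the first-order
Hermite–Rodriguez form is adopted (the literal alternative sits behind
`muap_params(hermite = FALSE)`). Unit amplitudes are exponential with mean
`7e-3`, drawn once per run. The superposition is computed on the fine grid
and box-averaged into 500-Hz samples (anti-aliasing the sharp MUAP onsets),
then Gaussian noise of sd 0.025 mV is added at the EMG rate.

### What the shipped operating regime does and does not emulate

With the placeholder synaptic parameters, high-frequency stimulation drives
the motor pool into fast, regularized firing. That regularization — loss of
coherent 6-Hz population bursting plus motor-unit "fusion" that moves
fluctuation energy above the 2–200 Hz analysis band — is what suppresses the
EMG power at ≥ 100 Hz relative to DBS-OFF, while low-frequency stimulation
produces large synchronized volleys and *raises* the power, consistent with
the clinical ineffectiveness of low-frequency Vim-DBS. The price of this
regime is that sustained motoneuron rates under strong stimulation exceed
the physiological 5–50 Hz range (which the model respects in the DBS-OFF
condition, the condition that range describes). A model with calibrated
upstream parameters would likely achieve suppression at more moderate rates;
without the published fits this is the regime that reproduces the
reference-side phenomenology, and the tests assert exactly that
phenomenology (power ordering, tremor peak, motoneuron DBS-OFF rates).

## The biomarker

The surrogate maps the standardized Vim rate through an order-25 polynomial,
`yhat = phi_0 + sum phi_n zeta^n + noise`, with `zeta = (x - mean)/sd`.
Design choices:

* **Global standardization.** The mean and sd are computed once on the
  concatenated training rates and frozen; a per-signal standardization would
  give each stimulation frequency its own map and break the controller.
* **Conditioning.** The least-squares problem is solved in a discrete
  orthogonal basis built by the Forsythe three-term recurrence; raw 25th
  powers of the regressor are never formed (the standardized rate has rare
  onset-transient values near 10 sd, where a monomial basis loses all
  precision). Monomial coefficients `phi_0..phi_25` are reported exactly via
  the recurrence for interpretability, but evaluation always uses the
  orthogonal form. Serialization to JSON keeps both.
* **Alignment lag.** The reference EMG trails the Vim rate by the model's own
  corticospinal latency: the two published conduction delays plus the cortical
  membrane integration lag, `td_cm + td_mm + tau_V` = 30 ms. Fitting the map
  strictly pointwise across that latency flattens the polynomial and
  decorrelates its transient, so `fit_reference_biomarker()` pairs
  `x(t)` with `y(t + lag)` at that fixed physiological lag, and prediction
  returns `psi(x(t - lag))` so the estimate carries the same timing. The lag
  is a constant of the model, not a fitted quantity; `fit_biomarker()` itself
  defaults to `lag = 0` for strictly pointwise use.
* **Noise.** Estimated EMG adds Gaussian noise of sd 0.038 mV, the residual
  scale of the published fit. The fit runs against the noisy reference EMG
  (as generated); a noise-free reference can be produced by setting
  `muap_params(noise_sd = 0)`.
* **Order selection.** `order_selection_curve()` refits at every order and
  reports training R², which is non-decreasing (nested least squares); the
  knee is the smallest order within tolerance of the maximum. Order 25 is the
  published choice and the default.

## Spectral system output

`p(f, t)` is a Hann-windowed short-time power (window 1 s, matching the 1-Hz
spacing of the integer analysis band 2–200 Hz at `fs` = 500 Hz, Nyquist
250 Hz), discretized as a plain Riemann sum with `ds = 1/fs`; `P(f, T)` is
its trapezoid time-integral on a 10-ms hop grid; the scalar output `z(u)` is
the horizon mean of the band sum over the first `T = 5` s. The published time
limits `[0, T]` are preserved by zero-padding the signal half a window on
each side; the resulting edge bias (the first and last half-window see
padding) is shared by reference and estimated signals and shrinks as `T`
grows. Closed forms used as test oracles: `H(0) = 1`, `H(±w/2) = 0`,
`int H = w/2`, `int H^2 = 3w/8`, sinusoid power `a^2 w / 16` at the tone and
`3a^2/32` after summing the two adjacent 1-Hz bins, and white-noise output
`199 * 3 sigma^2 / (8 fs)`. Halving the hop changes `z` by under 1%.

## The controller

The position-form PID is implemented literally as published: the *output* is
`Kp e + Ki sum e dt + Kd (e_m - e_{m-1})/dt`, clamped to [10, 200] Hz, with
the derivative defined zero at the first step and `u_init` = 10 Hz (the
lowest valid frequency; the published starting point is not stated). Two
consequences of the position form are handled explicitly:

* **Anti-windup.** With the published integral gain (1e5 Hz per mV² min), any
  sustained error winds the integral far past the clamp and the loop never
  recovers; the integral is therefore frozen whenever the clamp is active
  and the current error would push further outside. This is an artifact
  addition, documented as such.
* **Convergence.** The published account states convergence "in 10 min"
  without a criterion. The loop records a settling time — the first time the
  error has stayed within a noise band for three consecutive control steps —
  and a converged flag (in band over the final three steps). The band is
  twice the empirical sd of the plant output at the target-generating
  frequency, estimated from 10 replicates by `control_target()`.

The published gains are matched to the mV²-scale system output of the
biomarker plant. Demonstration plants on an order-1 power scale (such as the
linear plant used to verify fixed-point recovery) are run with the gains at
proportionally reduced magnitude, under which the loop converges to the
unique fixed point of any strictly decreasing plant.

## Validation utilities

`compute_psth()` aligns spikes to stimulation pulses (lags in [0, 7.7] ms,
the 130-Hz inter-pulse interval; for faster trains the window shrinks to the
actual interval), histograms at 0.05 ms, smooths with a 0.2-ms Gaussian
kernel truncated at ±4 sd and renormalized, and normalizes per pulse and per
second — so the curve integrates back to spikes per pulse. `psth_compare()`
scores a simulated PSTH against any external spike-time CSV with
`R^2 = 1 - SS_res/SS_tot`; no external recording ships with the package, so
the packaged checks use synthetic references only.

## Problem sizes and reproducibility

The shipped study conditions are the published ones: 150 M1 neurons, 120
motoneurons, fan-in 70, 5-s training runs at the nine training frequencies
(10, 50, 80, 100, 120, 130, 140, 160, 200 Hz), a 10-s DBS-OFF run for the
tremor spectrum, and 31-step control runs (10 min at 20-s steps). A full
training fit takes well under a minute on one core; unit tests use
`scale_config()` (30 M1 neurons, 24 motoneurons, fan-in 14) and the
`make_fixtures()` bundle (10/8 neurons, 2 s, order-5 biomarker) where the
full scale is not needed. Every stochastic stage (Poisson draws, wiring,
thresholds, amplitudes, noise) honours a single seed, and the whole pipeline
is bit-reproducible given `(config, seed)`. At reduced population sizes the
tremor's coherent signal (which scales with the squared population size)
falls below the noise floor, so scaled-down checks compare the low- versus
high-frequency contrast rather than DBS-OFF versus DBS-ON.

## Known limitations

* Upstream (Vim network and synapse) parameters are uncalibrated
  placeholders; all quantitative surrogate-fidelity results depend on them.
  In particular the estimated-EMG system output is nearly flat above
  ~100 Hz at the plant noise scale, so while the closed loop reliably
  reaches the *power* target within the horizon, the steady-state
  *frequency* is only weakly identified there — self-consistency recovery of
  a 130-Hz generating frequency lands well below 130 Hz. With a calibrated
  Vim model whose pulse-locked modulation remains strong and discriminable
  through 100–200 Hz, the same machinery recovers the generating frequency
  (as the linear-plant checks demonstrate for any plant with usable slope).
* The biomarker cannot represent EMG components absent from the Vim rate:
  the tremor background enters the pathway at M1, so the estimated EMG
  carries no coherent 6-Hz component and under-represents the tremor band
  at low stimulation frequencies.
* The memoryless map cannot reconcile carrier-phase misalignment at high
  stimulation frequencies; correlations there are carried by the onset
  transient and the shared envelope.
* No conductance-based synapses, electric-field/VTA or antidromic effects,
  no spiking Vim model, no motor-unit recruitment ordering, no
  amplitude/pulse-width control, and no gain auto-tuning (the published
  tuning procedure is unavailable; the published gains ship as defaults).
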