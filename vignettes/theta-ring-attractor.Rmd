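---
title: "A spiking ring attractor with intrinsic theta: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spiking ring attractor with intrinsic theta: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`thetaring` simulates a one-dimensional continuous-attractor network
(CAN) of grid-cell-like principal cells and interneurons. `N_E = 1024`
excitatory principal cells (E) and `N_I = 256` inhibitory interneurons
(I) sit uniformly on separate rings, each neuron labelled by its angular
position $\theta \in [0^\circ, 360^\circ)$. Every neuron is a leaky
integrate-and-fire (LIF) unit,

$$C_m \frac{dV_m}{dt} = -g_L (V_m - V_L) - I_{syn}(t) + I_{ext}(t),$$

firing when $V_m$ reaches $V_{th} = -50$ mV, then resetting to
$V_{reset} = -60$ mV for an absolute refractory period. Membrane
constants are $C_m = 0.5$ nF, $g_L = 25$ nS, $\tau_{ref} = 2$ ms for E
cells and $C_m = 0.2$ nF, $g_L = 20$ nS, $\tau_{ref} = 1$ ms for
interneurons; both have $V_L = -70$ mV.

There is no recurrent excitation between principal cells in the default
model. E cells excite interneurons through NMDA-conductance synapses
with the voltage-dependent magnesium block

$$B(V) = \frac{1}{1 + [\mathrm{Mg}^{2+}]\, e^{-0.062 V} / 3.57},$$

and interneurons inhibit both populations through GABA-A synapses.
NMDA gating is second order: an intermediate variable $x_j$ jumps by 1
at each presynaptic spike and decays with $\tau_x = 2$ ms, and the open
fraction obeys
$\dot S = -S/\tau_{NMDA} + \alpha x (1 - S)$ with
$\tau_{NMDA} = 100$ ms and $\alpha = 0.5$ kHz, saturating at 1. GABA
gating is first order with unit spike increments and
$\tau_{GABA} = 10$ ms. Maximal conductances are
$g^{E\to I}_{NMDA} = 0.4$ nS, $g^{I\to E}_{GABA} = 2.4$ nS and
$g^{I\to I}_{GABA} = 0.04$ nS; reversal potentials 0 mV (excitatory)
and $-70$ mV (inhibitory).

Coupling strengths depend only on the circular angular difference
$\Delta\theta \in [0^\circ, 180^\circ]$ between the neurons:

* E→I: $W(\Delta\theta) = J_- + (J_+ - J_-)
  \exp(-\Delta\theta^2 / 2\sigma^2)$ with $J_+ = 1.6$ and
  $\sigma = 30^\circ$ — strongest onto interneurons at the same angle;
* I→E: $W(\Delta\theta) = G \exp(-(\Delta\theta - 90^\circ)^2 /
  2\sigma^2)$ with $\sigma = 30^\circ$ — interneurons inhibit principal
  cells a quarter-ring away;
* I→I: uniform ($W = 1$) by default.

$J_-$ and $G$ are not free parameters: they are fixed by the
normalization that the mean of each profile over angular differences is
exactly 1 (at the defaults $J_- \approx 0.842$, $G \approx 2.40$). This
architecture makes two bump attractors (180° apart) the stable
configuration: active E cells excite nearby interneurons, which
suppress the E cells 90° away, while the interneurons *between* the
bumps return weaker inhibition onto the bumps themselves. That closed
E–I loop, paced by the slow NMDA decay, is what generates the
theta-band (4–12 Hz) oscillation intrinsically — no pacemaker input is
needed.

External drive is a constant excitatory background
($I^E_{back} = 750$ pA, $I^I_{back} = 325$ pA), a septal (MS) GABAergic
term delivered to interneurons only,
$I_{MS}(t) = I_{MS,0} + A\cos(2\pi f_{MS} t)$ with $I_{MS,0} = -100$ pA
and $A = 0$ by default, and an independent Ornstein–Uhlenbeck (OU)
noise current per neuron,

$$\tau_{n}\, dI_{n} = -I_{n}\, dt + \eta \sqrt{\tau_{n}}\, dW,$$

with $\eta = 150$ pA and $\tau_n = 2$ ms.

### A note on the noise amplitude convention

Under the equation above the stationary standard deviation of the noise
current is $\eta/\sqrt{2} \approx 106$ pA, not $\eta$. Because $\eta$
is sometimes described as "the standard deviation of the noise", the
package implements the equation as written by default
(`noise_convention = "as_written"`) and offers
`noise_convention = "target_sd"`, which rescales the innovation so the
stationary SD equals $\eta$ itself. All shipped results use the
as-written form.

## Protocols

* **Default** (`protocol_default()`): 8 s, $V_m(0) \sim U(-60, -50)$ mV
  per neuron, all gating zero, full noise; a 200 pA cue is injected
  into E cells in $[67.5^\circ, 112.5^\circ] \cup [247.5^\circ,
  292.5^\circ]$ for the first 500 ms so that the two bumps form at 90°
  and 270° on every trial. All analyses exclude the first second.
* **Deterministic / synchronous** (`protocol_deterministic()`): noise
  off, every $V_m(0) = -60$ mV, no cue, interneuron background reduced
  to 100 pA. With all E cells identical the whole population spikes in
  global volleys and the E–I loop is exposed in its purest form: each E
  volley loads the NMDA gating, the interneurons burst until that
  drive decays below their rheobase, and the E cells then recover and
  volley again, at a theta-band rate.

  The choice of drive currents here deserves a comment. The E-cell
  rheobase is $g_L (V_{th} - V_L) = 500$ pA, and principal cells
  receive only inhibitory synaptic input, so any constant E drive below
  500 pA provably silences the network forever — there is no rebound
  mechanism in a LIF cell with the GABA reversal at $V_L$. A
  synchronous oscillation therefore requires the E background to stay
  at its suprathreshold default (750 pA), and the protocol reduces only
  the interneuron background (to 100 pA, i.e. a net external drive of
  0 pA once the −100 pA septal term is added). This reproduces the
  intended dynamics: global E volleys at ≈ 5.3 Hz with interneurons
  firing ≈ 20 spikes per cycle in periodically-spaced bursts.
* **Suppression** (`protocol_suppression(w)`): default protocol plus a
  constant −200 pA current to interneurons within $w$ degrees of 0° or
  180° — the interneurons *between* the bumps, whose feedback carries
  the theta rhythm. Theta power falls monotonically as $w$ grows.
* **Rhythmic septal input** (`protocol_rhythmic(A, f_MS)`): default
  protocol with the cosine septal term; used for the
  entrainment/resonance sweeps.

## Numerical scheme

The coupled smooth system (membrane potentials and gating variables) is
advanced with Heun's method (explicit trapezoid), a second-order
Runge–Kutta scheme, at `dt = 0.02` ms. Discontinuous events are handled
outside the smooth step:

* **Noise** is updated once per step with the *exact* OU
  discretization, $I' = I e^{-dt/\tau} + \sigma_{st}\sqrt{1 -
  e^{-2dt/\tau}}\,\xi$, and held constant within the step, so its
  stationary statistics are correct at any `dt`.
* **Threshold and reset** are applied on the post-step potential; the
  spike time is the end-of-step time (no within-step interpolation —
  at 0.02 ms the interpolation error is far below any reported
  quantity's sensitivity).
* **Spike increments** to the presynaptic gating ($x \mathrel{+}= 1$,
  $S_{GABA} \mathrel{+}= 1$) are applied after threshold detection and
  first influence the following step, i.e. one integration step of
  synaptic latency and no axonal delay.
* **Refractoriness** clamps $V_m$ at $V_{reset}$ while the per-neuron
  clock runs down; gating and noise keep evolving. A neuron can never
  cross threshold while refractory, so inter-spike intervals are
  bounded below by $\tau_{ref}$.
* Gating variables that decay purely exponentially would reach the
  denormal floating-point range after a few quiet seconds and slow the
  arithmetic dramatically; values below $10^{-30}$ (some 25 orders of
  magnitude below any dynamical scale) are flushed to zero.

### Evaluating the synaptic drive

The drive sums $\sum_j W_{ij} S_j$ are the cost centre: the weight
matrices are circulant in the angular difference, so the package
evaluates them either densely (reference path) or by circular
convolution via FFT on the common fine grid (default on the standard
1024/256 rings). The two paths agree to relative $10^{-12}$ and produce
identical spike trains; the test suite asserts both. The discrete
normalisation is applied per presynaptic-offset class on the fine grid,
which makes every row mean of the built matrices exactly 1 — for the
I→E profile, whose circular-distance kernel has folds at 0° and 180°,
offset classes differ by a relative $10^{-5}$, and symmetric offsets
share the same constant so the matrix remains an even function of the
angular difference.

A Heun step with `dt = 0.02` ms changes the first hundred spike times
of the synchronous protocol by well under 0.1 ms when the step is
halved; population rates shift by ≲ 2%. Quantities tied to the
synchronous regime (volley rate, interneuron spikes per cycle) are the
most scheme-sensitive numbers the package reports, since every neuron
sits at threshold simultaneously; the stochastic-protocol spectral
metrics are far more forgiving.

## Analysis suite

* **pLFP**: the proxy of the local field potential is the population
  mean over principal cells of the GABA current each receives, delayed
  by $\tau_{GABA}$ (10 ms = 2 samples at the 200 Hz trace rate).
* **Spectra**: Welch's method with a periodic Hamming window, 256-sample
  segments, 128 overlap, 1024-point transforms, per-segment mean
  removal, one-sided density scaling (the implementation is validated
  against an independent reference to full precision in the tests).
  The primary peak frequency is the argmax of the density over
  (0, 50] Hz; the DC bin is excluded.
* **Peak power**: the ratio of a 2-Hz band centred on the peak to the
  whole 0–50 Hz range. Two conventions are implemented: the ratio of
  *mean densities* (default), which exceeds 1 for a sharp peak and
  approaches 25 in the single-bin limit, and the ratio of *integrated
  powers*, which is bounded by 1. The mean-density form is the default
  because it reproduces the ≈ 4 scale of the reported peak-power
  statistic, which a bounded power fraction cannot. Theta power is
  likewise the mean density over 4–12 Hz divided by the mean over
  0–50 Hz.
* **Bump tracking (PAV)**: in 400 ms windows sliding every 5 ms the
  population activity vector $P = \frac{1}{N_E}\sum_i f_i e^{j 2\theta_i}$
  is computed with doubled angles, so the two antipodal bumps reinforce
  rather than cancel; $\arg(P)/2$ is the bump centre, defined modulo
  180°. The branch continuous with the previous window is kept,
  initialised at 90° (the cued position). Across trials the centre
  spread $\sigma_{PAV}$ is a circular SD computed on doubled angles and
  halved — a linear SD would break at the branch cut and was not used.
* **Bump profile**: height is the maximal per-cell mean rate; FWHM is
  obtained by linear interpolation of the half-maximum crossings of the
  unsmoothed window-averaged rate profile (no smoothing kernel is
  applied, so on single trials this estimate is noisy); sharpness is
  the rate-weighted ratio $\langle d^4\rangle / \langle d^2\rangle^2$
  of angular offsets over the half ring centred on the bump — 3.0 for
  a Gaussian profile, 1.8 for a flat-top, independent of rate scale.
* **Phase locking**: the pLFP is band-passed to 4–12 Hz with a
  zero-phase (forward–backward) Butterworth filter of design order 4 —
  the filter family and order are a package choice; any zero-phase
  theta-band filter gives indistinguishable locking statistics — and
  the instantaneous phase is taken from the analytic signal with the
  peak defined as 0°. Spike phases are interpolated from the unwrapped
  phase at spike times and summarised by the Rayleigh vector
  $\Phi = \frac{1}{N_s}\sum e^{j\varphi_i}$. Locking to the rhythmic
  septal input uses the cosine's own phase $360 f_{MS} t$ directly.
  Across trials, the package averages per-trial moduli and takes the
  circular mean of per-trial arguments (rather than pooling spikes);
  with hundreds of spikes per trial the two differ negligibly, and the
  per-trial form keeps trials exchangeable units.
* **Attractor presence** (septal-strength sweeps): no analytic
  criterion exists for "a distinguishable attractor", so the package
  calls an attractor present when the time-median $|P|$ exceeds 3× the
  median $|P|$ of rate-shuffled rasters (neuron-to-angle assignment
  permuted, preserving all rates) *and* exceeds an absolute floor of
  0.15 Hz. The ratio alone is not sufficient: when the septal drive is
  weak the network falls nearly silent, and its few residual spikes
  still carry a spatial bias, so both the observed and the shuffled
  $|P|$ shrink together and their ratio stays large. The floor — the
  resultant a marginal bump (about an eighth of the ring at just over
  1 Hz) would produce — restores the intended separation: at the
  default drive the median $|P|$ is ≈ 0.7 Hz, at −50 pA ≈ 0.24 Hz, and
  in the no-attractor regimes (−30, −10 pA) ≤ 0.13 Hz.

## What the simulator emulates — and what it does not

The package generates all of its own data; there is no external
dataset. The simulated conditions are the model's study conditions: a
1D ring (a minimal periodic section of the 2D torus CAN), two bump
attractors, conductance synapses with a single slow excitatory receptor
class, stationary OU noise, and constant or sinusoidal septal drive.
Consequences to keep in mind when relating results to real recordings:

* the model exhibits phase *locking* but no phase *precession*; no
  velocity input moves the bumps, so no spatial firing fields exist;
* the pLFP is a synaptic-current proxy, not an extracellular potential;
  its absolute scale is arbitrary and only its rhythm matters;
* 2D torus topology, conduction delays, synaptic plasticity and
  multiple interneuron classes are out of scope;
* passing the shipped checks shows the implementation reproduces the
  model's reported behaviour, not that the model captures any
  particular animal's data.

## Problem sizes

Full-scale statistics in the source study used 100 trials per
condition. The package's shipped checks run the same protocols at desk
scale, a deliberate design choice: 10 trials for the default-protocol
statistics (with the reported across-trial SDs as tolerances), 2–3
trials per point and 5 s runs (analysis window 1–5 s) for sweeps where
only a monotone trend or an entrainment target is asserted. The
σ_PAV–τ_NMDA comparison keeps full 8 s runs with 8 trials per point and
compares the *time-averaged* σ_PAV trace: the across-trial circular
spread at a single late time point is dominated by single-trial
outliers at small trial counts, while the claim being checked is that
the whole spread trace moves down as τ_NMDA grows. All seeds derive
from a single base seed.

## Open choices

* Autapses: the uniform I→I matrix includes the diagonal (the stated
  uniform connectivity has no exclusions, and with
  $g^{I\to I}_{GABA} = 0.04$ nS the diagonal term is negligible); the
  E→E variant excludes it.
* The normalization integral is applied as a discrete mean over the
  network's angular grid (exactly testable, matches the finite
  network); the continuous-integral alternative is available via
  `connectivity_params(normalization = "integral")` and differs by
  $O(1/N)$.
* The Poisson input variant replaces the constant background and septal
  currents by homogeneous Poisson trains (1 kHz per neuron by default)
  filtered through fast exponential synapses whose weights are chosen
  to match the mean currents; the variant's unitary rates are a free
  configuration choice, not a calibrated value.
* In the synchronous protocol the E background stays at its default —
  see the rheobase argument above.

## Reproducing the shipped numbers

```{r, eval = FALSE}
library(thetaring)

cfg <- model_config()
r <- run_trial(cfg, protocol_default(), seed = 1)
trial_metrics(r)

# the full battery, as used by scripts/acceptance.R
# Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
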