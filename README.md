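# thetaring

A spiking-network simulator and analysis suite for the question of how
**theta oscillation (4–12 Hz)** can arise *intrinsically* in the
**continuous-attractor network (CAN)** of grid cells, coexisting with
the persistent "bump" activity that underlies grid firing fields. It is
aimed at computational neuroscientists studying entorhinal circuit
models: the package lets you run the full model, its perturbation
protocols and parameter sweeps, and compute every derived statistic,
from one seeded R session.

## The model in brief

1024 principal cells (E) and 256 interneurons (I) sit on a ring, each
labelled by an angular position θ. Every neuron is leaky
integrate-and-fire,

    C_m dV/dt = −g_L (V − V_L) − I_syn + I_ext,

with conductance synapses: E→I currents are NMDA-mediated
(second-order gating, τ_NMDA = 100 ms, voltage-dependent Mg²⁺ block),
I→E and I→I currents are GABA-A (τ_GABA = 10 ms). There is no E–E
coupling by default. Coupling strength depends only on the angular
difference Δθ:

    W_EI(Δθ) = J− + (J+ − J−) exp(−Δθ²/2σ²)        (peak at Δθ = 0)
    W_IE(Δθ) = G exp(−(Δθ − 90°)²/2σ²)             (peak at Δθ = 90°)
    W_II     = 1                                    (uniform)

with J+ = 1.6, σ = 30°, and J−, G fixed by the normalization that each
profile's mean over Δθ is exactly 1. Each neuron receives constant
background drive, interneurons additionally a (possibly rhythmic)
septal current I_MS(t) = I_MS,0 + A·cos(2π f_MS t), and all neurons an
Ornstein–Uhlenbeck noise current. Two bump attractors 180° apart form
and persist; the interneurons *between* the bumps close a delayed E–I
feedback loop whose period — set by the slow NMDA decay — lies in the
theta band. Spikes of cells inside the bumps are phase-locked near the
troughs of a local-field-potential proxy (pLFP), defined as the
population-mean, τ_GABA-delayed GABA current onto principal cells.

The analysis suite implements the pLFP, Welch power spectra with
theta-peak metrics, population-activity-vector (PAV) tracking of the
bump centre and its across-trial drift, bump-profile statistics
(height, FWHM, sharpness) and Rayleigh-vector spike-phase locking to
the pLFP or to the septal rhythm. The `run_experiment()` /
`run_rhythmic_ms_experiment()` layer orchestrates seeded multi-trial
protocols and parameter sweeps with machine-readable reports.

## A worked example

```r
library(thetaring)

cfg <- model_config()                       # all default parameters
r   <- run_trial(cfg, protocol_default(), seed = 1)
r
#> <simulation_result> default protocol, 8 s, seed 1
#>   6977 E spikes (0.85 Hz/cell), 21466 I spikes (10.48 Hz/cell)

m <- trial_metrics(r)                       # analysis window 1-8 s
sprintf("pLFP peak %.2f Hz, peak power %.2f, theta power %.2f",
        m$peak_freq, m$peak_power, m$theta_power)
#> "pLFP peak 8.40 Hz, peak power 3.95, theta power 2.57"
sprintf("max E rate %.2f Hz; E cell at 90 deg: |Phi| %.3f, arg %.1f deg",
        m$max_rate_E, m$lock_E_mod, m$lock_E_arg)
#> "max E rate 3.00 Hz; E cell at 90 deg: |Phi| 0.928, arg 239.6 deg"
```

Reading the numbers: the pLFP oscillates in the theta band (primary
spectral peak 8.4 Hz on this trial); the peak power ≈ 4 means the 2-Hz
band around the peak is four times denser than the 0–50 Hz average;
activated principal cells fire at up to ~3–4 Hz while interneurons
inside the bumps fire an order of magnitude faster; and the 90° E cell
is strongly locked (|Φ| ≈ 0.9) at ~240°, i.e. near the pLFP troughs.

Protocol variants: `protocol_deterministic()` (noise-free synchronous
regime), `protocol_suppression(w)` (inhibit the interneurons between
the bumps), `protocol_rhythmic(A, f_MS)` (rhythmic septal drive), all
composable with `modify_config()` for parameter sweeps. A thin CLI over
the same functions is installed at `inst/exec/thetaring`
(`simulate` / `analyze` / `experiment` subcommands).

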