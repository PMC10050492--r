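#' Membrane parameters of one population
#'
#' Leaky integrate-and-fire constants. Defaults are those of the principal
#' cells; see [model_config()] for the interneuron values.
#'
#' @param C_m membrane capacitance, nF.
#' @param g_L leak conductance, nS.
#' @param V_L resting (leak reversal) potential, mV.
#' @param V_th spike threshold, mV.
#' @param V_reset post-spike reset potential, mV.
#' @param tau_ref absolute refractory period, ms.
#' @return object of class `neuron_params`.
#' @export
neuron_params <- function(C_m = 0.5, g_L = 25, V_L = -70, V_th = -50,
                          V_reset = -60, tau_ref = 2) {
  stopifnot(C_m > 0, g_L > 0, tau_ref > 0, V_reset < V_th)
  structure(list(C_m = C_m, g_L = g_L, V_L = V_L, V_th = V_th,
                 V_reset = V_reset, tau_ref = tau_ref),
            class = "neuron_params")
}

#' Synaptic parameters
#'
#' Conductances and kinetics of the NMDA and GABA-A synapse models. The
#' NMDA gating is second order (an intermediate variable `x` jumps by 1 at
#' each presynaptic spike and decays with `tau_x`; the channel-open
#' fraction `S` relaxes with `tau_NMDA` and saturates at 1), and NMDA
#' currents carry the voltage-dependent magnesium block
#' `1 / (1 + Mg exp(-0.062 V) / 3.57)`. GABA gating is first order with
#' unit spike increments. The AMPA variant mixes a fast first-order
#' excitatory conductance into the E-to-I drive with weight
#' `ampa_fraction`.
#'
#' @param g_NMDA_EI,g_GABA_IE,g_GABA_II maximal conductances, nS.
#' @param g_NMDA_EE E-to-E conductance (recurrent-excitation variant), nS.
#' @param g_AMPA_EI AMPA conductance of the mixed-drive variant, nS.
#' @param V_E,V_I excitatory / inhibitory reversal potentials, mV.
#' @param Mg extracellular magnesium concentration, mM.
#' @param tau_NMDA NMDA decay time constant, ms.
#' @param alpha_NMDA NMDA rise rate, kHz (i.e. 1/ms).
#' @param tau_x decay of the intermediate NMDA variable, ms.
#' @param tau_GABA GABA decay time constant, ms.
#' @param tau_AMPA AMPA decay time constant, ms.
#' @param ampa_fraction fraction of the E-to-I drive carried by AMPA, in
#'   `[0, 1]` (0 = pure NMDA, the default model).
#' @return object of class `synapse_params`.
#' @export
synapse_params <- function(g_NMDA_EI = 0.4, g_GABA_IE = 2.4,
                           g_GABA_II = 0.04, g_NMDA_EE = 0,
                           g_AMPA_EI = 0.4,
                           V_E = 0, V_I = -70, Mg = 1,
                           tau_NMDA = 100, alpha_NMDA = 0.5, tau_x = 2,
                           tau_GABA = 10, tau_AMPA = 2,
                           ampa_fraction = 0) {
  stopifnot(g_NMDA_EI >= 0, g_GABA_IE >= 0, g_GABA_II >= 0, g_NMDA_EE >= 0,
            g_AMPA_EI >= 0, Mg >= 0,
            tau_NMDA > 0, alpha_NMDA >= 0, tau_x > 0, tau_GABA > 0,
            tau_AMPA > 0, ampa_fraction >= 0, ampa_fraction <= 1)
  structure(list(g_NMDA_EI = g_NMDA_EI, g_GABA_IE = g_GABA_IE,
                 g_GABA_II = g_GABA_II, g_NMDA_EE = g_NMDA_EE,
                 g_AMPA_EI = g_AMPA_EI, V_E = V_E, V_I = V_I, Mg = Mg,
                 tau_NMDA = tau_NMDA, alpha_NMDA = alpha_NMDA,
                 tau_x = tau_x, tau_GABA = tau_GABA, tau_AMPA = tau_AMPA,
                 ampa_fraction = ampa_fraction),
            class = "synapse_params")
}

#' External input parameters
#'
#' Constant excitatory background drive to both populations, a (possibly
#' rhythmic) GABAergic septal term delivered to interneurons only,
#' `I_MS(t) = I_MS0 + A cos(2 pi f_MS t)`, and an independent
#' Ornstein-Uhlenbeck noise current per neuron,
#' `tau_noise dI = -I dt + eta_noise sqrt(tau_noise) dW`.
#'
#' Under that equation the stationary standard deviation of the noise is
#' `eta_noise / sqrt(2)`; `noise_convention = "target_sd"` instead scales
#' the innovation so the stationary SD equals `eta_noise` itself.
#'
#' @param I_back_E,I_back_I constant background currents, pA.
#' @param I_MS0 constant septal current to interneurons, pA (negative =
#'   inhibitory).
#' @param A amplitude of the rhythmic septal component, pA.
#' @param f_MS frequency of the rhythmic septal component, Hz.
#' @param eta_noise noise strength, pA.
#' @param tau_noise noise correlation time, ms.
#' @param noise_convention `"as_written"` (stationary SD `eta/sqrt(2)`) or
#'   `"target_sd"` (stationary SD `eta`).
#' @param input_mode `"current"` (constant currents, the default) or
#'   `"poisson"`: background and septal drives realised as homogeneous
#'   Poisson trains filtered through fast exponential synapses with the
#'   same mean currents.
#' @param poisson_rate event rate of each Poisson train, Hz.
#' @param tau_poisson_exc,tau_poisson_inh synaptic filter time constants of
#'   the Poisson excitatory / inhibitory drives, ms.
#' @return object of class `external_input_params`.
#' @export
external_input_params <- function(I_back_E = 750, I_back_I = 325,
                                  I_MS0 = -100, A = 0, f_MS = 0,
                                  eta_noise = 150, tau_noise = 2,
                                  noise_convention = c("as_written",
                                                       "target_sd"),
                                  input_mode = c("current", "poisson"),
                                  poisson_rate = 1000,
                                  tau_poisson_exc = 2,
                                  tau_poisson_inh = 10) {
  noise_convention <- match.arg(noise_convention)
  input_mode <- match.arg(input_mode)
  stopifnot(tau_noise > 0, A >= 0, eta_noise >= 0, f_MS >= 0,
            poisson_rate > 0, tau_poisson_exc > 0, tau_poisson_inh > 0)
  structure(list(I_back_E = I_back_E, I_back_I = I_back_I, I_MS0 = I_MS0,
                 A = A, f_MS = f_MS, eta_noise = eta_noise,
                 tau_noise = tau_noise, noise_convention = noise_convention,
                 input_mode = input_mode, poisson_rate = poisson_rate,
                 tau_poisson_exc = tau_poisson_exc,
                 tau_poisson_inh = tau_poisson_inh),
            class = "external_input_params")
}

#' Full model configuration
#'
#' Bundles geometry, connectivity, membranes, synapses, external input and
#' integration settings. All arguments have the default-model values; pass
#' replacements built with the corresponding constructors, or use
#' [modify_config()] for targeted overrides.
#'
#' @param geom [ring_geometry()].
#' @param connectivity [connectivity_params()].
#' @param neurons_E,neurons_I [neuron_params()] per population.
#' @param synapses [synapse_params()].
#' @param external [external_input_params()].
#' @param dt integration step, ms.
#' @param coupling evaluation path for the synaptic drive sums:
#'   `"auto"` picks the circular-convolution path when the network is on
#'   the standard commensurate grid, `"dense"` forces dense matrix-vector
#'   products, `"conv"` forces the convolution path.
#' @param record_vm_E,record_vm_I angular positions (degrees) of neurons
#'   whose membrane potential is recorded at 200 Hz.
#' @return object of class `model_config`.
#' @export
model_config <- function(geom = ring_geometry(),
                         connectivity = connectivity_params(),
                         neurons_E = neuron_params(),
                         neurons_I = neuron_params(C_m = 0.2, g_L = 20,
                                                   tau_ref = 1),
                         synapses = synapse_params(),
                         external = external_input_params(),
                         dt = 0.02,
                         coupling = c("auto", "dense", "conv"),
                         record_vm_E = 90, record_vm_I = 90) {
  coupling <- match.arg(coupling)
  stopifnot(dt > 0)
  structure(list(geom = geom, connectivity = connectivity,
                 neurons_E = neurons_E, neurons_I = neurons_I,
                 synapses = synapses, external = external,
                 dt = dt, coupling = coupling,
                 record_vm_E = record_vm_E, record_vm_I = record_vm_I),
            class = "model_config")
}

#' Override fields of a model configuration
#'
#' Convenience for sweeps: `modify_config(cfg, synapses = list(tau_NMDA =
#' 50), external = list(I_MS0 = -50))` replaces the named leaves, keeping
#' everything else.
#'
#' @param config a [model_config()].
#' @param ... named lists of replacements per section (`geom`,
#'   `connectivity`, `neurons_E`, `neurons_I`, `synapses`, `external`), or
#'   top-level scalars (`dt`, `coupling`, `record_vm_E`, `record_vm_I`).
#' @return the modified `model_config`.
#' @export
modify_config <- function(config, ...) {
  mods <- list(...)
  for (section in names(mods)) {
    if (!section %in% names(config))
      stop("unknown config section: ", section)
    if (is.list(mods[[section]]) && !inherits(mods[[section]], "ring_geometry")) {
      for (leaf in names(mods[[section]])) {
        if (!leaf %in% names(config[[section]]))
          stop("unknown field ", leaf, " in section ", section)
        config[[section]][[leaf]] <- mods[[section]][[leaf]]
      }
    } else {
      config[[section]] <- mods[[section]]
    }
  }
  config
}

#' @export
print.model_config <- function(x, ...) {
  e <- x$external
  cat(sprintf(
    paste0("<model_config> %d E / %d I, dt = %g ms\n",
           "  drive: I_back_E = %g pA, I_back_I = %g pA, I_MS0 = %g pA",
           ", A = %g pA, f_MS = %g Hz\n",
           "  synapses: tau_NMDA = %g ms, tau_GABA = %g ms, noise eta = %g pA\n"),
    x$geom$n_E, x$geom$n_I, x$dt,
    e$I_back_E, e$I_back_I, e$I_MS0, e$A, e$f_MS,
    x$synapses$tau_NMDA, x$synapses$tau_GABA, e$eta_noise))
  invisible(x)
}

#' Simulation protocols
#'
#' A protocol fixes the run duration, initial conditions, cue and
#' suppression currents, and any parameter overrides relative to the base
#' configuration.
#'
#' * `protocol_default()`: 8 s run with full noise, membrane potentials
#'   initialised uniformly in `[-60, -50]` mV, and a 200 pA cue applied to
#'   principal cells in `[67.5, 112.5]` and `[247.5, 292.5]` degrees for
#'   the first 500 ms, seeding two bump attractors at 90 and 270 degrees.
#' * `protocol_deterministic()`: noise-free synchronous regime. All
#'   membrane potentials start at -60 mV, no cue; the network oscillates
#'   through global E and I volleys. See the methods vignette for the
#'   choice of drive currents in this protocol.
#' * `protocol_suppression(w)`: default protocol plus a constant -200 pA
#'   current to interneurons within `w` degrees of 0 or 180 degrees (the
#'   positions between the two attractors).
#' * `protocol_rhythmic(A, f_MS)`: default protocol with a rhythmic septal
#'   input `I_MS0 + A cos(2 pi f_MS t)`.
#'
#' @param duration_s run length, seconds.
#' @param cue_amplitude cue current, pA.
#' @param cue_t_off end of the cue window, ms.
#' @param cue_windows 2-column matrix of angular intervals (degrees)
#'   receiving the cue.
#' @param w suppression half-width, degrees, in `[0, 90]`.
#' @param suppression_amplitude suppression current, pA.
#' @param A,f_MS rhythmic septal amplitude (pA) and frequency (Hz).
#' @param overrides named list of config overrides applied on top of the
#'   base configuration (as in [modify_config()]).
#' @return object of class `sim_protocol`.
#' @name protocols
NULL

new_protocol <- function(name, duration_s, vm_init, cue, suppression,
                         overrides = list()) {
  structure(list(name = name, duration_s = duration_s, vm_init = vm_init,
                 cue = cue, suppression = suppression,
                 overrides = overrides),
            class = "sim_protocol")
}

#' @rdname protocols
#' @export
protocol_default <- function(duration_s = 8, cue_amplitude = 200,
                             cue_t_off = 500,
                             cue_windows = rbind(c(67.5, 112.5),
                                                 c(247.5, 292.5))) {
  new_protocol("default", duration_s,
               vm_init = list(mode = "uniform", lo = -60, hi = -50),
               cue = list(amplitude = cue_amplitude, t_off = cue_t_off,
                          windows = cue_windows),
               suppression = NULL)
}

#' @rdname protocols
#' @export
protocol_deterministic <- function(duration_s = 8, I_back_I = 100) {
  new_protocol("deterministic", duration_s,
               vm_init = list(mode = "fixed", value = -60),
               cue = NULL, suppression = NULL,
               overrides = list(external = list(eta_noise = 0,
                                                I_back_I = I_back_I)))
}

#' @rdname protocols
#' @export
protocol_suppression <- function(w, suppression_amplitude = -200,
                                 duration_s = 8) {
  stopifnot(w >= 0, w <= 90)
  p <- protocol_default(duration_s)
  p$name <- "suppression"
  p$suppression <- list(amplitude = suppression_amplitude, w = w,
                        centers = c(0, 180))
  p
}

#' @rdname protocols
#' @export
protocol_rhythmic <- function(A = 40, f_MS = 8, duration_s = 8) {
  p <- protocol_default(duration_s)
  p$name <- "rhythmic"
  p$overrides <- list(external = list(A = A, f_MS = f_MS))
  p
}

#' @export
print.sim_protocol <- function(x, ...) {
  cat(sprintf("<sim_protocol> %s, %g s\n", x$name, x$duration_s))
  invisible(x)
}

#' Read / write a model configuration as YAML or JSON
#'
#' The file holds the nested parameter lists by section; unspecified
#' fields keep their defaults.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @param config a [model_config()] (for writing).
#' @return `read_config()` returns a `model_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- model_config()
  if (!is.null(raw$geom)) {
    cfg$geom <- ring_geometry(raw$geom$n_E %||% 1024L,
                              raw$geom$n_I %||% 256L)
    raw$geom <- NULL
  }
  if (!is.null(raw$connectivity)) {
    cfg$connectivity <- do.call(connectivity_params, raw$connectivity)
    raw$connectivity <- NULL
  }
  do.call(modify_config, c(list(cfg), raw))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  flat <- lapply(config, function(x) if (is.list(x)) unclass(x) else x)
  flat$geom <- list(n_E = config$geom$n_E, n_I = config$geom$n_I)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(flat, path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
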