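#' @useDynLib thetaring, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Voltage-dependent magnesium block of the NMDA conductance
#'
#' `1 / (1 + Mg * exp(-0.062 * V_m) / 3.57)`, the factor multiplying the
#' NMDA driving force. Equals 1 at `Mg = 0` and increases monotonically
#' with depolarisation.
#'
#' @param V_m membrane potential, mV (vectorised).
#' @param Mg magnesium concentration, mM.
#' @return dimensionless factor in `(0, 1]`.
#' @export
mg_block_factor <- function(V_m, Mg = 1) {
  mg_block_cpp(as.numeric(V_m), Mg)
}

#' Simulate an Ornstein-Uhlenbeck noise path
#'
#' The exact exponential discretization used by the integrator:
#' decay `exp(-dt/tau)` per step with the matching Gaussian innovation, so
#' the stationary statistics are correct at any step size.
#'
#' @param n_steps number of steps.
#' @param dt step, ms.
#' @param tau correlation time, ms.
#' @param sd_stat stationary standard deviation, pA.
#' @param init initial value, pA.
#' @param seed RNG seed.
#' @return numeric vector of length `n_steps + 1`.
#' @export
ou_noise_path <- function(n_steps, dt, tau, sd_stat, init = 0, seed = 1) {
  ou_path_cpp(as.integer(n_steps), dt, tau, sd_stat, init, as.numeric(seed))
}

#' NMDA gating response to a presynaptic spike train
#'
#' Integrates the second-order NMDA gating system (intermediate variable
#' `x` with unit spike increments and decay `tau_x`; open fraction `S`
#' with decay `tau_NMDA`, rise rate `alpha` and saturation at 1) with the
#' same Heun scheme as the network integrator.
#'
#' @param spike_times presynaptic spike times, ms (sorted).
#' @param t_max end time, ms.
#' @param dt step, ms.
#' @param tau_NMDA,alpha,tau_x gating constants (ms, kHz, ms).
#' @return data frame with columns `t`, `x`, `S`.
#' @export
nmda_gating_trace <- function(spike_times, t_max, dt = 0.02,
                              tau_NMDA = 100, alpha = 0.5, tau_x = 2) {
  m <- nmda_gating_trace_cpp(as.numeric(spike_times), t_max, dt,
                             tau_NMDA, alpha, tau_x)
  data.frame(t = m[, 1], x = m[, 2], S = m[, 3])
}

# Index (1-based) of the neuron at a given angular position, nearest grid
# point.
neuron_at_angle <- function(angle, n) {
  (round((angle %% 360) / 360 * n) %% n) + 1L
}

# Logical mask of positions falling in any [lo, hi] interval (degrees).
angle_mask <- function(theta, windows) {
  if (is.null(windows)) return(rep(FALSE, length(theta)))
  m <- rep(FALSE, length(theta))
  for (r in seq_len(nrow(windows))) {
    lo <- windows[r, 1]; hi <- windows[r, 2]
    m <- m | (theta >= lo & theta <= hi)
  }
  m
}

#' Run one simulation trial
#'
#' Integrates the full network under a protocol and returns spikes and
#' traces sampled at 200 Hz. Deterministic given `seed`: the membrane
#' initial conditions and every noise innovation derive from one seeded
#' stream.
#'
#' @param config a [model_config()].
#' @param protocol a protocol from [protocols], e.g. [protocol_default()].
#' @param seed integer seed for this trial.
#' @return An object of class `simulation_result`: list with
#'   * `spikes`: data frame (`population`, `neuron`, `angle_deg`,
#'     `time_ms`),
#'   * `t_ms`: 200 Hz sample times,
#'   * `vm_E`, `vm_I`: membrane-potential traces of the recorded neurons
#'     (columns named by angular position),
#'   * `igaba_E`: per-principal-cell GABA current trace (pA),
#'   * `inmda_I`: per-interneuron NMDA current trace (pA),
#'   * `mean_currents`: population-mean synaptic/external/total currents
#'     and the septal waveform,
#'   * `s_nmda_range`: range of the NMDA open fraction over the run,
#'   * `config`, `protocol`, `seed`: provenance.
#' @export
run_trial <- function(config = model_config(),
                      protocol = protocol_default(),
                      seed = 1L) {
  stopifnot(inherits(config, "model_config"),
            inherits(protocol, "sim_protocol"))
  if (length(protocol$overrides))
    config <- do.call(modify_config, c(list(config), protocol$overrides))

  geom <- config$geom
  conn <- build_connectivity(geom, config$connectivity)
  syn <- config$synapses
  ext <- config$external
  nE <- config$neurons_E
  nI <- config$neurons_I

  use_conv <- switch(config$coupling,
    dense = FALSE,
    conv = TRUE,
    auto = is_pow2_r(geom$n_E) && is_pow2_r(geom$n_I) &&
      geom$n_E %% geom$n_I == 0
  )
  if (config$coupling == "conv" &&
      !(is_pow2_r(geom$n_E) && is_pow2_r(geom$n_I) &&
        geom$n_E %% geom$n_I == 0))
    stop("convolution coupling requires commensurate power-of-two rings")

  sd_stat <- if (ext$noise_convention == "as_written")
    ext$eta_noise / sqrt(2) else ext$eta_noise
  if (ext$input_mode == "poisson" && ext$A > 0)
    stop("rhythmic septal input is not supported in poisson input mode")

  n_steps <- as.integer(round(protocol$duration_s * 1000 / config$dt))
  record_every <- as.integer(round(5 / config$dt))
  if (abs(record_every * config$dt - 5) > 1e-9)
    stop("dt must divide the 5 ms recording interval")

  cue <- protocol$cue
  sup <- protocol$suppression
  vm <- protocol$vm_init

  # Poisson-drive weights chosen so each filtered train has the same mean
  # current as the constant it replaces: mean I = w * rate * tau.
  rate_ms <- ext$poisson_rate / 1000
  w_pe_E <- ext$I_back_E / (rate_ms * ext$tau_poisson_exc)
  w_pe_I <- ext$I_back_I / (rate_ms * ext$tau_poisson_exc)
  w_pi_I <- abs(ext$I_MS0) / (rate_ms * ext$tau_poisson_inh)

  args <- list(
    n_E = geom$n_E, n_I = geom$n_I, dt = config$dt, n_steps = n_steps,
    record_every = record_every, use_conv = use_conv,
    ee_enabled = isTRUE(config$connectivity$ee_enabled),
    ii_uniform = config$connectivity$w_II_mode == "uniform",
    kEI = conn$kernels$EI_fine, kIE = conn$kernels$IE_fine,
    kII = conn$kernels$II, kEE = conn$kernels$EE_fine %||% numeric(0),
    W_EI = conn$W_EI, W_IE = conn$W_IE, W_II = conn$W_II,
    W_EE = conn$W_EE %||% matrix(0, 0, 0),
    Cm_E = nE$C_m, gL_E = nE$g_L, VL_E = nE$V_L, Vth_E = nE$V_th,
    Vreset_E = nE$V_reset, tauref_E = nE$tau_ref,
    Cm_I = nI$C_m, gL_I = nI$g_L, VL_I = nI$V_L, Vth_I = nI$V_th,
    Vreset_I = nI$V_reset, tauref_I = nI$tau_ref,
    g_NMDA_EI = syn$g_NMDA_EI, g_GABA_IE = syn$g_GABA_IE,
    g_GABA_II = syn$g_GABA_II, g_NMDA_EE = syn$g_NMDA_EE,
    g_AMPA_EI = syn$g_AMPA_EI, V_E = syn$V_E, V_I = syn$V_I, Mg = syn$Mg,
    tau_NMDA = syn$tau_NMDA, alpha_NMDA = syn$alpha_NMDA, tau_x = syn$tau_x,
    tau_GABA = syn$tau_GABA, tau_AMPA = syn$tau_AMPA,
    ampa_fraction = syn$ampa_fraction,
    I_back_E = ext$I_back_E, I_back_I = ext$I_back_I, I_MS0 = ext$I_MS0,
    A = ext$A, f_MS = ext$f_MS, tau_noise = ext$tau_noise,
    noise_sd_stat = sd_stat,
    poisson_mode = ext$input_mode == "poisson",
    poisson_rate_ms = rate_ms,
    tau_poisson_exc = ext$tau_poisson_exc,
    tau_poisson_inh = ext$tau_poisson_inh,
    w_pois_exc_E = w_pe_E, w_pois_exc_I = w_pe_I, w_pois_inh_I = w_pi_I,
    cue_amp = cue$amplitude %||% 0,
    cue_t_off = cue$t_off %||% 0,
    cue_mask_E = angle_mask(geom$theta_E, cue$windows),
    sup_amp = sup$amplitude %||% 0,
    sup_mask_I = if (is.null(sup)) rep(FALSE, geom$n_I) else
      (angular_difference(geom$theta_I, sup$centers[1]) <= sup$w |
       angular_difference(geom$theta_I, sup$centers[2]) <= sup$w),
    vm_init_mode = if (vm$mode == "fixed") 0L else 1L,
    vm_fixed = vm$value %||% -60,
    vm_lo = vm$lo %||% -60, vm_hi = vm$hi %||% -50,
    seed = as.numeric(seed),
    idx_vm_E = neuron_at_angle(config$record_vm_E, geom$n_E) - 1L,
    idx_vm_I = neuron_at_angle(config$record_vm_I, geom$n_I) - 1L
  )

  raw <- simulate_network_cpp(args)

  spikes <- rbind(
    data.frame(population = rep("E", length(raw$spike_t_E)),
               neuron = raw$spike_id_E + 1L,
               angle_deg = geom$theta_E[raw$spike_id_E + 1L],
               time_ms = raw$spike_t_E),
    data.frame(population = rep("I", length(raw$spike_t_I)),
               neuron = raw$spike_id_I + 1L,
               angle_deg = geom$theta_I[raw$spike_id_I + 1L],
               time_ms = raw$spike_t_I)
  )

  vm_E <- raw$vm_E
  colnames(vm_E) <- paste0("E_", signif(config$record_vm_E, 6))
  vm_I <- raw$vm_I
  colnames(vm_I) <- paste0("I_", signif(config$record_vm_I, 6))

  structure(
    list(spikes = spikes, t_ms = raw$t_ms,
         vm_E = vm_E, vm_I = vm_I,
         igaba_E = raw$igaba_E, inmda_I = raw$inmda_I,
         mean_currents = raw$mean_currents,
         s_nmda_range = c(raw$s_nmda_min, raw$s_nmda_max),
         config = config, protocol = protocol, seed = seed),
    class = "simulation_result"
  )
}

is_pow2_r <- function(n) n > 0 && bitwAnd(n, n - 1L) == 0

#' @export
print.simulation_result <- function(x, ...) {
  nsp <- table(factor(x$spikes$population, levels = c("E", "I")))
  dur <- x$protocol$duration_s
  cat(sprintf(
    paste0("<simulation_result> %s protocol, %g s, seed %s\n",
           "  %d E spikes (%.2f Hz/cell), %d I spikes (%.2f Hz/cell)\n"),
    x$protocol$name, dur, format(x$seed),
    nsp[["E"]], nsp[["E"]] / x$config$geom$n_E / dur,
    nsp[["I"]], nsp[["I"]] / x$config$geom$n_I / dur))
  invisible(x)
}

#' Population firing rates of a trial
#'
#' Mean rate per neuron over a time window, and the population means.
#'
#' @param result a [run_trial()] result.
#' @param window analysis window `c(t0, t1)` in ms (default 1-8 s).
#' @return list with `rate_E`, `rate_I` (per-neuron Hz vectors) and
#'   `mean_E`, `mean_I`, `max_E`.
#' @export
firing_rates <- function(result, window = c(1000, 8000)) {
  dur_s <- (window[2] - window[1]) / 1000
  sp <- result$spikes
  inwin <- sp$time_ms > window[1] & sp$time_ms <= window[2]
  n_E <- result$config$geom$n_E
  n_I <- result$config$geom$n_I
  cnt_E <- tabulate(sp$neuron[inwin & sp$population == "E"], nbins = n_E)
  cnt_I <- tabulate(sp$neuron[inwin & sp$population == "I"], nbins = n_I)
  list(rate_E = cnt_E / dur_s, rate_I = cnt_I / dur_s,
       mean_E = sum(cnt_E) / n_E / dur_s,
       mean_I = sum(cnt_I) / n_I / dur_s,
       max_E = max(cnt_E) / dur_s)
}

#' Save a simulation result to disk
#'
#' Spikes go to a CSV file, traces and metadata to an RDS file next to it.
#'
#' @param result a [run_trial()] result.
#' @param dir output directory.
#' @param stem file-name stem.
#' @return invisibly, the paths written.
#' @export
write_simulation_result <- function(result, dir, stem = "trial") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(stem, "_spikes.csv"))
  utils::write.csv(result$spikes, csv, row.names = FALSE)
  rds <- file.path(dir, paste0(stem, ".rds"))
  saveRDS(result, rds)
  invisible(c(spikes = csv, result = rds))
}
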