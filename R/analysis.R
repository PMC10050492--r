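#' Local-field-potential proxy
#'
#' The pLFP is the population mean over principal cells of the GABAergic
#' synaptic current each receives, delayed by the GABA decay time
#' constant: `pLFP(t) = mean_i I_GABA,i(t - tau_GABA)`. With the 200 Hz
#' trace sampling and `tau_GABA = 10` ms the delay is exactly 2 samples.
#'
#' @param result a [run_trial()] result with per-cell GABA current traces.
#' @param window analysis window `c(t0, t1)` in ms; samples with
#'   `t0 <= t < t1` are returned.
#' @return data frame with `time_ms` and `plfp` (pA).
#' @export
compute_plfp <- function(result, window = c(1000, 8000)) {
  if (is.null(result$igaba_E))
    stop("per-cell GABA current traces missing from this result")
  tau_gaba <- result$config$synapses$tau_GABA
  t <- result$t_ms
  dt_samp <- t[2] - t[1]
  delay <- as.integer(round(tau_gaba / dt_samp))
  m <- rowMeans(result$igaba_E)
  keep <- which(t >= window[1] & t < window[2])
  src <- keep - delay
  if (any(src < 1))
    stop("analysis window starts before the delayed trace is defined")
  data.frame(time_ms = t[keep], plfp = m[src])
}

#' Welch power spectral density
#'
#' Welch's averaged-periodogram estimate with a periodic Hamming window,
#' per-segment mean removal, and one-sided density scaling, matching the
#' conventions of standard scientific signal-processing libraries.
#'
#' @param x numeric signal, uniformly sampled.
#' @param fs sampling rate, Hz (200 for all traces in this package).
#' @param nperseg segment length (256).
#' @param noverlap overlapping samples between segments (128).
#' @param nfft transform length, zero-padded (1024), giving a frequency
#'   resolution of `fs/nfft` (about 0.195 Hz at the defaults).
#' @return An object of class `spectral_result`: list with `freq` (Hz)
#'   and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs = 200, nperseg = 256, noverlap = 128,
                      nfft = 1024) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < nperseg)
    stop("signal shorter than one Welch segment (", nperseg, " samples)")
  step <- nperseg - noverlap
  starts <- seq(1, n - nperseg + 1, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nperseg - 1)) / nperseg)
  scale <- 1 / (fs * sum(w^2))
  n_keep <- nfft %/% 2 + 1
  acc <- numeric(n_keep)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(c(seg, numeric(nfft - nperseg)))[1:n_keep]
    acc <- acc + Mod(X)^2
  }
  psd <- acc / length(starts) * scale
  psd[2:(n_keep - 1)] <- 2 * psd[2:(n_keep - 1)]  # one-sided
  structure(list(freq = (0:(n_keep - 1)) * fs / nfft, psd = psd),
            class = "spectral_result")
}

#' @export
print.spectral_result <- function(x, ...) {
  pk <- primary_peak_metrics(x)
  cat(sprintf(
    "<spectral_result> %d bins, df = %.4g Hz; primary peak %.2f Hz\n",
    length(x$freq), x$freq[2] - x$freq[1], pk$frequency))
  invisible(x)
}

#' Primary spectral peak frequency and power
#'
#' The primary peak frequency is the frequency of the largest spectral
#' density over `(0, 50]` Hz (the zero-frequency bin is excluded; after
#' per-segment detrending it carries no power). The peak power compares a
#' 2-Hz band centred on the peak with the whole 0-50 Hz range:
#' with `convention = "mean"` it is the mean density in
#' `[f_p - 1, f_p + 1]` divided by the mean density in `[0, 50]` (a
#' sharply concentrated spectrum can exceed 1, approaching 25 in the
#' single-bin limit); with `convention = "integrated"` it is the ratio of
#' trapezoid-integrated powers (bounded by 1).
#'
#' @param spec a [welch_psd()] result.
#' @param f_max upper frequency of the search and normalisation range, Hz.
#' @param convention `"mean"` or `"integrated"` (see above).
#' @return list with `frequency` (Hz) and `power` (dimensionless ratio).
#' @export
primary_peak_metrics <- function(spec, f_max = 50,
                                 convention = c("mean", "integrated")) {
  convention <- match.arg(convention)
  sel <- spec$freq > 0 & spec$freq <= f_max
  if (!any(sel)) stop("empty spectrum in (0, f_max]")
  fp <- spec$freq[sel][which.max(spec$psd[sel])]
  inband <- spec$freq >= fp - 1 & spec$freq <= fp + 1
  total <- spec$freq <= f_max
  power <- if (convention == "mean") {
    mean(spec$psd[inband]) / mean(spec$psd[total])
  } else {
    trapz(spec$freq[inband], spec$psd[inband]) /
      trapz(spec$freq[total], spec$psd[total])
  }
  list(frequency = fp, power = power)
}

trapz <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)

#' Theta power of a spectrum
#'
#' Mean spectral density in the theta band divided by the mean density
#' over the whole 0-50 Hz range.
#'
#' @param spec a [welch_psd()] result.
#' @param band theta band, Hz.
#' @param total normalisation range, Hz.
#' @return dimensionless ratio.
#' @export
theta_power <- function(spec, band = c(4, 12), total = c(0, 50)) {
  inband <- spec$freq >= band[1] & spec$freq <= band[2]
  intot <- spec$freq >= total[1] & spec$freq <= total[2]
  mean(spec$psd[inband]) / mean(spec$psd[intot])
}

#' Population spike counts in fixed bins
#'
#' Counts spikes from all neurons of one population in half-open time
#' bins: a spike falling exactly on a bin edge is assigned to the later
#' bin.
#'
#' @param result a [run_trial()] result (or a spikes data frame).
#' @param bin_ms bin width, ms.
#' @param population `"E"` or `"I"`.
#' @param window analysis window `c(t0, t1)` in ms; bins tile
#'   `[t0, t1)`.
#' @return data frame with `time_ms` (left bin edges) and `count`.
#' @export
bin_spike_counts <- function(result, bin_ms = 5, population = "E",
                             window = c(1000, 8000)) {
  sp <- if (inherits(result, "simulation_result")) result$spikes else result
  tt <- sp$time_ms[sp$population == population]
  edges <- seq(window[1], window[2], by = bin_ms)
  n_bins <- length(edges) - 1
  idx <- floor((tt - window[1]) / bin_ms) + 1
  idx <- idx[idx >= 1 & idx <= n_bins]
  data.frame(time_ms = edges[-length(edges)],
             count = tabulate(idx, nbins = n_bins))
}

#' Population activity vector series
#'
#' Tracks the bump attractors: in each sliding window the firing rate
#' `f_i` of every principal cell is computed and the Rayleigh vector of
#' doubled angular positions, `P = mean_i f_i exp(j 2 theta_i)`, is
#' formed. Doubling maps the two attractors (180 degrees apart) onto each
#' other so that `|P|` measures their joint strength and `arg(P)/2` their
#' centre. The halved argument is defined up to 180 degrees; the branch
#' continuous with the previous window is kept, initialised at 90 degrees
#' (the seeded attractor position).
#'
#' @param result a [run_trial()] result.
#' @param window_ms sliding-window length, ms (400).
#' @param stride_ms window stride, ms (5).
#' @param window analysis window `c(t0, t1)` in ms; only windows fully
#'   inside it are evaluated.
#' @param init_deg branch initialisation, degrees.
#' @return data frame of class `pav_series` with `time_ms` (window
#'   centres), `magnitude` (Hz), `theta_pav` (degrees in `[0, 360)`, `NA`
#'   for empty windows).
#' @export
pav_series <- function(result, window_ms = 400, stride_ms = 5,
                       window = c(1000, 8000), init_deg = 90) {
  geom <- result$config$geom
  sp <- result$spikes
  eok <- sp$population == "E" & sp$time_ms >= window[1] &
    sp$time_ms < window[2]
  tt <- sp$time_ms[eok]
  ph <- exp(2i * sp$angle_deg[eok] * pi / 180)

  n_bins <- as.integer(round((window[2] - window[1]) / stride_ms))
  idx <- floor((tt - window[1]) / stride_ms) + 1
  keep <- idx >= 1 & idx <= n_bins
  zr <- tapply(Re(ph[keep]), factor(idx[keep], levels = 1:n_bins), sum)
  zi <- tapply(Im(ph[keep]), factor(idx[keep], levels = 1:n_bins), sum)
  zr[is.na(zr)] <- 0; zi[is.na(zi)] <- 0
  cnt <- tabulate(idx[keep], nbins = n_bins)

  per_win <- as.integer(round(window_ms / stride_ms))
  n_win <- n_bins - per_win + 1
  if (n_win < 1) stop("analysis window shorter than the sliding window")
  win_sum <- function(v) {
    cs <- c(0, cumsum(v))
    cs[(per_win + 1):(n_bins + 1)] - cs[1:n_win]
  }
  P <- (win_sum(as.numeric(zr)) + 1i * win_sum(as.numeric(zi))) /
    (geom$n_E * window_ms / 1000)
  n_spk <- win_sum(cnt)

  theta_raw <- (Arg(P) * 180 / pi / 2) %% 180
  theta <- numeric(n_win)
  prev <- init_deg
  for (k in seq_len(n_win)) {
    if (n_spk[k] == 0) {
      theta[k] <- NA_real_
    } else {
      cand <- c(theta_raw[k], theta_raw[k] + 180)
      d <- angular_difference(cand, prev)
      theta[k] <- cand[which.min(d)]
      prev <- theta[k]
    }
  }
  out <- data.frame(
    time_ms = window[1] + window_ms / 2 + (seq_len(n_win) - 1) * stride_ms,
    magnitude = Mod(P),
    theta_pav = theta %% 360
  )
  class(out) <- c("pav_series", "data.frame")
  out
}

#' Across-trial circular spread of the bump centre
#'
#' Standard deviation of `theta_pav` across trials at each window centre.
#' Because the bump centre is periodic with period 180 degrees, the
#' statistic is computed circularly on doubled angles and halved:
#' `sigma = sqrt(-2 log R) / 2` (in radians) where `R` is the resultant
#' length of `exp(2 i theta)` across trials.
#'
#' @param trials list of [pav_series()] on a common time grid.
#' @param at_ms if given, return the scalar value at the window centre
#'   nearest this time; otherwise the whole series.
#' @return data frame with `time_ms`, `sigma_deg`, or a scalar.
#' @export
sigma_pav <- function(trials, at_ms = NULL) {
  stopifnot(length(trials) >= 2)
  t_grid <- trials[[1]]$time_ms
  ang <- vapply(trials, function(p) {
    stopifnot(isTRUE(all.equal(p$time_ms, t_grid)))
    p$theta_pav
  }, numeric(length(t_grid)))
  if (anyNA(ang))
    warning("empty-window angles excluded from the circular SD")
  z <- exp(2i * ang * pi / 180)
  R <- abs(rowMeans(z, na.rm = TRUE))
  R <- pmin(R, 1)
  sigma <- sqrt(-2 * log(R)) / 2 * 180 / pi
  if (!is.null(at_ms)) return(sigma[which.min(abs(t_grid - at_ms))])
  data.frame(time_ms = t_grid, sigma_deg = sigma)
}

#' Sharpness of a bump firing-rate profile
#'
#' Rate-weighted ratio of the fourth moment to the squared second moment
#' of the angular offsets from the bump centre,
#' `S = (sum F d^4 / sum F) / (sum F d^2 / sum F)^2`,
#' a kurtosis-like shape statistic: 3.0 for a Gaussian profile, 1.8 for a
#' flat-top (plateau) profile. Invariant under uniform rescaling of the
#' rates.
#'
#' @param theta_deg angular positions of the cells, degrees.
#' @param rate firing rates `F_i` (any common unit).
#' @param theta0 bump centre, degrees.
#' @return dimensionless sharpness.
#' @export
bump_sharpness <- function(theta_deg, rate, theta0) {
  d <- signed_circular_diff(theta_deg, theta0)
  m2 <- sum(rate * d^2) / sum(rate)
  m4 <- sum(rate * d^4) / sum(rate)
  m4 / m2^2
}

# signed circular difference in (-180, 180]
signed_circular_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Bump-attractor profile metrics
#'
#' Characterises one bump attractor by its height (maximal per-cell mean
#' rate), full width at half maximum (linear interpolation of the rate
#' profile's half-maximum crossings around the centre) and sharpness (see
#' [bump_sharpness()]). The profile is the per-cell mean firing rate over
#' the window; the evaluation is restricted to the half ring (`n_E / 2`
#' cells) centred on the bump, which under the default two-attractor state
#' isolates one bump.
#'
#' @param result a [run_trial()] result.
#' @param window analysis window, ms.
#' @param theta0 bump centre in degrees; by default the circular mean of
#'   the [pav_series()] over the window (branch near 90 degrees).
#' @return list with `height` (Hz), `fwhm` (degrees), `sharpness`,
#'   `theta0`.
#' @export
bump_profile <- function(result, window = c(1000, 8000), theta0 = NULL) {
  fr <- firing_rates(result, window)
  if (all(fr$rate_E == 0)) stop("no principal-cell spikes in the window")
  geom <- result$config$geom
  if (is.null(theta0)) {
    pav <- pav_series(result, window = window)
    z <- exp(2i * pav$theta_pav[!is.na(pav$theta_pav)] * pi / 180)
    th <- (Arg(mean(z)) * 180 / pi / 2) %% 180
    theta0 <- if (angular_difference(th, 90) <= 90) th else th + 180
  }
  d <- signed_circular_diff(geom$theta_E, theta0)
  half <- abs(d) <= 90
  # keep exactly n_E/2 cells in case of boundary ties
  ord <- order(abs(d))
  half <- seq_along(d) %in% ord[seq_len(geom$n_E %/% 2)]
  dd <- d[half]
  FF <- fr$rate_E[half]
  o <- order(dd)
  dd <- dd[o]; FF <- FF[o]

  height <- max(FF)
  half_max <- height / 2
  ipk <- which.max(FF)
  # first half-maximum crossings moving out from the peak
  left <- NA_real_
  if (ipk > 1) for (i in rev(seq_len(ipk - 1))) {
    if (FF[i] < half_max) {
      left <- dd[i] + (half_max - FF[i]) / (FF[i + 1] - FF[i]) *
        (dd[i + 1] - dd[i])
      break
    }
  }
  right <- NA_real_
  if (ipk < length(FF)) for (i in (ipk + 1):length(FF)) {
    if (FF[i] < half_max) {
      right <- dd[i - 1] + (half_max - FF[i - 1]) / (FF[i] - FF[i - 1]) *
        (dd[i] - dd[i - 1])
      break
    }
  }
  list(height = height,
       fwhm = if (is.na(left) || is.na(right)) NA_real_ else right - left,
       sharpness = bump_sharpness(geom$theta_E[half], fr$rate_E[half],
                                  theta0),
       theta0 = theta0)
}

# analytic signal via FFT (Hilbert transform)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# zero-phase theta-band filter + instantaneous phase (degrees in [0,360),
# peak of the filtered wave = 0)
instantaneous_phase <- function(x, fs, band = c(4, 12), order = 4) {
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x - mean(x))
  (Arg(analytic_signal(xf)) * 180 / pi) %% 360
}

#' Spike-phase locking to a rhythmic reference
#'
#' Assigns each spike of one neuron the instantaneous theta phase of a
#' reference signal and summarises the phases with the Rayleigh vector
#' `mean(exp(j phi))`. For the pLFP reference the signal is band-passed
#' to 4-12 Hz with a zero-phase (forward-backward) Butterworth filter and
#' the phase is taken from the analytic signal, so a spike at a pLFP peak
#' has phase 0 and one at a trough 180 degrees. For the rhythmic septal
#' reference the cosine's own phase `360 f_MS t` is used directly.
#'
#' @param result a [run_trial()] result.
#' @param population `"E"` or `"I"`.
#' @param angle angular position of the neuron, degrees (nearest cell).
#' @param reference `"plfp"` or `"ms"`.
#' @param band pass band for the pLFP reference, Hz.
#' @param window analysis window, ms.
#' @param filter_order Butterworth design order.
#' @return list with `modulus` (`NA` when the neuron never spiked),
#'   `argument_deg` in `[0, 360)`, `n_spikes`, and the spike `phases_deg`.
#' @export
spike_phase_locking <- function(result, population = "E", angle = 90,
                                reference = c("plfp", "ms"),
                                band = c(4, 12), window = c(1000, 8000),
                                filter_order = 4) {
  reference <- match.arg(reference)
  geom <- result$config$geom
  n_pop <- if (population == "E") geom$n_E else geom$n_I
  idx <- neuron_at_angle(angle, n_pop)
  sp <- result$spikes
  tt <- sp$time_ms[sp$population == population & sp$neuron == idx &
                   sp$time_ms >= window[1] & sp$time_ms < window[2]]
  if (length(tt) == 0)
    return(list(modulus = NA_real_, argument_deg = NA_real_,
                n_spikes = 0L, phases_deg = numeric(0)))
  if (reference == "ms") {
    f <- result$config$external$f_MS
    if (f <= 0) stop("no rhythmic septal input in this configuration")
    phases <- (360 * f * tt / 1000) %% 360
  } else {
    pl <- compute_plfp(result, window)
    fs <- 1000 / (pl$time_ms[2] - pl$time_ms[1])
    ph <- instantaneous_phase(pl$plfp, fs, band, filter_order)
    # interpolate the unwrapped phase at spike times
    unw <- unwrap_deg(ph)
    phases <- stats::approx(pl$time_ms, unw, xout = tt, rule = 2)$y %% 360
  }
  z <- mean(exp(1i * phases * pi / 180))
  list(modulus = Mod(z), argument_deg = (Arg(z) * 180 / pi) %% 360,
       n_spikes = length(tt), phases_deg = phases)
}

unwrap_deg <- function(p) {
  d <- diff(p)
  steps <- cumsum(c(0, round(-d / 360)))
  p + 360 * steps
}

#' Standard per-trial metric battery
#'
#' Computes the quantities reported per trial throughout the analysis:
#' pLFP spectral peak frequency and power, theta power, spike-count and
#' membrane-potential spectral peaks, maximal principal-cell rate, PAV
#' magnitude statistics, bump profile, and phase locking of the recorded
#' 90-degree principal cell and interneuron to the pLFP (and to the
#' septal rhythm when present).
#'
#' @param result a [run_trial()] result.
#' @param window analysis window, ms.
#' @return one-row data frame.
#' @export
trial_metrics <- function(result, window = c(1000, 8000)) {
  pl <- compute_plfp(result, window)
  spec <- welch_psd(pl$plfp)
  pk <- primary_peak_metrics(spec)
  pk_int <- primary_peak_metrics(spec, convention = "integrated")
  sc <- bin_spike_counts(result, 5, "E", window)
  pk_sc <- primary_peak_metrics(welch_psd(sc$count))
  tsel <- result$t_ms >= window[1] & result$t_ms < window[2]
  pk_vm <- primary_peak_metrics(welch_psd(result$vm_E[tsel, 1]))
  fr <- firing_rates(result, window)
  pav <- pav_series(result, window = window)
  bp <- tryCatch(bump_profile(result, window),
                 error = function(e) list(height = NA, fwhm = NA,
                                          sharpness = NA, theta0 = NA))
  lockE <- spike_phase_locking(result, "E", 90, "plfp", window = window)
  lockI <- spike_phase_locking(result, "I", 90, "plfp", window = window)
  has_ms <- result$config$external$A > 0 && result$config$external$f_MS > 0
  lockE_ms <- if (has_ms)
    spike_phase_locking(result, "E", 90, "ms", window = window)
  data.frame(
    seed = result$seed,
    peak_freq = pk$frequency,
    peak_power = pk$power,
    peak_power_integrated = pk_int$power,
    theta_power = theta_power(spec),
    sc_peak_freq = pk_sc$frequency,
    vm_peak_freq = pk_vm$frequency,
    max_rate_E = fr$max_E,
    mean_rate_E = fr$mean_E,
    mean_rate_I = fr$mean_I,
    pav_mean = mean(pav$magnitude),
    pav_cv = stats::sd(pav$magnitude) / mean(pav$magnitude),
    pav_median = stats::median(pav$magnitude),
    bump_height = bp$height,
    bump_fwhm = bp$fwhm,
    bump_sharpness = bp$sharpness,
    lock_E_mod = lockE$modulus,
    lock_E_arg = lockE$argument_deg,
    lock_I_mod = lockI$modulus,
    lock_I_arg = lockI$argument_deg,
    lock_E_ms_mod = if (has_ms) lockE_ms$modulus else NA_real_,
    lock_E_ms_arg = if (has_ms) lockE_ms$argument_deg else NA_real_
  )
}

#' Circular mean of angles in degrees
#'
#' @param deg angles in degrees.
#' @return circular mean in `[0, 360)`.
#' @export
circular_mean_deg <- function(deg) {
  (Arg(mean(exp(1i * deg * pi / 180))) * 180 / pi) %% 360
}

#' Synaptic currents for an explicit network state
#'
#' Evaluates the conductance-synapse currents for given membrane
#' potentials and gating variables: NMDA current onto each interneuron
#' `g (V - V_E) B(V) sum_j W_ij S_j` with the magnesium-block factor `B`,
#' and GABA currents `g (V - V_I) sum_j W_ij S_j` onto both populations.
#' Positive values are hyperpolarising (the synaptic current enters the
#' membrane equation with a minus sign). Useful for inspecting the drive
#' implied by a recorded state; the integrator evaluates the same
#' expressions internally.
#'
#' @param V_E,V_I membrane potentials, mV.
#' @param S_NMDA,S_GABA gating variables per presynaptic E / I cell.
#' @param conn a [build_connectivity()] result.
#' @param syn a [synapse_params()].
#' @return list with `I_E_to_I` (NMDA, per interneuron), `I_I_to_E`
#'   (GABA, per principal cell), `I_I_to_I` (GABA, per interneuron), all
#'   pA, plus `I_total_E`, `I_total_I`.
#' @export
synaptic_currents <- function(V_E, V_I, S_NMDA, S_GABA, conn,
                              syn = synapse_params()) {
  stopifnot(length(V_E) == conn$geom$n_E, length(V_I) == conn$geom$n_I,
            length(S_NMDA) == conn$geom$n_E,
            length(S_GABA) == conn$geom$n_I)
  B <- mg_block_factor(V_I, syn$Mg)
  I_EI <- syn$g_NMDA_EI * (V_I - syn$V_E) * B *
    as.numeric(conn$W_EI %*% S_NMDA)
  I_IE <- syn$g_GABA_IE * (V_E - syn$V_I) *
    as.numeric(conn$W_IE %*% S_GABA)
  I_II <- syn$g_GABA_II * (V_I - syn$V_I) *
    as.numeric(conn$W_II %*% S_GABA)
  list(I_E_to_I = I_EI, I_I_to_E = I_IE, I_I_to_I = I_II,
       I_total_E = I_IE, I_total_I = I_EI + I_II)
}

#' Is a bump attractor distinguishable?
#'
#' Criterion for sweeps over the septal drive strength: the attractor is
#' called present when the time-median PAV magnitude over the analysis
#' window (i) exceeds `factor` times the median magnitude of
#' rate-shuffled rasters (the same spike trains with the neuron-to-angle
#' assignment randomly permuted, which preserves every rate but destroys
#' the spatial organisation) and (ii) exceeds an absolute floor
#' `min_pav`. The floor is needed because a nearly silent network can
#' retain a weak spatial bias in its sporadic spikes: the shuffled
#' reference then shrinks along with the rates and the ratio alone stays
#' large even though no persistent bump exists. The default floor,
#' 0.15 Hz, is the resultant a marginal bump would produce (about an
#' eighth of the ring firing at little over 1 Hz).
#'
#' @param result a [run_trial()] result.
#' @param window analysis window, ms.
#' @param factor multiple of the shuffled reference (3).
#' @param min_pav absolute floor on the median PAV magnitude, Hz.
#' @param n_shuffle number of shuffles averaged.
#' @param seed RNG seed for the permutations.
#' @return list with `present` (logical), `observed` and `reference`
#'   median magnitudes (Hz).
#' @export
attractor_present <- function(result, window = c(1000, 8000), factor = 3,
                              min_pav = 0.15, n_shuffle = 5, seed = 1) {
  obs <- stats::median(pav_series(result, window = window)$magnitude)
  geom <- result$config$geom
  ref <- withr::with_seed(seed, {
    mean(vapply(seq_len(n_shuffle), function(k) {
      shuf <- result
      perm <- sample.int(geom$n_E)
      eidx <- shuf$spikes$population == "E"
      shuf$spikes$angle_deg[eidx] <-
        geom$theta_E[perm[shuf$spikes$neuron[eidx]]]
      stats::median(pav_series(shuf, window = window)$magnitude)
    }, numeric(1)))
  })
  list(present = obs > factor * ref && obs > min_pav,
       observed = obs, reference = ref)
}
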