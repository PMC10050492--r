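test_that("Welch spectra reproduce frozen reference values", {
  # deterministic three-tone signal; reference densities computed once
  # with scipy.signal.welch (hamming, nperseg 256, noverlap 128, nfft
  # 1024, fs 200) and frozen here
  t <- (0:1399) / 200
  x <- sin(2 * pi * 9 * t) + 0.5 * sin(2 * pi * 23.4 * t) +
    0.3 * sin(2 * pi * 41.7 * t + 1)
  s <- welch_psd(x)
  expect_equal(s$freq[which.max(s$psd)], 8.984375)
  ref <- c(`1` = 0.00028796134965448423, `47` = 0.4691075659814289,
           `121` = 0.11688357887253208, `214` = 0.04125603545239184,
           `513` = 1.4902306198864932e-07)
  for (i in names(ref))
    expect_equal(s$psd[as.integer(i)], ref[[i]], tolerance = 1e-10)
})

test_that("Welch spectra satisfy sinusoid, constant and noise properties", {
  t <- (0:1399) / 200
  s <- welch_psd(sin(2 * pi * 9 * t))
  expect_lt(abs(s$freq[which.max(s$psd)] - 9), 0.2)

  s0 <- welch_psd(rep(3.7, 1400))
  expect_lt(max(s0$psd), 1e-20)  # detrending removes a constant

  # white noise: flat spectrum and total power close to the variance
  set.seed(42)
  tot <- replicate(20, {
    x <- rnorm(1400)
    s <- welch_psd(x)
    sum(diff(s$freq) * (s$psd[-1] + s$psd[-length(s$psd)]) / 2) / var(x)
  })
  expect_equal(mean(tot), 1, tolerance = 0.1)
  set.seed(43)
  ps <- rowMeans(replicate(40, welch_psd(rnorm(1400))$psd))
  expect_lt(max(ps) / median(ps), 5)
  expect_error(welch_psd(rnorm(100)))  # shorter than one segment
})

test_that("peak metrics and theta power follow their definitions", {
  freq <- (0:512) * 200 / 1024
  psd <- numeric(513); psd[48] <- 100  # one loaded bin at 9.18 Hz
  spec <- structure(list(freq = freq, psd = psd),
                    class = "spectral_result")
  pk <- primary_peak_metrics(spec, convention = "integrated")
  expect_equal(pk$frequency, freq[48])
  expect_equal(pk$power, 1, tolerance = 1e-10)
  pk_m <- primary_peak_metrics(spec, convention = "mean")
  n_band <- sum(freq >= pk$frequency - 1 & freq <= pk$frequency + 1)
  n_tot <- sum(freq <= 50)
  expect_equal(pk_m$power, n_tot / n_band, tolerance = 1e-10)

  # all power inside the theta band: ratio equals the bin-count ratio
  psd2 <- numeric(513)
  intheta <- freq >= 4 & freq <= 12
  psd2[intheta] <- 1
  spec2 <- structure(list(freq = freq, psd = psd2),
                     class = "spectral_result")
  expect_equal(theta_power(spec2),
               mean(psd2[intheta]) / mean(psd2[freq <= 50]))

  # white noise: in-band and total means agree in expectation
  set.seed(7)
  tp <- replicate(30, theta_power(welch_psd(rnorm(1400))))
  expect_equal(mean(tp), 1, tolerance = 0.1)

  # DC is excluded from the peak search
  psd3 <- numeric(513); psd3[1] <- 100; psd3[40] <- 1
  spec3 <- structure(list(freq = freq, psd = psd3),
                     class = "spectral_result")
  expect_equal(primary_peak_metrics(spec3)$frequency, freq[40])
})

test_that("spike-count binning uses half-open bins", {
  geom <- ring_geometry(16L, 8L)
  sp <- spike_df("E", c(1L, 2L, 3L), c(1000, 1005, 1007.5), geom)
  r <- fake_result(sp, geom)
  b <- bin_spike_counts(r, 5, "E", window = c(1000, 1020))
  expect_equal(b$count, c(1, 2, 0, 0))  # edge spike joins the later bin
  empty <- bin_spike_counts(fake_result(sp[0, ], geom), 5, "E",
                            c(1000, 1020))
  expect_equal(empty$count, rep(0, 4))
})

test_that("PAV series matches a brute-force evaluation and its limits", {
  geom <- ring_geometry(32L, 8L)

  # every cell firing equally: full cancellation
  sp <- spike_df("E", rep(1:32, 3), rep(c(100, 200, 300), each = 32), geom)
  pav <- pav_series(fake_result(sp, geom), window = c(0, 400),
                    window_ms = 400)
  expect_lt(pav$magnitude[1], 1e-12)

  # single cluster at 90 degrees
  i90 <- which(geom$theta_E %in% c(78.75, 90, 101.25))
  sp1 <- spike_df("E", rep(i90, 5), rep(seq(50, 250, 50), each = 3), geom)
  p1 <- pav_series(fake_result(sp1, geom), window = c(0, 400),
                   window_ms = 400)
  expect_equal(p1$theta_pav[1], 90, tolerance = 1e-9)

  # adding the mirror cluster at 270 degrees doubles the magnitude
  i270 <- which(geom$theta_E %in% c(258.75, 270, 281.25))
  sp2 <- rbind(sp1, spike_df("E", rep(i270, 5),
                             rep(seq(50, 250, 50), each = 3), geom))
  p2 <- pav_series(fake_result(sp2, geom), window = c(0, 400),
                   window_ms = 400)
  expect_equal(p2$theta_pav[1], 90, tolerance = 1e-9)
  expect_equal(p2$magnitude[1], 2 * p1$magnitude[1], tolerance = 1e-12)

  # brute-force oracle on a random raster, including window sliding
  set.seed(5)
  n_spk <- 400
  sp3 <- spike_df("E", sample.int(32, n_spk, TRUE),
                  sort(runif(n_spk, 0, 2000)), geom)
  r3 <- fake_result(sp3, geom)
  pav3 <- pav_series(r3, window = c(0, 2000), window_ms = 400,
                     stride_ms = 5)
  for (k in c(1, 57, 203, nrow(pav3))) {
    t0 <- pav3$time_ms[k] - 200; t1 <- pav3$time_ms[k] + 200
    f <- vapply(1:32, function(i) {
      sum(sp3$neuron == i & sp3$time_ms >= t0 & sp3$time_ms < t1) / 0.4
    }, numeric(1))
    P <- mean(f * exp(2i * geom$theta_E * pi / 180))
    expect_equal(pav3$magnitude[k], Mod(P), tolerance = 1e-12)
    if (Mod(P) > 0) {
      cand <- ((Arg(P) * 90 / pi) %% 180) + c(0, 180)
      expect_true(min(abs(pav3$theta_pav[k] - cand)) < 1e-9)
    }
  }

  # empty window flagged
  spE <- spike_df("E", 1L, 1500, geom)
  pE <- pav_series(fake_result(spE, geom), window = c(0, 2000))
  expect_true(any(is.na(pE$theta_pav)))
  expect_equal(pE$magnitude[1], 0)
})

test_that("bump-centre spread uses circular statistics on doubled angles", {
  mk <- function(theta) data.frame(time_ms = c(1200, 1205),
                                   magnitude = 1,
                                   theta_pav = theta)
  expect_equal(sigma_pav(list(mk(c(90, 91)), mk(c(90, 91))))$sigma_deg,
               c(0, 0))
  s <- sigma_pav(list(mk(c(89, 89)), mk(c(91, 91))))
  expect_equal(s$sigma_deg, c(1, 1), tolerance = 1e-3)
  # equivalent branches 180 degrees apart coincide after doubling
  s2 <- sigma_pav(list(mk(c(89, 89)), mk(c(271, 271))))
  expect_equal(s2$sigma_deg[1], 1, tolerance = 1e-3)
  expect_equal(sigma_pav(list(mk(c(89, 89)), mk(c(91, 91))),
                         at_ms = 1203), 1, tolerance = 1e-3)
})

test_that("sharpness is 3.0 for Gaussian and 1.8 for plateau profiles", {
  theta0 <- 90
  theta <- seq(theta0 - 90, theta0 + 90, length.out = 513)[-513]
  gauss <- exp(-(theta - theta0)^2 / (2 * 10^2))
  expect_equal(bump_sharpness(theta %% 360, gauss, theta0), 3.0,
               tolerance = 1e-3)
  plateau <- as.numeric(abs(theta - theta0) <= 30)
  expect_equal(bump_sharpness(theta %% 360, plateau, theta0), 1.8,
               tolerance = 1e-2)
  # invariant under uniform rescaling of the rates
  expect_equal(bump_sharpness(theta %% 360, 7.3 * gauss, theta0),
               bump_sharpness(theta %% 360, gauss, theta0))
})

test_that("bump profile recovers height and width of a known profile", {
  geom <- ring_geometry(1024L, 256L)
  sigma <- 20
  d <- ((geom$theta_E - 90) %% 360); d <- ifelse(d > 180, d - 360, d)
  rate <- 4 * exp(-d^2 / (2 * sigma^2))
  # synthesise spikes matching these rates over 7 s (deterministic count)
  counts <- round(rate * 7)
  neurons <- rep(seq_len(geom$n_E), counts)
  times <- unlist(lapply(counts, function(k)
    if (k > 0) seq(1100, 7900, length.out = k)))
  sp <- data.frame(population = "E", neuron = neurons,
                   angle_deg = geom$theta_E[neurons], time_ms = times)
  r <- fake_result(sp, geom)
  bp <- bump_profile(r, window = c(1000, 8000), theta0 = 90)
  expect_equal(bp$height, max(counts) / 7, tolerance = 0.05)
  expect_equal(bp$fwhm, 2.355 * sigma, tolerance = 0.05)
  expect_equal(bp$sharpness, 3.0, tolerance = 0.1)
})

test_that("phase locking follows the peak-is-zero convention", {
  geom <- ring_geometry(16L, 8L)
  t_ms <- seq(0, 9000, by = 5)
  f0 <- 9  # Hz
  # per-cell currents arranged so the delayed population mean is a pure
  # 9 Hz cosine: pLFP(t) = cos(2 pi f0 t)
  wave <- cos(2 * pi * f0 * (t_ms + 10) / 1000)
  igaba <- matrix(wave, nrow = length(t_ms), ncol = geom$n_E)
  period <- 1000 / f0

  peaks <- seq(0, 80) * period + period * ceiling(1000 / period)
  peaks <- peaks[peaks >= 1000 & peaks < 8000]
  mk <- function(times) fake_result(
    spike_df("E", rep(5L, length(times)), times, geom), geom,
    t_ms = t_ms, igaba_E = igaba)

  lock <- spike_phase_locking(mk(peaks), "E", geom$theta_E[5], "plfp")
  expect_gt(lock$modulus, 0.99)
  expect_lt(min(lock$argument_deg %% 360, 360 - lock$argument_deg %% 360),
            3)

  # quarter period later: 90 degrees
  lock90 <- spike_phase_locking(mk(peaks + period / 4), "E",
                                geom$theta_E[5], "plfp")
  expect_equal(lock90$argument_deg, 90, tolerance = 3)

  # uniformly spread phases: vanishing modulus
  set.seed(1)
  lockU <- spike_phase_locking(mk(runif(600, 1000, 8000)), "E",
                               geom$theta_E[5], "plfp")
  expect_lt(lockU$modulus, 0.12)

  # no spikes: flagged undefined
  lock0 <- spike_phase_locking(mk(numeric(0)), "E", geom$theta_E[5],
                               "plfp")
  expect_true(is.na(lock0$modulus))
  expect_equal(lock0$n_spikes, 0L)
})

test_that("septal-rhythm locking matches a direct Rayleigh evaluation", {
  geom <- ring_geometry(16L, 8L)
  f <- 8
  times <- c(1000, 1030, 1100, 1220, 1475, 2000, 3333)
  r <- fake_result(spike_df("E", rep(5L, length(times)), times, geom),
                   geom, external = list(f_MS = f))
  lock <- spike_phase_locking(r, "E", geom$theta_E[5], "ms")
  phi <- (360 * f * times / 1000) %% 360
  z <- mean(exp(1i * phi * pi / 180))
  expect_equal(lock$modulus, Mod(z), tolerance = 1e-12)
  expect_equal(lock$argument_deg, (Arg(z) * 180 / pi) %% 360,
               tolerance = 1e-9)
  # spikes exactly at input peaks lock at phase zero with unit modulus
  pk <- seq(1000, 7000, by = 1000 / f)
  rpk <- fake_result(spike_df("E", rep(5L, length(pk)), pk, geom), geom,
                     external = list(f_MS = f))
  lpk <- spike_phase_locking(rpk, "E", geom$theta_E[5], "ms")
  expect_equal(lpk$modulus, 1, tolerance = 1e-9)
})

test_that("pLFP is the delayed population mean of the GABA currents", {
  geom <- ring_geometry(8L, 4L)
  t_ms <- seq(0, 2000, by = 5)
  ig <- matrix(0, length(t_ms), geom$n_E)
  r0 <- fake_result(spike_df("E", integer(0), numeric(0), geom), geom,
                    t_ms = t_ms, igaba_E = ig)
  expect_true(all(compute_plfp(r0, c(1000, 2000))$plfp == 0))

  wave <- sin(2 * pi * 7 * t_ms / 1000)
  r1 <- fake_result(spike_df("E", integer(0), numeric(0), geom), geom,
                    t_ms = t_ms, igaba_E = matrix(wave, length(t_ms),
                                                  geom$n_E))
  pl <- compute_plfp(r1, c(1000, 2000))
  expect_equal(pl$plfp,
               sin(2 * pi * 7 * (pl$time_ms - 10) / 1000),
               tolerance = 1e-12)
})
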