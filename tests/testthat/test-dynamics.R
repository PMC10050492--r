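test_that("magnesium block follows the printed voltage dependence", {
  expect_equal(mg_block_factor(-60, Mg = 0), 1)
  expect_equal(mg_block_factor(0, Mg = 0), 1)
  expect_equal(mg_block_factor(-60, Mg = 1),
               1 / (1 + exp(0.062 * 60) / 3.57), tolerance = 1e-12)
  expect_equal(mg_block_factor(-60, Mg = 1), 0.0796, tolerance = 1e-3)
  v <- seq(-90, 0, by = 1)
  expect_true(all(diff(mg_block_factor(v, Mg = 1)) > 0))  # monotone
})

test_that("NMDA gating matches closed forms and a fine-step oracle", {
  # intermediate variable: unit jump at the spike, then exp decay
  # (the first row is the state before the t = 0 spike is applied)
  tr <- nmda_gating_trace(0, t_max = 20, dt = 0.02)[-1, ]
  expect_lt(max(abs(tr$x - exp(-tr$t / 2))), 1e-4)

  # open fraction: independent fine-step RK4 integration as oracle
  oracle <- function(dt) {
    n <- round(50 / dt); x <- 1; S <- 0
    f <- function(x, S) c(-x / 2, -S / 100 + 0.5 * x * (1 - S))
    for (k in 1:n) {
      k1 <- f(x, S)
      k2 <- f(x + dt / 2 * k1[1], S + dt / 2 * k1[2])
      k3 <- f(x + dt / 2 * k2[1], S + dt / 2 * k2[2])
      k4 <- f(x + dt * k3[1], S + dt * k3[2])
      x <- x + dt / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
      S <- S + dt / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
    }
    S
  }
  tr50 <- nmda_gating_trace(0, t_max = 50, dt = 0.02)
  expect_equal(tr50$S[nrow(tr50)], oracle(0.002), tolerance = 1e-4)
  expect_true(all(tr50$S >= 0 & tr50$S <= 1))

  # late tail decays at the slow time constant once x has vanished
  tr2 <- nmda_gating_trace(0, t_max = 400, dt = 0.02)
  i1 <- which.min(abs(tr2$t - 200)); i2 <- which.min(abs(tr2$t - 300))
  expect_equal(tr2$S[i2] / tr2$S[i1], exp(-100 / 100), tolerance = 1e-3)
})

test_that("OU noise uses the exact discretization", {
  # deterministic decay when the innovation vanishes
  p <- ou_noise_path(1000, dt = 0.02, tau = 2, sd_stat = 0, init = 100)
  expect_equal(p[1001], 100 * exp(-20 / 2), tolerance = 1e-10)

  # stationary SD and lag-tau autocorrelation over a long sample
  sd_st <- 150 / sqrt(2)
  p <- ou_noise_path(5e6, dt = 0.02, tau = 2, sd_stat = sd_st, seed = 11)
  expect_equal(sd(p), sd_st, tolerance = 0.03)
  lag <- 100  # tau / dt
  ac <- cor(p[1:(length(p) - lag)], p[(lag + 1):length(p)])
  expect_equal(ac, exp(-1), tolerance = 0.05)
})

test_that("external currents assemble background, septal, cue and noise", {
  cfg <- toy_config(external = external_input_params(eta_noise = 0))
  r <- run_trial(cfg, protocol_default(duration_s = 0.1), seed = 1)
  geom <- cfg$geom
  n_cue <- sum(
    (geom$theta_E >= 67.5 & geom$theta_E <= 112.5) |
    (geom$theta_E >= 247.5 & geom$theta_E <= 292.5))
  # during the cue: background 750 plus 200 to the cued cells
  expect_equal(unname(r$mean_currents[1, "I_ext_E"]),
               750 + 200 * n_cue / geom$n_E)
  # interneurons: background 325 with constant septal -100
  expect_equal(unname(r$mean_currents[1, "I_ext_I"]), 325 - 100)
  expect_equal(unname(r$mean_currents[1, "I_MS"]), -100)

  # rhythmic septal input: cosine at phase zero adds its full amplitude
  rr <- run_trial(cfg, protocol_rhythmic(A = 40, f_MS = 8,
                                         duration_s = 0.1), seed = 1)
  expect_equal(unname(rr$mean_currents[1, "I_MS"]), -100 + 40)

  # suppression adds -200 pA to interneurons near 0 and 180 degrees
  rs <- run_trial(cfg, protocol_suppression(22.5, duration_s = 0.1),
                  seed = 1)
  n_sup <- sum(angular_difference(geom$theta_I, 0) <= 22.5 |
               angular_difference(geom$theta_I, 180) <= 22.5)
  expect_equal(unname(rs$mean_currents[1, "I_ext_I"]),
               325 - 100 - 200 * n_sup / geom$n_I)
})

test_that("synaptic currents match a double-loop evaluation on a toy net", {
  geom <- ring_geometry(4L, 2L)
  conn <- build_connectivity(geom)
  syn <- synapse_params()
  V_E <- c(-55, -60, -65, -58); V_I <- c(-52, -61)
  S <- c(0.3, 0.1, 0.8, 0.0); SG <- c(0.5, 0.2)

  out <- synaptic_currents(V_E, V_I, S, SG, conn, syn)

  I_EI <- numeric(2); I_IE <- numeric(4); I_II <- numeric(2)
  for (i in 1:2) {
    b <- 1 / (1 + exp(-0.062 * V_I[i]) / 3.57)
    acc <- 0
    for (j in 1:4) acc <- acc + conn$W_EI[i, j] * S[j]
    I_EI[i] <- 0.4 * (V_I[i] - 0) * b * acc
    acc2 <- 0
    for (j in 1:2) acc2 <- acc2 + conn$W_II[i, j] * SG[j]
    I_II[i] <- 0.04 * (V_I[i] + 70) * acc2
  }
  for (i in 1:4) {
    acc <- 0
    for (j in 1:2) acc <- acc + conn$W_IE[i, j] * SG[j]
    I_IE[i] <- 2.4 * (V_E[i] + 70) * acc
  }
  expect_equal(out$I_E_to_I, I_EI, tolerance = 1e-12)
  expect_equal(out$I_I_to_E, I_IE, tolerance = 1e-12)
  expect_equal(out$I_I_to_I, I_II, tolerance = 1e-12)

  # trivial cases: zero gating, and membrane at the reversal potential
  z <- synaptic_currents(V_E, V_I, rep(0, 4), rep(0, 2), conn, syn)
  expect_true(all(unlist(z) == 0))
  atrev <- synaptic_currents(rep(-70, 4), V_I, S, SG, conn, syn)
  expect_equal(atrev$I_I_to_E, rep(0, 4))
})

test_that("identical seeds give bit-identical simulations", {
  cfg <- toy_config()
  r1 <- run_trial(cfg, protocol_default(duration_s = 1), seed = 33)
  r2 <- run_trial(cfg, protocol_default(duration_s = 1), seed = 33)
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(r1$igaba_E, r2$igaba_E)
  r3 <- run_trial(cfg, protocol_default(duration_s = 1), seed = 34)
  expect_false(identical(r1$spikes, r3$spikes))
})

test_that("dense and convolution coupling paths agree", {
  p <- protocol_default(duration_s = 1)
  rd <- run_trial(toy_config(coupling = "dense"), p, seed = 7)
  rc <- run_trial(toy_config(coupling = "conv"), p, seed = 7)
  expect_identical(rd$spikes, rc$spikes)
  sc <- max(abs(rd$igaba_E))
  expect_lt(max(abs(rd$igaba_E - rc$igaba_E)) / sc, 1e-12)
  expect_lt(max(abs(rd$inmda_I - rc$inmda_I)) / max(abs(rd$inmda_I)),
            1e-12)
})

test_that("spike times converge as the step is refined", {
  first_spikes <- function(dt) {
    cfg <- model_config(dt = dt)
    r <- run_trial(cfg, protocol_deterministic(duration_s = 1.2), seed = 1)
    sp <- r$spikes[r$spikes$population == "E", ]
    sp <- sp[order(sp$time_ms, sp$neuron), ]
    head(sp$time_ms, 100)
  }
  expect_lt(max(abs(first_spikes(0.02) - first_spikes(0.01))), 0.1)
})

test_that("poisson input mode reproduces the mean drive currents", {
  cfg <- toy_config(external = external_input_params(
    input_mode = "poisson", eta_noise = 0))
  r <- run_trial(cfg, protocol_deterministic(duration_s = 4), seed = 5)
  iE <- mean(r$mean_currents[, "I_ext_E"])
  expect_equal(iE, 750, tolerance = 0.1)
  # deterministic protocol lowers the interneuron background to 100;
  # the septal train contributes its -100 pA mean
  iI <- mean(r$mean_currents[, "I_ext_I"])
  expect_equal(iI, 0, tolerance = 0.1 * 750)
  expect_error(run_trial(
    toy_config(external = external_input_params(input_mode = "poisson",
                                                A = 40, f_MS = 8)),
    protocol_default(duration_s = 0.1), seed = 1))
})

test_that("AMPA-mixed and recurrent-excitation variants run", {
  cfg <- toy_config(synapses = synapse_params(ampa_fraction = 0.3))
  r <- run_trial(cfg, protocol_default(duration_s = 0.5), seed = 2)
  expect_gt(nrow(r$spikes), 0)

  cfg2 <- toy_config(
    connectivity = connectivity_params(ee_enabled = TRUE, sigma_EE = 30),
    synapses = synapse_params(g_NMDA_EE = 0.1))
  r2 <- run_trial(cfg2, protocol_default(duration_s = 0.5), seed = 2)
  expect_gt(nrow(r2$spikes), 0)

  cfg3 <- toy_config(
    connectivity = connectivity_params(w_II_mode = "bimodal"))
  r3 <- run_trial(cfg3, protocol_default(duration_s = 0.5), seed = 2)
  expect_gt(nrow(r3$spikes), 0)
})
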