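# Shared fixtures. Full-size trials are expensive, so each is simulated
# once per test run and memoised; every consumer draws from the cache.

.tr_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .tr_cache))
    assign(key, force(expr), envir = .tr_cache)
  get(key, envir = .tr_cache)
}

# full-size default-protocol trial (8 s), the study condition
default_trial <- function(seed) {
  cached(sprintf("default_%d", seed),
         run_trial(model_config(), protocol_default(), seed = seed))
}

default_metrics <- function(seeds = 1:10) {
  do.call(rbind, lapply(seeds, function(s)
    cached(sprintf("metrics_%d", s), trial_metrics(default_trial(s)))))
}

default_pavs <- function(seeds = 1:10) {
  lapply(seeds, function(s)
    cached(sprintf("pav_%d", s), pav_series(default_trial(s))))
}

# full-size noise-free synchronous-regime trial (8 s)
det_trial <- function() {
  cached("det", run_trial(model_config(), protocol_deterministic(),
                          seed = 1))
}

# small ring for cheap dynamics tests
toy_config <- function(...) {
  model_config(geom = ring_geometry(64L, 16L), ...)
}

# minimal stand-in simulation result for analysis functions, built from
# synthetic rasters (and optionally synthetic traces)
fake_result <- function(spikes, geom, t_ms = NULL, igaba_E = NULL,
                        synapses = synapse_params(), external = NULL) {
  structure(list(spikes = spikes, t_ms = t_ms, igaba_E = igaba_E,
                 config = list(geom = geom, synapses = synapses,
                               external = external)),
            class = "simulation_result")
}

spike_df <- function(population, neuron, time_ms, geom) {
  theta <- if (population[1] == "E") geom$theta_E else geom$theta_I
  data.frame(population = rep(population[1], length(neuron)),
             neuron = neuron, angle_deg = theta[neuron],
             time_ms = time_ms)
}
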