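#' Experiment configuration
#'
#' Describes a multi-trial run or a one-dimensional parameter sweep:
#' a base model configuration, a protocol (or a function of the sweep
#' value returning one), the number of trials per condition, and seeds.
#' Per-trial seeds are derived deterministically from `base_seed` and are
#' distinct across trials and sweep points, so results are reproducible
#' from the configuration alone and independent of execution order.
#'
#' @param config base [model_config()].
#' @param protocol a `sim_protocol`, or a function `value -> sim_protocol`
#'   when the sweep acts on the protocol (e.g. suppression width).
#' @param n_trials trials per condition.
#' @param base_seed integer; trial seeds are `base_seed * 1000 + offset`.
#' @param sweep optional list with `section`, `field`, `values` sweeping a
#'   config field (e.g. `list(section = "synapses", field = "tau_NMDA",
#'   values = c(50, 100, 150))`), or `list(values = ...)` alone when
#'   `protocol` is a function of the value.
#' @param window analysis window, ms.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(config = model_config(),
                              protocol = protocol_default(),
                              n_trials = 10, base_seed = 1,
                              sweep = NULL, window = c(1000, 8000)) {
  stopifnot(n_trials >= 1)
  if (!is.null(sweep)) stopifnot(!is.null(sweep$values))
  structure(list(config = config, protocol = protocol,
                 n_trials = n_trials, base_seed = base_seed,
                 sweep = sweep, window = window),
            class = "experiment_config")
}

trial_seed <- function(base_seed, point, trial) {
  (base_seed * 1009 + point * 131 + trial) %% .Machine$integer.max
}

config_at <- function(cfg, sweep, value) {
  if (is.null(sweep$field)) return(cfg)
  mods <- stats::setNames(list(stats::setNames(list(value), sweep$field)),
                          sweep$section)
  do.call(modify_config, c(list(cfg), mods))
}

protocol_at <- function(protocol, value) {
  if (is.function(protocol)) protocol(value) else protocol
}

#' Run a multi-trial experiment or parameter sweep
#'
#' Runs `n_trials` independent trials per sweep point (or a single
#' condition when no sweep is given), applies [trial_metrics()] to each,
#' and aggregates per point. Failed trials are logged, excluded and
#' counted.
#'
#' @param ecfg an [experiment_config()].
#' @param keep_pav keep each trial's [pav_series()] (needed for
#'   [sigma_pav()] across trials); stored in the result's `pav` field.
#' @param verbose print per-trial progress.
#' @return An object of class `sweep_result`: list with
#'   * `per_trial`: data frame of trial metrics (with `sweep_value`),
#'   * `aggregate`: per-point means and SDs of every metric,
#'   * `sigma_pav_7s`: per-point across-trial bump-centre spread at 7 s
#'     (when `keep_pav` and at least 2 trials),
#'   * `n_failed`, `ecfg`.
#' @export
run_experiment <- function(ecfg, keep_pav = TRUE, verbose = FALSE) {
  stopifnot(inherits(ecfg, "experiment_config"))
  values <- if (is.null(ecfg$sweep)) NA else ecfg$sweep$values
  per_trial <- list()
  pav_store <- list()
  sig7 <- data.frame()
  n_failed <- 0L
  for (pi in seq_along(values)) {
    v <- values[pi]
    cfg <- if (is.null(ecfg$sweep)) ecfg$config else
      config_at(ecfg$config, ecfg$sweep, v)
    prot <- protocol_at(ecfg$protocol, v)
    pavs <- list()
    for (ti in seq_len(ecfg$n_trials)) {
      seed <- trial_seed(ecfg$base_seed, pi, ti)
      res <- tryCatch({
        r <- run_trial(cfg, prot, seed)
        m <- trial_metrics(r, ecfg$window)
        m$sweep_value <- v
        if (keep_pav) pavs[[length(pavs) + 1L]] <-
            pav_series(r, window = ecfg$window)
        m
      }, error = function(e) {
        warning(sprintf("trial %d at point %s failed: %s",
                        ti, format(v), conditionMessage(e)))
        NULL
      })
      if (is.null(res)) n_failed <- n_failed + 1L else
        per_trial[[length(per_trial) + 1L]] <- res
      if (verbose)
        message(sprintf("point %s trial %d done", format(v), ti))
    }
    if (keep_pav && length(pavs) >= 2) {
      sig7 <- rbind(sig7, data.frame(
        sweep_value = v,
        sigma_pav_7s = sigma_pav(pavs, at_ms = 7000)))
      pav_store[[pi]] <- pavs
    }
  }
  if (length(per_trial) == 0) {
    empty <- trial_metrics_template()
    return(structure(list(per_trial = empty, aggregate = empty,
                          sigma_pav_7s = NULL, pav = NULL,
                          n_failed = n_failed, ecfg = ecfg),
                     class = "sweep_result"))
  }
  per_trial <- do.call(rbind, per_trial)
  num_cols <- setdiff(names(per_trial), c("seed", "sweep_value"))
  grp <- factor(per_trial$sweep_value, exclude = NULL)  # keep NA group
  agg <- do.call(rbind, lapply(split(per_trial, grp),
    function(d) {
      out <- data.frame(sweep_value = d$sweep_value[1], n = nrow(d))
      for (cn in num_cols) {
        out[[paste0(cn, "_mean")]] <- mean(d[[cn]], na.rm = TRUE)
        out[[paste0(cn, "_sd")]] <- if (nrow(d) > 1)
          stats::sd(d[[cn]], na.rm = TRUE) else 0
      }
      # circular statistics for locking angles
      out$lock_E_arg_mean <- circular_mean_deg(d$lock_E_arg)
      out$lock_I_arg_mean <- circular_mean_deg(d$lock_I_arg)
      out
    }))
  rownames(agg) <- NULL
  # preserve sweep ordering (split() sorts by value as character)
  if (!all(is.na(values)))
    agg <- agg[match(values, agg$sweep_value), ]
  structure(list(per_trial = per_trial, aggregate = agg,
                 sigma_pav_7s = if (nrow(sig7)) sig7,
                 pav = if (keep_pav) pav_store,
                 n_failed = n_failed, ecfg = ecfg),
            class = "sweep_result")
}

# zero-row data frame with the trial-metrics columns, for empty sweeps
trial_metrics_template <- function() {
  cols <- c("seed", "peak_freq", "peak_power", "peak_power_integrated",
            "theta_power", "sc_peak_freq", "vm_peak_freq", "max_rate_E",
            "mean_rate_E", "mean_rate_I", "pav_mean", "pav_cv",
            "pav_median", "bump_height", "bump_fwhm", "bump_sharpness",
            "lock_E_mod", "lock_E_arg", "lock_I_mod", "lock_I_arg",
            "lock_E_ms_mod", "lock_E_ms_arg", "sweep_value")
  out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)),
                                       cols))
  out
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d trials over %d point(s), %d failed\n",
              nrow(x$per_trial), nrow(x$aggregate), x$n_failed))
  cols <- intersect(c("sweep_value", "n", "peak_freq_mean",
                      "peak_power_mean", "theta_power_mean"),
                    names(x$aggregate))
  print(x$aggregate[, cols], digits = 4, row.names = FALSE)
  invisible(x)
}

#' Rhythmic septal-input experiment
#'
#' Sweeps the frequency of the rhythmic septal drive at fixed amplitude,
#' collecting per-point spectral peaks, bump-centre spread at 7 s, bump
#' sharpness and phase locking to both the pLFP and the input rhythm.
#'
#' @param A input amplitude, pA.
#' @param f_values input frequencies, Hz.
#' @param config base [model_config()].
#' @param n_trials trials per frequency.
#' @param base_seed seed.
#' @param duration_s trial length, s.
#' @param window analysis window, ms.
#' @return a `sweep_result` (sweep value = `f_MS`).
#' @export
run_rhythmic_ms_experiment <- function(A = 40,
                                       f_values = c(2, 4, 6, 8, 11, 14),
                                       config = model_config(),
                                       n_trials = 10, base_seed = 1,
                                       duration_s = 8,
                                       window = c(1000, 8000)) {
  ecfg <- experiment_config(
    config = config,
    protocol = function(f) protocol_rhythmic(A = A, f_MS = f,
                                             duration_s = duration_s),
    n_trials = n_trials, base_seed = base_seed,
    sweep = list(values = f_values), window = window)
  run_experiment(ecfg)
}

#' Write a sweep result to disk
#'
#' Per-trial metrics and per-point aggregates as CSV, the whole result as
#' JSON, and a short human-readable summary.
#'
#' @param sweep a [run_experiment()] result.
#' @param dir output directory (created).
#' @return invisibly, the paths written.
#' @export
report_sweep <- function(sweep, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "per_trial.csv")
  utils::write.csv(sweep$per_trial, p1, row.names = FALSE)
  p2 <- file.path(dir, "aggregate.csv")
  utils::write.csv(sweep$aggregate, p2, row.names = FALSE)
  p3 <- file.path(dir, "sweep.json")
  jsonlite::write_json(
    list(per_trial = sweep$per_trial, aggregate = sweep$aggregate,
         sigma_pav_7s = sweep$sigma_pav_7s, n_failed = sweep$n_failed),
    p3, auto_unbox = TRUE, digits = NA, dataframe = "columns", null = "null")
  p4 <- file.path(dir, "summary.txt")
  con <- file(p4, "w")
  sink(con); print(sweep); sink()
  close(con)
  invisible(c(per_trial = p1, aggregate = p2, json = p3, summary = p4))
}

#' Read a sweep report back
#'
#' @param dir directory written by [report_sweep()].
#' @return list with `per_trial` and `aggregate` data frames (plus
#'   `sigma_pav_7s` when present).
#' @export
read_sweep_report <- function(dir) {
  j <- jsonlite::read_json(file.path(dir, "sweep.json"),
                           simplifyVector = TRUE)
  j$per_trial <- as.data.frame(j$per_trial)
  j$aggregate <- as.data.frame(j$aggregate)
  if (!is.null(j$sigma_pav_7s)) j$sigma_pav_7s <- as.data.frame(j$sigma_pav_7s)
  j
}
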