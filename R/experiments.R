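#' Simulate one stimulus condition and summarize its coherence
#'
#' Builds a network realization, simulates \code{n_trials} independent trials
#' (fresh background input, transmission failures and initial conditions per
#' trial; identical periodic drive), converts rasters to smoothed population
#' rates over the analysis window, and computes the ITPC spectrum and its
#' band mean around the stimulus frequency for both populations. Conditions
#' whose excitatory activity runs away are flagged and report no coherence.
#'
#' @param params a \code{\link{network_params}}.
#' @param stim a \code{\link{stimulus_config}} with periodic input enabled.
#' @param n_trials trial count (>= 2); defaults to \code{stim$n_trials}.
#' @param seed master seed (split into network and per-trial streams).
#' @param dt integration step (ms).
#' @param trial_seeds optional explicit per-trial seeds (overrides the
#'   derived ones; repeated seeds give identical trials).
#' @param runaway_threshold mean E rate (Hz/neuron) above which the condition
#'   is flagged.
#' @param rate_cap hard per-trial abort cap passed to the simulator
#'   (Hz/neuron; 0 disables).
#' @param keep_rates keep the per-trial smoothed rate series in the result.
#' @return A \code{condition_result}: list with \code{mean_itpc_band} (named
#'   E/I; NA when flagged), \code{itpc} (per-population
#'   \code{itpc_result}s, NULL when flagged), \code{runaway},
#'   \code{mean_rate} (Hz/neuron per population), \code{n_trials},
#'   \code{f_s}, and optionally \code{rates}.
#' @export
run_condition <- function(params, stim, n_trials = stim$n_trials,
                          seed = NULL, dt = 0.05, trial_seeds = NULL,
                          runaway_threshold = 100, rate_cap = 400,
                          keep_rates = FALSE) {
  if (n_trials < 2) stop("ITPC is undefined for fewer than 2 trials")
  if (!stim$periodic_input)
    stop("run_condition requires periodic input; see spontaneous_psd_experiment")
  seeds <- derive_seeds(if (is.null(seed)) sample.int(1e9, 1) else seed,
                        1 + n_trials)
  if (is.null(trial_seeds)) trial_seeds <- seeds[-1]
  if (length(trial_seeds) != n_trials)
    stop("trial_seeds must have one entry per trial")

  net <- build_network(params, seed = seeds[1])
  cnet <- compile_network(net, dt)
  rm(net)

  duration <- stim$warmup + stim$analysis_window
  window <- c(stim$warmup, duration)
  n <- params$n_e + params$n_i

  rates_e <- vector("list", n_trials)
  rates_i <- vector("list", n_trials)
  mean_rate_e <- numeric(n_trials)
  mean_rate_i <- numeric(n_trials)
  any_truncated <- FALSE

  for (j in seq_len(n_trials)) {
    ts <- derive_seeds(trial_seeds[j], 2)
    inputs <- make_input_trains(stim, n_neurons = n, duration = duration,
                                trial_id = j, seed = ts[1])
    raster <- simulate_trial(cnet, params, inputs, duration = duration,
                             dt = dt, seed = ts[2],
                             max_mean_rate_hz = rate_cap)
    any_truncated <- any_truncated || isTRUE(attr(raster, "truncated"))
    dur_s <- attr(raster, "duration_simulated") / 1000
    n_e <- params$n_e
    mean_rate_e[j] <- sum(raster$neuron <= n_e) / (n_e * dur_s)
    mean_rate_i[j] <- sum(raster$neuron > n_e) / (params$n_i * dur_s)
    if (!isTRUE(attr(raster, "truncated"))) {
      rates_e[[j]] <- gaussian_smooth(population_rate(raster, "E", window))
      rates_i[[j]] <- gaussian_smooth(population_rate(raster, "I", window))
    }
  }

  runaway <- any_truncated || mean(mean_rate_e) > runaway_threshold
  out <- list(mean_itpc_band = c(E = NA_real_, I = NA_real_),
              itpc = NULL, runaway = runaway,
              mean_rate = c(E = mean(mean_rate_e), I = mean(mean_rate_i)),
              n_trials = n_trials, f_s = stim$f_s, seed = seed,
              params = params, stim = stim)
  if (!runaway) {
    itpc_e <- itpc_spectrum(rates_e)
    itpc_i <- itpc_spectrum(rates_i)
    out$itpc <- list(E = itpc_e, I = itpc_i)
    out$mean_itpc_band <- c(E = mean_itpc(itpc_e, stim$f_s),
                            I = mean_itpc(itpc_i, stim$f_s))
  }
  if (keep_rates) out$rates <- list(E = rates_e, I = rates_i)
  class(out) <- "condition_result"
  out
}

#' @export
print.condition_result <- function(x, ...) {
  cat(sprintf("<condition_result> f_s = %g Hz, T = %d\n", x$f_s, x$n_trials))
  if (x$runaway) {
    cat(sprintf("  RUNAWAY (mean E rate %.1f Hz); no coherence reported\n",
                x$mean_rate[["E"]]))
  } else {
    cat(sprintf("  band-mean ITPC: E = %.3f, I = %.3f (mean E rate %.2f Hz)\n",
                x$mean_itpc_band[["E"]], x$mean_itpc_band[["I"]],
                x$mean_rate[["E"]]))
  }
  invisible(x)
}

#' Specify a parameter sweep
#'
#' Either a single swept parameter (\code{param} + \code{values}) or an
#' explicit list of multi-parameter \code{conditions} (named lists of
#' \code{\link{network_params}} overrides). Swept values are validated
#' against the model's studied ranges: \code{g_ie} in [0.0017, 0.0045],
#' \code{g_ei} in [0.013, 0.018], \code{theta_epsp} in [5, 10] mV,
#' \code{w_in_i} in [0.1, 0.5] mV.
#'
#' @param param name of the swept parameter (ignored when \code{conditions}
#'   is given).
#' @param values numeric values of the swept parameter.
#' @param f_s stimulus frequencies (Hz) to run each condition at.
#' @param n_trials trials per evaluation.
#' @param n_evaluations independent network realizations per condition
#'   (>= 2 for a dispersion estimate).
#' @param seed master seed.
#' @param base_params baseline \code{network_params}.
#' @param stim baseline \code{stimulus_config} (its \code{f_s} is overridden).
#' @param conditions optional list of named override lists; names of the list
#'   entries become condition labels.
#' @return A \code{sweep_spec}.
#' @export
sweep_spec <- function(param = NULL, values = NULL, f_s = 80,
                       n_trials = 20, n_evaluations = 3, seed = 1,
                       base_params = network_params(),
                       stim = stimulus_config(n_trials = n_trials),
                       conditions = NULL) {
  ranges <- list(g_ie = c(0.0017, 0.0045), g_ei = c(0.013, 0.018),
                 theta_epsp = c(5, 10), w_in_i = c(0.1, 0.5))
  if (is.null(conditions)) {
    if (is.null(param) || is.null(values))
      stop("give either param + values or conditions")
    if (!param %in% names(ranges))
      stop("swept parameter must be one of: ", paste(names(ranges), collapse = ", "))
    rg <- ranges[[param]]
    if (any(values < rg[1] - 1e-12 | values > rg[2] + 1e-12))
      stop(sprintf("%s values must lie in [%g, %g]", param, rg[1], rg[2]))
    conditions <- lapply(values, function(v) stats::setNames(list(v), param))
    names(conditions) <- format(values)
  } else {
    for (cond in conditions) {
      for (nm in intersect(names(cond), names(ranges))) {
        rg <- ranges[[nm]]
        if (cond[[nm]] < rg[1] - 1e-12 || cond[[nm]] > rg[2] + 1e-12)
          stop(sprintf("%s values must lie in [%g, %g]", nm, rg[1], rg[2]))
      }
    }
    if (is.null(names(conditions)))
      names(conditions) <- paste0("cond", seq_along(conditions))
  }
  if (n_evaluations < 1) stop("n_evaluations must be >= 1")
  structure(list(param = param, conditions = conditions, f_s = f_s,
                 n_trials = n_trials, n_evaluations = n_evaluations,
                 seed = seed, base_params = base_params, stim = stim),
            class = "sweep_spec")
}

#' Run a parameter sweep
#'
#' For every (condition, stimulus frequency) pair, runs
#' \code{n_evaluations} independent network realizations (fresh connectivity
#' seed each) of \code{\link{run_condition}} and aggregates the band-mean
#' ITPC across evaluations. Failures and runaway conditions are recorded and
#' the sweep continues.
#'
#' @param spec a \code{\link{sweep_spec}}.
#' @param dt integration step (ms).
#' @param verbose print progress lines.
#' @return A data.frame with one row per (condition, f_s, population):
#'   columns \code{condition}, \code{value} (the swept value, NA for
#'   multi-parameter conditions), \code{f_s}, \code{population},
#'   \code{mean_itpc}, \code{sd_itpc}, \code{mean_rate},
#'   \code{runaway_frac}, \code{n_evaluations}, \code{n_trials}.
#' @export
run_sweep <- function(spec, dt = 0.05, verbose = interactive()) {
  stopifnot(inherits(spec, "sweep_spec"))
  n_cond <- length(spec$conditions)
  n_cell <- n_cond * length(spec$f_s)
  seeds <- matrix(derive_seeds(spec$seed, n_cell * spec$n_evaluations),
                  nrow = spec$n_evaluations)
  rows <- list()
  cell <- 0L
  for (ci in seq_len(n_cond)) {
    overrides <- spec$conditions[[ci]]
    p <- spec$base_params
    for (nm in names(overrides)) p[[nm]] <- overrides[[nm]]
    validate_network_params(unclass(p))
    for (f in spec$f_s) {
      cell <- cell + 1L
      st <- spec$stim
      st$f_s <- f
      band_e <- band_i <- rate_e <- rep(NA_real_, spec$n_evaluations)
      run_flag <- logical(spec$n_evaluations)
      for (ev in seq_len(spec$n_evaluations)) {
        res <- tryCatch(
          run_condition(p, st, n_trials = spec$n_trials,
                        seed = seeds[ev, cell], dt = dt),
          error = function(e) e)
        if (inherits(res, "error")) {
          warning(sprintf("condition %s @ %g Hz, evaluation %d failed: %s",
                          names(spec$conditions)[ci], f, ev,
                          conditionMessage(res)))
          run_flag[ev] <- NA
          next
        }
        run_flag[ev] <- res$runaway
        band_e[ev] <- res$mean_itpc_band[["E"]]
        band_i[ev] <- res$mean_itpc_band[["I"]]
        rate_e[ev] <- res$mean_rate[["E"]]
      }
      val <- if (length(overrides) == 1) overrides[[1]] else NA_real_
      for (popn in c("E", "I")) {
        b <- if (popn == "E") band_e else band_i
        rows[[length(rows) + 1L]] <- data.frame(
          condition = names(spec$conditions)[ci], value = val, f_s = f,
          population = popn,
          mean_itpc = if (all(is.na(b))) NA_real_ else mean(b, na.rm = TRUE),
          sd_itpc = if (sum(!is.na(b)) > 1) sd(b, na.rm = TRUE) else NA_real_,
          mean_rate = mean(rate_e, na.rm = TRUE),
          runaway_frac = mean(run_flag, na.rm = TRUE),
          n_evaluations = spec$n_evaluations, n_trials = spec$n_trials)
      }
      if (verbose)
        message(sprintf("sweep %s @ %g Hz: ITPC(E) = %s",
                        names(spec$conditions)[ci], f,
                        format(mean(band_e, na.rm = TRUE), digits = 3)))
    }
  }
  do.call(rbind, rows)
}

#' Spontaneous-activity power spectra across conditions
#'
#' Disables the periodic drive (background Poisson input only) and computes
#' the trial-averaged power spectrum of the smoothed excitatory population
#' rate for each parameter set.
#'
#' @param params_list list of \code{\link{network_params}} (names become
#'   condition labels).
#' @param stim a \code{\link{stimulus_config}}; its periodic input is forced
#'   off.
#' @param n_trials trials per condition (default 10).
#' @param seed master seed.
#' @param dt integration step (ms).
#' @param f_max upper frequency cut for the returned spectra (Hz).
#' @param rate_cap per-trial abort cap (Hz/neuron; 0 disables).
#' @return Named list of \code{power_spectrum} objects.
#' @export
spontaneous_psd_experiment <- function(params_list,
                                       stim = stimulus_config(periodic_input = FALSE),
                                       n_trials = 10, seed = NULL, dt = 0.05,
                                       f_max = 200, rate_cap = 0) {
  stim$periodic_input <- FALSE
  if (is.null(names(params_list)))
    names(params_list) <- paste0("cond", seq_along(params_list))
  seeds <- derive_seeds(if (is.null(seed)) sample.int(1e9, 1) else seed,
                        length(params_list))
  duration <- stim$warmup + stim$analysis_window
  window <- c(stim$warmup, duration)
  out <- list()
  for (ci in seq_along(params_list)) {
    p <- params_list[[ci]]
    s <- derive_seeds(seeds[ci], 1 + n_trials)
    net <- build_network(p, seed = s[1])
    cnet <- compile_network(net, dt)
    rm(net)
    rates <- vector("list", n_trials)
    for (j in seq_len(n_trials)) {
      ts <- derive_seeds(s[1 + j], 2)
      inputs <- make_input_trains(stim, n_neurons = p$n_e + p$n_i,
                                  duration = duration, trial_id = j,
                                  seed = ts[1])
      raster <- simulate_trial(cnet, p, inputs, duration = duration, dt = dt,
                               seed = ts[2], max_mean_rate_hz = rate_cap)
      rates[[j]] <- gaussian_smooth(population_rate(raster, "E", window))
    }
    out[[names(params_list)[ci]]] <- power_spectrum(rates, f_max = f_max)
    rm(cnet)
  }
  out
}

#' Preset sweeps of the four studied manipulations
#'
#' Returns ready-made \code{\link{sweep_spec}}s for the four experiment
#' families: \code{"inhibition"} (PV-to-Pyr weight g_ie, GABA maturation,
#' at 40 and 80 Hz), \code{"glutamatergic"} (Pyr-to-PV weight g_ei reduction),
#' \code{"input-strength"} (reduced input jump onto PV cells, alone and
#' combined with the g_ei reduction) and \code{"epsp-threshold"} (EPSP
#' truncation threshold). \code{scale = "reduced"} uses anchor values with
#' T = 20 trials and 3 evaluations; \code{scale = "full"} uses the complete
#' grids with T = 100 and 10 evaluations (long-running).
#'
#' @param name preset name.
#' @param scale \code{"reduced"} or \code{"full"}.
#' @param seed master seed.
#' @return A \code{sweep_spec}.
#' @export
preset_sweep <- function(name = c("inhibition", "glutamatergic",
                                  "input-strength", "epsp-threshold"),
                         scale = c("reduced", "full"), seed = 1) {
  name <- match.arg(name)
  scale <- match.arg(scale)
  reduced <- scale == "reduced"
  n_trials <- if (reduced) 20 else 100
  n_eval <- if (reduced) 3 else 10
  window <- if (reduced) 500 else 1000
  stim <- stimulus_config(n_trials = n_trials, analysis_window = window)
  switch(name,
    "inhibition" = sweep_spec(
      param = "g_ie",
      values = if (reduced) c(0.0017, 0.0027, 0.0045)
               else c(0.0017, 0.0018, 0.0019, 0.0020, 0.0027, 0.0045),
      f_s = c(40, 80), n_trials = n_trials, n_evaluations = n_eval,
      seed = seed, stim = stim),
    "glutamatergic" = sweep_spec(
      param = "g_ei", values = c(0.013, 0.016, 0.018),
      f_s = 80, n_trials = n_trials, n_evaluations = n_eval,
      seed = seed, stim = stim),
    "input-strength" = sweep_spec(
      conditions = list(baseline = list(w_in_i = 0.5, g_ei = 0.018),
                        reduced_input = list(w_in_i = 0.1, g_ei = 0.018),
                        reduced_both = list(w_in_i = 0.1, g_ei = 0.013)),
      f_s = 80, n_trials = n_trials, n_evaluations = n_eval,
      seed = seed, stim = stim),
    "epsp-threshold" = sweep_spec(
      param = "theta_epsp",
      values = if (reduced) c(5, 6, 10) else 5:10,
      f_s = 80, n_trials = n_trials, n_evaluations = n_eval,
      seed = seed, stim = stim))
}
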