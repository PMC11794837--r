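#' Simulate one trial of the conductance-based LIF network
#'
#' Integrates the membrane equation
#' \deqn{dv/dt = -(v - V_L)/\tau_m - g_E (v - V_E) - g_I (v - V_I) + \sum W^{in} \delta(t - s_i)}
#' with exponentially decaying synaptic conductances. Each presynaptic spike
#' at time s schedules a conductance increment G at s + d on its targets
#' (Pyr-to-Pyr events are independently dropped with their transmission
#' failure probability); input spikes add an instantaneous voltage jump; a
#' crossing of \code{v_thr} emits a spike and resets the neuron to \code{v_r}
#' (no refractory period). The integrator uses an exponential-Euler update
#' (exact for the leak and conductance decays, conductances held constant
#' within a step) with events delivered on the dt grid.
#'
#' @param synapses a \code{\link{build_network}} result, or a pre-compiled
#'   network from \code{\link{compile_network}}.
#' @param params a \code{\link{network_params}} object.
#' @param inputs a \code{\link{make_input_trains}} object.
#' @param duration trial duration (ms); defaults to the input trains'.
#' @param dt integration step (ms); must be <= 0.1.
#' @param seed optional seed covering initial conditions and transmission
#'   failures (the inputs carry their own seed).
#' @param v_init initial membrane potentials: \code{NULL} for uniform random
#'   in (v_l, v_thr), a scalar applied to all neurons, or a full vector.
#' @param record_neuron optional 1-based neuron id whose membrane potential
#'   and conductances are recorded every step (for diagnostics/validation).
#' @param max_mean_rate_hz safety cap: abort the trial once the running mean
#'   excitatory rate implied by the spike count exceeds this value (Hz per
#'   neuron); the raster is then marked \code{truncated}. 0 disables.
#' @return A \code{spike_raster}: data.frame with \code{time} (ms) and
#'   \code{neuron} (1-based; E neurons 1..N_E, I neurons N_E+1..N_E+N_I),
#'   with attributes \code{n_e}, \code{n_i}, \code{duration},
#'   \code{duration_simulated}, \code{truncated}, \code{trial_id} and, if
#'   requested, \code{trace} (time, v, g_ampa, g_gaba).
#' @examples
#' p <- network_params(n_e = 50, n_i = 10, p_conn_ee = 0.2)
#' net <- build_network(p, seed = 1)
#' inp <- make_input_trains(stimulus_config(f_s = 40, analysis_window = 500),
#'                          n_neurons = 60, duration = 200, seed = 2)
#' r <- simulate_trial(net, p, inp, duration = 200, seed = 3)
#' @export
simulate_trial <- function(synapses, params, inputs, duration = NULL,
                           dt = 0.05, seed = NULL, v_init = NULL,
                           record_neuron = NULL, max_mean_rate_hz = 0) {
  if (dt <= 0 || dt > 0.1) stop("dt must be positive and <= 0.1 ms")
  if (is.null(duration)) duration <- inputs$duration
  if (duration <= 0) stop("duration must be positive")

  net <- compile_network(synapses, dt)
  n_e <- net$n_e
  n_i <- net$n_i
  n <- n_e + n_i

  seeds <- if (is.null(seed)) c(NULL, NULL) else derive_seeds(seed, 2)
  if (is.null(v_init)) {
    v0 <- with_seed(seeds[1], function() runif(n, params$v_l, params$v_thr))
  } else if (length(v_init) == 1) {
    v0 <- rep(v_init, n)
  } else {
    if (length(v_init) != n) stop("v_init must be scalar or length n_e + n_i")
    v0 <- v_init
  }

  fan <- if (is.null(inputs$fan_out)) 1 else inputs$fan_out
  mask <- if (fan >= 1) integer(0) else {
    m <- integer(n)
    m[seq_len(floor(fan * n_e))] <- 1L
    if (n_i > 0) m[n_e + seq_len(floor(fan * n_i))] <- 1L
    m
  }

  max_e_spikes <- if (max_mean_rate_hz > 0)
    max_mean_rate_hz * n_e * duration / 1000 else 0

  # decay constants (ampa_onto_e, gaba_onto_e, ampa_onto_i, gaba_onto_i)
  taus <- if (identical(params$tau_s_indexing %||% "presynaptic",
                        "postsynaptic")) {
    c(params$tau_s_ampa, params$tau_s_ampa,
      params$tau_s_gaba, params$tau_s_gaba)
  } else {
    c(params$tau_s_ampa, params$tau_s_gaba,
      params$tau_s_ampa, params$tau_s_gaba)
  }

  res <- with_seed(seeds[2], function() {
    cpp_simulate(n_e, n_i,
                 net$csr$ptr, net$csr$post, net$csr$w, net$csr$dsteps,
                 net$csr$pfail,
                 params$v_l, params$v_thr, params$v_r, params$v_e, params$v_i,
                 params$tau_m_e, params$tau_m_i,
                 taus[1], taus[2], taus[3], taus[4],
                 inputs$periodic,
                 params$w_in_e * (inputs$stim_fibers %||% 1),
                 params$w_in_i * (inputs$stim_fibers %||% 1),
                 mask,
                 params$w_in_e, params$w_in_i,
                 inputs$background$time, as.integer(inputs$background$neuron - 1L),
                 inputs$bg_rate %||% 0,
                 duration, dt, v0,
                 if (is.null(record_neuron)) -1L else as.integer(record_neuron - 1L),
                 max_e_spikes)
  })

  raster <- data.frame(time = res$time, neuron = res$neuron)
  attr(raster, "n_e") <- n_e
  attr(raster, "n_i") <- n_i
  attr(raster, "duration") <- duration
  attr(raster, "duration_simulated") <- res$duration_simulated
  attr(raster, "truncated") <- res$truncated
  attr(raster, "trial_id") <- inputs$trial_id
  if (!is.null(record_neuron)) {
    ns <- length(res$v_trace)
    attr(raster, "trace") <- data.frame(time = seq_len(ns) * dt,
                                        v = res$v_trace,
                                        g_ampa = res$ge_trace,
                                        g_gaba = res$gg_trace)
  }
  class(raster) <- c("spike_raster", "data.frame")
  raster
}

#' Pre-compile a synapse table for repeated simulation
#'
#' Groups synapses by presynaptic neuron and rounds delays to the dt grid
#' once, so repeated trials on the same network skip that work.
#'
#' @param synapses a \code{synapse_table} (or an already compiled network,
#'   returned unchanged if the dt matches).
#' @param dt integration step (ms).
#' @return An object of class \code{compiled_network}.
#' @export
compile_network <- function(synapses, dt = 0.05) {
  if (inherits(synapses, "compiled_network")) {
    if (!isTRUE(all.equal(synapses$dt, dt)))
      stop("network was compiled for dt = ", synapses$dt)
    return(synapses)
  }
  if (!inherits(synapses, "synapse_table")) stop("expected a synapse_table")
  structure(list(csr = as_csr(synapses, dt), dt = dt,
                 n_e = synapses$n_e, n_i = synapses$n_i),
            class = "compiled_network")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d spikes, %d E + %d I neurons, %g ms%s\n",
              nrow(x), attr(x, "n_e"), attr(x, "n_i"),
              attr(x, "duration_simulated"),
              if (isTRUE(attr(x, "truncated"))) " (truncated)" else ""))
  invisible(x)
}

#' Flag runaway network activity
#'
#' A completed trial is flagged as runaway when the mean per-neuron
#' excitatory firing rate exceeds the threshold (strict inequality), or when
#' the simulation was aborted early by the rate cap. Runaway conditions are
#' excluded from coherence summaries rather than reported.
#'
#' @param raster a \code{spike_raster}.
#' @param threshold_rate mean E rate threshold, Hz per neuron (default 100).
#' @return Logical flag.
#' @export
detect_runaway <- function(raster, threshold_rate = 100) {
  if (isTRUE(attr(raster, "truncated"))) return(TRUE)
  n_e <- attr(raster, "n_e")
  dur_s <- attr(raster, "duration_simulated") / 1000
  if (nrow(raster) == 0 || dur_s <= 0) return(FALSE)
  mean_rate <- sum(raster$neuron <= n_e) / (n_e * dur_s)
  mean_rate > threshold_rate
}

#' Write a spike raster as a two-column event list
#'
#' @param raster a \code{spike_raster}.
#' @param path output CSV path (columns time_ms, neuron_id).
#' @export
write_raster <- function(raster, path) {
  write.csv(data.frame(time_ms = raster$time, neuron_id = raster$neuron),
            path, row.names = FALSE)
  invisible(path)
}
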