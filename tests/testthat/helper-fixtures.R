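# Small hand-built fixtures used across test files.

# A synapse table assembled directly from vectors (bypasses sampling).
manual_synapses <- function(pre, post, kind, weight, delay, p_fail,
                            n_e, n_i, params) {
  structure(list(pre = as.integer(pre), post = as.integer(post),
                 kind = factor(kind, levels = c("EE", "EI", "IE", "II")),
                 weight = weight, delay = delay, p_fail = p_fail,
                 n_e = as.integer(n_e), n_i = as.integer(n_i),
                 params = params, seed = NULL),
            class = "synapse_table")
}

empty_synapses <- function(params) {
  manual_synapses(integer(0), integer(0), character(0), numeric(0),
                  numeric(0), numeric(0), params$n_e, params$n_i, params)
}

# Input trains with no stimulus and no background at all.
silent_inputs <- function(duration) {
  structure(list(periodic = numeric(0),
                 background = data.frame(time = numeric(0), neuron = integer(0)),
                 bg_rate = 0, stim_fibers = 0, duration = duration,
                 trial_id = 1L, seed = NULL, fan_out = 1),
            class = "input_trains")
}

# A spike raster assembled directly (for analysis-stage tests).
manual_raster <- function(time, neuron, n_e, n_i, duration) {
  r <- data.frame(time = time, neuron = as.integer(neuron))
  attr(r, "n_e") <- as.integer(n_e)
  attr(r, "n_i") <- as.integer(n_i)
  attr(r, "duration") <- duration
  attr(r, "duration_simulated") <- duration
  attr(r, "truncated") <- FALSE
  class(r) <- c("spike_raster", "data.frame")
  r
}

# A rate_series assembled directly.
manual_rates <- function(r, dt = 0.1, population = "E", smoothed = TRUE) {
  structure(list(t = (seq_along(r) - 0.5) * dt, r = r, dt = dt,
                 population = population, smoothed = smoothed),
            class = "rate_series")
}

# noiseless synthetic ensembles legitimately contain exact-zero Fourier
# components off the tone frequency; silence the zero-component warning
itpc_quiet <- function(...) suppressWarnings(itpc_spectrum(...))
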