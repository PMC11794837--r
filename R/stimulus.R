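#' Deterministic periodic input spike train
#'
#' Spike times at \code{onset_time + k * 1000/f_s} for all k with times
#' strictly below \code{duration}. The train is shared by all receiving
#' neurons and identical across trials, so the stimulus phase is perfectly
#' defined and trial-to-trial variability comes only from network noise.
#'
#' @param config a \code{\link{stimulus_config}}.
#' @param duration trial duration (ms); must cover at least one period.
#' @return Numeric vector of spike times (ms).
#' @examples
#' make_periodic_train(stimulus_config(f_s = 40), duration = 100)  # 0 25 50 75
#' @export
make_periodic_train <- function(config, duration) {
  period <- 1000 / config$f_s
  if (duration < period) stop("duration must cover at least one stimulus period")
  if (!config$periodic_input) return(numeric(0))
  t0 <- config$onset_time
  if (t0 >= duration) return(numeric(0))
  t0 + period * seq.int(0L, floor((duration - t0 - 1e-9) / period))
}

#' Poisson background spike trains
#'
#' Independent homogeneous Poisson trains, one per neuron, delivered as
#' voltage jumps of the receiving neuron's input weight. These maintain
#' spontaneous network activity.
#'
#' @param rate Poisson rate per neuron (Hz); non-negative.
#' @param n_neurons number of target neurons.
#' @param duration trial duration (ms).
#' @param seed optional seed.
#' @return A data.frame with columns \code{time} (ms, globally sorted) and
#'   \code{neuron} (1-based target id).
#' @export
make_poisson_background <- function(rate, n_neurons, duration, seed = NULL) {
  if (rate < 0) stop("rate must be non-negative")
  if (rate == 0 || n_neurons == 0)
    return(data.frame(time = numeric(0), neuron = integer(0)))
  with_seed(seed, function() {
    counts <- rpois(n_neurons, rate * duration / 1000)
    neuron <- rep.int(seq_len(n_neurons), counts)
    time <- runif(sum(counts), 0, duration)
    ord <- order(time)
    data.frame(time = time[ord], neuron = neuron[ord])
  })
}

#' Per-trial input spike trains
#'
#' Bundles the shared periodic train and the per-neuron Poisson background
#' for one trial. The periodic train is deterministic (bit-identical across
#' trials); only the background consumes randomness.
#'
#' The background of \code{bg_fibers} independent fibers per neuron, each at
#' \code{poisson_rate} Hz, is by default drawn on the fly inside the
#' simulator (an aggregate Poisson train of rate
#' \code{poisson_rate * bg_fibers} per neuron, too dense to materialize);
#' \code{explicit_background = TRUE} materializes it as an event list
#' instead, which is practical for small networks and required for
#' exporting input trains.
#'
#' @param config a \code{\link{stimulus_config}}.
#' @param n_neurons total number of neurons receiving background input.
#' @param duration trial duration (ms); defaults to warmup + analysis window.
#' @param trial_id identifier recorded in the result.
#' @param seed optional seed for the background (only consumed when the
#'   background is materialized here).
#' @param explicit_background materialize background spikes as an event list.
#' @return An object of class \code{input_trains}: list with \code{periodic}
#'   (times, ms), \code{background} (data.frame time/neuron; empty when the
#'   background is drawn in the simulator), \code{bg_rate} (aggregate Hz per
#'   neuron for simulator-side generation), \code{trial_id} and \code{seed}.
#' @export
make_input_trains <- function(config, n_neurons, duration = NULL,
                              trial_id = 1L, seed = NULL,
                              explicit_background = FALSE) {
  if (is.null(duration)) duration <- config$warmup + config$analysis_window
  periodic <- if (config$periodic_input)
    make_periodic_train(config, duration) else numeric(0)
  rate <- config$poisson_rate * config$bg_fibers
  if (explicit_background) {
    background <- make_poisson_background(rate, n_neurons, duration,
                                          seed = seed)
    rate <- 0
  } else {
    background <- data.frame(time = numeric(0), neuron = integer(0))
  }
  structure(list(periodic = periodic, background = background,
                 bg_rate = rate, stim_fibers = config$stim_fibers,
                 duration = duration, trial_id = trial_id, seed = seed,
                 fan_out = config$fan_out),
            class = "input_trains")
}
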