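#' Network parameters
#'
#' Scalar constants of the excitatory (pyramidal, Pyr) / inhibitory
#' (parvalbumin-positive, PV) conductance-based LIF network, plus the
#' quantities that are swept in the experiments: the PV-to-Pyr weight
#' \code{g_ie} (GABAergic maturation), the Pyr-to-PV weight \code{g_ei}
#' (glutamatergic drive onto PV cells), the EPSP truncation threshold
#' \code{theta_epsp}, and the input jump sizes \code{w_in_e}, \code{w_in_i}.
#'
#' Pyr-to-Pyr weights are drawn from a lognormal EPSP distribution with
#' parameters \code{sigma_lognormal} and \code{mu_lognormal}; the default
#' ties the two through \code{mu - sigma^2 = log(0.2)} so that the bulk of
#' EPSPs sits near 0.2 mV with a long tail. EPSP amplitudes at or above
#' \code{theta_epsp} mV are rejected and redrawn. An EPSP amplitude V (mV)
#' maps to a dimensionless conductance weight V/100, and its transmission
#' failure probability is \code{a_fail / (a_fail + V)}.
#'
#' @param n_e,n_i number of excitatory / inhibitory neurons.
#' @param v_l,v_thr,v_r leak reversal, spike threshold, reset potential (mV).
#' @param v_e,v_i excitatory / inhibitory synaptic reversal potentials (mV).
#' @param tau_m_e,tau_m_i membrane time constants (ms) for Pyr / PV neurons.
#' @param tau_s_ampa,tau_s_gaba synaptic conductance decay constants (ms).
#' @param tau_s_indexing how the two decay constants attach to synapses:
#'   \code{"presynaptic"} (the default) reads them as transmitter classes --
#'   AMPA conductances (Pyr spikes) decay with \code{tau_s_ampa}, GABA
#'   conductances (PV spikes) with \code{tau_s_gaba} on every target;
#'   \code{"postsynaptic"} attaches them to the receiving cell -- all
#'   conductances on Pyr neurons decay with \code{tau_s_ampa}, all on PV
#'   neurons with \code{tau_s_gaba}.
#' @param g_ei,g_ie,g_ii scalar conductance weights for Pyr-to-PV, PV-to-Pyr
#'   and PV-to-PV synapses (dimensionless).
#' @param sigma_lognormal,mu_lognormal lognormal parameters of the EPSP
#'   amplitude distribution (log-mV scale).
#' @param theta_epsp EPSP truncation threshold (mV).
#' @param a_fail transmission-failure constant (mV).
#' @param p_conn_ee,p_conn_ei,p_conn_ie,p_conn_ii connection probabilities
#'   per ordered pre/post pair for the four synapse classes.
#' @param delay_range_ee,delay_range_other synaptic delay ranges (ms),
#'   \code{c(lower, upper)}; delays are drawn uniformly.
#' @param w_in_e,w_in_i input-spike voltage jumps (mV) onto Pyr / PV neurons.
#'
#' @return An object of class \code{network_params} (a validated named list).
#' @examples
#' p <- network_params(n_e = 100, n_i = 20)
#' p$g_ie
#' @export
network_params <- function(n_e = 10000L, n_i = 2000L,
                           v_l = -70, v_thr = -50, v_r = -60,
                           v_e = 0, v_i = -80,
                           tau_m_e = 10.5, tau_m_i = 3.1,
                           tau_s_ampa = 2, tau_s_gaba = 4,
                           g_ei = 0.018, g_ie = 0.0027, g_ii = 0.0025,
                           sigma_lognormal = 1.0,
                           mu_lognormal = log(0.2) + sigma_lognormal^2,
                           theta_epsp = 5,
                           a_fail = 0.1,
                           p_conn_ee = 0.1, p_conn_ei = 0.1,
                           p_conn_ie = 0.5, p_conn_ii = 0.5,
                           delay_range_ee = c(1, 3),
                           delay_range_other = c(0, 2),
                           w_in_e = 0.5, w_in_i = 0.5,
                           tau_s_indexing = c("presynaptic", "postsynaptic")) {
  tau_s_indexing <- match.arg(tau_s_indexing)
  p <- list(n_e = as.integer(n_e), n_i = as.integer(n_i),
            v_l = v_l, v_thr = v_thr, v_r = v_r, v_e = v_e, v_i = v_i,
            tau_m_e = tau_m_e, tau_m_i = tau_m_i,
            tau_s_ampa = tau_s_ampa, tau_s_gaba = tau_s_gaba,
            g_ei = g_ei, g_ie = g_ie, g_ii = g_ii,
            sigma_lognormal = sigma_lognormal, mu_lognormal = mu_lognormal,
            theta_epsp = theta_epsp, a_fail = a_fail,
            p_conn_ee = p_conn_ee, p_conn_ei = p_conn_ei,
            p_conn_ie = p_conn_ie, p_conn_ii = p_conn_ii,
            delay_range_ee = delay_range_ee,
            delay_range_other = delay_range_other,
            w_in_e = w_in_e, w_in_i = w_in_i,
            tau_s_indexing = tau_s_indexing)
  validate_network_params(p)
  class(p) <- "network_params"
  p
}

validate_network_params <- function(p) {
  stopifnot(p$n_e >= 1, p$n_i >= 0)
  taus <- c(p$tau_m_e, p$tau_m_i, p$tau_s_ampa, p$tau_s_gaba)
  if (any(taus <= 0)) stop("all time constants must be positive")
  if (!(p$v_i < p$v_r && p$v_r < p$v_thr && p$v_thr < p$v_e))
    stop("potentials must be ordered v_i < v_r < v_thr < v_e")
  pr <- c(p$p_conn_ee, p$p_conn_ei, p$p_conn_ie, p$p_conn_ii)
  if (any(pr < 0 | pr > 1)) stop("connection probabilities must be in [0,1]")
  for (d in list(p$delay_range_ee, p$delay_range_other)) {
    if (length(d) != 2 || any(d < 0) || d[1] > d[2])
      stop("delay ranges must be c(lower, upper) with 0 <= lower <= upper")
  }
  if (p$theta_epsp <= 0) stop("theta_epsp must be positive")
  if (p$a_fail <= 0) stop("a_fail must be positive")
  if (p$sigma_lognormal <= 0) stop("sigma_lognormal must be positive")
  invisible(p)
}

#' @export
print.network_params <- function(x, ...) {
  cat("<network_params>\n")
  cat(sprintf("  N_E = %d, N_I = %d\n", x$n_e, x$n_i))
  cat(sprintf("  g_ie = %g, g_ei = %g, g_ii = %g, theta_epsp = %g mV\n",
              x$g_ie, x$g_ei, x$g_ii, x$theta_epsp))
  cat(sprintf("  w_in_e = %g mV, w_in_i = %g mV\n", x$w_in_e, x$w_in_i))
  invisible(x)
}

#' Read network parameters from a flat key/value config file
#'
#' Accepts a YAML file with flat keys matching the arguments of
#' \code{\link{network_params}} (e.g. \code{g_ie: 0.0027}); unknown keys are
#' an error. Delay ranges may be given as two-element sequences.
#'
#' @param path path to a YAML config file.
#' @return A \code{network_params} object.
#' @export
read_network_params <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read config files")
  vals <- yaml::read_yaml(path)
  known <- names(formals(network_params))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(network_params, vals)
}

#' Stimulus configuration
#'
#' Defines the per-trial input: a deterministic periodic (gamma-band) spike
#' train shared by all neurons, delivered as voltage jumps \code{w_in_e} /
#' \code{w_in_i} taken from the network parameters, plus an independent
#' low-rate Poisson background train per neuron that maintains spontaneous
#' activity. The analysis window starts after a warmup period that is
#' discarded; trial-to-trial variability comes only from the background and
#' from stochastic transmission failures, never from the stimulus itself.
#'
#' @param f_s stimulus frequency (Hz), typically 40 or 80.
#' @param poisson_rate firing rate of each background fiber (Hz).
#' @param bg_fibers number of independent background fibers converging on
#'   each neuron. The aggregate background a neuron sees is a Poisson train
#'   of rate \code{poisson_rate * bg_fibers}; with the default 1000 fibers at
#'   2.5 Hz and 0.5 mV jumps the mean background depolarization is
#'   rate x jump x tau_m of order 10 mV, the fluctuation-driven regime that
#'   sustains spontaneous activity.
#' @param stim_fibers number of input fibers firing synchronously on each
#'   cycle of the periodic train, so the per-cycle voltage jump is
#'   \code{stim_fibers * w_in} of the receiving class. The default (8, i.e.
#'   a 4 mV volley onto Pyr cells at \code{w_in_e} = 0.5 mV) places the
#'   stimulus at roughly twice the standard deviation of the
#'   background-driven membrane-potential fluctuations: strong enough to
#'   entrain threshold crossings, weak enough not to saturate the response.
#' @param n_trials number of trials entering the ITPC estimate (>= 2).
#' @param warmup warmup duration (ms) discarded before analysis.
#' @param analysis_window analysis window length (ms); must hold an integer
#'   number of stimulus cycles when the periodic input is enabled.
#' @param onset_time onset of the periodic train (ms), common to all trials.
#' @param periodic_input logical; \code{FALSE} gives spontaneous activity
#'   (background only).
#' @param fan_out fraction of neurons receiving the periodic train (1 = all).
#' @return An object of class \code{stimulus_config}.
#' @examples
#' stimulus_config(f_s = 80, n_trials = 20)
#' @export
stimulus_config <- function(f_s = 80, poisson_rate = 2.5, bg_fibers = 1000,
                            stim_fibers = 8,
                            n_trials = 100L,
                            warmup = 500, analysis_window = 1000,
                            onset_time = 0, periodic_input = TRUE,
                            fan_out = 1) {
  stopifnot(f_s > 0, poisson_rate >= 0, bg_fibers >= 0, stim_fibers >= 0,
            n_trials >= 2,
            warmup >= 0, analysis_window > 0, onset_time >= 0,
            fan_out >= 0, fan_out <= 1)
  if (periodic_input) {
    n_cycles <- analysis_window * f_s / 1000
    if (abs(n_cycles - round(n_cycles)) > 1e-9)
      stop("analysis_window must contain an integer number of stimulus cycles")
  }
  structure(list(f_s = f_s, poisson_rate = poisson_rate,
                 bg_fibers = bg_fibers, stim_fibers = stim_fibers,
                 n_trials = as.integer(n_trials), warmup = warmup,
                 analysis_window = analysis_window, onset_time = onset_time,
                 periodic_input = periodic_input, fan_out = fan_out),
            class = "stimulus_config")
}

#' @export
print.stimulus_config <- function(x, ...) {
  cat("<stimulus_config>\n")
  cat(sprintf("  f_s = %g Hz (%s), background %g fibers x %g Hz\n", x$f_s,
              if (x$periodic_input) "on" else "off",
              x$bg_fibers, x$poisson_rate))
  cat(sprintf("  %d trials, warmup %g ms, window %g ms\n",
              x$n_trials, x$warmup, x$analysis_window))
  invisible(x)
}

#' Derive independent sub-seeds from a master seed
#'
#' One master seed is split into named integer sub-seeds for the independent
#' random stages of a run (connectivity, weights, delays, input spikes,
#' transmission failures and initial conditions), so that each stage can be
#' re-run in isolation.
#'
#' @param seed master seed (integer).
#' @param n number of sub-seeds.
#' @return Integer vector of length \code{n}.
#' @export
derive_seeds <- function(seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

# Run fn under a temporary seed (NULL = use ambient RNG stream).
with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  fn()
}
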