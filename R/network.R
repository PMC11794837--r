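#' Sample EPSP amplitudes from the truncated lognormal distribution
#'
#' Draws excitatory postsynaptic potential (EPSP) amplitudes from a lognormal
#' distribution with log-scale parameters \code{mu_lognormal} and
#' \code{sigma_lognormal}, rejecting and redrawing any value at or above the
#' truncation threshold \code{theta_epsp}. The result is therefore distributed
#' as the lognormal conditioned on being below the threshold (true rejection
#' sampling, not clipping), preserving the long-tailed shape below the cut.
#'
#' @param n number of amplitudes to draw.
#' @param params a \code{\link{network_params}} object.
#' @param seed optional integer seed; \code{NULL} uses the ambient RNG stream.
#' @return Numeric vector of \code{n} positive amplitudes (mV), all strictly
#'   below \code{params$theta_epsp}.
#' @examples
#' v <- sample_epsp_amplitudes(1000, network_params(), seed = 1)
#' max(v) < 5
#' @export
sample_epsp_amplitudes <- function(n, params, seed = NULL) {
  if (length(n) != 1 || n < 1) stop("n must be a positive count")
  n <- as.integer(n)
  mu <- params$mu_lognormal
  sigma <- params$sigma_lognormal
  theta <- params$theta_epsp
  if (theta <= 0) stop("theta_epsp must be positive")
  with_seed(seed, function() {
    x <- exp(rnorm(n, mu, sigma))
    bad <- which(x >= theta)
    guard <- 0L
    while (length(bad) > 0L) {
      x[bad] <- exp(rnorm(length(bad), mu, sigma))
      bad <- bad[x[bad] >= theta]
      guard <- guard + 1L
      if (guard > 10000L) stop("rejection sampling failed to terminate")
    }
    x
  })
}

#' Convert an EPSP amplitude to a synaptic conductance weight
#'
#' An observable EPSP amplitude V (mV) corresponds to the dimensionless
#' Pyr-to-Pyr conductance weight V/100.
#'
#' @param v_epsp EPSP amplitude(s), mV; must be positive.
#' @return Conductance weight(s), \code{v_epsp / 100}.
#' @examples
#' epsp_to_weight(0.2)  # 0.002
#' @export
epsp_to_weight <- function(v_epsp) {
  if (any(v_epsp <= 0)) stop("EPSP amplitudes must be positive")
  v_epsp / 100
}

#' Transmission failure probability of a Pyr-to-Pyr synapse
#'
#' Small EPSPs fail to transmit often, large ones rarely:
#' \code{p = a_fail / (a_fail + v_epsp)}, strictly within (0, 1) and
#' monotonically decreasing in the EPSP amplitude.
#'
#' @param v_epsp EPSP amplitude(s), mV; positive.
#' @param a_fail failure constant (mV), default 0.1.
#' @return Failure probability in (0, 1), applied as an independent Bernoulli
#'   drop per transmitted spike.
#' @examples
#' failure_probability(0.1)  # 0.5
#' failure_probability(0.9)  # 0.1
#' @export
failure_probability <- function(v_epsp, a_fail = 0.1) {
  if (any(v_epsp <= 0)) stop("EPSP amplitudes must be positive")
  if (any(a_fail <= 0)) stop("a_fail must be positive")
  a_fail / (a_fail + v_epsp)
}

#' Sample the network connectivity, weights, delays and failure probabilities
#'
#' Each ordered (pre, post) pair of a synapse class is connected independently
#' with the class connection probability (self-connections excluded).
#' Pyr-to-Pyr (EE) weights come from the truncated lognormal EPSP distribution
#' via \code{\link{epsp_to_weight}}; EI, IE and II weights are the scalar class
#' constants. Delays are uniform within the class range (1-3 ms for EE,
#' 0-2 ms otherwise); transmission-failure probabilities are populated for EE
#' synapses only.
#'
#' The master seed is split into independent sub-streams for connectivity,
#' weights and delays, so e.g. the same adjacency can be re-realized with
#' fresh weights.
#'
#' @param params a \code{\link{network_params}} object.
#' @param seed optional master seed for the sampling.
#' @return An object of class \code{synapse_table}: a list with vectors
#'   \code{pre}, \code{post} (1-based global neuron ids; excitatory neurons
#'   are 1..N_E, inhibitory N_E+1..N_E+N_I), \code{kind} (factor EE/EI/IE/II),
#'   \code{weight}, \code{delay} (ms) and \code{p_fail}, plus \code{n_e},
#'   \code{n_i} and the generating parameters.
#' @examples
#' net <- build_network(network_params(n_e = 50, n_i = 10), seed = 1)
#' head(as.data.frame(net))
#' @export
build_network <- function(params, seed = NULL) {
  validate_network_params(unclass(params))
  seeds <- if (is.null(seed)) {
    # still split streams, from an ambient draw
    derive_seeds(sample.int(.Machine$integer.max - 1L, 1), 3)
  } else derive_seeds(seed, 3)

  n_e <- params$n_e
  n_i <- params$n_i

  adj <- with_seed(seeds[1], function() {
    ee <- cpp_sample_adjacency(n_e, n_e, params$p_conn_ee, 1L, 1L, TRUE)
    ei <- cpp_sample_adjacency(n_e, n_i, params$p_conn_ei, 1L, n_e + 1L, FALSE)
    ie <- cpp_sample_adjacency(n_i, n_e, params$p_conn_ie, n_e + 1L, 1L, FALSE)
    ii <- cpp_sample_adjacency(n_i, n_i, params$p_conn_ii, n_e + 1L, n_e + 1L, TRUE)
    list(ee = ee, ei = ei, ie = ie, ii = ii)
  })

  counts <- vapply(adj, function(a) length(a$pre), integer(1))
  kind <- factor(rep(c("EE", "EI", "IE", "II"), counts),
                 levels = c("EE", "EI", "IE", "II"))

  weight <- with_seed(seeds[2], function() {
    w_ee <- if (counts[["ee"]] > 0)
      epsp_to_weight(sample_epsp_amplitudes(counts[["ee"]], params))
    else numeric(0)
    c(w_ee,
      rep(params$g_ei, counts[["ei"]]),
      rep(params$g_ie, counts[["ie"]]),
      rep(params$g_ii, counts[["ii"]]))
  })

  delay <- with_seed(seeds[3], function() {
    dr_ee <- params$delay_range_ee
    dr_o <- params$delay_range_other
    c(runif(counts[["ee"]], dr_ee[1], dr_ee[2]),
      runif(sum(counts[c("ei", "ie", "ii")]), dr_o[1], dr_o[2]))
  })

  p_fail <- numeric(length(kind))
  if (counts[["ee"]] > 0) {
    idx <- seq_len(counts[["ee"]])
    p_fail[idx] <- failure_probability(100 * weight[idx], params$a_fail)
  }

  structure(list(pre = c(adj$ee$pre, adj$ei$pre, adj$ie$pre, adj$ii$pre),
                 post = c(adj$ee$post, adj$ei$post, adj$ie$post, adj$ii$post),
                 kind = kind, weight = weight, delay = delay, p_fail = p_fail,
                 n_e = n_e, n_i = n_i, params = params, seed = seed),
            class = "synapse_table")
}

#' @export
print.synapse_table <- function(x, ...) {
  cat("<synapse_table>\n")
  cat(sprintf("  %d neurons (%d E + %d I), %d synapses\n",
              x$n_e + x$n_i, x$n_e, x$n_i, length(x$pre)))
  print(table(x$kind))
  invisible(x)
}

#' @export
as.data.frame.synapse_table <- function(x, ...) {
  data.frame(pre = x$pre, post = x$post, kind = x$kind,
             weight = x$weight, delay_ms = x$delay, p_fail = x$p_fail)
}

#' Write a synapse table to CSV
#'
#' Columns: pre, post, kind, weight, delay_ms, p_fail.
#'
#' @param synapses a \code{synapse_table}.
#' @param path output file path.
#' @export
write_synapse_table <- function(synapses, path) {
  write.csv(as.data.frame(synapses), path, row.names = FALSE)
  invisible(path)
}

# Compile a synapse table into the CSR (grouped-by-presynaptic) arrays the
# C++ integrator consumes, with delays rounded to the dt grid (minimum one
# step so delivery is always causal). Within each presynaptic neuron the
# synapses are sorted by (delay step, target) so event delivery writes each
# ring-buffer slot region sequentially (cache locality).
as_csr <- function(synapses, dt) {
  n <- synapses$n_e + synapses$n_i
  if (any(synapses$p_fail[synapses$pre > synapses$n_e] > 0))
    stop("transmission failure is defined for Pyr-to-Pyr synapses only")
  dsteps <- pmax(1L, as.integer(round(synapses$delay / dt)))
  ord <- order(synapses$pre, dsteps, synapses$post)
  ptr <- c(0L, cumsum(tabulate(synapses$pre, nbins = n)))
  list(ptr = as.integer(ptr),
       post = as.integer(synapses$post[ord] - 1L),
       w = synapses$weight[ord],
       dsteps = dsteps[ord],
       pfail = synapses$p_fail[ord])
}
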