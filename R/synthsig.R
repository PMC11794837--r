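#' Specification of a synthetic rate-trace ensemble
#'
#' Describes an ensemble of sinusoidal rate-like traces with a known
#' ground-truth phase-coherence structure, used to validate the ITPC stage
#' independently of the network simulator. Trial j is
#' \code{baseline + amplitude * sin(2 pi f0 t + phi_j) + noise}, with the
#' per-trial phase phi_j either locked (identical), uniform on [0, 2 pi), or
#' von Mises with concentration kappa.
#'
#' @param n_trials number of trials.
#' @param window trace length (ms).
#' @param f0 oscillation frequency (Hz); should sit on the FFT grid
#'   (an integer number of cycles per window) for exact ground truth.
#' @param amplitude,baseline sinusoid amplitude and DC offset (rate units);
#'   \code{baseline >= amplitude} keeps the noiseless rate non-negative.
#' @param phase_dist one of \code{"locked"}, \code{"uniform"},
#'   \code{"vonmises"}.
#' @param kappa von Mises concentration (>= 0), used for
#'   \code{phase_dist = "vonmises"}.
#' @param noise_sd additive white Gaussian noise sd (clipped at zero rate).
#' @param dt time step (ms), default 0.1 to match simulator rate series.
#' @return A \code{synthetic_ensemble_spec}.
#' @export
synthetic_ensemble_spec <- function(n_trials = 100L, window = 1000, f0 = 80,
                                    amplitude = 1, baseline = 2,
                                    phase_dist = c("locked", "uniform", "vonmises"),
                                    kappa = 0, noise_sd = 0, dt = 0.1) {
  phase_dist <- match.arg(phase_dist)
  stopifnot(n_trials >= 2, window > 0, f0 > 0, amplitude >= 0,
            kappa >= 0, noise_sd >= 0, dt > 0)
  if (baseline < amplitude)
    stop("baseline must be >= amplitude to keep rates non-negative")
  structure(list(n_trials = as.integer(n_trials), window = window, f0 = f0,
                 amplitude = amplitude, baseline = baseline,
                 phase_dist = phase_dist, kappa = kappa,
                 noise_sd = noise_sd, dt = dt),
            class = "synthetic_ensemble_spec")
}

#' Generate a synthetic rate ensemble with known coherence
#'
#' @param spec a \code{\link{synthetic_ensemble_spec}}.
#' @param seed optional seed.
#' @return A list of \code{rate_series} trials, consumable by
#'   \code{\link{itpc_spectrum}} and \code{\link{power_spectrum}}.
#' @examples
#' sp <- synthetic_ensemble_spec(n_trials = 10, window = 500, f0 = 40,
#'                               phase_dist = "locked")
#' tr <- generate_ensemble(sp, seed = 1)
#' mean_itpc(itpc_spectrum(tr), 40, halfwidth = 0)  # 1
#' @export
generate_ensemble <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_ensemble_spec"))
  with_seed(seed, function() {
    n <- round(spec$window / spec$dt)
    t_ms <- (seq_len(n) - 0.5) * spec$dt
    phi <- switch(spec$phase_dist,
                  locked = rep(0, spec$n_trials),
                  uniform = runif(spec$n_trials, 0, 2 * pi),
                  vonmises = rvonmises(spec$n_trials, spec$kappa))
    lapply(seq_len(spec$n_trials), function(j) {
      r <- spec$baseline +
        spec$amplitude * sin(2 * pi * spec$f0 * t_ms / 1000 + phi[j])
      if (spec$noise_sd > 0) r <- pmax(0, r + rnorm(n, 0, spec$noise_sd))
      structure(list(t = t_ms, r = r, dt = spec$dt,
                     population = "synthetic", smoothed = TRUE),
                class = "rate_series")
    })
  })
}

#' Expected ITPC of a synthetic ensemble
#'
#' Closed-form (large-T) ground truth: 1 for locked phases,
#' \code{sqrt(pi)/(2 sqrt(T))} for uniform phases (expectation of the
#' normalized Rayleigh resultant), and the Bessel ratio
#' \code{I1(kappa)/I0(kappa)} for von Mises phases.
#'
#' @param phase_dist \code{"locked"}, \code{"uniform"} or \code{"vonmises"}.
#' @param T number of trials.
#' @param kappa von Mises concentration.
#' @return Expected ITPC at the ensemble frequency.
#' @export
expected_itpc <- function(phase_dist, T, kappa = 0) {
  switch(phase_dist,
         locked = 1,
         uniform = sqrt(pi) / (2 * sqrt(T)),
         vonmises = besselI(kappa, 1) / besselI(kappa, 0),
         stop("unknown phase distribution"))
}

# von Mises sampler (Best & Fisher 1979 rejection scheme); kappa ~ 0 falls
# back to uniform.
rvonmises <- function(n, kappa) {
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(pmin(1, pmax(-1, f)))
      i <- i + 1L
    }
  }
  out
}
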