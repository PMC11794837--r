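#' Population firing rate from a spike raster
#'
#' Bins the spikes of one population into time bins of \code{dt_bin} ms and
#' converts counts to an instantaneous population rate
#' \code{r(t) = 1e3 * S(t) / dt_bin} (Hz), where S(t) is the spike count of
#' the whole population in the bin. Before smoothing, the rate conserves the
#' spike count: \code{sum(r) * dt_bin / 1e3} equals the number of in-window
#' spikes.
#'
#' @param raster a \code{spike_raster}.
#' @param population \code{"E"} or \code{"I"}.
#' @param window \code{c(t0, t1)} ms; spikes with t0 <= t < t1 are counted.
#'   Defaults to the full simulated duration.
#' @param dt_bin bin width (ms), default 0.1.
#' @return A \code{rate_series}: list with \code{t} (bin centers, ms),
#'   \code{r} (Hz), \code{dt}, \code{population}, \code{smoothed = FALSE}.
#' @examples
#' # three spikes in one 0.1 ms bin -> 30000 Hz in that bin
#' @export
population_rate <- function(raster, population = c("E", "I"),
                            window = NULL, dt_bin = 0.1) {
  population <- match.arg(population)
  n_e <- attr(raster, "n_e")
  if (is.null(window)) window <- c(0, attr(raster, "duration_simulated"))
  span <- window[2] - window[1]
  if (span <= 0) stop("empty analysis window")
  nbins <- round(span / dt_bin)
  if (abs(nbins * dt_bin - span) > 1e-6)
    stop("window length must be a multiple of dt_bin")

  sel <- if (population == "E") raster$neuron <= n_e else raster$neuron > n_e
  tt <- raster$time[sel]
  tt <- tt[tt >= window[1] & tt < window[2]]
  idx <- floor((tt - window[1]) / dt_bin) + 1L
  idx[idx > nbins] <- nbins  # guard against edge rounding
  counts <- tabulate(idx, nbins = nbins)

  structure(list(t = window[1] + (seq_len(nbins) - 0.5) * dt_bin,
                 r = 1e3 * counts / dt_bin,
                 dt = dt_bin, population = population, smoothed = FALSE),
            class = "rate_series")
}

#' Gaussian smoothing of a rate series
#'
#' Convolves the rate with a unit-area Gaussian kernel (standard deviation
#' \code{kernel_width} ms, support +/- 4 sd) using reflective edge handling,
#' so the total integral is preserved.
#'
#' @param rate an unsmoothed \code{rate_series}.
#' @param kernel_width Gaussian sd (ms), default 1.
#' @return The smoothed \code{rate_series}.
#' @export
gaussian_smooth <- function(rate, kernel_width = 1) {
  stopifnot(inherits(rate, "rate_series"))
  half <- as.integer(ceiling(4 * kernel_width / rate$dt))
  n <- length(rate$r)
  if (2 * half + 1 > 2 * n) stop("kernel wider than the series")
  k <- dnorm((-half:half) * rate$dt, sd = kernel_width)
  k <- k / sum(k)
  # reflective padding
  x <- c(rate$r[half:1], rate$r, rate$r[n:(n - half + 1)])
  sm <- stats::filter(x, k, sides = 2)
  rate$r <- as.numeric(sm[(half + 1):(half + n)])
  rate$smoothed <- TRUE
  rate
}

#' Inter-trial phase coherence spectrum
#'
#' For each trial the de-meaned rate series is Fourier transformed
#' (rectangular taper, no zero padding; frequency resolution 1/window). Each
#' Fourier component is normalized to unit modulus, averaged across trials,
#' and the modulus of the average is the ITPC: 1 means the phase at that
#' frequency is identical in every trial, values near zero mean random
#' phases. Amplitudes do not enter, so per-trial rescaling leaves the
#' estimate unchanged.
#'
#' If a trial has an exactly zero Fourier component at some frequency it
#' contributes a zero vector there (with a warning); the trial count is not
#' reduced.
#'
#' @param trials list of \code{rate_series} on a common time grid.
#' @param T number of trials (defaults to \code{length(trials)}).
#' @return An \code{itpc_result}: list with \code{f} (Hz, up to Nyquist),
#'   \code{itpc} in [0,1], \code{T} and \code{population}.
#' @export
itpc_spectrum <- function(trials, T = length(trials)) {
  if (T < 2) stop("ITPC requires at least 2 trials")
  if (length(trials) != T) stop("T must equal the number of trials")
  len <- vapply(trials, function(x) length(x$r), integer(1))
  if (length(unique(len)) != 1) stop("all trials must share one time grid")
  n <- len[1]
  dt_s <- trials[[1]]$dt / 1000

  mat <- vapply(trials, function(x) x$r - mean(x$r), numeric(n))
  F <- mvfft(mat)
  mod <- Mod(F)
  zero <- mod == 0
  if (any(zero[-1, , drop = FALSE]))
    warning("zero Fourier component in some trial; it contributes a zero vector")
  mod[zero] <- 1  # unit-normalize; zero components stay zero vectors
  Fn <- F / mod
  Fn[zero] <- 0
  itpc <- Mod(rowSums(Fn)) / T

  nf <- floor(n / 2) + 1
  structure(list(f = (seq_len(nf) - 1) / (n * dt_s),
                 itpc = itpc[seq_len(nf)],
                 T = T,
                 population = trials[[1]]$population),
            class = "itpc_result")
}

#' Band-averaged ITPC around the stimulus frequency
#'
#' Arithmetic mean of the ITPC over grid frequencies within
#' \code{f_s +/- halfwidth} (inclusive endpoints); with \code{halfwidth = 0}
#' the value at the grid frequency nearest \code{f_s}.
#'
#' @param result an \code{itpc_result}.
#' @param f_s stimulus frequency (Hz).
#' @param halfwidth band half-width (Hz), default 2.
#' @return Scalar band-mean ITPC.
#' @export
mean_itpc <- function(result, f_s, halfwidth = 2) {
  f <- result$f
  if (halfwidth == 0) return(result$itpc[which.min(abs(f - f_s))])
  sel <- f >= f_s - halfwidth - 1e-9 & f <= f_s + halfwidth + 1e-9
  if (!any(sel)) stop("band outside the frequency grid")
  mean(result$itpc[sel])
}

#' Trial-averaged power spectrum of a rate series
#'
#' Per-trial periodogram of the de-meaned rate (rectangular taper, power
#' \code{|F|^2 / n}), averaged across trials with the per-frequency standard
#' deviation.
#'
#' @param trials list of \code{rate_series} on a common grid (>= 2).
#' @param f_max optional upper frequency cut (Hz) for the returned grid.
#' @return A \code{power_spectrum}: list with \code{f}, \code{power} (mean),
#'   \code{power_sd}, \code{n_trials}.
#' @export
power_spectrum <- function(trials, f_max = NULL) {
  if (length(trials) < 2) stop("power_spectrum requires at least 2 trials")
  len <- vapply(trials, function(x) length(x$r), integer(1))
  if (length(unique(len)) != 1) stop("all trials must share one time grid")
  n <- len[1]
  dt_s <- trials[[1]]$dt / 1000

  mat <- vapply(trials, function(x) x$r - mean(x$r), numeric(n))
  P <- Mod(mvfft(mat))^2 / n
  nf <- floor(n / 2) + 1
  f <- (seq_len(nf) - 1) / (n * dt_s)
  P <- P[seq_len(nf), , drop = FALSE]
  if (!is.null(f_max)) {
    keep <- f <= f_max
    f <- f[keep]
    P <- P[keep, , drop = FALSE]
  }
  structure(list(f = f,
                 power = rowMeans(P),
                 power_sd = apply(P, 1, sd),
                 n_trials = length(trials)),
            class = "power_spectrum")
}

#' Total power in a frequency band
#'
#' Sum of mean power over grid frequencies in [f_lo, f_hi] (inclusive); used
#' e.g. to summarize gamma-band (30-100 Hz) spontaneous power.
#'
#' @param spectrum a \code{power_spectrum}.
#' @param f_lo,f_hi band edges (Hz).
#' @return Scalar band power.
#' @export
band_power <- function(spectrum, f_lo = 30, f_hi = 100) {
  sel <- spectrum$f >= f_lo - 1e-9 & spectrum$f <= f_hi + 1e-9
  if (!any(sel)) stop("band outside the frequency grid")
  sum(spectrum$power[sel])
}

#' @export
print.itpc_result <- function(x, ...) {
  cat(sprintf("<itpc_result> %s population, T = %d, %d frequencies (%g-%g Hz)\n",
              x$population %||% "?", x$T, length(x$f), min(x$f), max(x$f)))
  invisible(x)
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d trials, %d frequencies (%g-%g Hz)\n",
              x$n_trials, length(x$f), min(x$f), max(x$f)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an ITPC or power spectrum result to CSV
#'
#' Columns \code{f, value} (ITPC) or \code{f, power, power_sd}.
#'
#' @param x an \code{itpc_result} or \code{power_spectrum}.
#' @param path output CSV path.
#' @export
write_spectrum <- function(x, path) {
  df <- if (inherits(x, "itpc_result")) {
    data.frame(f = x$f, value = x$itpc)
  } else {
    data.frame(f = x$f, power = x$power, power_sd = x$power_sd)
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
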