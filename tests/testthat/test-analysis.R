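test_that("population rate implements r = 1e3 S / dt and conserves counts", {
  # three spikes in one 0.1 ms bin -> 30000 Hz there
  r <- manual_raster(time = c(0.32, 0.33, 0.38), neuron = c(1, 2, 3),
                     n_e = 5, n_i = 0, duration = 1)
  rs <- population_rate(r, "E", window = c(0, 1))
  expect_identical(length(rs$r), 10L)
  expect_identical(rs$r[4], 30000)
  expect_identical(sum(rs$r), 30000)

  # empty raster -> all-zero series
  r0 <- manual_raster(numeric(0), integer(0), 5, 0, 1)
  expect_true(all(population_rate(r0, "E", c(0, 1))$r == 0))

  # count conservation: sum(r) * dt / 1e3 equals in-window spike count
  set.seed(1)
  tt <- runif(500, 0, 50)
  nn <- sample(1:20, 500, TRUE)
  n_in <- sum(tt >= 10 & tt < 40 & nn <= 15)
  r2 <- manual_raster(tt, nn, 15, 5, 50)
  rsE <- population_rate(r2, "E", c(10, 40))
  expect_equal(sum(rsE$r) * 0.1 / 1e3, n_in)

  # population split: I spikes only counted for I
  rsI <- population_rate(r2, "I", c(10, 40))
  expect_equal(sum(rsI$r) * 0.1 / 1e3, sum(tt >= 10 & tt < 40 & nn > 15))

  expect_error(population_rate(r2, "E", c(10, 10)), "empty")
})

test_that("Gaussian smoothing preserves mass, DC level and matches direct convolution", {
  # impulse response: one spike's mass is preserved and spread as a Gaussian
  r <- manual_raster(10.02, 1L, 1, 0, 20)
  rs <- population_rate(r, "E", c(0, 20))
  sm <- gaussian_smooth(rs, kernel_width = 1)
  expect_equal(sum(sm$r) * 0.1 / 1e3, 1, tolerance = 1e-3)
  expect_equal(sm$t[which.max(sm$r)], rs$t[which.max(rs$r)])
  expect_true(sm$smoothed)

  # DC invariance: constant series unchanged
  const <- manual_rates(rep(7, 2000), smoothed = FALSE)
  smc <- gaussian_smooth(const)
  expect_equal(smc$r, rep(7, 2000), tolerance = 1e-10)

  # two deltas 0.2 ms apart vs brute-force discrete convolution
  x <- numeric(400)
  x[200] <- 1e4
  x[202] <- 1e4
  rsx <- manual_rates(x, smoothed = FALSE)
  smx <- gaussian_smooth(rsx, kernel_width = 1)
  half <- ceiling(4 * 1 / 0.1)
  k <- dnorm((-half:half) * 0.1, sd = 1)
  k <- k / sum(k)
  brute <- numeric(400)
  for (i in seq_len(400)) {
    for (j in -half:half) {
      src <- i - j
      if (src < 1) src <- 1 - src            # reflective
      if (src > 400) src <- 2 * 400 + 1 - src
      brute[i] <- brute[i] + k[j + half + 1] * x[src]
    }
  }
  expect_equal(smx$r, brute, tolerance = 1e-10)

  expect_error(gaussian_smooth(manual_rates(rep(1, 5), smoothed = FALSE),
                               kernel_width = 10), "wider")
})

test_that("ITPC is 1 for phase-locked trials and respects its bounds", {
  sp <- synthetic_ensemble_spec(n_trials = 12, window = 500, f0 = 40,
                                phase_dist = "locked")
  trials <- generate_ensemble(sp, seed = 1)
  it <- itpc_quiet(trials)
  expect_equal(mean_itpc(it, 40, halfwidth = 0), 1, tolerance = 1e-9)
  expect_true(all(it$itpc >= 0 & it$itpc <= 1 + 1e-12))

  # bounds hold on arbitrary random data too
  set.seed(33)
  rnd <- lapply(1:8, function(i) manual_rates(runif(256)))
  itr <- itpc_spectrum(rnd)
  expect_true(all(itr$itpc >= 0 & itr$itpc <= 1 + 1e-12))

  expect_error(itpc_spectrum(rnd[1]), "at least 2")
  expect_error(itpc_spectrum(list(manual_rates(1:10), manual_rates(1:20))),
               "time grid")
})

test_that("uniform-phase ITPC matches the Rayleigh-resultant expectation", {
  T <- 100
  # independent oracle: Monte-Carlo of |mean of T unit phasors| directly
  set.seed(5)
  nrep <- 2e4
  phases <- matrix(runif(nrep * T, 0, 2 * pi), nrep, T)
  oracle <- mean(Mod(rowMeans(exp(1i * phases))))
  expect_equal(oracle, sqrt(pi) / (2 * sqrt(T)), tolerance = 3e-3)

  # the estimator on synthetic ensembles reproduces the oracle
  est <- vapply(1:60, function(k) {
    sp <- synthetic_ensemble_spec(n_trials = T, window = 250, f0 = 40,
                                  phase_dist = "uniform", dt = 0.5)
    mean_itpc(itpc_quiet(generate_ensemble(sp, seed = 400 + k)),
              40, halfwidth = 0)
  }, numeric(1))
  # sd of a single uniform-phase ITPC is ~sqrt((4-pi)/(4T)); 60 replicates
  se <- sqrt((4 - pi) / (4 * T)) / sqrt(60)
  expect_lt(abs(mean(est) - oracle), 4 * se)
})

test_that("ITPC is amplitude-invariant and shift-covariant", {
  sp <- synthetic_ensemble_spec(n_trials = 10, window = 500, f0 = 40,
                                phase_dist = "vonmises", kappa = 1,
                                noise_sd = 0.2)
  trials <- generate_ensemble(sp, seed = 2)
  base <- itpc_quiet(trials)$itpc

  # per-trial positive rescaling leaves ITPC unchanged
  set.seed(6)
  scaled <- lapply(trials, function(x) { x$r <- x$r * runif(1, 0.1, 10); x })
  expect_equal(itpc_spectrum(scaled)$itpc, base, tolerance = 1e-12)

  # a common circular time shift applied to ALL trials leaves ITPC unchanged
  shift <- 250  # bins
  shifted <- lapply(trials, function(x) {
    x$r <- c(x$r[-seq_len(shift)], x$r[seq_len(shift)]); x
  })
  expect_equal(itpc_spectrum(shifted)$itpc, base, tolerance = 1e-9)

  # independent per-trial phase jitter lowers coherence at f0
  spj <- synthetic_ensemble_spec(n_trials = 50, window = 500, f0 = 40,
                                 phase_dist = "vonmises", kappa = 1)
  splk <- synthetic_ensemble_spec(n_trials = 50, window = 500, f0 = 40,
                                  phase_dist = "locked")
  itj <- mean_itpc(itpc_quiet(generate_ensemble(spj, seed = 3)), 40, 0)
  itl <- mean_itpc(itpc_quiet(generate_ensemble(splk, seed = 3)), 40, 0)
  expect_lt(itj, itl - 0.2)
})

test_that("band averaging uses inclusive endpoints on the grid", {
  fake <- structure(list(f = 0:100, itpc = rep(0.7, 101), T = 10,
                         population = "E"), class = "itpc_result")
  expect_identical(mean_itpc(fake, 80), 0.7)

  fake$itpc[79:83] <- c(0.6, 0.8, 1.0, 0.8, 0.6)
  expect_identical(mean_itpc(fake, 80), 0.76)
  expect_identical(mean_itpc(fake, 80, halfwidth = 0), 1.0)
  expect_error(mean_itpc(fake, 500), "outside")
})

test_that("power spectra locate tones and scale with amplitude squared", {
  t_ms <- (1:10000 - 0.5) * 0.1
  tone <- function(f, a) a * sin(2 * pi * f * t_ms / 1000)
  trials <- lapply(1:5, function(i) manual_rates(10 + tone(80, 2)))
  ps <- power_spectrum(trials)
  expect_identical(ps$f[which.max(ps$power)], 80)

  # 40 Hz amplitude 2 + 80 Hz amplitude 1 -> power ratio 4
  tr2 <- lapply(1:5, function(i) manual_rates(10 + tone(40, 2) + tone(80, 1)))
  ps2 <- power_spectrum(tr2)
  p40 <- ps2$power[ps2$f == 40]
  p80 <- ps2$power[ps2$f == 80]
  expect_equal(p40 / p80, 4, tolerance = 1e-6)

  # white noise: flat expected spectrum (log-log slope ~ 0)
  set.seed(12)
  trw <- lapply(1:20, function(i) manual_rates(rnorm(4096)))
  psw <- power_spectrum(trw)
  sel <- psw$f > 0
  fit <- lm(log(psw$power[sel]) ~ log(psw$f[sel]))
  expect_lt(abs(coef(fit)[2]), 0.05)

  expect_error(power_spectrum(trials[1]), "at least 2")

  # band power over the gamma range
  expect_gt(band_power(ps, 70, 90), 0.99 * sum(ps$power))
})
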