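test_that("EPSP-to-weight conversion and failure probability are exact", {
  expect_identical(epsp_to_weight(0.2), 0.002)
  expect_identical(epsp_to_weight(5.0), 0.05)
  expect_identical(epsp_to_weight(10.0), 0.1)
  expect_error(epsp_to_weight(0), "positive")
  expect_error(epsp_to_weight(-1), "positive")

  expect_identical(failure_probability(0.1, 0.1), 0.5)
  expect_identical(failure_probability(0.9, 0.1), 0.1)
  # monotone decreasing, vanishing for large EPSPs
  v <- c(0.01, 0.1, 1, 10, 1000)
  p <- failure_probability(v)
  expect_true(all(diff(p) < 0))
  expect_true(all(p > 0 & p < 1))
  expect_lt(failure_probability(1e9), 1e-9)
  expect_error(failure_probability(-1), "positive")
  expect_error(failure_probability(1, a_fail = 0), "positive")
})

test_that("EPSP sampler matches the lognormal's closed-form median", {
  # untruncated (theta effectively infinite): median of lognormal is exp(mu)
  p <- network_params(theta_epsp = Inf)
  x <- sample_epsp_amplitudes(1e6, p, seed = 11)
  m_true <- exp(p$mu_lognormal)        # 0.2 * e
  expect_equal(m_true, 0.2 * exp(1), tolerance = 1e-12)
  # se of the sample median: 1 / (2 f(m) sqrt(n))
  f_m <- dnorm(0) / m_true
  se <- 1 / (2 * f_m * sqrt(1e6))
  expect_lt(abs(median(x) - m_true), 3 * se)
})

test_that("rejection truncation matches the normal-CDF tail mass", {
  p5 <- network_params(theta_epsp = 5)
  x <- sample_epsp_amplitudes(1e5, p5, seed = 7)
  expect_true(all(x > 0))
  expect_lt(max(x), 5)

  # fraction of an untruncated reference sample above 5 mV matches
  # 1 - Phi((log 5 - mu)/sigma)
  pinf <- network_params(theta_epsp = Inf)
  y <- sample_epsp_amplitudes(2e5, pinf, seed = 8)
  tail_true <- 1 - pnorm((log(5) - pinf$mu_lognormal) / pinf$sigma_lognormal)
  expect_equal(tail_true, 0.01326, tolerance = 1e-3)
  se <- sqrt(tail_true * (1 - tail_true) / 2e5)
  expect_lt(abs(mean(y >= 5) - tail_true), 4 * se)
})

test_that("samples agree with the truncated-lognormal CDF (KS, n = 1e5)", {
  p <- network_params(theta_epsp = 5)
  mu <- p$mu_lognormal
  sigma <- p$sigma_lognormal

  # independent oracle: numeric integration of the density, cross-checking
  # the closed-form CDF used in the KS test at several quantiles
  dens <- function(x) exp(-(log(x) - mu)^2 / (2 * sigma^2)) /
    (sqrt(2 * pi) * sigma * x)
  for (q in c(0.1, 0.5, 1, 2, 4.5)) {
    num <- integrate(dens, 0, q, rel.tol = 1e-10)$value
    expect_equal(num, plnorm(q, mu, sigma), tolerance = 1e-7)
  }

  cdf_trunc <- function(q) plnorm(q, mu, sigma) / plnorm(5, mu, sigma)
  x <- sample_epsp_amplitudes(1e5, p, seed = 13)
  ks <- suppressWarnings(ks.test(x, cdf_trunc))
  expect_gt(ks$p.value, 0.01)
})

test_that("sampler is deterministic under a fixed seed", {
  p <- network_params()
  expect_identical(sample_epsp_amplitudes(1, p, seed = 5),
                   sample_epsp_amplitudes(1, p, seed = 5))
  expect_identical(sample_epsp_amplitudes(1000, p, seed = 5),
                   sample_epsp_amplitudes(1000, p, seed = 5))
})

test_that("connectivity counts follow the class Bernoulli model", {
  p <- network_params(n_e = 100, n_i = 20)
  net <- build_network(p, seed = 21)
  counts <- table(net$kind)

  binom_ok <- function(k, npairs, prob) {
    abs(k - npairs * prob) < 4 * sqrt(npairs * prob * (1 - prob)) + 1
  }
  expect_true(binom_ok(counts[["EE"]], 100 * 99, 0.1))
  expect_true(binom_ok(counts[["EI"]], 100 * 20, 0.1))
  expect_true(binom_ok(counts[["IE"]], 20 * 100, 0.5))
  expect_true(binom_ok(counts[["II"]], 20 * 19, 0.5))

  # no self-connections anywhere
  expect_false(any(net$pre == net$post))
})

test_that("degenerate connection probabilities give empty/complete graphs", {
  p0 <- network_params(n_e = 30, n_i = 10, p_conn_ee = 0, p_conn_ei = 0,
                       p_conn_ie = 0, p_conn_ii = 0)
  expect_identical(length(build_network(p0, seed = 1)$pre), 0L)

  p1 <- network_params(n_e = 30, n_i = 10, p_conn_ee = 1, p_conn_ei = 1,
                       p_conn_ie = 1, p_conn_ii = 1)
  net <- build_network(p1, seed = 1)
  counts <- table(net$kind)
  expect_identical(as.integer(counts[["EE"]]), 30L * 29L)
  expect_identical(as.integer(counts[["EI"]]), 30L * 10L)
  expect_identical(as.integer(counts[["IE"]]), 10L * 30L)
  expect_identical(as.integer(counts[["II"]]), 10L * 9L)
})

test_that("synapse table invariants hold", {
  p <- network_params(n_e = 200, n_i = 40, theta_epsp = 5)
  net <- build_network(p, seed = 31)
  ee <- net$kind == "EE"

  # truncation carried through the conversion
  expect_true(all(100 * net$weight[ee] < p$theta_epsp))
  # failure probability stored bit-exactly as a/(a + 100 w), EE only
  expect_identical(net$p_fail[ee], p$a_fail / (p$a_fail + 100 * net$weight[ee]))
  expect_true(all(net$p_fail[!ee] == 0))
  # class weights are the scalar constants
  expect_true(all(net$weight[net$kind == "EI"] == p$g_ei))
  expect_true(all(net$weight[net$kind == "IE"] == p$g_ie))
  expect_true(all(net$weight[net$kind == "II"] == p$g_ii))
  # delays lie in the configured class ranges
  expect_true(all(net$delay[ee] >= 1 & net$delay[ee] <= 3))
  expect_true(all(net$delay[!ee] >= 0 & net$delay[!ee] <= 2))
  # populations: E presynaptic for EE/EI, I for IE/II
  expect_true(all(net$pre[net$kind %in% c("EE", "EI")] <= p$n_e))
  expect_true(all(net$pre[net$kind %in% c("IE", "II")] > p$n_e))
})

test_that("identical seed reproduces the synapse table row for row", {
  p <- network_params(n_e = 80, n_i = 16)
  a <- build_network(p, seed = 99)
  b <- build_network(p, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- build_network(p, seed = 100)
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("parameter validation rejects inconsistent settings", {
  expect_error(network_params(tau_m_e = 0), "time constants")
  expect_error(network_params(v_r = -90), "ordered")
  expect_error(network_params(p_conn_ee = 1.5), "probabilities")
  expect_error(network_params(delay_range_ee = c(3, 1)), "delay ranges")
  expect_error(network_params(theta_epsp = -1), "theta_epsp")
  # default ties mu - sigma^2 = log(0.2) to machine precision
  p <- network_params()
  expect_equal(p$mu_lognormal - p$sigma_lognormal^2, log(0.2), tolerance = 1e-15)
})

test_that("synapse tables round-trip through CSV and config files read back", {
  p <- network_params(n_e = 20, n_i = 5)
  net <- build_network(p, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_synapse_table(net, path)
  df <- read.csv(path)
  expect_identical(names(df), c("pre", "post", "kind", "weight", "delay_ms", "p_fail"))
  expect_equal(df$weight, net$weight)

  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_e: 50", "n_i: 10", "g_ie: 0.004", "theta_epsp: 7"), cfg)
  q <- read_network_params(cfg)
  expect_identical(q$n_e, 50L)
  expect_identical(q$g_ie, 0.004)
  expect_equal(q$theta_epsp, 7)
  writeLines("not_a_param: 1", cfg)
  expect_error(read_network_params(cfg), "unknown config keys")
})
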