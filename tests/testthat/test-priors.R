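test_that("T2 prior calibration satisfies all printed constraints", {
  pr <- calibrate_t2_prior(shift = 5, mode = 50, q95 = 210)
  # closed-form solution of the quadratic in log_sd
  expect_equal(pr$log_sd, 0.6583613, tolerance = 1e-6)
  expect_equal(pr$log_mu, 4.240102, tolerance = 1e-6)
  # defining constraints hold to solver precision
  expect_equal(exp(pr$log_mu - pr$log_sd^2), 50 - 5, tolerance = 1e-10)
  expect_equal(pt2prior(210, pr), 0.95, tolerance = 1e-10)
  # implied tail probability and mode
  expect_equal(pt2prior(500, pr), 0.998, tolerance = 1e-3)
  mode_hat <- stats::optimize(function(x) dt2prior(x, pr),
                              c(5.001, 210), maximum = TRUE)$maximum
  expect_equal(mode_hat, 50, tolerance = 1e-3)
  expect_error(calibrate_t2_prior(50, 50, 210), class = "t2relax_calibration_error")
})

test_that("S0 prior calibration reproduces the stated mixture probabilities", {
  pr <- calibrate_s0_prior(cap = 500, q95 = 1700)
  expect_equal(pr$tail_scale, 1200 / log(10), tolerance = 1e-12)
  expect_equal(ps0prior(500, pr), 0.50, tolerance = 1e-12)
  expect_equal(ps0prior(1700, pr), 0.95, tolerance = 1e-12)
  expect_equal(ps0prior(2500, pr), 0.99, tolerance = 2e-3)
  expect_error(calibrate_s0_prior(500, 400), class = "t2relax_calibration_error")
})

test_that("prior samplers follow their calibrated distributions", {
  pr <- default_priors()
  t2 <- withr::with_seed(1, rt2prior(2e5, pr$t2))
  # median of the shifted log-normal is shift + exp(log_mu)
  expect_equal(median(t2), 5 + exp(pr$t2$log_mu), tolerance = 0.01)
  expect_true(all(t2 > 5))
  expect_equal(mean(t2 < 210), 0.95, tolerance = 0.01)
  s0 <- withr::with_seed(2, rs0prior(2e5, pr$s0))
  expect_true(all(s0 > 0))
  expect_equal(mean(s0 <= 500), 0.50, tolerance = 0.01)
  expect_equal(mean(s0 <= 1700), 0.95, tolerance = 0.01)
})

test_that("echo configurations respect acquisition priors", {
  cfg <- sample_echo_config(1e4, seed = 3)
  expect_true(all(cfg$te_start > 5 & cfg$te_start < 15))
  expect_true(all(cfg$te_step > 2 & cfg$te_step < 15))
  expect_setequal(unique(cfg$n_echoes), 5:15)
  # te_k = te_start + k * te_step, strictly increasing
  i <- which.max(cfg$n_echoes)
  expect_equal(cfg$te[[i]],
               cfg$te_start[i] + (0:(cfg$n_echoes[i] - 1)) * cfg$te_step[i])
  expect_true(all(vapply(cfg$te, function(v) all(diff(v) > 0), logical(1))))
  # replay under the same seed is identical
  expect_identical(cfg, sample_echo_config(1e4, seed = 3))
})

test_that("the standard 7-echo scheme is representable", {
  # TE = 10, 20, ..., 70 ms arises from te_start = 10, te_step = 10, n = 7
  te <- 10 + (0:6) * 10
  expect_equal(te, seq(10, 70, by = 10))
})

test_that("sample sets are pure functions of (counts, priors, seed)", {
  a <- simulate_decays(c(train = 100, val = 10, test = 10), seed = 7)
  b <- simulate_decays(c(train = 100, val = 10, test = 10), seed = 7)
  expect_identical(a, b)
  expect_equal(table(a$split)[["train"]], 100)
  expect_true(all(a$s0 > 0))
  expect_true(all(a$n_echoes >= 5 & a$n_echoes <= 15))
  expect_true(all(a$sigma > 0 & a$sigma <= 300))
  expect_equal(a$snr, a$s0 / a$sigma)
  expect_equal(lengths(a$te), a$n_echoes)
})

test_that("generated T2 follows the calibrated prior", {
  d <- simulate_decays(c(train = 2e5), seed = 11)
  expect_equal(median(d$t2), 5 + exp(calibrate_t2_prior()$log_mu),
               tolerance = 0.01)
})

test_that("fixed-SNR sets pin every sample at the requested SNR", {
  d <- simulate_fixed_snr(500, snr = 5, seed = 9)
  expect_equal(d$s0 / d$sigma, rep(5, 500))
  expect_identical(d, simulate_fixed_snr(500, snr = 5, seed = 9))
  # infinite SNR -> noise-free magnitudes
  d0 <- simulate_fixed_snr(20, snr = Inf, seed = 10)
  expect_true(all(d0$sigma == 0))
  clean <- purrr::pmap(list(d0$s0, d0$t2, d0$te),
                       function(s0, t2, te) mono_exp_signal(s0, t2, te))
  expect_equal(d0$magnitude, clean)
})

test_that("decay CSV round trip preserves the sample set", {
  d <- simulate_decays(c(test = 25), seed = 5)
  p <- withr::local_tempfile(fileext = ".csv")
  write_decays(d, p, priors = default_priors(), seed = 5)
  expect_true(file.exists(paste0(p, ".json")))
  r <- read_decays(p)
  expect_equal(r$t2, d$t2)
  expect_equal(r$magnitude, d$magnitude, tolerance = 1e-12)
  expect_equal(r$te, d$te, tolerance = 1e-12)
})
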