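# a narrow network keeps the training tests fast; the full-width default is
# exercised by the parameter-count check and the acceptance suite
small_spec <- network_spec(width = 32)

test_that("the default architecture lands in the ~1M parameter budget", {
  spec <- network_spec()
  expect_equal(spec$dims, c(30, 512, 512, 512, 512, 512, 2))
  # closed-form count: sum of weights and biases over the 6 weight layers
  dims <- spec$dims
  expect_equal(n_parameters(spec),
               sum(dims[-length(dims)] * dims[-1]) + sum(dims[-1]))
  expect_gt(n_parameters(spec), 0.9e6)
  expect_lt(n_parameters(spec), 1.2e6)
})

test_that("input encoding pads with -1 and round-trips", {
  d <- simulate_decays(c(test = 30), seed = 41)
  x <- encode_echo_trains(d)
  expect_equal(dim(x), c(30, 30))
  for (i in seq_len(nrow(d))) {
    k <- d$n_echoes[i]
    expect_equal(sum(x[i, ] == -1), 2 * (15 - k))
    expect_equal(x[i, seq_len(k)], d$magnitude[[i]])
    expect_equal(x[i, 15 + seq_len(k)], d$te[[i]])
  }
  dec <- decode_network_input(x)
  expect_equal(dec$te, d$te)
  expect_equal(dec$magnitude, d$magnitude)
  expect_equal(dec$n_echoes, d$n_echoes)
  # a full-length train has no padding
  d15 <- d[d$n_echoes == 15, ]
  if (nrow(d15) > 0) expect_false(any(encode_echo_trains(d15) == -1))
  # trains longer than the input width are rejected
  too_long <- tibble::tibble(te = list(1:16), magnitude = list(rep(1, 16)))
  expect_error(encode_echo_trains(too_long), class = "t2relax_invalid_input")
})

test_that("training is deterministic given a seed and selects the argmin epoch", {
  tr <- simulate_decays(c(train = 600), seed = 42)
  va <- simulate_decays(c(val = 200), seed = 43)
  cfg <- train_config(epochs = 4, batch_size = 128)
  n1 <- train_t2net(tr, va, spec = small_spec, config = cfg, seed = 7)
  n2 <- train_t2net(tr, va, spec = small_spec, config = cfg, seed = 7)
  expect_identical(n1$weights, n2$weights)
  expect_identical(n1$log, n2$log)
  # selected checkpoint has the lowest validation loss of all epochs
  expect_equal(n1$best_val_loss, min(n1$log$val_loss))
  expect_equal(n1$best_epoch, which.min(n1$log$val_loss))
  lg <- tidy(n1)
  expect_true(lg$selected[n1$best_epoch])
  expect_equal(glance(n1)$n_parameters, n_parameters(small_spec))
})

test_that("training refuses s0 = 0 samples and empty sets", {
  tr <- simulate_decays(c(train = 50), seed = 44)
  tr$s0[1] <- 0
  va <- simulate_decays(c(val = 20), seed = 45)
  expect_error(train_t2net(tr, va, spec = small_spec,
                           config = train_config(epochs = 1)), "s0 = 0")
})

test_that("predictions are non-negative, per-sample, and order-equivariant", {
  tr <- simulate_decays(c(train = 600), seed = 46)
  va <- simulate_decays(c(val = 200), seed = 47)
  net <- train_t2net(tr, va, spec = small_spec,
                     config = train_config(epochs = 2, batch_size = 128), seed = 8)
  d <- simulate_decays(c(test = 100), seed = 48)
  p <- predict(net, d)
  expect_true(all(p$s0_hat >= 0))
  expect_true(all(p$t2_hat >= 0))
  perm <- sample(seq_len(nrow(d)))
  p2 <- predict(net, d[perm, ])
  expect_equal(p2$t2_hat, p$t2_hat[perm])
  # batch composition does not matter
  p3 <- predict(net, d[1:3, ])
  expect_equal(p3$t2_hat, p$t2_hat[1:3])
})

test_that("a small noise-free training run learns the decay family", {
  # 2k clean decays, narrow net, small batches so the optimizer takes enough
  # steps at this scale; the full-width network is trained in the
  # reproduction suite
  tr <- simulate_fixed_snr(2000, snr = Inf, seed = 49)
  va <- simulate_fixed_snr(400, snr = Inf, seed = 50)
  net <- train_t2net(tr, va, spec = network_spec(width = 64),
                     config = train_config(epochs = 60, batch_size = 64),
                     seed = 9)
  ho <- simulate_fixed_snr(500, snr = Inf, seed = 51)
  p <- predict(net, ho)
  expect_lt(median(arqe(p$t2_hat, ho$t2)), 10)
})

test_that("checkpoints round-trip through JSON", {
  tr <- simulate_decays(c(train = 300), seed = 52)
  va <- simulate_decays(c(val = 100), seed = 53)
  net <- train_t2net(tr, va, spec = small_spec,
                     config = train_config(epochs = 2, batch_size = 128), seed = 10)
  path <- withr::local_tempfile(fileext = ".json")
  write_t2net(net, path)
  back <- read_t2net(path)
  expect_equal(back$weights, net$weights)
  expect_equal(back$best_epoch, net$best_epoch)
  d <- simulate_decays(c(test = 20), seed = 54)
  expect_equal(predict(back, d), predict(net, d))
})
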