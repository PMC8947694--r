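# Shared fixtures for the in-silico reproduction suite. Everything is
# memoized so several test blocks can reuse the same generated sets, fits
# and trained network without recomputation.
.repro <- new.env(parent = emptyenv())

repro_memo <- function(key, expr) {
  if (!exists(key, envir = .repro, inherits = FALSE)) {
    assign(key, force(expr), envir = .repro)
  }
  get(key, envir = .repro, inherits = FALSE)
}

# 10,000-sample test set pinned at one SNR, drawn from the calibrated priors
repro_set <- function(snr) {
  repro_memo(paste0("set_", snr), simulate_fixed_snr(1e4, snr, seed = 4000 + snr))
}

# fit of the first `n` samples of the SNR set with one method (true sigma
# supplied to the noise-corrected fitter via the set's sigma column)
repro_fit <- function(method, snr, n = 1e4) {
  n <- as.integer(n)
  repro_memo(paste0("fit_", method, "_", snr, "_", n), {
    d <- repro_set(snr)[seq_len(n), ]
    fit_decays(d, method)
  })
}

repro_median_arqe <- function(method, snr, n = 1e4) {
  f <- repro_fit(method, snr, n)
  median(arqe(f$t2_hat, f$t2))
}

repro_median_rqe <- function(method, snr, n = 1e4) {
  f <- repro_fit(method, snr, n)
  median(rqe(f$t2_hat, f$t2))
}

# Scaled-down training of the full-width network: 200k training decays and
# 20k validation decays for 10 epochs (the full-scale study is 67M/8M for
# 30 epochs; the scaled sizes are the package's CPU-budget defaults)
repro_net <- function() {
  repro_memo("net", {
    tr <- simulate_decays(c(train = 2e5), seed = 4101)
    va <- simulate_decays(c(val = 2e4), seed = 4102)
    train_t2net(tr, va, config = train_config(epochs = 10), seed = 4103)
  })
}

repro_nn_median_arqe <- function(snr) {
  d <- repro_set(snr)
  p <- predict(repro_net(), d)
  median(arqe(p$t2_hat, d$t2))
}
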