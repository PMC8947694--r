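#' Sample multi-echo acquisition configurations
#'
#' Draws echo-train layouts from the acquisition priors: first echo time
#' `te_start ~ U(te_start_range)`, spacing `te_step ~ U(te_step_range)`, and
#' number of echoes `n_echoes` discrete-uniform on `n_range`. Echo times are
#' `te_k = te_start + k * te_step`, `k = 0 .. n_echoes - 1`.
#'
#' @param n Number of configurations to draw.
#' @param priors A `prior_config`, see [default_priors()].
#' @param seed Optional integer seed applied locally.
#'
#' @return A tibble with columns `te_start`, `te_step`, `n_echoes` and a
#'   list-column `te` of echo-time vectors (ms).
#'
#' @examples
#' sample_echo_config(3, seed = 1)
#' @export
sample_echo_config <- function(n, priors = default_priors(), seed = NULL) {
  draw <- function() {
    tibble::tibble(
      te_start = stats::runif(n, priors$te_start_range[1], priors$te_start_range[2]),
      te_step = stats::runif(n, priors$te_step_range[1], priors$te_step_range[2]),
      n_echoes = sample(seq(priors$n_range[1], priors$n_range[2]), n, replace = TRUE)
    )
  }
  cfg <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  cfg$te <- purrr::pmap(cfg, function(te_start, te_step, n_echoes) {
    te_start + (seq_len(n_echoes) - 1) * te_step
  })
  cfg
}

# vectorized core: one padded-matrix dataset; sigma either from the prior
# (heterogeneous) or s0/snr (fixed-SNR), snr = Inf -> noise-free
generate_core <- function(n, priors, snr = NULL) {
  s0 <- rs0prior(n, priors$s0)
  t2 <- rt2prior(n, priors$t2)
  sigma <- if (is.null(snr)) {
    sg <- stats::runif(n, 0, priors$sigma_max)
    # uniform on (0, sigma_max]: exact zeros redrawn so annotated SNR is finite
    while (any(sg == 0)) sg[sg == 0] <- stats::runif(sum(sg == 0), 0, priors$sigma_max)
    sg
  } else if (is.infinite(snr)) {
    rep(0, n)
  } else {
    s0 / snr
  }
  te_start <- stats::runif(n, priors$te_start_range[1], priors$te_start_range[2])
  te_step <- stats::runif(n, priors$te_step_range[1], priors$te_step_range[2])
  n_echoes <- sample(seq(priors$n_range[1], priors$n_range[2]), n, replace = TRUE)

  width <- priors$n_range[2]
  k <- matrix(seq_len(width) - 1, n, width, byrow = TRUE)
  te <- te_start + k * te_step
  pad <- k >= n_echoes
  s <- s0 * exp(-te / t2)
  noisy <- sqrt((s + matrix(stats::rnorm(n * width, 0, sigma), n, width))^2 +
                  matrix(stats::rnorm(n * width, 0, sigma), n, width)^2)
  noisy[pad] <- NA_real_
  te[pad] <- NA_real_
  list(s0 = s0, t2 = t2, sigma = sigma, n_echoes = n_echoes,
       te = te, magnitude = noisy)
}

core_to_tibble <- function(core) {
  n <- length(core$s0)
  tibble::tibble(
    s0 = core$s0, t2 = core$t2, sigma = core$sigma,
    snr = snr_of(core$s0, core$sigma),
    n_echoes = core$n_echoes,
    te = lapply(seq_len(n), function(i) core$te[i, seq_len(core$n_echoes[i])]),
    magnitude = lapply(seq_len(n), function(i) core$magnitude[i, seq_len(core$n_echoes[i])])
  )
}

#' Simulate synthetic multi-echo decays from the calibrated priors
#'
#' Generates a split-tagged sample set of Rician-corrupted mono-exponential
#' decays. For every sample, `s0` (never exactly 0), `t2`, `sigma`, and an
#' echo-train layout are drawn from `priors`; the noise-free decay is
#' evaluated at the echo times and corrupted with complex Gaussian noise of
#' standard deviation `sigma` per channel. Each row is annotated with its
#' SNR (`s0 / sigma`).
#'
#' The generation is a pure function of `(counts, priors, seed)`.
#'
#' @param counts Named integer vector of split sizes, e.g.
#'   `c(train = 1000, val = 100, test = 100)`; unnamed scalars become a
#'   single `"test"` split.
#' @param priors A `prior_config`, see [default_priors()].
#' @param seed Optional integer seed applied locally.
#'
#' @return A tibble with one row per decay: `split`, `s0`, `t2`, `sigma`,
#'   `snr`, `n_echoes`, and list-columns `te`, `magnitude`.
#'
#' @examples
#' simulate_decays(c(train = 50, test = 10), seed = 1)
#' @export
simulate_decays <- function(counts, priors = default_priors(), seed = NULL) {
  if (is.null(names(counts))) {
    if (length(counts) != 1) {
      rlang::abort("`counts` must be named per split or a single size.")
    }
    names(counts) <- "test"
  }
  if (any(counts < 1)) rlang::abort("All split counts must be >= 1.")
  run <- function() {
    purrr::imap(as.list(counts), function(nn, split) {
      dplyr::mutate(core_to_tibble(generate_core(nn, priors)),
                    split = split, .before = 1)
    }) |> purrr::list_rbind()
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a test set pinned at one SNR
#'
#' Like [simulate_decays()], but instead of drawing the noise level from its
#' prior, each sample's `sigma` is set to `s0 / snr`, so every decay sits at
#' exactly the requested SNR. This is the sampling mode behind the
#' SNR-resolved error tables. `snr = Inf` produces noise-free decays
#' (`sigma = 0`).
#'
#' @param n Number of samples.
#' @param snr Target signal-to-noise ratio (> 0, or `Inf`).
#' @param priors A `prior_config`.
#' @param seed Optional integer seed applied locally.
#'
#' @return A tibble as in [simulate_decays()] with `split = "test"`.
#'
#' @examples
#' simulate_fixed_snr(10, snr = 5, seed = 1)
#' @export
simulate_fixed_snr <- function(n, snr, priors = default_priors(), seed = NULL) {
  if (!(snr > 0)) rlang::abort("`snr` must be positive (or Inf).")
  run <- function() {
    dplyr::mutate(core_to_tibble(generate_core(n, priors, snr = snr)),
                  split = "test", .before = 1)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Write / read a decay sample set as CSV with a JSON sidecar
#'
#' Decays are written in a fixed-width layout: 15 magnitude columns then 15
#' echo-time columns, padded with -1 beyond `n_echoes` (the same convention
#' the neural network input uses), plus the truth columns. A JSON sidecar
#' (`<path>.json`) records the prior calibration and, when supplied, the
#' seed and counts used.
#'
#' @param data A decay tibble from [simulate_decays()].
#' @param path CSV file path.
#' @param priors,seed Optional metadata stored in the sidecar.
#'
#' @return `write_decays` returns `path` invisibly; `read_decays` returns
#'   the decay tibble.
#'
#' @examples
#' p <- tempfile(fileext = ".csv")
#' write_decays(simulate_decays(c(test = 5), seed = 1), p)
#' read_decays(p)
#' @export
write_decays <- function(data, path, priors = NULL, seed = NULL) {
  width <- 15L
  enc <- encode_echo_trains(data, width = width)
  flat <- as.data.frame(enc)
  names(flat) <- c(paste0("mag", seq_len(width)), paste0("te", seq_len(width)))
  meta <- data[, intersect(c("split", "s0", "t2", "sigma", "snr", "n_echoes"), names(data))]
  utils::write.csv(cbind(meta, flat), path, row.names = FALSE)
  sidecar <- list(n = nrow(data), pad_value = -1, width = width)
  if (!is.null(seed)) sidecar$seed <- seed
  if (!is.null(priors)) {
    sidecar$priors <- list(
      te_start_range = priors$te_start_range, te_step_range = priors$te_step_range,
      n_range = priors$n_range, sigma_max = priors$sigma_max,
      t2 = priors$t2[c("shift", "mode", "q95", "log_mu", "log_sd")],
      s0 = priors$s0[c("cap", "q95", "tail_scale")]
    )
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_decays
#' @export
read_decays <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  width <- 15L
  magc <- paste0("mag", seq_len(width))
  tec <- paste0("te", seq_len(width))
  meta <- df[, setdiff(names(df), c(magc, tec)), drop = FALSE]
  out <- tibble::as_tibble(meta)
  out$te <- lapply(seq_len(nrow(df)), function(i)
    unlist(df[i, tec], use.names = FALSE)[seq_len(df$n_echoes[i])])
  out$magnitude <- lapply(seq_len(nrow(df)), function(i)
    unlist(df[i, magc], use.names = FALSE)[seq_len(df$n_echoes[i])])
  out
}
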