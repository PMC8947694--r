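#' Noise-free mono-exponential spin-echo signal
#'
#' Evaluates the mono-exponential transverse decay
#' \eqn{|S| = S_0 \exp(-TE / T_2)} at one or more echo times. This is the
#' forward model underlying all fitters in the package.
#'
#' @param s0 Apparent proton density (arbitrary units, >= 0).
#' @param t2 Transverse relaxation time in ms (> 0).
#' @param te Echo time(s) in ms (>= 0).
#'
#' @return Numeric vector of noise-free signal magnitudes, recycled to the
#'   common length of the arguments.
#'
#' @examples
#' mono_exp_signal(250, 50, c(10, 30, 50))
#' @export
mono_exp_signal <- function(s0, t2, te) {
  if (any(t2 <= 0)) {
    rlang::abort("`t2` must be strictly positive (ms).", class = "t2relax_invalid_parameter")
  }
  if (any(te < 0)) {
    rlang::abort("`te` must be non-negative (ms).", class = "t2relax_invalid_parameter")
  }
  s0 * exp(-te / t2)
}

#' Corrupt a magnitude signal with Rician noise
#'
#' Adds independent zero-mean Gaussian noise of standard deviation `sigma`
#' to the real and imaginary channels of a complex signal whose phase is
#' zero, and returns the magnitude:
#' \eqn{|S_{noisy}| = \sqrt{(S + \epsilon_{re})^2 + \epsilon_{im}^2}}.
#' The result follows a Rician distribution with non-centrality `signal`
#' and scale `sigma`. With `sigma = 0` the signal is returned unchanged.
#'
#' Randomness is drawn from R's global generator; pass `seed` (or call
#' `set.seed()` beforehand) for reproducibility.
#'
#' @param signal Noise-free magnitude(s), >= 0.
#' @param sigma Per-channel Gaussian noise standard deviation, >= 0.
#'   Recycled against `signal`.
#' @param seed Optional integer seed applied locally for this draw.
#'
#' @return Numeric vector of noisy magnitudes (always >= 0).
#'
#' @examples
#' add_rician_noise(mono_exp_signal(250, 50, seq(10, 70, 10)), sigma = 25, seed = 1)
#' @export
add_rician_noise <- function(signal, sigma, seed = NULL) {
  if (any(sigma < 0)) {
    rlang::abort("`sigma` must be non-negative.", class = "t2relax_invalid_parameter")
  }
  draw <- function() {
    n <- max(length(signal), length(sigma))
    sqrt((signal + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Expected magnitude of a Rician-distributed signal
#'
#' The mean of a Rician distribution with non-centrality `signal` and scale
#' `sigma`:
#' \deqn{E|S| = \sigma\sqrt{\pi/2}\, e^{-\alpha}\left[(1+2\alpha)I_0(\alpha)
#'   + 2\alpha I_1(\alpha)\right], \quad \alpha = \left(\frac{S}{2\sigma}\right)^2,}
#' where \eqn{I_0, I_1} are modified Bessel functions of the first kind.
#' This is the model function of the noise-corrected fitter ([fit_nclse()]):
#' instead of the noise-free decay it predicts the magnitude the scanner
#' actually measures, which flattens out at the Rayleigh noise floor
#' \eqn{\sigma\sqrt{\pi/2}} instead of decaying to zero.
#'
#' Exponentially scaled Bessel functions are used so the expression stays
#' finite at arbitrarily large \eqn{\alpha} (high SNR), where the expectation
#' converges to `signal` itself. `sigma = 0` returns `signal` unchanged
#' (the continuous limit).
#'
#' @param signal Noise-free magnitude(s), >= 0.
#' @param sigma Per-channel noise standard deviation, >= 0. Recycled.
#'
#' @return Expected noisy magnitude(s); always >= `signal` and >=
#'   `sigma * sqrt(pi/2)` where `sigma > 0`.
#'
#' @examples
#' rician_expected_magnitude(0, 1)      # Rayleigh mean sqrt(pi/2)
#' rician_expected_magnitude(1000, 1)   # ~ 1000 (noise negligible)
#' @export
rician_expected_magnitude <- function(signal, sigma) {
  if (any(sigma < 0)) {
    rlang::abort("`sigma` must be non-negative.", class = "t2relax_invalid_parameter")
  }
  n <- max(length(signal), length(sigma))
  signal <- rep_len(signal, n)
  sigma <- rep_len(sigma, n)
  out <- signal
  pos <- sigma > 0
  if (any(pos)) {
    s <- signal[pos]
    sg <- sigma[pos]
    a <- (s / (2 * sg))^2
    v <- numeric(length(a))
    # besselI(.., expon.scaled = TRUE) returns e^{-a} I_nu(a), but underflows
    # to 0 beyond a ~ 1e5; past a = 1e4 the asymptote sqrt(s^2 + sg^2) agrees
    # with the exact mean to ~1e-10 relative, so switch over there
    lo <- a <= 1e4
    if (any(lo)) {
      al <- a[lo]
      v[lo] <- sg[lo] * sqrt(pi / 2) *
        ((1 + 2 * al) * besselI(al, 0, expon.scaled = TRUE) +
           2 * al * besselI(al, 1, expon.scaled = TRUE))
    }
    if (any(!lo)) v[!lo] <- sqrt(s[!lo]^2 + sg[!lo]^2)
    out[pos] <- v
  }
  out
}

#' Signal-to-noise ratio of a decay
#'
#' SNR is defined as the apparent proton density divided by the per-channel
#' noise standard deviation, `s0 / sigma`. A noise-free decay (`sigma = 0`)
#' reports `Inf`.
#'
#' @param s0 Apparent proton density (>= 0).
#' @param sigma Noise standard deviation (>= 0).
#'
#' @return Numeric vector of SNR values.
#'
#' @examples
#' snr_of(500, 100)
#' @export
snr_of <- function(s0, sigma) {
  if (any(s0 < 0) || any(sigma < 0)) {
    rlang::abort("`s0` and `sigma` must be non-negative.", class = "t2relax_invalid_parameter")
  }
  ifelse(sigma == 0, Inf, s0 / sigma)
}
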