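#' Calibrate the shifted log-normal T2 prior
#'
#' The T2 sampling distribution is a log-normal shifted by a lower
#' threshold: \eqn{T_2 = shift + X}, \eqn{\log X \sim N(\mu, s^2)}. The two
#' free parameters are solved from (i) the mode of the shifted density and
#' (ii) a 95th-percentile constraint:
#' \deqn{e^{\mu - s^2} = mode - shift, \qquad P(T_2 < q_{95}) = 0.95.}
#' Substituting the mode condition into the quantile condition gives a
#' quadratic in `s`, solved in closed form; with the defaults this yields
#' `log_sd` ~ 0.658 and `log_mu` ~ 4.240, a median of ~74.4 ms, and a tail
#' probability P(T2 < 500 ms) of ~99.9%.
#'
#' @param shift Lower threshold in ms (no mass below it).
#' @param mode Statistical mode of the shifted density, ms.
#' @param q95 Value below which 95% of the mass lies, ms.
#'
#' @return A list of class `t2_prior` with elements `shift`, `mode`, `q95`,
#'   `log_mu`, `log_sd`.
#'
#' @examples
#' calibrate_t2_prior()
#' @export
calibrate_t2_prior <- function(shift = 5, mode = 50, q95 = 210) {
  if (!(shift < mode && mode < q95)) {
    rlang::abort("Require shift < mode < q95.", class = "t2relax_calibration_error")
  }
  z <- stats::qnorm(0.95)
  # s^2 + z s - log((q95 - shift)/(mode - shift)) = 0
  cc <- log((q95 - shift) / (mode - shift))
  disc <- z^2 + 4 * cc
  if (disc <= 0) {
    rlang::abort("No real calibration solution.", class = "t2relax_calibration_error")
  }
  log_sd <- (-z + sqrt(disc)) / 2
  log_mu <- log(mode - shift) + log_sd^2
  structure(
    list(shift = shift, mode = mode, q95 = q95, log_mu = log_mu, log_sd = log_sd),
    class = "t2_prior"
  )
}

#' T2 prior density, distribution and sampling
#'
#' Density, cumulative probability and random generation for the calibrated
#' shifted log-normal T2 prior produced by [calibrate_t2_prior()].
#'
#' @param x,q T2 values in ms.
#' @param n Number of draws.
#' @param prior A `t2_prior` object.
#'
#' @return `dt2prior` and `pt2prior` return numeric vectors; `rt2prior`
#'   returns `n` random T2 values (ms).
#'
#' @examples
#' pr <- calibrate_t2_prior()
#' pt2prior(500, pr)     # ~ 0.9986
#' @name t2prior
NULL

#' @rdname t2prior
#' @export
dt2prior <- function(x, prior) {
  out <- numeric(length(x))
  ok <- x > prior$shift
  out[ok] <- stats::dlnorm(x[ok] - prior$shift, prior$log_mu, prior$log_sd)
  out
}

#' @rdname t2prior
#' @export
pt2prior <- function(q, prior) {
  ifelse(q <= prior$shift, 0,
         stats::plnorm(q - prior$shift, prior$log_mu, prior$log_sd))
}

#' @rdname t2prior
#' @export
rt2prior <- function(n, prior) {
  prior$shift + stats::rlnorm(n, prior$log_mu, prior$log_sd)
}

#' Calibrate the uniform-plus-exponential-tail S0 prior
#'
#' Apparent proton density is sampled from an equal-weight mixture: with
#' probability 1/2 uniform on `[0, cap]`, and with probability 1/2
#' `cap + Exponential(tail_scale)`. The tail scale is solved from the
#' constraint \eqn{P(S_0 \le q_{95}) = 0.95}, i.e.
#' \eqn{0.5\, e^{-(q_{95}-cap)/scale} = 0.05}. With the defaults the scale
#' is \eqn{1200/\ln 10 \approx 521}, giving P(S0 <= 500) = 0.50 exactly and
#' P(S0 <= 2500) ~ 0.989.
#'
#' @param cap Upper edge of the uniform body (arbitrary units).
#' @param q95 95th percentile of the full mixture.
#'
#' @return A list of class `s0_prior` with elements `cap`, `q95`,
#'   `tail_scale`.
#'
#' @examples
#' calibrate_s0_prior()
#' @export
calibrate_s0_prior <- function(cap = 500, q95 = 1700) {
  if (!(cap < q95)) {
    rlang::abort("Require cap < q95.", class = "t2relax_calibration_error")
  }
  tail_scale <- (q95 - cap) / log(10)
  structure(
    list(cap = cap, q95 = q95, tail_scale = tail_scale),
    class = "s0_prior"
  )
}

#' S0 prior distribution and sampling
#'
#' Cumulative probability and random generation for the mixture S0 prior
#' produced by [calibrate_s0_prior()]. `rs0prior` rejects exact zeros so no
#' generated decay has `s0 = 0`.
#'
#' @param q S0 values.
#' @param n Number of draws.
#' @param prior An `s0_prior` object.
#'
#' @return `ps0prior` returns probabilities; `rs0prior` returns `n` strictly
#'   positive draws.
#'
#' @examples
#' pr <- calibrate_s0_prior()
#' ps0prior(c(500, 1700, 2500), pr)
#' @name s0prior
NULL

#' @rdname s0prior
#' @export
ps0prior <- function(q, prior) {
  ifelse(q < 0, 0,
         ifelse(q <= prior$cap, 0.5 * q / prior$cap,
                0.5 + 0.5 * (1 - exp(-(q - prior$cap) / prior$tail_scale))))
}

#' @rdname s0prior
#' @export
rs0prior <- function(n, prior) {
  out <- ifelse(stats::runif(n) < 0.5,
                stats::runif(n, 0, prior$cap),
                prior$cap + stats::rexp(n, rate = 1 / prior$tail_scale))
  # s0 = 0 is excluded from every sample set; a uniform draw of exactly 0
  # has probability zero but floating-point can produce it
  zero <- out == 0
  while (any(zero)) {
    out[zero] <- stats::runif(sum(zero), 0, prior$cap)
    zero <- out == 0
  }
  out
}

#' Default prior configuration for synthetic decays
#'
#' Bundles every sampling distribution the synthetic generator uses:
#' first echo time uniform on `te_start_range` (ms), echo spacing uniform on
#' `te_step_range` (ms), number of echoes discrete-uniform on `n_range`,
#' per-channel noise standard deviation uniform on `(0, sigma_max]`, the
#' calibrated shifted log-normal T2 prior, and the calibrated mixture S0
#' prior.
#'
#' @param te_start_range Range of the first echo time, ms.
#' @param te_step_range Range of the echo spacing, ms.
#' @param n_range Integer range of the number of echoes.
#' @param sigma_max Upper end of the uniform noise-level prior.
#' @param t2 A `t2_prior`, by default [calibrate_t2_prior()].
#' @param s0 An `s0_prior`, by default [calibrate_s0_prior()].
#'
#' @return A list of class `prior_config`.
#'
#' @examples
#' default_priors()
#' @export
default_priors <- function(te_start_range = c(5, 15),
                           te_step_range = c(2, 15),
                           n_range = c(5L, 15L),
                           sigma_max = 300,
                           t2 = calibrate_t2_prior(),
                           s0 = calibrate_s0_prior()) {
  stopifnot(diff(te_start_range) > 0, diff(te_step_range) > 0,
            n_range[2] >= n_range[1], sigma_max > 0)
  structure(
    list(te_start_range = te_start_range, te_step_range = te_step_range,
         n_range = as.integer(n_range), sigma_max = sigma_max,
         t2 = t2, s0 = s0),
    class = "prior_config"
  )
}

#' @export
print.t2_prior <- function(x, ...) {
  cat(sprintf(
    "Shifted log-normal T2 prior: shift %g ms, mode %g ms, P(T2 < %g) = 0.95\n  log_mu = %.4f, log_sd = %.4f\n",
    x$shift, x$mode, x$q95, x$log_mu, x$log_sd))
  invisible(x)
}

#' @export
print.s0_prior <- function(x, ...) {
  cat(sprintf(
    "Mixture S0 prior: 0.5 Uniform(0, %g) + 0.5 (%g + Exp(scale %.1f))\n",
    x$cap, x$cap, x$tail_scale))
  invisible(x)
}
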