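#' @importFrom minpack.lm nls.lm nls.lm.control
NULL

# Parameter box shared by all least-squares fitters: S0 in [0, 2500],
# T2 in [5, 500] ms, offset c in [0, 2500] (a non-negative noise floor).
fit_bounds <- function(n_par) {
  list(lower = c(0, 5, 0)[seq_len(n_par)],
       upper = c(2500, 500, 2500)[seq_len(n_par)])
}

# Standard initial values (S0 = 250, T2 = 50 ms, c = 0) plus a small fixed
# set of auxiliary restarts. Projected Levenberg-Marquardt can stall on the
# box boundary (typically at T2 = 500 or S0 = 2500) when started far from
# the optimum; restarting from a few spread-out points and keeping the
# lowest-SSR solution recovers the optimum an interior trust-region method
# finds from the single standard start.
fit_starts <- function(n_par) {
  base <- list(c(250, 50), c(1000, 20), c(1000, 150), c(250, 400))
  if (n_par == 3) base <- lapply(base, function(p) c(p, 0)) # c starts at 0
  base
}

ms_nls_fit <- function(fn, jac = NULL, n_par, maxfev = 10000) {
  b <- fit_bounds(n_par)
  best <- NULL
  best_ssr <- Inf
  best_conv <- FALSE
  for (start in fit_starts(n_par)) {
    res <- try(suppressWarnings(
      nls.lm(par = start, fn = fn, jac = jac,
             lower = b$lower, upper = b$upper,
             control = nls.lm.control(maxiter = 100, maxfev = maxfev))
    ), silent = TRUE)
    if (inherits(res, "try-error")) next
    ssr <- sum(res$fvec^2)
    if (!all(is.finite(res$par)) || !is.finite(ssr)) next
    if (ssr < best_ssr) {
      best_ssr <- ssr
      best <- res$par
      best_conv <- res$info %in% 1:4
    }
  }
  if (is.null(best)) {
    # optimizer failure: fall back to the lower bounds
    list(par = b$lower, converged = FALSE, fallback = TRUE, ssr = NA_real_)
  } else {
    list(par = best, converged = best_conv, fallback = FALSE, ssr = best_ssr)
  }
}

fit_result <- function(par, method, converged, fallback, offset = NA_real_) {
  tibble::tibble(
    method = method,
    s0_hat = par[1], t2_hat = par[2], offset_hat = offset,
    converged = converged, fallback = fallback
  )
}

check_train <- function(te, magnitude, min_n = 2) {
  if (length(te) != length(magnitude)) {
    rlang::abort("`te` and `magnitude` must have the same length.",
                 class = "t2relax_invalid_input")
  }
  if (length(te) < min_n) {
    rlang::abort(sprintf("At least %d echoes are required.", min_n),
                 class = "t2relax_invalid_input")
  }
  if (any(diff(te) <= 0)) {
    rlang::abort("`te` must be strictly increasing.",
                 class = "t2relax_invalid_input")
  }
}

#' Traditional bounded least-squares T2 fit (LSE)
#'
#' Fits the noise-free mono-exponential model \eqn{S_0 e^{-TE/T_2}} to the
#' measured magnitudes by bounded nonlinear least squares. Initial values
#' are `(S0, T2) = (250, 50 ms)`; bounds are S0 in `[0, 2500]` and T2 in
#' `[5, 500]` ms. If the minimization fails the lower bounds are returned
#' with the `fallback` flag set.
#'
#' Because the measured magnitudes are Rician, their expectation never
#' reaches zero; at low SNR this noise floor drags the fitted decay out and
#' the traditional fit systematically *over*estimates T2.
#'
#' @param te Echo times in ms, strictly increasing.
#' @param magnitude Measured signal magnitudes (>= 0).
#'
#' @return A one-row tibble: `method`, `s0_hat`, `t2_hat`, `offset_hat`
#'   (`NA` here), `converged`, `fallback`.
#'
#' @examples
#' te <- seq(10, 70, 10)
#' fit_lse(te, mono_exp_signal(250, 50, te))
#' @export
fit_lse <- function(te, magnitude) {
  check_train(te, magnitude)
  fn <- function(p) p[1] * exp(-te / p[2]) - magnitude
  jac <- function(p) {
    e <- exp(-te / p[2])
    cbind(e, p[1] * e * te / p[2]^2)
  }
  r <- ms_nls_fit(fn, jac, n_par = 2)
  fit_result(r$par, "lse", r$converged, r$fallback)
}

#' Offset least-squares T2 fit (OLSE)
#'
#' Fits \eqn{S_0 e^{-TE/T_2} + c}, where the constant `c` absorbs the
#' Rician noise floor. Initial values are `(250, 50 ms, 0)`; `c` is bounded
#' to `[0, 2500]` (a noise floor cannot be negative). Echo trains with
#' fewer than 3 points are underdetermined for the 3-parameter model and
#' return the fallback result.
#'
#' @inheritParams fit_lse
#'
#' @return A one-row tibble as in [fit_lse()] with `offset_hat` filled in.
#'
#' @examples
#' te <- seq(10, 70, 10)
#' fit_olse(te, mono_exp_signal(250, 50, te) + 40)
#' @export
fit_olse <- function(te, magnitude) {
  check_train(te, magnitude)
  if (length(te) < 3) {
    b <- fit_bounds(3)
    return(fit_result(b$lower, "olse", FALSE, TRUE, offset = b$lower[3]))
  }
  fn <- function(p) p[1] * exp(-te / p[2]) + p[3] - magnitude
  jac <- function(p) {
    e <- exp(-te / p[2])
    cbind(e, p[1] * e * te / p[2]^2, rep(1, length(te)))
  }
  r <- ms_nls_fit(fn, jac, n_par = 3)
  fit_result(r$par[1:2], "olse", r$converged, r$fallback,
             offset = if (r$fallback) fit_bounds(3)$lower[3] else r$par[3])
}

#' Noise-corrected least-squares T2 fit (NCLSE)
#'
#' Fits the *expected Rician magnitude* of the mono-exponential decay
#' ([rician_expected_magnitude()]) instead of the noise-free decay itself,
#' which removes the noise-floor bias — at the cost of requiring the noise
#' standard deviation `sigma` for the sample. With `sigma = 0` the model
#' reduces exactly to the traditional fit.
#'
#' @inheritParams fit_lse
#' @param sigma Known or externally estimated per-channel noise standard
#'   deviation (>= 0).
#'
#' @return A one-row tibble as in [fit_lse()].
#'
#' @examples
#' te <- seq(10, 70, 10)
#' y <- add_rician_noise(mono_exp_signal(250, 50, te), 50, seed = 1)
#' fit_nclse(te, y, sigma = 50)
#' @export
fit_nclse <- function(te, magnitude, sigma) {
  check_train(te, magnitude)
  if (length(sigma) != 1 || is.na(sigma) || sigma < 0) {
    rlang::abort("`sigma` must be a single non-negative number.",
                 class = "t2relax_invalid_parameter")
  }
  if (sigma == 0) {
    out <- fit_lse(te, magnitude)
    out$method <- "nclse"
    return(out)
  }
  fn <- function(p) {
    rician_expected_magnitude(p[1] * exp(-te / p[2]), sigma) - magnitude
  }
  # Jacobian left to finite differences: the Bessel-function model has no
  # convenient closed-form derivative and the trains are short
  r <- ms_nls_fit(fn, jac = NULL, n_par = 2)
  fit_result(r$par, "nclse", r$converged, r$fallback)
}

#' Fit a set of decays voxel-/sample-wise
#'
#' Applies one of the four estimators to every row of a decay tibble (as
#' produced by [simulate_decays()] or [simulate_fixed_snr()]) and returns
#' the input with fit columns appended, ready for [rqe()] / [arqe()] /
#' [error_table()].
#'
#' For `method = "nclse"` the noise level is taken from `sigma_known` if
#' supplied (scalar or per-row vector), otherwise from the data's `sigma`
#' column — i.e. by default the fitter is given the true per-sample noise.
#' For `method = "nn"` a trained model must be supplied.
#'
#' @param data Tibble with list-columns `te` and `magnitude`.
#' @param method One of `"lse"`, `"olse"`, `"nclse"`, `"nn"`.
#' @param sigma_known Optional noise level(s) for `"nclse"`.
#' @param model A trained `t2net` (for `method = "nn"`).
#'
#' @return The input tibble with columns `method`, `s0_hat`, `t2_hat`,
#'   `offset_hat`, `converged`, `fallback` appended.
#'
#' @examples
#' d <- simulate_fixed_snr(5, snr = 10, seed = 1)
#' fit_decays(d, "lse")
#' @export
fit_decays <- function(data, method = c("lse", "olse", "nclse", "nn"),
                       sigma_known = NULL, model = NULL) {
  method <- rlang::arg_match(method)
  if (method == "nn") {
    if (is.null(model)) rlang::abort("`model` is required for method = \"nn\".")
    pred <- stats::predict(model, data)
    return(dplyr::bind_cols(data, pred))
  }
  fits <- switch(method,
    lse = purrr::map2(data$te, data$magnitude, fit_lse),
    olse = purrr::map2(data$te, data$magnitude, fit_olse),
    nclse = {
      sg <- if (!is.null(sigma_known)) rep_len(sigma_known, nrow(data)) else data$sigma
      if (is.null(sg)) {
        rlang::abort("NCLSE needs `sigma_known` or a `sigma` column.",
                     class = "t2relax_invalid_input")
      }
      purrr::pmap(list(data$te, data$magnitude, sg), fit_nclse)
    }
  )
  dplyr::bind_cols(data, purrr::list_rbind(fits))
}
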