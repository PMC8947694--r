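#' Plot an SNR-resolved error table
#'
#' Median ARQE per method as a function of SNR, with the 2.5th-97.5th
#' percentile band. The accuracy of every estimator improves (error
#' decreases) with SNR; methods separate most at low SNR.
#'
#' @param object A `t2_error_table` from [error_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.t2_error_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$snr, y = .data$median_arqe,
                                       colour = .data$method, group = .data$method)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$`arqe_p2.5`,
                                      ymax = .data$`arqe_p97.5`,
                                      fill = .data$method),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "SNR", y = "ARQE [%]",
                  colour = "Method", fill = "Method",
                  title = "T2 quantification error vs SNR",
                  subtitle = "Median with 2.5th-97.5th percentile band") +
    ggplot2::theme_minimal()
}

#' Plot a quantitative map
#'
#' Renders the fitted (or true) T2 or S0 map as a raster image; out-of-mask
#' voxels are blank.
#'
#' @param object A `quant_map`.
#' @param what `"t2"` or `"s0"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.quant_map <- function(object, what = c("t2", "s0"), ...) {
  what <- rlang::arg_match(what)
  vox <- tidy.quant_map(object, masked_only = FALSE)
  if (!what %in% names(vox)) {
    rlang::abort(sprintf("Map has no `%s` values; fit it first.", what))
  }
  vox$value <- ifelse(vox$mask, vox[[what]], NA_real_)
  ggplot2::ggplot(vox, ggplot2::aes(x = .data$col, y = .data$row,
                                    fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(fill = if (what == "t2") "T2 [ms]" else "S0 [a.u.]",
                  x = NULL, y = NULL,
                  title = sprintf("%s map%s", toupper(what),
                                  if (!is.null(object$method))
                                    paste0(" (", object$method, ")") else "")) +
    ggplot2::theme_minimal()
}

#' Plot a measured decay with fitted curves
#'
#' Shows the measured magnitudes of one echo train and, optionally, the
#' decay curves implied by one or more fit results.
#'
#' @param te Echo times, ms.
#' @param magnitude Measured magnitudes.
#' @param fits Optional fit tibble(s) (rows from [fit_lse()] and friends);
#'   one curve per row, labelled by `method`.
#' @return A ggplot object.
#' @export
plot_decay <- function(te, magnitude, fits = NULL) {
  obs <- tibble::tibble(te = te, magnitude = magnitude)
  p <- ggplot2::ggplot(obs, ggplot2::aes(x = .data$te, y = .data$magnitude)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "TE [ms]", y = "Magnitude [a.u.]") +
    ggplot2::theme_minimal()
  if (!is.null(fits)) {
    grid <- seq(0, max(te), length.out = 200)
    curves <- purrr::pmap(
      list(fits$s0_hat, fits$t2_hat,
           ifelse(is.na(fits$offset_hat), 0, fits$offset_hat),
           fits$method),
      function(s0, t2, c0, m) {
        tibble::tibble(te = grid, magnitude = s0 * exp(-grid / t2) + c0, method = m)
      }) |> purrr::list_rbind()
    p <- p + ggplot2::geom_line(
      data = curves,
      ggplot2::aes(colour = .data$method)
    ) + ggplot2::labs(colour = "Method")
  }
  p
}
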