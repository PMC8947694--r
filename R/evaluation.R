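#' Relative T2 quantification error
#'
#' `rqe()` is the signed relative error in percent,
#' \eqn{(T_{2,pred} - T_{2,ref}) / T_{2,ref} \times 100}; positive values
#' indicate overestimation of the reference. `arqe()` is its absolute value,
#' which prevents positive and negative errors cancelling when summarized.
#'
#' @param t2_pred Predicted T2 values, ms.
#' @param t2_ref Reference (true) T2 values, ms; must be > 0.
#'
#' @return Numeric vector of errors in percent.
#'
#' @examples
#' rqe(62, 50)   # +24
#' arqe(40, 50)  # 20
#' @export
rqe <- function(t2_pred, t2_ref) {
  if (any(t2_ref <= 0, na.rm = TRUE)) {
    rlang::abort("`t2_ref` must be strictly positive.",
                 class = "t2relax_invalid_input")
  }
  (t2_pred - t2_ref) / t2_ref * 100
}

#' @rdname rqe
#' @export
arqe <- function(t2_pred, t2_ref) {
  abs(rqe(t2_pred, t2_ref))
}

#' Mood's median test
#'
#' Nonparametric comparison of two group medians. Both samples are pooled;
#' each observation is classified as above or not-above the pooled grand
#' median (ties with the grand median count in the "not above" cell), and
#' independence of the resulting 2x2 contingency table is tested by a
#' chi-square test without continuity correction.
#'
#' When used for post-hoc comparisons of several fitting methods against a
#' common baseline, lower the significance threshold accordingly (e.g.
#' 0.05 / 3 with three comparisons).
#'
#' @param x,y Numeric samples (each of length >= 2).
#'
#' @return An object of class `htest` with the chi-square `statistic`,
#'   `parameter` (df), `p.value`, the grand median (`estimate`) and the
#'   contingency table in `observed`.
#'
#' @examples
#' moods_median_test(c(1, 2, 3, 4), c(5, 6, 7, 8))
#' @export
moods_median_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    rlang::abort("Each group needs at least 2 observations.",
                 class = "t2relax_invalid_input")
  }
  gm <- stats::median(c(x, y))
  tab <- rbind(
    x = c(above = sum(x > gm), not_above = sum(x <= gm)),
    y = c(above = sum(y > gm), not_above = sum(y <= gm))
  )
  if (any(colSums(tab) == 0)) {
    rlang::abort("Degenerate contingency table: all values tied at the grand median.",
                 class = "t2relax_degenerate_table")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(
    list(statistic = ct$statistic, parameter = ct$parameter,
         p.value = ct$p.value,
         estimate = c(`grand median` = gm),
         observed = tab,
         method = "Mood's median test (chi-square, no continuity correction)",
         data.name = paste(deparse(substitute(x)), "and", deparse(substitute(y)))),
    class = "htest"
  )
}

#' Summarize T2 quantification errors per method and SNR
#'
#' Builds the SNR-resolved error table: per `(method, snr)` cell, the median
#' and IQR of the signed relative error (RQE), the median of the absolute
#' relative error (ARQE) with its 2.5th and 97.5th percentiles, and the cell
#' size. Percentiles use linear interpolation between order statistics
#' (`quantile()` type 7).
#'
#' The reference is the column named by `ref` (by default the simulation
#' truth `t2`); in image mode pass the high-SNR reference fit instead (see
#' [compare_to_reference()]). Rows with a non-finite reference are dropped
#' with a message.
#'
#' @param data A fitted decay tibble (from [fit_decays()]) containing
#'   `t2_hat`, `method` and the reference column, or a voxel comparison from
#'   [compare_to_reference()] containing `t2_pred`/`t2_ref`.
#' @param ref Name of the reference column (default `"t2"`).
#' @param snr_bins Optional numeric vector of bin edges used to bin a
#'   heterogeneous-SNR set; by default the exact `snr` values group the
#'   table (appropriate for fixed-SNR sets).
#'
#' @return A tibble of class `t2_error_table` with columns `method`, `snr`,
#'   `n`, `median_rqe`, `iqr_rqe`, `median_arqe`, `arqe_p2.5`, `arqe_p97.5`.
#'
#' @examples
#' d <- fit_decays(simulate_fixed_snr(200, snr = 10, seed = 1), "lse")
#' error_table(d)
#' @export
error_table <- function(data, ref = "t2", snr_bins = NULL) {
  if ("t2_pred" %in% names(data) && !"t2_hat" %in% names(data)) {
    data <- dplyr::rename(data, t2_hat = "t2_pred")
    if (!ref %in% names(data) && "t2_ref" %in% names(data)) ref <- "t2_ref"
  }
  if (!all(c("t2_hat", ref) %in% names(data))) {
    rlang::abort(sprintf("`data` must contain `t2_hat` and `%s`.", ref),
                 class = "t2relax_invalid_input")
  }
  refv <- data[[ref]]
  bad <- !is.finite(refv)
  if (any(bad)) {
    message(sprintf("Dropping %d row(s) with non-finite reference T2.", sum(bad)))
    data <- data[!bad, ]
    refv <- refv[!bad]
  }
  data$.rqe <- rqe(data$t2_hat, refv)
  if (!"method" %in% names(data)) data$method <- "fit"
  if (!is.null(snr_bins)) {
    data$snr <- cut(data$snr, snr_bins)
  } else if (!"snr" %in% names(data)) {
    data$snr <- NA
  }
  empty_warned <- FALSE
  out <- data |>
    dplyr::group_by(.data$method, .data$snr) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_rqe = stats::median(.data$.rqe),
      iqr_rqe = stats::IQR(.data$.rqe),
      median_arqe = stats::median(abs(.data$.rqe)),
      `arqe_p2.5` = stats::quantile(abs(.data$.rqe), 0.025, names = FALSE),
      `arqe_p97.5` = stats::quantile(abs(.data$.rqe), 0.975, names = FALSE),
      .groups = "drop"
    )
  if (!is.null(snr_bins) && anyNA(out$snr)) {
    warning("Some samples fell outside `snr_bins` and were omitted.")
    out <- out[!is.na(out$snr), ]
  }
  class(out) <- c("t2_error_table", class(out))
  out
}

#' Render an error table as aligned text
#'
#' Formats an error table in the conventional layout: one row per method,
#' one column per SNR, cells as `median [p2.5, p97.5]` of the ARQE.
#'
#' @param x A `t2_error_table`.
#' @param digits Number of digits for the cells.
#' @return A character vector of lines, invisibly; printed as a side effect.
#' @export
format_error_table <- function(x, digits = 0) {
  fmt <- function(m, lo, hi) sprintf("%.*f [%.*f, %.*f]", digits, m, digits, lo, digits, hi)
  wide <- x |>
    dplyr::mutate(cell = fmt(.data$median_arqe, .data$`arqe_p2.5`, .data$`arqe_p97.5`)) |>
    dplyr::select("method", "snr", "cell") |>
    tidyr::pivot_wider(names_from = "snr", values_from = "cell",
                       names_prefix = "SNR = ")
  lines <- utils::capture.output(print(as.data.frame(wide), row.names = FALSE))
  cat(lines, sep = "\n")
  invisible(lines)
}
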