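#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data %||%
NULL

#' Tidy the training log of a fitted network
#'
#' @param x A `t2net`.
#' @param ... Unused.
#' @return A tibble with one row per epoch: `epoch`, `train_loss`,
#'   `val_loss`, and `selected` marking the checkpoint that was kept.
#' @export
tidy.t2net <- function(x, ...) {
  dplyr::mutate(x$log, selected = .data$epoch == x$best_epoch)
}

#' One-row summary of a fitted network
#'
#' @param x A `t2net`.
#' @param ... Unused.
#' @return A one-row tibble: parameter count, epochs run, selected epoch and
#'   its validation loss.
#' @export
glance.t2net <- function(x, ...) {
  tibble::tibble(
    n_parameters = n_parameters(x),
    epochs = nrow(x$log),
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss
  )
}

#' Tidy a quantitative map into a voxel tibble
#'
#' @param x A `quant_map`.
#' @param masked_only Keep only in-mask voxels?
#' @param ... Unused.
#' @return A tibble with `row`, `col`, `mask`, and any available `s0`, `t2`
#'   values per voxel.
#' @export
tidy.quant_map <- function(x, masked_only = TRUE, ...) {
  d <- dim(x$mask)
  out <- tibble::tibble(
    row = rep(seq_len(d[1]), d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    mask = as.vector(x$mask)
  )
  if (!is.null(x$s0)) out$s0 <- as.vector(x$s0)
  if (!is.null(x$t2)) out$t2 <- as.vector(x$t2)
  if (masked_only) out <- out[out$mask, ]
  out
}

#' One-row summary of a quantitative map
#'
#' @param x A `quant_map`.
#' @param ... Unused.
#' @return A one-row tibble: grid size, echo count and range, masked voxel
#'   count, method tag, fallback count (if fitted).
#' @export
glance.quant_map <- function(x, ...) {
  tibble::tibble(
    rows = dim(x$stack)[1], cols = dim(x$stack)[2],
    n_echoes = length(x$te),
    te_min = min(x$te), te_max = max(x$te),
    n_masked = sum(x$mask),
    method = x$method %||% NA_character_,
    n_fallback = attr(x, "n_fallback") %||% NA_integer_
  )
}
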