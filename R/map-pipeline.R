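#' Construct a quantitative map container
#'
#' A `quant_map` bundles a multi-echo magnitude image stack with its echo
#' times, a binary mask, and (after fitting, or for simulated truth) the
#' per-voxel S0 and T2 maps. Maps are defined only inside the mask;
#' out-of-mask voxels hold `NA`.
#'
#' @param stack Numeric array `rows x cols x n_echoes` of magnitudes.
#' @param te Echo times in ms, strictly increasing, one per stack plane.
#' @param mask Logical matrix `rows x cols`.
#' @param s0,t2 Optional parameter maps (matrices).
#' @param sigma Optional noise level: a scalar or a per-voxel matrix.
#' @param method Tag of the method that produced the maps.
#'
#' @return A list of class `quant_map`.
#' @export
quant_map <- function(stack, te, mask, s0 = NULL, t2 = NULL,
                      sigma = NULL, method = NULL) {
  stopifnot(length(dim(stack)) == 3, dim(stack)[3] == length(te))
  if (any(diff(te) <= 0)) {
    rlang::abort("`te` must be strictly increasing.", class = "t2relax_invalid_input")
  }
  if (!is.logical(mask) || !all(dim(mask) == dim(stack)[1:2])) {
    rlang::abort("`mask` must be a logical matrix matching the stack grid.",
                 class = "t2relax_invalid_input")
  }
  if (min(stack, na.rm = TRUE) < 0) {
    rlang::abort("Magnitude stack must be non-negative.", class = "t2relax_invalid_input")
  }
  structure(
    list(stack = stack, te = te, mask = mask, s0 = s0, t2 = t2,
         sigma = sigma, method = method),
    class = "quant_map"
  )
}

#' @export
print.quant_map <- function(x, ...) {
  cat(sprintf("quant_map: %d x %d grid, %d echoes (%g..%g ms), %d masked voxels%s\n",
              dim(x$stack)[1], dim(x$stack)[2], length(x$te),
              min(x$te), max(x$te), sum(x$mask),
              if (!is.null(x$method)) paste0(", method: ", x$method) else ""))
  invisible(x)
}

#' Synthetic cartilage-like T2 phantom
#'
#' Builds an annular band emulating articular cartilage on a bone: within
#' the band, T2 increases linearly with depth from the inner (bone)
#' interface to the outer (fluid) interface across `t2_range`, the
#' characteristic depth-wise stratification of cartilage. S0 is constant
#' inside the band and 0 outside. The multi-echo stack (by default 7 echoes
#' at 10..70 ms) is evaluated from the truth maps and corrupted with Rician
#' noise of standard deviation `sigma`.
#'
#' @param shape Grid size, `c(rows, cols)`, each >= 16.
#' @param t2_range Depth-wise T2 range `c(inner, outer)` in ms.
#' @param s0_level Apparent proton density inside the band.
#' @param sigma Per-channel noise standard deviation (0 gives a noise-free
#'   stack).
#' @param te Echo times in ms.
#' @param seed Optional integer seed applied locally to the noise draw.
#'
#' @return A list with elements `truth` (a `quant_map` holding the
#'   noise-free stack and the true S0/T2 maps) and `noisy` (the same
#'   geometry with the Rician-corrupted stack).
#'
#' @examples
#' ph <- make_phantom(shape = c(32, 32), sigma = 50, seed = 1)
#' ph$noisy
#' @export
make_phantom <- function(shape = c(64, 64), t2_range = c(20, 60),
                         s0_level = 500, sigma = 0,
                         te = seq(10, 70, by = 10), seed = NULL) {
  if (any(shape < 16)) {
    rlang::abort("`shape` must be at least 16 x 16.", class = "t2relax_invalid_input")
  }
  if (sigma < 0) {
    rlang::abort("`sigma` must be non-negative.", class = "t2relax_invalid_parameter")
  }
  r <- shape[1]; cl <- shape[2]
  cx <- (r + 1) / 2; cy <- (cl + 1) / 2
  rad <- sqrt(outer((seq_len(r) - cx)^2, (seq_len(cl) - cy)^2, "+"))
  r_out <- 0.45 * min(shape)
  r_in <- 0.25 * min(shape)
  mask <- rad >= r_in & rad <= r_out
  depth <- pmin(pmax((rad - r_in) / (r_out - r_in), 0), 1)
  t2_map <- matrix(NA_real_, r, cl)
  t2_map[mask] <- t2_range[1] + depth[mask] * diff(t2_range)
  s0_map <- matrix(NA_real_, r, cl)
  s0_map[mask] <- s0_level

  ne <- length(te)
  clean <- array(0, c(r, cl, ne))
  for (k in seq_len(ne)) {
    plane <- matrix(0, r, cl)
    plane[mask] <- s0_level * exp(-te[k] / t2_map[mask])
    clean[, , k] <- plane
  }
  noisy_stack <- if (sigma == 0) clean else {
    array(add_rician_noise(as.vector(clean), sigma, seed = seed), dim(clean))
  }
  list(
    truth = quant_map(clean, te, mask, s0 = s0_map, t2 = t2_map,
                      sigma = 0, method = "truth"),
    noisy = quant_map(noisy_stack, te, mask, sigma = sigma)
  )
}

#' Fit a parameter map voxel-wise
#'
#' Applies one of the estimators to every voxel inside the mask of a
#' `quant_map` and returns a new `quant_map` carrying the fitted S0 and T2
#' maps. Out-of-mask voxels are `NA`. The number of voxels that hit the
#' optimizer fallback is stored in the `n_fallback` attribute of the result
#' and reported with a message when non-zero.
#'
#' For `method = "nclse"`, `sigma` may be a scalar or a per-voxel matrix
#' (an externally estimated noise map); by default the `sigma` stored in
#' the map is used.
#'
#' @param map_in A `quant_map`.
#' @param method `"lse"`, `"olse"`, `"nclse"`, or `"nn"`.
#' @param sigma Noise level(s) for `"nclse"`.
#' @param model A trained `t2net` for `"nn"`.
#'
#' @return A fitted `quant_map`.
#'
#' @examples
#' ph <- make_phantom(shape = c(16, 16))
#' fit_map(ph$noisy, "lse")
#' @export
fit_map <- function(map_in, method = c("lse", "olse", "nclse", "nn"),
                    sigma = NULL, model = NULL) {
  method <- rlang::arg_match(method)
  if (sum(map_in$mask) == 0) {
    rlang::abort("Mask is empty.", class = "t2relax_invalid_input")
  }
  idx <- which(map_in$mask, arr.ind = TRUE)
  n <- nrow(idx)
  mags <- lapply(seq_len(n), function(i) map_in$stack[idx[i, 1], idx[i, 2], ])
  vox <- tibble::tibble(
    te = rep(list(map_in$te), n),
    magnitude = mags
  )
  if (method == "nclse") {
    sg <- if (!is.null(sigma)) sigma else map_in$sigma
    if (is.null(sg)) {
      rlang::abort("NCLSE needs a `sigma` (scalar or per-voxel map).",
                   class = "t2relax_invalid_input")
    }
    vox$sigma <- if (is.matrix(sg)) sg[idx] else rep_len(sg, n)
    fits <- fit_decays(vox, "nclse")
  } else {
    fits <- fit_decays(vox, method, model = model)
  }
  shape <- dim(map_in$stack)[1:2]
  t2_map <- matrix(NA_real_, shape[1], shape[2])
  s0_map <- matrix(NA_real_, shape[1], shape[2])
  t2_map[idx] <- fits$t2_hat
  s0_map[idx] <- fits$s0_hat
  out <- quant_map(map_in$stack, map_in$te, map_in$mask,
                   s0 = s0_map, t2 = t2_map, sigma = map_in$sigma,
                   method = method)
  n_fb <- sum(fits$fallback)
  attr(out, "n_fallback") <- n_fb
  if (n_fb > 0) message(sprintf("%d voxel(s) used the fallback result.", n_fb))
  out
}

#' Compare a fitted map to a reference map voxel-wise
#'
#' Computes the signed and absolute relative T2 quantification error of a
#' (typically low-SNR) fitted map against a reference map (typically the
#' traditional fit of a high-SNR acquisition of the same geometry), inside
#' the common mask. Results from several specimens can be concatenated
#' with `dplyr::bind_rows()` before summarizing.
#'
#' @param low_snr_fit,reference_fit Fitted `quant_map`s on the same grid.
#' @param mask Optional logical matrix overriding the maps' common mask.
#'
#' @return A tibble with one row per masked voxel: `row`, `col`, `method`,
#'   `t2_pred`, `t2_ref`, `rqe`, `arqe`. Feed it to [error_table()] for the
#'   summary.
#'
#' @examples
#' ph <- make_phantom(shape = c(16, 16))
#' f <- fit_map(ph$noisy, "lse")
#' compare_to_reference(f, f)  # self-comparison: all-zero errors
#' @export
compare_to_reference <- function(low_snr_fit, reference_fit, mask = NULL) {
  if (!all(dim(low_snr_fit$t2) == dim(reference_fit$t2))) {
    rlang::abort("Maps are not on the same grid.", class = "t2relax_invalid_input")
  }
  if (is.null(mask)) {
    if (!identical(low_snr_fit$mask, reference_fit$mask)) {
      rlang::abort("Masks differ; pass an explicit `mask`.",
                   class = "t2relax_invalid_input")
    }
    mask <- low_snr_fit$mask
  }
  idx <- which(mask, arr.ind = TRUE)
  pred <- low_snr_fit$t2[idx]
  ref <- reference_fit$t2[idx]
  keep <- is.finite(ref)
  if (any(!keep)) {
    message(sprintf("Dropping %d voxel(s) with non-finite reference.", sum(!keep)))
  }
  tibble::tibble(
    row = idx[keep, 1], col = idx[keep, 2],
    method = low_snr_fit$method %||% "fit",
    t2_pred = pred[keep], t2_ref = ref[keep],
    rqe = rqe(pred[keep], ref[keep]),
    arqe = arqe(pred[keep], ref[keep])
  )
}

#' Wall-clock timing of map fitting methods
#'
#' Runs each requested method on the same map several times and reports the
#' mean elapsed seconds. Timings are hardware-dependent and informational
#' only.
#'
#' @param map_in A `quant_map`.
#' @param methods Character vector of method tags.
#' @param repeats Number of repetitions per method (>= 1).
#' @param sigma,model Passed through to [fit_map()] as needed.
#'
#' @return A tibble with columns `method`, `mean_seconds`, `repeats`.
#' @export
timing_harness <- function(map_in, methods, repeats = 3, sigma = NULL,
                           model = NULL) {
  if (repeats < 1) rlang::abort("`repeats` must be >= 1.")
  rows <- lapply(methods, function(m) {
    secs <- vapply(seq_len(repeats), function(i) {
      unname(system.time(
        suppressMessages(fit_map(map_in, m, sigma = sigma, model = model))
      )["elapsed"])
    }, numeric(1))
    tibble::tibble(method = m, mean_seconds = mean(secs), repeats = repeats)
  })
  purrr::list_rbind(rows)
}

#' NIfTI import/export for echo stacks and parameter maps
#'
#' `write_echo_stack()` writes the magnitude stack as a 4D NIfTI volume
#' (echo as the 4th axis), the mask as a NIfTI volume, and the echo times
#' as a JSON sidecar (NIfTI has no echo-time field). `read_echo_stack()`
#' reads them back into a `quant_map`. `write_quant_map()` writes fitted
#' `T2.nii.gz` and `S0.nii.gz` maps (out-of-mask voxels stored as `NaN`).
#'
#' @param qm A `quant_map`.
#' @param dir Output directory (created if missing).
#' @param stack_path,tes_path,mask_path Paths written by `write_echo_stack`.
#'
#' @return The directory (writers, invisibly) or a `quant_map` (reader).
#' @export
write_echo_stack <- function(qm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(qm$stack)
  RNifti::writeNifti(array(qm$stack, c(d[1], d[2], 1, d[3])),
                     file.path(dir, "stack.nii.gz"))
  RNifti::writeNifti(array(as.numeric(qm$mask), c(dim(qm$mask), 1)),
                     file.path(dir, "mask.nii.gz"))
  jsonlite::write_json(list(te_ms = qm$te, sigma = qm$sigma),
                       file.path(dir, "tes.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_echo_stack
#' @export
read_echo_stack <- function(stack_path, tes_path, mask_path) {
  arr <- as.array(RNifti::readNifti(stack_path))
  d <- dim(arr)
  stack <- array(arr, c(d[1], d[2], d[length(d)]))
  side <- jsonlite::read_json(tes_path, simplifyVector = TRUE)
  m <- as.array(RNifti::readNifti(mask_path))
  mask <- matrix(as.logical(m), dim(m)[1], dim(m)[2])
  quant_map(stack, side$te_ms, mask, sigma = side$sigma)
}

#' @rdname write_echo_stack
#' @export
write_quant_map <- function(qm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  to_nan <- function(m) { m[is.na(m)] <- NaN; m }
  RNifti::writeNifti(to_nan(qm$t2), file.path(dir, "T2.nii.gz"))
  RNifti::writeNifti(to_nan(qm$s0), file.path(dir, "S0.nii.gz"))
  invisible(dir)
}
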