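#' Architecture of the fully connected T2 regressor
#'
#' The network is a plain multilayer perceptron: an input of 30 values (15
#' signal magnitudes then 15 echo times, each padded with `pad_value` when
#' fewer than 15 echoes are available), five 512-wide hidden layers with
#' leaky-ReLU activations, and a 2-unit output layer (S0, T2) with a ReLU
#' activation so estimates are non-negative by construction. That is six
#' weight layers in total, about 1.07 million trainable parameters.
#'
#' Counting convention: "six layers deep" is read here as six *weight*
#' layers including the output layer; counting the output layer separately
#' (i.e. six 512-wide hidden layers) would give ~1.33 million parameters,
#' outside the intended ~1 million budget.
#'
#' No input normalization is applied: raw magnitudes and echo times (ms)
#' are fed directly, matching the scale of the -1 padding sentinel.
#'
#' @param width Hidden layer width.
#' @param n_hidden Number of hidden (leaky-ReLU) layers.
#' @param max_echoes Maximum echo-train length the input encoding holds.
#' @param pad_value Padding sentinel for missing echoes.
#' @param negative_slope Slope of the leaky ReLU for negative inputs.
#'
#' @return A list of class `network_spec`; its `dims` element gives the
#'   layer dimensions, e.g. `c(30, 512, 512, 512, 512, 512, 2)`.
#'
#' @examples
#' network_spec()
#' @export
network_spec <- function(width = 512, n_hidden = 5, max_echoes = 15,
                         pad_value = -1, negative_slope = 0.01) {
  structure(
    list(width = width, n_hidden = n_hidden, max_echoes = max_echoes,
         pad_value = pad_value, negative_slope = negative_slope,
         dims = c(2L * max_echoes, rep(width, n_hidden), 2L)),
    class = "network_spec"
  )
}

#' Training configuration for the T2 regressor
#'
#' Mini-batch Adam with the SmoothL1 (Huber) loss on the `(S0, T2)` pair,
#' averaged over both outputs. After each epoch the loss on the validation
#' set is computed and the weights with the lowest validation loss are the
#' ones returned.
#'
#' @param epochs Number of passes over the training set.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param huber_beta Transition point of the SmoothL1 loss.
#'
#' @return A list of class `train_config`.
#' @examples
#' train_config(epochs = 5)
#' @export
train_config <- function(epochs = 3, batch_size = 1024,
                         learning_rate = 1e-3, huber_beta = 1) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0, huber_beta > 0)
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, huber_beta = huber_beta),
    class = "train_config"
  )
}

#' Encode echo trains as fixed-length network inputs
#'
#' Packs each decay into a vector of `2 * width` values: positions
#' `1..n_echoes` hold the magnitudes, positions `width+1 .. width+n_echoes`
#' the echo times (ms), and every remaining position holds the padding
#' sentinel.
#'
#' @param data A decay tibble with list-columns `te` and `magnitude`.
#' @param width Maximum echo count (input is `2 * width` wide).
#' @param pad_value Padding sentinel.
#'
#' @return A numeric matrix with one row per decay.
#'
#' @examples
#' encode_echo_trains(simulate_decays(c(test = 3), seed = 1))
#' @export
encode_echo_trains <- function(data, width = 15, pad_value = -1) {
  n_echoes <- lengths(data$magnitude)
  if (any(n_echoes > width)) {
    rlang::abort(sprintf("Echo trains longer than %d are not supported.", width),
                 class = "t2relax_invalid_input")
  }
  n <- nrow(data)
  x <- matrix(pad_value, n, 2 * width)
  for (i in seq_len(n)) {
    k <- n_echoes[i]
    x[i, seq_len(k)] <- data$magnitude[[i]]
    x[i, width + seq_len(k)] <- data$te[[i]]
  }
  x
}

#' Decode a padded network input back into echo trains
#'
#' Inverse of [encode_echo_trains()] on valid inputs.
#'
#' @param x Matrix (or vector) of encoded inputs.
#' @param width Maximum echo count used in the encoding.
#' @param pad_value Padding sentinel used in the encoding.
#'
#' @return A tibble with list-columns `te`, `magnitude` and column
#'   `n_echoes`.
#' @export
decode_network_input <- function(x, width = 15, pad_value = -1) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  mag <- x[, seq_len(width), drop = FALSE]
  te <- x[, width + seq_len(width), drop = FALSE]
  n_echoes <- rowSums(te != pad_value)
  tibble::tibble(
    n_echoes = as.integer(n_echoes),
    te = lapply(seq_len(nrow(x)), function(i) te[i, seq_len(n_echoes[i])]),
    magnitude = lapply(seq_len(nrow(x)), function(i) mag[i, seq_len(n_echoes[i])])
  )
}

init_weights <- function(dims) {
  W <- vector("list", length(dims) - 1)
  b <- vector("list", length(dims) - 1)
  for (l in seq_along(W)) {
    k <- 1 / sqrt(dims[l])
    W[[l]] <- matrix(stats::runif(dims[l] * dims[l + 1], -k, k), dims[l], dims[l + 1])
    b[[l]] <- stats::runif(dims[l + 1], -k, k)
  }
  list(W = W, b = b)
}

net_forward <- function(weights, X, slope, keep = FALSE) {
  L <- length(weights$W)
  A <- X
  Zs <- if (keep) vector("list", L) else NULL
  acts <- if (keep) vector("list", L) else NULL
  for (l in seq_len(L)) {
    if (keep) acts[[l]] <- A
    Z <- sweep(A %*% weights$W[[l]], 2, weights$b[[l]], "+")
    A <- if (l < L) Z * ((Z > 0) + slope * (Z <= 0)) else Z * (Z > 0)
    if (keep) Zs[[l]] <- Z
  }
  if (keep) list(out = A, Zs = Zs, acts = acts) else A
}

huber_loss <- function(d, beta) {
  a <- abs(d)
  mean(ifelse(a < beta, 0.5 * a^2 / beta, a - 0.5 * beta))
}

batched_val_loss <- function(weights, x, y, slope, beta, batch = 8192) {
  n <- nrow(x)
  tot <- 0
  for (start in seq(1, n, by = batch)) {
    idx <- start:min(start + batch - 1, n)
    out <- net_forward(weights, x[idx, , drop = FALSE], slope)
    d <- abs(out - y[idx, , drop = FALSE])
    tot <- tot + sum(ifelse(d < beta, 0.5 * d^2 / beta, d - 0.5 * beta))
  }
  tot / (2 * n)
}

as_xy <- function(data, spec) {
  if (is.list(data) && !is.data.frame(data) && !is.null(data$x)) {
    return(data)
  }
  if (!all(c("s0", "t2") %in% names(data))) {
    rlang::abort("Training data need `s0` and `t2` truth columns.")
  }
  if (any(data$s0 == 0)) {
    rlang::abort("Samples with s0 = 0 must be excluded from training.")
  }
  list(x = encode_echo_trains(data, spec$max_echoes, spec$pad_value),
       y = cbind(data$s0, data$t2))
}

#' Train the fully connected T2 regressor on synthetic decays
#'
#' Runs mini-batch Adam on the Huber loss between predicted and true
#' `(S0, T2)`, evaluating the validation loss after every epoch; the
#' weights from the epoch with the lowest validation loss are returned.
#' Training is fully deterministic given `seed`.
#'
#' @param train_data,val_data Decay tibbles (with `s0`, `t2` truth columns),
#'   or lists `list(x = <n x 30 matrix>, y = <n x 2 matrix>)`.
#' @param spec A [network_spec()].
#' @param config A [train_config()].
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @param verbose Print per-epoch losses?
#'
#' @return An object of class `t2net`: weights, spec, config, the per-epoch
#'   training log, and the index of the selected epoch.
#'
#' @examples
#' \donttest{
#' tr <- simulate_decays(c(train = 2000), seed = 1)
#' va <- simulate_decays(c(val = 500), seed = 2)
#' net <- train_t2net(tr, va, config = train_config(epochs = 2), seed = 3)
#' }
#' @export
train_t2net <- function(train_data, val_data, spec = network_spec(),
                        config = train_config(), seed = 1, verbose = FALSE) {
  tr <- as_xy(train_data, spec)
  va <- as_xy(val_data, spec)
  if (nrow(tr$x) == 0 || nrow(va$x) == 0) {
    rlang::abort("Training and validation sets must be non-empty.")
  }
  slope <- spec$negative_slope
  beta <- config$huber_beta
  lr <- config$learning_rate
  withr::with_seed(seed, {
    weights <- init_weights(spec$dims)
    L <- length(weights$W)
    mW <- lapply(weights$W, function(w) w * 0); vW <- mW
    mb <- lapply(weights$b, function(x) x * 0); vb <- mb
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
    n <- nrow(tr$x)
    log <- vector("list", config$epochs)
    best_val <- Inf
    best_weights <- weights
    best_epoch <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      n_batch <- 0L
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        X <- tr$x[idx, , drop = FALSE]
        Y <- tr$y[idx, , drop = FALSE]
        f <- net_forward(weights, X, slope, keep = TRUE)
        d <- f$out - Y
        if (!all(is.finite(d))) {
          rlang::abort("Training diverged: non-finite loss.",
                       class = "t2relax_training_diverged")
        }
        ep_loss <- ep_loss + huber_loss(d, beta)
        n_batch <- n_batch + 1L
        # Huber gradient, averaged over all elements of the (S0, T2) pair
        G <- pmin(pmax(d / beta, -1), 1) / length(d)
        t <- t + 1
        dZ <- G * (f$Zs[[L]] > 0)
        for (l in L:1) {
          dW <- crossprod(f$acts[[l]], dZ)
          db <- colSums(dZ)
          if (l > 1) {
            dA <- tcrossprod(dZ, weights$W[[l]])
            Zp <- f$Zs[[l - 1]]
            dZ <- dA * ((Zp > 0) + slope * (Zp <= 0))
          }
          mW[[l]] <- b1 * mW[[l]] + (1 - b1) * dW
          vW[[l]] <- b2 * vW[[l]] + (1 - b2) * dW^2
          mb[[l]] <- b1 * mb[[l]] + (1 - b1) * db
          vb[[l]] <- b2 * vb[[l]] + (1 - b2) * db^2
          weights$W[[l]] <- weights$W[[l]] -
            lr * (mW[[l]] / (1 - b1^t)) / (sqrt(vW[[l]] / (1 - b2^t)) + eps)
          weights$b[[l]] <- weights$b[[l]] -
            lr * (mb[[l]] / (1 - b1^t)) / (sqrt(vb[[l]] / (1 - b2^t)) + eps)
        }
      }
      val <- batched_val_loss(weights, va$x, va$y, slope, beta)
      log[[ep]] <- tibble::tibble(epoch = ep, train_loss = ep_loss / n_batch,
                                  val_loss = val)
      if (val < best_val) {
        best_val <- val
        best_weights <- weights
        best_epoch <- ep
      }
      if (verbose) {
        message(sprintf("epoch %d  train %.4f  val %.4f", ep,
                        ep_loss / n_batch, val))
      }
    }
    structure(
      list(weights = best_weights, spec = spec, config = config, seed = seed,
           log = purrr::list_rbind(log), best_epoch = best_epoch,
           best_val_loss = best_val),
      class = "t2net"
    )
  })
}

#' Number of trainable parameters of a network
#'
#' @param x A `t2net` or `network_spec`.
#' @return Integer count of weights plus biases.
#' @examples
#' n_parameters(network_spec())
#' @export
n_parameters <- function(x) {
  dims <- if (inherits(x, "t2net")) x$spec$dims else x$dims
  sum(dims[-length(dims)] * dims[-1]) + sum(dims[-1])
}

#' Predict S0 and T2 for a batch of echo trains
#'
#' Deterministic forward pass of a trained network. Each sample is
#' processed independently, so predictions do not depend on batch
#' composition or ordering. Outputs are non-negative by construction
#' (output-layer ReLU).
#'
#' @param object A trained `t2net`.
#' @param newdata A decay tibble (list-columns `te`, `magnitude`) or an
#'   encoded input matrix.
#' @param batch_size Internal forward-pass chunk size.
#' @param ... Unused.
#'
#' @return A tibble with columns `method` (`"nn"`), `s0_hat`, `t2_hat`,
#'   `offset_hat` (`NA`), `converged`, `fallback`.
#' @export
predict.t2net <- function(object, newdata, batch_size = 8192, ...) {
  x <- if (is.matrix(newdata)) newdata
       else encode_echo_trains(newdata, object$spec$max_echoes, object$spec$pad_value)
  n <- nrow(x)
  out <- matrix(NA_real_, n, 2)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    out[idx, ] <- net_forward(object$weights, x[idx, , drop = FALSE],
                              object$spec$negative_slope)
  }
  tibble::tibble(method = "nn", s0_hat = out[, 1], t2_hat = out[, 2],
                 offset_hat = NA_real_, converged = TRUE, fallback = FALSE)
}

#' @export
print.t2net <- function(x, ...) {
  cat(sprintf(
    "Fully connected T2 regressor: dims %s, %s parameters\n  selected epoch %d/%d (val loss %.4f)\n",
    paste(x$spec$dims, collapse = "-"),
    format(n_parameters(x), big.mark = ","),
    x$best_epoch, nrow(x$log), x$best_val_loss))
  invisible(x)
}

#' Save / load a trained network as JSON
#'
#' The checkpoint is a single JSON document holding the architecture,
#' training configuration, training log and all weights at full precision.
#'
#' @param model A `t2net`.
#' @param path File path.
#' @return `write_t2net` returns `path` invisibly; `read_t2net` returns the
#'   restored `t2net`.
#' @export
write_t2net <- function(model, path) {
  doc <- list(
    spec = unclass(model$spec),
    config = unclass(model$config),
    seed = model$seed,
    best_epoch = model$best_epoch,
    best_val_loss = model$best_val_loss,
    log = model$log,
    W = lapply(model$weights$W, function(w) list(dim = dim(w), data = as.vector(w))),
    b = model$weights$b
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_t2net
#' @export
read_t2net <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- structure(doc$spec, class = "network_spec")
  spec$dims <- as.integer(spec$dims)
  W <- lapply(seq_len(nrow(doc$W)), function(l) {
    matrix(doc$W$data[[l]], doc$W$dim[[l]][1], doc$W$dim[[l]][2])
  })
  structure(
    list(weights = list(W = W, b = doc$b),
         spec = spec,
         config = structure(doc$config, class = "train_config"),
         seed = doc$seed,
         log = tibble::as_tibble(doc$log),
         best_epoch = doc$best_epoch,
         best_val_loss = doc$best_val_loss),
    class = "t2net"
  )
}
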