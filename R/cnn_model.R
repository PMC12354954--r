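# Compact convolutional network for amplitude-spectrum feature vectors.
#
# Architecture: input mapping (learnable linear projection to a
# reshape_dim^2 vector, or zero-padding) -> row-major reshape to a
# reshape_dim x reshape_dim x 1 grid -> single valid convolution layer
# (square kernel, configurable stride and filter count) -> 2x2 max pooling
# (stride 2, no padding; skipped when the conv map is 1x1) -> a dense
# stack whose depth and width are hyperparameters, each layer followed by
# 30% dropout -> 2-unit softmax. Trained with Adam on cross-entropy.
#
# The network is small enough (grids <= 8x8, <= 32-unit layers) that all
# forward/backward passes are plain R matrix algebra over mini-batches;
# convolution is done patch-wise (im2col) so both passes are matrix
# products.

SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

activate <- function(x, name) {
  switch(name,
         relu = pmax(x, 0),
         selu = ifelse(x > 0, SELU_LAMBDA * x,
                       SELU_LAMBDA * SELU_ALPHA * (exp(x) - 1)),
         stop("unknown activation: ", name, call. = FALSE))
}

# Derivative w.r.t. the pre-activation.
activate_grad <- function(x, name) {
  switch(name,
         relu = (x > 0) + 0,
         selu = ifelse(x > 0, SELU_LAMBDA,
                       SELU_LAMBDA * SELU_ALPHA * exp(x)),
         stop("unknown activation: ", name, call. = FALSE))
}

#' Hyperparameter bundle for the network
#'
#' The six knobs tuned by random search: the side of the square grid the
#' features are mapped onto, the convolution kernel side and stride, the
#' depth and width of the dense head, and the activation function.
#'
#' @param reshape_dim Grid side (search space 6, 7, 8).
#' @param conv_kernel Square kernel side (3, 4, 5); must not exceed
#'   \code{reshape_dim}.
#' @param conv_stride Convolution stride (1, 2, 3).
#' @param dense_layers Number of dense layers in the head (1, 2, 3).
#' @param dense_units Units per dense layer (4, 8, 16, 32).
#' @param activation "relu" or "selu" (applied to the conv and dense
#'   layers; the input projection is linear).
#' @return A \code{"hyperparams"} list.
#' @examples
#' # configuration selected for the human training set
#' hyperparams(8, 5, 3, 2, 32, "selu")
#' @export
hyperparams <- function(reshape_dim, conv_kernel, conv_stride,
                        dense_layers, dense_units, activation) {
  activation <- tolower(activation)
  stopifnot(reshape_dim >= 1, conv_kernel >= 1, conv_stride >= 1,
            dense_layers >= 1, dense_units >= 1)
  if (!activation %in% c("relu", "selu")) {
    stop("activation must be 'relu' or 'selu'", call. = FALSE)
  }
  if (conv_kernel > reshape_dim) {
    stop("conv_kernel (", conv_kernel, ") exceeds reshape_dim (",
         reshape_dim, ")", call. = FALSE)
  }
  structure(list(reshape_dim = as.integer(reshape_dim),
                 conv_kernel = as.integer(conv_kernel),
                 conv_stride = as.integer(conv_stride),
                 dense_layers = as.integer(dense_layers),
                 dense_units = as.integer(dense_units),
                 activation = activation),
            class = "hyperparams")
}

#' Output side of a valid convolution
#'
#' @param input_side Side of the square input grid.
#' @param kernel Kernel side; must not exceed \code{input_side}.
#' @param stride Stride, at least 1.
#' @return \code{floor((input_side - kernel) / stride) + 1}.
#' @export
conv_output_side <- function(input_side, kernel, stride) {
  stopifnot(stride >= 1)
  if (kernel > input_side) {
    stop("kernel (", kernel, ") exceeds input side (", input_side, ")",
         call. = FALSE)
  }
  as.integer((input_side - kernel) %/% stride + 1L)
}

#' Map a feature vector onto a square grid
#'
#' In \code{zero_pad} mode the vector is extended with
#' \code{reshape_dim^2 - length} zeros and reshaped row-major (so a
#' 60-dimensional vector on an 8x8 grid gains exactly 4 zeros). In
#' \code{dense_projection} mode the map is a learnable linear layer; its
#' weights (\code{list(W, b)}) must be supplied, as during training they
#' belong to the model.
#'
#' @param features Numeric feature vector.
#' @param reshape_dim Grid side.
#' @param mode "zero_pad" or "dense_projection".
#' @param weights For dense_projection: \code{list(W, b)} with W of shape
#'   length(features) x reshape_dim^2.
#' @return A \code{reshape_dim x reshape_dim} numeric matrix.
#' @export
map_input <- function(features, reshape_dim,
                      mode = c("zero_pad", "dense_projection"),
                      weights = NULL) {
  mode <- match.arg(mode)
  d <- length(features)
  m2 <- reshape_dim^2
  if (mode == "zero_pad") {
    if (m2 < d) {
      stop("zero_pad needs reshape_dim^2 >= feature dimension (",
           m2, " < ", d, ")", call. = FALSE)
    }
    v <- c(features, rep(0, m2 - d))
  } else {
    if (is.null(weights)) {
      stop("dense_projection mapping requires learned weights (list(W, b))",
           call. = FALSE)
    }
    v <- as.numeric(features %*% weights$W + weights$b)
  }
  matrix(v, reshape_dim, reshape_dim, byrow = TRUE)
}

# Row-major flat index of grid cell (r, c) on a side x side grid.
rm_index <- function(r, c, side) (r - 1L) * side + c

# im2col index matrix: one row per conv output position (row-major over
# the output grid), one column per kernel offset (row-major), entries are
# flat indices into the input grid.
conv_patch_index <- function(side, kernel, stride) {
  out <- conv_output_side(side, kernel, stride)
  idx <- matrix(0L, out * out, kernel * kernel)
  p <- 0L
  for (i in seq_len(out)) {
    for (j in seq_len(out)) {
      p <- p + 1L
      r0 <- (i - 1L) * stride
      c0 <- (j - 1L) * stride
      q <- 0L
      for (a in seq_len(kernel)) {
        for (b in seq_len(kernel)) {
          q <- q + 1L
          idx[p, q] <- rm_index(r0 + a, c0 + b, side)
        }
      }
    }
  }
  idx
}

# 2x2/stride-2 pooling index matrix: one row per pooled cell, 4 columns of
# conv-map flat indices (row-major on the conv map).
pool_patch_index <- function(conv_side) {
  out <- conv_side %/% 2L
  idx <- matrix(0L, out * out, 4L)
  p <- 0L
  for (i in seq_len(out)) {
    for (j in seq_len(out)) {
      p <- p + 1L
      idx[p, ] <- c(rm_index(2L * i - 1L, 2L * j - 1L, conv_side),
                    rm_index(2L * i - 1L, 2L * j, conv_side),
                    rm_index(2L * i, 2L * j - 1L, conv_side),
                    rm_index(2L * i, 2L * j, conv_side))
    }
  }
  idx
}

#' Resolve the network architecture for given hyperparameters
#'
#' Pure shape arithmetic; no weights are created. The conv map side is
#' \code{floor((reshape_dim - conv_kernel) / conv_stride) + 1}; pooling is
#' 2x2 with stride 2 and no padding, and is skipped (with a message) when
#' the conv map is 1x1, where pooling is undefined but the network is
#' still shape-legal.
#'
#' @param hp A \code{\link{hyperparams}} object.
#' @param input_dim Feature dimension (40 for 21-nt windows, 60 for
#'   31-nt).
#' @param filters Number of convolution filters (default 16).
#' @param mode Input mapping mode; \code{dense_projection} (default) uses
#'   a learnable linear map, \code{zero_pad} appends zeros (illegal when
#'   \code{reshape_dim^2 < input_dim}).
#' @param quiet Suppress the pooling-skip message.
#' @return A \code{"model_spec"} list with all layer shapes resolved.
#' @export
build_model <- function(hp, input_dim, filters = 16L,
                        mode = c("dense_projection", "zero_pad"),
                        quiet = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(hp, "hyperparams"), input_dim >= 1, filters >= 1)
  if (mode == "zero_pad" && hp$reshape_dim^2 < input_dim) {
    stop("zero_pad mapping illegal: reshape_dim^2 = ", hp$reshape_dim^2,
         " < input_dim = ", input_dim, call. = FALSE)
  }
  conv_side <- conv_output_side(hp$reshape_dim, hp$conv_kernel,
                                hp$conv_stride)
  pool_skipped <- conv_side < 2L
  pool_side <- if (pool_skipped) conv_side else conv_side %/% 2L
  if (pool_skipped && !quiet) {
    message("conv map is ", conv_side, "x", conv_side,
            "; 2x2 pooling skipped")
  }
  flat_size <- pool_side^2 * filters
  structure(list(
    input_dim = as.integer(input_dim),
    mode = mode,
    reshape_dim = hp$reshape_dim,
    conv_kernel = hp$conv_kernel,
    conv_stride = hp$conv_stride,
    filters = as.integer(filters),
    conv_side = conv_side,
    pool_side = as.integer(pool_side),
    pool_skipped = pool_skipped,
    flat_size = as.integer(flat_size),
    dense_layers = hp$dense_layers,
    dense_units = hp$dense_units,
    activation = hp$activation,
    dropout = 0.30,
    n_classes = 2L), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", x$input_dim, "->",
      paste0("[", x$mode, "] ", x$reshape_dim, "x", x$reshape_dim),
      "-> conv", paste0(x$conv_kernel, "x", x$conv_kernel, "/s",
                        x$conv_stride, " (", x$filters, "f) ->"),
      paste0(x$conv_side, "x", x$conv_side),
      if (x$pool_skipped) "-> [pool skipped]" else
        paste0("-> pool 2x2 -> ", x$pool_side, "x", x$pool_side),
      "->", paste(rep(x$dense_units, x$dense_layers), collapse = "+"),
      paste0("(", x$activation, ", dropout ", x$dropout, ")"),
      "-> softmax(2)\n")
  invisible(x)
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

init_weights <- function(spec) {
  w <- list()
  if (spec$mode == "dense_projection") {
    w$W0 <- glorot(spec$input_dim, spec$reshape_dim^2)
    w$b0 <- rep(0, spec$reshape_dim^2)
  }
  k2 <- spec$conv_kernel^2
  w$K <- glorot(k2, spec$filters)
  w$bK <- rep(0, spec$filters)
  nin <- spec$flat_size
  for (l in seq_len(spec$dense_layers)) {
    w[[paste0("W", l)]] <- glorot(nin, spec$dense_units)
    w[[paste0("b", l)]] <- rep(0, spec$dense_units)
    nin <- spec$dense_units
  }
  w$Wout <- glorot(nin, spec$n_classes)
  w$bout <- rep(0, spec$n_classes)
  w
}

# Forward pass over a batch. Returns activations needed for backprop.
# `dropmask` is NULL at prediction time (dropout disabled).
forward_pass <- function(spec, w, Xb, cidx, pidx, dropmask = NULL) {
  B <- nrow(Xb)
  Z0 <- if (spec$mode == "dense_projection") {
    sweep(Xb %*% w$W0, 2, w$b0, "+")
  } else {
    cbind(Xb, matrix(0, B, spec$reshape_dim^2 - spec$input_dim))
  }
  np <- nrow(cidx)                         # conv output positions
  FL <- spec$filters
  conv_pre <- matrix(0, B, np * FL)        # filter-contiguous blocks
  for (p in seq_len(np)) {
    out_p <- sweep(Z0[, cidx[p, ], drop = FALSE] %*% w$K, 2, w$bK, "+")
    conv_pre[, p + np * (seq_len(FL) - 1L)] <- out_p
  }
  conv_act <- activate(conv_pre, spec$activation)
  if (spec$pool_skipped) {
    flat <- conv_act
    argmax <- NULL
  } else {
    nq <- nrow(pidx)
    flat <- matrix(0, B, nq * FL)
    argmax <- matrix(0L, B, nq * FL)
    rows <- seq_len(B)
    for (f in seq_len(FL)) {
      off <- np * (f - 1L)
      for (q in seq_len(nq)) {
        cols <- pidx[q, ] + off
        sub <- conv_act[, cols, drop = FALSE]
        am <- max.col(sub, ties.method = "first")
        j <- nq * (f - 1L) + q
        flat[, j] <- sub[cbind(rows, am)]
        argmax[, j] <- cols[am]
      }
    }
  }
  H <- flat
  dense_pre <- vector("list", spec$dense_layers)
  dense_in <- vector("list", spec$dense_layers)
  for (l in seq_len(spec$dense_layers)) {
    dense_in[[l]] <- H
    Z <- sweep(H %*% w[[paste0("W", l)]], 2, w[[paste0("b", l)]], "+")
    dense_pre[[l]] <- Z
    H <- activate(Z, spec$activation)
    if (!is.null(dropmask)) H <- H * dropmask[[l]]
  }
  logits <- sweep(H %*% w$Wout, 2, w$bout, "+")
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  P <- e / rowSums(e)
  list(Z0 = Z0, conv_pre = conv_pre, flat = flat, argmax = argmax,
       dense_pre = dense_pre, dense_in = dense_in, H_last = H, P = P)
}

backward_pass <- function(spec, w, Xb, Y, fw, cidx, pidx, dropmask) {
  B <- nrow(Xb)
  g <- list()
  dlogits <- (fw$P - Y) / B
  g$Wout <- t(fw$H_last) %*% dlogits
  g$bout <- colSums(dlogits)
  dH <- dlogits %*% t(w$Wout)
  for (l in rev(seq_len(spec$dense_layers))) {
    dH <- dH * dropmask[[l]]
    dZ <- dH * activate_grad(fw$dense_pre[[l]], spec$activation)
    g[[paste0("W", l)]] <- t(fw$dense_in[[l]]) %*% dZ
    g[[paste0("b", l)]] <- colSums(dZ)
    dH <- dZ %*% t(w[[paste0("W", l)]])
  }
  np <- nrow(cidx)
  FL <- spec$filters
  if (spec$pool_skipped) {
    dconv_act <- dH
  } else {
    dconv_act <- matrix(0, B, np * FL)
    rows <- seq_len(B)
    # pooling windows are disjoint, so scatter without accumulation
    for (j in seq_len(ncol(fw$argmax))) {
      dconv_act[cbind(rows, fw$argmax[, j])] <- dH[, j]
    }
  }
  dconv_pre <- dconv_act * activate_grad(fw$conv_pre, spec$activation)
  g$K <- matrix(0, spec$conv_kernel^2, FL)
  g$bK <- rep(0, FL)
  dZ0 <- matrix(0, B, spec$reshape_dim^2)
  fcols <- np * (seq_len(FL) - 1L)
  for (p in seq_len(np)) {
    dout_p <- dconv_pre[, p + fcols, drop = FALSE]
    patch <- fw$Z0[, cidx[p, ], drop = FALSE]
    g$K <- g$K + t(patch) %*% dout_p
    g$bK <- g$bK + colSums(dout_p)
    dZ0[, cidx[p, ]] <- dZ0[, cidx[p, ], drop = FALSE] + dout_p %*% t(w$K)
  }
  if (spec$mode == "dense_projection") {
    g$W0 <- t(Xb) %*% dZ0
    g$b0 <- colSums(dZ0)
  }
  g
}

#' Train the network
#'
#' Mini-batch Adam on softmax cross-entropy. One integer seed drives
#' weight initialization, epoch shuffling, and dropout masks, so training
#' is deterministic given the seed (on the same platform). Dropout (rate
#' 0.30, inverted scaling) is active only during training.
#'
#' @param spec A \code{"model_spec"} from \code{\link{build_model}}.
#' @param X Feature matrix (rows = samples).
#' @param y Binary labels (0/1), one per row.
#' @param epochs Number of passes over the data (at least 1).
#' @param seed Integer seed for all stochastic components.
#' @param lr Adam learning rate (default 1e-3; beta1 0.9, beta2 0.999).
#' @param batch_size Mini-batch size (default 32).
#' @return A \code{"pseucnn_model"}: the spec, learned weights, and
#'   training metadata (epochs, seed, per-epoch mean loss).
#' @export
train_cnn <- function(spec, X, y, epochs = 30L, seed = 1L, lr = 1e-3,
                      batch_size = 32L) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X)
  y <- as.integer(y)
  if (nrow(X) != length(y)) stop("rows of X must match y", call. = FALSE)
  if (ncol(X) != spec$input_dim) {
    stop("X has ", ncol(X), " columns; model expects ", spec$input_dim,
         call. = FALSE)
  }
  if (length(unique(y)) < 2) {
    stop("binary task requires both classes in y", call. = FALSE)
  }
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  set.seed(seed)
  w <- init_weights(spec)
  cidx <- conv_patch_index(spec$reshape_dim, spec$conv_kernel,
                           spec$conv_stride)
  pidx <- if (spec$pool_skipped) NULL else pool_patch_index(spec$conv_side)
  m <- lapply(w, function(p) p * 0)
  v <- lapply(w, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  tstep <- 0L
  n <- nrow(X)
  keep <- 1 - spec$dropout
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      bi <- ord[start:min(start + batch_size - 1L, n)]
      Xb <- X[bi, , drop = FALSE]
      yb <- y[bi]
      Y <- cbind(1 - yb, yb)
      dropmask <- lapply(seq_len(spec$dense_layers), function(l) {
        matrix(stats::rbinom(length(bi) * spec$dense_units, 1L, keep) / keep,
               length(bi), spec$dense_units)
      })
      fw <- forward_pass(spec, w, Xb, cidx, pidx, dropmask)
      loss <- -mean(log(pmax(fw$P[cbind(seq_along(yb), yb + 1L)], 1e-12)))
      if (!is.finite(loss)) {
        stop("non-finite training loss at epoch ", ep,
             "; try a lower learning rate", call. = FALSE)
      }
      ep_loss <- ep_loss + loss
      nb <- nb + 1L
      g <- backward_pass(spec, w, Xb, Y, fw, cidx, pidx, dropmask)
      tstep <- tstep + 1L
      corr1 <- 1 - beta1^tstep
      corr2 <- 1 - beta2^tstep
      for (nm in names(w)) {
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g[[nm]]
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g[[nm]]^2
        w[[nm]] <- w[[nm]] -
          lr * (m[[nm]] / corr1) / (sqrt(v[[nm]] / corr2) + eps)
      }
    }
    losses[ep] <- ep_loss / nb
  }
  structure(list(spec = spec, weights = w, epochs = as.integer(epochs),
                 seed = as.integer(seed), lr = lr,
                 batch_size = as.integer(batch_size),
                 losses = losses, final_loss = losses[epochs]),
            class = "pseucnn_model")
}

#' @export
print.pseucnn_model <- function(x, ...) {
  cat("trained pseucnn model (", x$epochs, "epochs, seed", x$seed,
      ", final loss", format(x$final_loss, digits = 4), ")\n")
  print(x$spec)
  invisible(x)
}

#' Predict class-1 (pseudouridine) probabilities
#'
#' Dropout is disabled, so prediction is deterministic: two calls on the
#' same model and data give identical output. The two class probabilities
#' sum to one per row; this returns the pseudouridine column.
#'
#' @param model A \code{"pseucnn_model"} from \code{\link{train_cnn}}.
#' @param X Feature matrix with \code{model$spec$input_dim} columns.
#' @return Numeric vector of class-1 probabilities in [0, 1].
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "pseucnn_model"))
  X <- as.matrix(X)
  spec <- model$spec
  if (ncol(X) != spec$input_dim) {
    stop("X has ", ncol(X), " columns; model expects ", spec$input_dim,
         call. = FALSE)
  }
  cidx <- conv_patch_index(spec$reshape_dim, spec$conv_kernel,
                           spec$conv_stride)
  pidx <- if (spec$pool_skipped) NULL else pool_patch_index(spec$conv_side)
  fw <- forward_pass(spec, model$weights, X, cidx, pidx, dropmask = NULL)
  as.numeric(fw$P[, 2])
}

#' Closed-form parameter count of the dense stack
#'
#' Weights plus biases of the dense layers and the softmax head implied by
#' a model spec; useful for auditing model capacity.
#'
#' @param spec A \code{"model_spec"}.
#' @return Integer parameter count.
#' @export
dense_param_count <- function(spec) {
  nin <- spec$flat_size
  total <- 0L
  for (l in seq_len(spec$dense_layers)) {
    total <- total + (nin + 1L) * spec$dense_units
    nin <- spec$dense_units
  }
  total + (nin + 1L) * spec$n_classes
}

#' Save a trained model to a JSON archive
#'
#' The spec and every weight tensor (with shapes) are serialized to a
#' single JSON file, so models survive as plain text.
#'
#' @param model A \code{"pseucnn_model"}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pseucnn_model"))
  ser <- list(
    spec = unclass(model$spec),
    weights = lapply(model$weights, function(p) {
      # 17 significant digits keep the load() round-trip bit-exact
      list(dim = if (is.matrix(p)) dim(p) else length(p),
           data = sprintf("%.17g", as.numeric(p)))
    }),
    epochs = model$epochs, seed = model$seed, lr = model$lr,
    batch_size = model$batch_size, losses = model$losses)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model saved by \code{\link{save_model}}
#'
#' @param path Path to the JSON archive.
#' @return A \code{"pseucnn_model"}.
#' @export
load_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- ser$spec
  int_fields <- c("input_dim", "reshape_dim", "conv_kernel", "conv_stride",
                  "filters", "conv_side", "pool_side", "flat_size",
                  "dense_layers", "dense_units", "n_classes")
  for (f in int_fields) spec[[f]] <- as.integer(spec[[f]])
  class(spec) <- "model_spec"
  weights <- lapply(ser$weights, function(p) {
    v <- as.numeric(p$data)
    if (length(p$dim) == 2) matrix(v, p$dim[1], p$dim[2]) else v
  })
  structure(list(spec = spec, weights = weights,
                 epochs = as.integer(ser$epochs), seed = as.integer(ser$seed),
                 lr = ser$lr, batch_size = as.integer(ser$batch_size),
                 losses = ser$losses,
                 final_loss = ser$losses[length(ser$losses)]),
            class = "pseucnn_model")
}
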