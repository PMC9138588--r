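#' Convolutional feature extractor
#'
#' A small convolutional network turns the fixed 20 x 20 protein matrix into
#' a low-dimensional learned representation.  Layers are valid
#' cross-correlation (`conv_layer`), non-overlapping mean pooling
#' (`pool_layer`) and fully connected (`dense_layer`); the final dense layer
#' has width 2 (interacting / non-interacting class scores) and the
#' activations of the penultimate dense layer are the extracted feature
#' vector.  Training minimises softmax cross-entropy plus an L2 weight
#' penalty `theta/2 * sum(W^2)` (biases unpenalised) by full-batch gradient
#' descent with learning rate `epsilon`.
#'
#' @param filters,kernel Convolution output channels and (square) kernel
#'   size.
#' @param size Pooling window (non-overlapping `size` x `size` mean; a
#'   trailing row/column that does not fill a window is dropped).
#' @param units Dense layer width.
#' @name cnn
NULL

#' @rdname cnn
#' @export
conv_layer <- function(filters, kernel = 3) {
  list(kind = "conv", filters = as.integer(filters), kernel = as.integer(kernel))
}

#' @rdname cnn
#' @export
pool_layer <- function(size = 2) list(kind = "pool", size = as.integer(size))

#' @rdname cnn
#' @export
dense_layer <- function(units) list(kind = "dense", units = as.integer(units))

#' CNN configuration
#'
#' @param layers Ordered list of [conv_layer()], [pool_layer()] and
#'   [dense_layer()] specs.  Must contain at least one conv and one dense
#'   layer, and the last dense layer must have width 2.  The default stack
#'   (conv 3x3 x8, pool 2, conv 3x3 x16, pool 2, dense 128, dense 2) is the
#'   smallest architecture exercising every layer type on a 20 x 20 input.
#' @param input_dim Side length of the square single-channel input.
#' @param theta L2 regularisation strength (>= 0).
#' @param epsilon Gradient-descent learning rate (> 0).
#' @param epochs Number of full-batch epochs.
#' @param seed Seed for the uniform(-0.1, 0.1) weight initialisation.
#' @param activation Hidden activation: "relu", "tanh", "sigmoid" or
#'   "identity".
#' @param pool Pooling rule, "mean" (default, smooth gradients) or "max".
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(layers = list(conv_layer(8), pool_layer(),
                                     conv_layer(16), pool_layer(),
                                     dense_layer(128), dense_layer(2)),
                       input_dim = 20, theta = 1e-4, epsilon = 0.05,
                       epochs = 10, seed = 42,
                       activation = c("relu", "tanh", "sigmoid", "identity"),
                       pool = c("mean", "max")) {
  activation <- match.arg(activation)
  pool <- match.arg(pool)
  kinds <- vapply(layers, `[[`, character(1), "kind")
  if (!any(kinds == "conv") || !any(kinds == "dense")) {
    stop_dtiforge("need at least one conv and one dense layer",
                  "dtiforge_config_error")
  }
  dense_idx <- which(kinds == "dense")
  if (layers[[dense_idx[length(dense_idx)]]]$units != 2) {
    stop_dtiforge("last dense layer must have width 2 (binary class scores)",
                  "dtiforge_config_error")
  }
  stopifnot(theta >= 0, epsilon >= 0, epochs >= 0)
  structure(list(layers = layers, input_dim = as.integer(input_dim),
                 theta = theta, epsilon = epsilon,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 activation = activation, pool = pool),
            class = "cnn_config")
}

act_fun <- function(name) {
  switch(name,
         relu = list(f = function(z) pmax(z, 0),
                     df = function(z, a) (z > 0) * 1),
         tanh = list(f = tanh, df = function(z, a) 1 - a^2),
         sigmoid = list(f = stats::plogis,
                        df = function(z, a) a * (1 - a)),
         identity = list(f = identity, df = function(z, a) 1))
}

# Geometry compiler: per-layer shapes plus gather/scatter index tables.
# Sample vectors use position-major layout: index of cell (r, c, ch) in an
# h x w x ch map is r + (c-1)*h + (ch-1)*h*w.
compile_cnn <- function(cfg) {
  h <- cfg$input_dim; w <- cfg$input_dim; ch <- 1L
  compiled <- list()
  flat <- NULL
  for (i in seq_along(cfg$layers)) {
    spec <- cfg$layers[[i]]
    if (spec$kind == "conv") {
      if (!is.null(flat)) {
        stop_dtiforge("conv layer after dense layer is not supported",
                      "dtiforge_config_error")
      }
      k <- spec$kernel
      oh <- h - k + 1L; ow <- w - k + 1L
      if (oh < 1 || ow < 1) {
        stop_dtiforge(sprintf("layer %d: kernel %d exceeds input %dx%d",
                              i, k, h, w), "dtiforge_config_error")
      }
      pos <- expand.grid(r = seq_len(oh), c = seq_len(ow))
      off <- expand.grid(dr = seq_len(k), dc = seq_len(k), dch = seq_len(ch))
      idx <- outer(pos$r, off$dr - 1L, `+`) +
        (outer(pos$c, off$dc - 1L, `+`) - 1L) * h +
        matrix((off$dch - 1L) * h * w, nrow(pos), nrow(off), byrow = TRUE)
      compiled[[i]] <- list(kind = "conv", idx = idx, ksz = nrow(off),
                            npos = nrow(pos), in_ch = ch,
                            filters = spec$filters,
                            in_dim = h * w * ch,
                            out_dim = oh * ow * spec$filters)
      h <- oh; w <- ow; ch <- spec$filters
    } else if (spec$kind == "pool") {
      if (!is.null(flat)) {
        stop_dtiforge("pool layer after dense layer is not supported",
                      "dtiforge_config_error")
      }
      s <- spec$size
      oh <- h %/% s; ow <- w %/% s
      if (oh < 1 || ow < 1) {
        stop_dtiforge(sprintf("layer %d: pool %d exceeds input %dx%d",
                              i, s, h, w), "dtiforge_config_error")
      }
      pos <- expand.grid(r = seq_len(oh), c = seq_len(ow), f = seq_len(ch))
      members <- expand.grid(dr = seq_len(s), dc = seq_len(s))
      idx <- outer((pos$r - 1L) * s + 1L, members$dr - 1L, `+`) +
        (outer((pos$c - 1L) * s + 1L, members$dc - 1L, `+`) - 1L) * h +
        matrix((pos$f - 1L) * h * w, nrow(pos), nrow(members))
      compiled[[i]] <- list(kind = "pool", idx = idx, win = nrow(members),
                            in_dim = h * w * ch, out_dim = oh * ow * ch)
      h <- oh; w <- ow
    } else {
      in_dim <- if (is.null(flat)) h * w * ch else flat
      compiled[[i]] <- list(kind = "dense", in_dim = in_dim,
                            out_dim = spec$units)
      flat <- spec$units
    }
  }
  compiled
}

#' Initialise a CNN
#'
#' Weights are drawn i.i.d. uniform(-0.1, 0.1) under the config seed;
#' biases start at zero.  Deterministic given the seed.
#'
#' @param cfg A [cnn_config()].
#' @return A `cnn_model` (untrained).
#' @export
cnn_init <- function(cfg) {
  stopifnot(inherits(cfg, "cnn_config"))
  compiled <- compile_cnn(cfg)
  params <- with_seed(cfg$seed, lapply(compiled, function(ly) {
    if (ly$kind == "conv") {
      list(w = matrix(runif(ly$ksz * ly$filters, -0.1, 0.1),
                      ly$ksz, ly$filters),
           b = numeric(ly$filters))
    } else if (ly$kind == "dense") {
      list(w = matrix(runif(ly$in_dim * ly$out_dim, -0.1, 0.1),
                      ly$in_dim, ly$out_dim),
           b = numeric(ly$out_dim))
    } else NULL
  }))
  structure(list(config = cfg, compiled = compiled, params = params,
                 loss_history = numeric()),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, function(p) {
    if (is.null(p)) 0L else length(p$w) + length(p$b)
  }, integer(1)))
  cat(sprintf("<cnn_model> %d layers, %d parameters, %d training epochs run\n",
              length(x$compiled), n_par, length(x$loss_history)))
  invisible(x)
}

# Coerce input to a batch matrix (n x input_dim^2), column-major per sample.
as_cnn_batch <- function(m, x) {
  d <- m$config$input_dim
  if (is.list(x)) {
    x <- t(vapply(x, function(a) as.vector(as.matrix(a)), numeric(d * d)))
  } else if (is.matrix(x) && nrow(x) == d && ncol(x) == d) {
    x <- matrix(as.vector(x), 1)
  } else if (!is.matrix(x)) {
    x <- matrix(as.numeric(x), 1)
  }
  if (ncol(x) != d * d) {
    stop_dtiforge(sprintf("input has %d values per sample, expected %d",
                          ncol(x), d * d), "dtiforge_config_error")
  }
  x
}

# Batched forward pass.  Returns scores plus (optionally) per-layer traces
# needed for backprop: the layer input, patch matrix, pre-activation and
# activation.
cnn_forward_batch <- function(m, xb, keep_trace = FALSE) {
  act <- act_fun(m$config$activation)
  n <- nrow(xb)
  dense_seen <- 0L
  n_dense <- sum(vapply(m$compiled, function(l) l$kind == "dense", logical(1)))
  trace <- if (keep_trace) vector("list", length(m$compiled)) else NULL
  cur <- xb
  feature <- NULL
  for (i in seq_along(m$compiled)) {
    ly <- m$compiled[[i]]
    if (ly$kind == "conv") {
      pm <- cur[, as.vector(ly$idx), drop = FALSE]
      dim(pm) <- c(n * ly$npos, ly$ksz)
      z <- pm %*% m$params[[i]]$w
      z <- z + rep(m$params[[i]]$b, each = nrow(z))
      a <- act$f(z)
      out <- a
      dim(out) <- c(n, ly$npos * ly$filters)
      if (keep_trace) trace[[i]] <- list(input = cur, pm = pm, z = z, a = a)
      cur <- out
    } else if (ly$kind == "pool") {
      if (m$config$pool == "mean") {
        out <- matrix(0, n, nrow(ly$idx))
        for (j in seq_len(ly$win)) out <- out + cur[, ly$idx[, j], drop = FALSE]
        out <- out / ly$win
        if (keep_trace) trace[[i]] <- list(in_dim = ly$in_dim)
      } else {
        stacked <- array(cur[, as.vector(ly$idx)], c(n, nrow(ly$idx), ly$win))
        out <- apply(stacked, c(1, 2), max)
        if (keep_trace) {
          amax <- apply(stacked, c(1, 2), which.max)
          trace[[i]] <- list(in_dim = ly$in_dim, amax = amax)
        }
      }
      cur <- out
    } else {
      dense_seen <- dense_seen + 1L
      z <- cur %*% m$params[[i]]$w
      z <- z + rep(m$params[[i]]$b, each = nrow(z))
      if (dense_seen < n_dense) {
        a <- act$f(z)
        if (dense_seen == n_dense - 1L) feature <- a
      } else {
        a <- z                      # raw class scores; softmax lives in the loss
      }
      if (keep_trace) trace[[i]] <- list(input = cur, z = z, a = a)
      cur <- a
    }
  }
  list(scores = cur, feature = feature, trace = trace)
}

#' Forward pass with feature-map trace
#'
#' Runs one protein matrix through the network and returns the final
#' 2-vector of class scores together with every intermediate feature map
#' (as h x w x channels arrays for conv/pool layers, vectors for dense
#' layers).
#'
#' @param m A `cnn_model`.
#' @param x A 20 x 20 protein matrix.
#' @return List with `scores` (length 2) and `maps` (list per layer).
#' @export
cnn_forward <- function(m, x) {
  stopifnot(inherits(m, "cnn_model"))
  xb <- as_cnn_batch(m, x)
  fw <- cnn_forward_batch(m, xb, keep_trace = TRUE)
  d <- m$config$input_dim
  h <- d; w <- d; ch <- 1L
  maps <- vector("list", length(m$compiled))
  cur_dims <- NULL
  for (i in seq_along(m$compiled)) {
    ly <- m$compiled[[i]]
    if (ly$kind == "conv") {
      k <- sqrt(ly$ksz / ly$in_ch)
      h <- h - k + 1; w <- w - k + 1; ch <- ly$filters
      v <- fw$trace[[i]]$a
      maps[[i]] <- array(as.vector(v), c(h, w, ch))
    } else if (ly$kind == "pool") {
      s <- m$config$layers[[i]]$size
      h <- h %/% s; w <- w %/% s
      # recompute pooled output from the next layer's input or directly
      maps[[i]] <- NULL
    } else {
      maps[[i]] <- as.vector(fw$trace[[i]]$a)
    }
  }
  # fill pool maps from the stored inputs of their successor layers
  for (i in seq_along(m$compiled)) {
    if (m$compiled[[i]]$kind == "pool") {
      nxt <- fw$trace[[i + 1]]$input %||% NULL
      if (!is.null(nxt)) {
        dims <- pool_out_dims(m, i)
        maps[[i]] <- array(as.vector(nxt), dims)
      }
    }
  }
  list(scores = as.vector(fw$scores), maps = maps)
}

pool_out_dims <- function(m, i) {
  h <- m$config$input_dim; w <- h; ch <- 1L
  for (j in seq_len(i)) {
    ly <- m$config$layers[[j]]
    if (ly$kind == "conv") {
      h <- h - ly$kernel + 1; w <- w - ly$kernel + 1; ch <- ly$filters
    } else if (ly$kind == "pool") {
      h <- h %/% ly$size; w <- w %/% ly$size
    }
  }
  c(h, w, ch)
}

sum_sq_weights <- function(m) {
  sum(vapply(m$params, function(p) if (is.null(p)) 0 else sum(p$w^2),
             numeric(1)))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Training loss
#'
#' Mean softmax cross-entropy over the batch plus the L2 penalty
#' `theta/2 * sum(W^2)` over all convolution kernels and dense weight
#' matrices (biases excluded).
#'
#' @param m A `cnn_model`.
#' @param x Batch of inputs (list of matrices, or n x 400 matrix).
#' @param y Binary labels (0/1), one per sample.
#' @return Scalar loss.
#' @export
cnn_loss <- function(m, x, y) {
  stopifnot(inherits(m, "cnn_model"), length(y) >= 1)
  xb <- as_cnn_batch(m, x)
  p <- softmax_rows(cnn_forward_batch(m, xb)$scores)
  picked <- p[cbind(seq_along(y), ifelse(y == 1, 2L, 1L))]
  data_term <- -mean(log(pmax(picked, .Machine$double.xmin)))
  data_term + m$config$theta / 2 * sum_sq_weights(m)
}

# Analytic gradients of cnn_loss wrt every parameter, by backprop.
cnn_gradients <- function(m, xb, y) {
  fw <- cnn_forward_batch(m, xb, keep_trace = TRUE)
  cnn_backward(m, fw, y)
}

# Backprop given a traced forward pass.
cnn_backward <- function(m, fw, y) {
  act <- act_fun(m$config$activation)
  n <- length(y)
  p <- softmax_rows(fw$scores)
  yhot <- cbind(1 - y, y)
  d_cur <- (p - yhot) / n          # gradient wrt final pre-activation scores
  grads <- vector("list", length(m$compiled))
  for (i in rev(seq_along(m$compiled))) {
    ly <- m$compiled[[i]]
    tr <- fw$trace[[i]]
    if (ly$kind == "dense") {
      grads[[i]] <- list(
        w = crossprod(tr$input, d_cur) + m$config$theta * m$params[[i]]$w,
        b = colSums(d_cur)
      )
      d_cur <- d_cur %*% t(m$params[[i]]$w)
      # activation derivative of the producing layer handled when reached
    } else if (ly$kind == "pool") {
      d_in <- matrix(0, n, ly$in_dim)
      if (m$config$pool == "mean") {
        for (j in seq_len(ly$win)) {
          d_in[, ly$idx[, j]] <- d_in[, ly$idx[, j]] + d_cur / ly$win
        }
      } else {
        for (j in seq_len(ly$win)) {
          mask <- (tr$amax == j) * 1
          d_in[, ly$idx[, j]] <- d_in[, ly$idx[, j]] + d_cur * mask
        }
      }
      d_cur <- d_in
    } else {                        # conv
      dz <- d_cur
      dim(dz) <- c(n * ly$npos, ly$filters)
      dz <- dz * act$df(tr$z, tr$a)
      grads[[i]] <- list(
        w = crossprod(tr$pm, dz) + m$config$theta * m$params[[i]]$w,
        b = colSums(dz)
      )
      dpm <- dz %*% t(m$params[[i]]$w)
      d_in <- matrix(0, n, ly$in_dim)
      for (j in seq_len(ly$ksz)) {
        slice <- dpm[, j]
        dim(slice) <- c(n, ly$npos)
        d_in[, ly$idx[, j]] <- d_in[, ly$idx[, j]] + slice
      }
      d_cur <- d_in
    }
    # apply the hidden-activation derivative of the upstream layer's output
    if (i > 1) {
      up <- m$compiled[[i - 1]]
      uptr <- fw$trace[[i - 1]]
      last_dense <- i - 1 == length(m$compiled)
      if (up$kind == "dense" && !last_dense) {
        d_cur <- d_cur * act$df(uptr$z, uptr$a)
      }
      # conv activations are differentiated inside the conv branch itself;
      # pool has no activation
    }
  }
  grads
}

#' Train by full-batch gradient descent
#'
#' Runs `epochs` iterations of `W <- W - epsilon * dL/dW`,
#' `b <- b - epsilon * dL/db` on the whole batch, recording the loss before
#' each update.  Deterministic given the config seed and data order.
#'
#' @inheritParams cnn_loss
#' @param epochs,epsilon Optional overrides of the config values.
#' @return The trained `cnn_model` with `loss_history` appended.
#' @export
cnn_train <- function(m, x, y, epochs = NULL, epsilon = NULL) {
  stopifnot(inherits(m, "cnn_model"))
  if (length(y) == 0) {
    stop_dtiforge("training data is empty", "dtiforge_config_error")
  }
  if (!all(y %in% c(0, 1))) {
    stop_dtiforge("labels must be binary 0/1", "dtiforge_config_error")
  }
  xb <- as_cnn_batch(m, x)
  epochs <- epochs %||% m$config$epochs
  epsilon <- epsilon %||% m$config$epsilon
  for (ep in seq_len(epochs)) {
    fw <- cnn_forward_batch(m, xb, keep_trace = epsilon > 0)
    p <- softmax_rows(fw$scores)
    picked <- p[cbind(seq_along(y), ifelse(y == 1, 2L, 1L))]
    loss <- -mean(log(pmax(picked, .Machine$double.xmin))) +
      m$config$theta / 2 * sum_sq_weights(m)
    if (!is.finite(loss)) {
      stop_dtiforge(sprintf("training diverged at epoch %d (non-finite loss)",
                            ep),
                    "dtiforge_divergence_error")
    }
    m$loss_history <- c(m$loss_history, loss)
    if (epsilon == 0) next
    g <- cnn_backward(m, fw, y)
    for (i in seq_along(m$params)) {
      if (is.null(m$params[[i]])) next
      m$params[[i]]$w <- m$params[[i]]$w - epsilon * g[[i]]$w
      m$params[[i]]$b <- m$params[[i]]$b - epsilon * g[[i]]$b
    }
  }
  m
}

#' Extract learned protein features
#'
#' Returns the activations of the penultimate dense layer — the learned
#' representation that feeds the downstream classifier.
#'
#' @param m A `cnn_model`.
#' @param x One protein matrix, a list of them, or a batch matrix.
#' @return A numeric matrix, one row per sample (a vector for one sample).
#' @export
cnn_extract <- function(m, x) {
  stopifnot(inherits(m, "cnn_model"))
  xb <- as_cnn_batch(m, x)
  f <- cnn_forward_batch(m, xb)$feature
  if (nrow(f) == 1) as.vector(f) else f
}
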