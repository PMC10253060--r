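# Self-contained convolutional network core.
#
# Layout conventions:
#   activations  : 4-d arrays (N, H, W, C), column-major
#   conv weights : matrix (9 * C_in, C_out); kernel offsets (di, dj) in
#                  {0,1,2}^2 enumerated row-major, channels fastest
#   dense weights: matrix (C_in, C_out)
# Convolutions are 3x3, stride 1, zero same-padding, realized as im2col
# gathers + one BLAS matmul per layer; 2x2 max pooling, stride 2.

# conv with optionally fused ReLU (the tiny CNN always fuses)
conv_forward <- function(x, W, b, relu = TRUE) {
  d <- dim(x)
  res <- cpp_conv_forward(x, as.integer(d), W, b, relu)
  out <- res$out
  dim(out) <- c(d[1], d[2], d[3], ncol(W))
  list(out = out, col = res$col, in_dim = d, relu = relu)
}

conv_backward <- function(dout, cache, W, need_dx = TRUE) {
  d <- cache$in_dim
  dm <- dout
  dim(dm) <- c(d[1] * d[2] * d[3], ncol(W))
  res <- cpp_conv_backward(dm, as.integer(d), cache$col, W, cache$out,
                           cache$relu, need_dx)
  dx <- res$dx
  if (!is.null(dx)) dim(dx) <- d
  list(dW = res$dW, db = as.vector(res$db), dx = dx)
}

# instance normalization (per sample and channel over spatial positions)
# fused with ReLU; no learnable parameters, so evaluation equals training
in_relu_forward <- function(x, eps = 1e-5) {
  d <- dim(x)
  res <- cpp_in_relu_forward(x, as.integer(d), eps)
  out <- res$out
  dim(out) <- d
  list(out = out, y = res$y, sd = res$sd, in_dim = d)
}

in_relu_backward <- function(dout, cache) {
  dx <- cpp_in_relu_backward(dout, cache$y, cache$sd,
                             as.integer(cache$in_dim))
  dim(dx) <- cache$in_dim
  dx
}

maxpool_forward <- function(x) {
  d <- dim(x)
  res <- cpp_maxpool_forward(x, as.integer(d))
  out <- res$out
  dim(out) <- c(d[1], d[2] %/% 2, d[3] %/% 2, d[4])
  list(out = out, arg = res$arg, in_dim = d)
}

maxpool_backward <- function(dout, cache) {
  dx <- cpp_maxpool_backward(dout, cache$arg, as.integer(cache$in_dim))
  dim(dx) <- cache$in_dim
  dx
}

gap_forward <- function(x) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1], d[2] * d[3], d[4])
  out <- colMeans(aperm(xm, c(2, 1, 3)))  # (N, C)
  list(out = out, in_dim = d)
}

gap_backward <- function(dout, cache) {
  d <- cache$in_dim
  hw <- d[2] * d[3]
  dx <- array(0, dim = d)
  for (ch in seq_len(d[4])) {
    dx[, , , ch] <- array(rep(dout[, ch] / hw, times = hw), dim = d[1:3])
  }
  dx
}

dense_forward <- function(x, W, b) {
  y <- x %*% W
  y <- y + rep(b, each = nrow(y))
  list(out = y, x = x)
}

dense_backward <- function(dout, cache, W) {
  list(dW = crossprod(cache$x, dout), db = colSums(dout),
       dx = dout %*% t(W))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- tiny CNN ---------------------------------------------------------

init_tiny_cnn_params <- function(channels, n_outputs, input_size) {
  params <- list()
  ci <- 3
  for (k in seq_along(channels)) {
    co <- channels[k]
    fan_in <- 9 * ci
    params[[paste0("conv", k)]] <- list(
      W = matrix(stats::rnorm(fan_in * co, 0, sqrt(2 / fan_in)), fan_in, co),
      b = numeric(co))
    ci <- co
  }
  params$head <- list(
    W = matrix(stats::rnorm(ci * n_outputs, 0, sqrt(1 / ci)), ci, n_outputs),
    b = numeric(n_outputs))
  params
}

new_tiny_cnn <- function(n_outputs, freeze_fraction = 0.5, input_size = 32L,
                         channels = c(8L, 16L, 32L, 64L), seed = 1L) {
  params <- withr::with_seed(as.integer(seed),
                             init_tiny_cnn_params(channels, n_outputs, input_size))
  nb <- length(channels)
  n_frozen <- ceiling(freeze_fraction * nb)
  structure(list(
    family = "tiny-cnn",
    input_size = as.integer(input_size),
    channels = as.integer(channels),
    n_outputs = as.integer(n_outputs),
    freeze_fraction = freeze_fraction,
    frozen = seq_len(nb) <= n_frozen,
    params = params
  ), class = "tiny_cnn")
}

#' @export
print.tiny_cnn <- function(x, ...) {
  np <- sum(vapply(unlist(x$params, recursive = FALSE), length, numeric(1)))
  cat(sprintf(
    "<tiny_cnn> input %dx%dx3, blocks [%s], %d outputs, %d params, frozen blocks: %s\n",
    x$input_size, x$input_size, paste(x$channels, collapse = ","),
    x$n_outputs, np,
    if (any(x$frozen)) paste(which(x$frozen), collapse = ",") else "none"))
  invisible(x)
}

# forward pass; x is (N, S, S, 3). Returns logits and layer caches.
tiny_cnn_forward <- function(model, x) {
  p <- model$params
  caches <- list()
  a <- x
  nb <- length(model$channels)
  for (k in seq_len(nb)) {
    cv <- conv_forward(a, p[[paste0("conv", k)]]$W, p[[paste0("conv", k)]]$b,
                       relu = FALSE)
    nr <- in_relu_forward(cv$out)
    if (k < nb) {
      pl <- maxpool_forward(nr$out)
      a <- pl$out
      caches[[k]] <- list(conv = cv, norm = nr, pool = pl)
    } else {
      gp <- gap_forward(nr$out)
      a <- gp$out
      caches[[k]] <- list(conv = cv, norm = nr, gap = gp)
    }
  }
  hd <- dense_forward(a, p$head$W, p$head$b)
  list(logits = hd$out, caches = caches, head = hd)
}

# backward from dlogits; returns grads for all trainable params.
# Gradient flow stops above the deepest frozen block (frozen blocks form a
# prefix, so nothing below the first trainable block needs gradients).
tiny_cnn_backward <- function(model, fwd, dlogits) {
  p <- model$params
  nb <- length(model$channels)
  lt <- if (any(!model$frozen)) min(which(!model$frozen)) else nb + 1L
  grads <- list()
  dh <- dense_backward(dlogits, fwd$head, p$head$W)
  grads$head <- list(W = dh$dW, b = dh$db)
  da <- dh$dx
  if (lt > nb) return(grads)
  for (k in nb:lt) {
    cache <- fwd$caches[[k]]
    if (k < nb) {
      da <- maxpool_backward(da, cache$pool)
    } else {
      da <- gap_backward(da, cache$gap)
    }
    da <- in_relu_backward(da, cache$norm)
    cb <- conv_backward(da, cache$conv, p[[paste0("conv", k)]]$W,
                        need_dx = k > lt)
    grads[[paste0("conv", k)]] <- list(W = cb$dW, b = cb$db)
    da <- cb$dx
  }
  grads
}

# class probabilities for a batch tensor
tiny_cnn_proba <- function(model, x) {
  softmax_rows(tiny_cnn_forward(model, x)$logits)
}

# ---- optimizers -------------------------------------------------------

# state shared across steps; params updated functionally.
optimizer_init <- function(method = c("radam", "sgd")) {
  method <- match.arg(method)
  list(method = method, t = 0L, m = list(), v = list(),
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

# one update over the gradient list; frozen entries are simply absent from
# `grads` and therefore untouched.
optimizer_step <- function(state, params, grads, lr, weight_decay = 0) {
  state$t <- state$t + 1L
  t <- state$t
  b1 <- state$beta1; b2 <- state$beta2
  rho_inf <- 2 / (1 - b2) - 1
  rho_t <- rho_inf - 2 * t * b2^t / (1 - b2^t)
  for (layer in names(grads)) {
    for (slot in names(grads[[layer]])) {
      g <- grads[[layer]][[slot]]
      w <- params[[layer]][[slot]]
      if (weight_decay > 0) g <- g + weight_decay * w
      key <- paste(layer, slot, sep = ".")
      if (state$method == "sgd") {
        params[[layer]][[slot]] <- w - lr * g
        next
      }
      m <- if (is.null(state$m[[key]])) g * 0 else state$m[[key]]
      v <- if (is.null(state$v[[key]])) g * 0 else state$v[[key]]
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g * g
      state$m[[key]] <- m
      state$v[[key]] <- v
      m_hat <- m / (1 - b1^t)
      if (rho_t > 4) {
        r_t <- sqrt(((rho_t - 4) * (rho_t - 2) * rho_inf) /
                      ((rho_inf - 4) * (rho_inf - 2) * rho_t))
        v_hat <- sqrt(v / (1 - b2^t)) + state$eps
        params[[layer]][[slot]] <- w - lr * r_t * m_hat / v_hat
      } else {
        params[[layer]][[slot]] <- w - lr * m_hat
      }
    }
  }
  list(state = state, params = params)
}
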