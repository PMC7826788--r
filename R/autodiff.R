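# Minimal reverse-mode automatic differentiation on dense arrays.
#
# Activations are 4-D arrays laid out (H, W, C, N); channel descriptors
# (global-average-pooled features, MLP activations) are (C, N) matrices.
# Each op builds a graph node holding the forward value, its parents and a
# closure that pushes the output gradient onto the parents. ag_backward()
# walks the graph in reverse topological order. The engine is internal; the
# exported attention/network functions are thin forward-only wrappers.

.ag <- new.env(parent = emptyenv())
.ag$counter <- 0L

ag_node <- function(value, parents = list(), backward = NULL) {
  n <- new.env(parent = emptyenv())
  .ag$counter <- .ag$counter + 1L
  n$id <- .ag$counter
  n$value <- value
  n$grad <- NULL
  n$parents <- parents
  n$backward <- backward
  n$is_param <- FALSE
  class(n) <- "ag_node"
  n
}

ag_param <- function(value) {
  n <- ag_node(value)
  n$is_param <- TRUE
  n
}

ag_const <- function(value) ag_node(value)

ag_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

# Reverse topological order by iterative depth-first search, then gradient push.
ag_backward <- function(root, seed_grad = 1) {
  order <- vector("list", 64L)
  n_ord <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, expanded = FALSE))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(top$node$id)
    if (top$expanded) {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- top$node
    } else if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = top$node, expanded = TRUE)
      for (p in top$node$parents) {
        if (is.null(seen[[as.character(p$id)]])) {
          stack[[length(stack) + 1L]] <- list(node = p, expanded = FALSE)
        }
      }
    }
  }
  root$grad <- seed_grad
  for (i in seq_len(n_ord)) {
    node <- order[[n_ord - i + 1L]]
    if (!is.null(node$backward) && !is.null(node$grad)) node$backward(node$grad)
  }
  invisible(root)
}

# ---- elementwise ops ------------------------------------------------------

ag_add <- function(a, b) {
  out <- ag_node(a$value + b$value, list(a, b))
  out$backward <- function(g) {
    ag_accum(a, g)
    ag_accum(b, g)
  }
  out
}

ag_mul <- function(a, b) {
  out <- ag_node(a$value * b$value, list(a, b))
  out$backward <- function(g) {
    ag_accum(a, g * b$value)
    ag_accum(b, g * a$value)
  }
  out
}

ag_relu <- function(x) {
  v <- x$value
  v[v < 0] <- 0
  out <- ag_node(v, list(x))
  out$backward <- function(g) ag_accum(x, g * (x$value > 0))
  out
}

ag_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  out <- ag_node(s, list(x))
  out$backward <- function(g) ag_accum(x, g * s * (1 - s))
  out
}

ag_identity_act <- function(x) x

# ---- convolution ----------------------------------------------------------

# x: (H, W, Cin, N) node; w: (K, K, Cin, Cout) param; b: length-Cout param.
ag_conv2d <- function(x, w, b, stride = 1L, pad = 1L) {
  out <- ag_node(conv2d_fwd_cpp(x$value, w$value, b$value, stride, pad),
                 list(x, w, b))
  out$backward <- function(g) {
    gr <- conv2d_bwd_cpp(x$value, w$value, g, stride, pad)
    ag_accum(x, gr$gx)
    ag_accum(w, gr$gw)
    ag_accum(b, gr$gb)
  }
  out
}

# Transposed convolution, kernel 2, stride 2 (learned x2 upsampling).
# w: (2, 2, Cin, Cout). out[2i-1+a, 2j-1+b, ., n] = x[i, j, ., n] %*% W[a, b, , ].
ag_conv_transpose2 <- function(x, w, b) {
  d <- dim(x$value)
  H <- d[1]; W <- d[2]; Cin <- d[3]; N <- d[4]
  Cout <- dim(w$value)[4]
  out_v <- array(0, c(2L * H, 2L * W, Cout, N))
  for (n in seq_len(N)) {
    xm <- matrix(x$value[, , , n], H * W, Cin)
    for (a in 1:2) {
      for (bb in 1:2) {
        Wab <- matrix(w$value[a, bb, , ], Cin, Cout)
        out_v[seq(a, 2L * H, 2L), seq(bb, 2L * W, 2L), , n] <-
          array(xm %*% Wab, c(H, W, Cout))
      }
    }
  }
  out_v <- sweep_channels4(out_v, b$value)
  out <- ag_node(out_v, list(x, w, b))
  out$backward <- function(g) {
    gx <- array(0, d)
    gw <- array(0, dim(w$value))
    gb <- numeric(Cout)
    for (n in seq_len(N)) {
      xm <- matrix(x$value[, , , n], H * W, Cin)
      gxm <- matrix(0, H * W, Cin)
      for (a in 1:2) {
        for (bb in 1:2) {
          Wab <- matrix(w$value[a, bb, , ], Cin, Cout)
          gsub <- matrix(g[seq(a, 2L * H, 2L), seq(bb, 2L * W, 2L), , n],
                         H * W, Cout)
          gxm <- gxm + gsub %*% t(Wab)
          gw[a, bb, , ] <- gw[a, bb, , ] + t(xm) %*% gsub
          gb <- gb + colSums(gsub)
        }
      }
      gx[, , , n] <- array(gxm, c(H, W, Cin))
    }
    ag_accum(x, gx)
    ag_accum(w, gw)
    ag_accum(b, gb)
  }
  out
}

# add a per-channel vector to a (H, W, C, N) array
sweep_channels4 <- function(v, vec) {
  d <- dim(v)
  v + rep(rep(vec, each = d[1] * d[2]), times = d[4])
}

# multiply each channel plane of x (H, W, C, N) by scalars s (C, N)
ag_scale_channels <- function(x, s) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  fac <- rep(as.vector(s$value), each = hw)
  out <- ag_node(x$value * fac, list(x, s))
  out$backward <- function(g) {
    ag_accum(x, g * fac)
    gs <- matrix(colSums(matrix(g * x$value, nrow = hw)), d[3], d[4])
    ag_accum(s, gs)
  }
  out
}

# ---- pooling / reshaping --------------------------------------------------

# global average pooling: (H, W, C, N) -> (C, N)
ag_gap <- function(x) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  out <- ag_node(matrix(colMeans(matrix(x$value, nrow = hw)), d[3], d[4]),
                 list(x))
  out$backward <- function(g) {
    ag_accum(x, array(rep(as.vector(g), each = hw) / hw, d))
  }
  out
}

# dense layer on channel descriptors: x (Cin, N), w (Cout, Cin), b (Cout)
ag_linear <- function(x, w, b) {
  out <- ag_node(w$value %*% x$value + b$value, list(x, w, b))
  out$backward <- function(g) {
    ag_accum(x, t(w$value) %*% g)
    ag_accum(w, g %*% t(x$value))
    ag_accum(b, rowSums(g))
  }
  out
}

# channel concatenation of two (H, W, C, N) arrays
ag_concat_channels <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  v <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  v[, , seq_len(da[3]), ] <- a$value
  v[, , da[3] + seq_len(db[3]), ] <- b$value
  out <- ag_node(v, list(a, b))
  out$backward <- function(g) {
    ag_accum(a, g[, , seq_len(da[3]), , drop = FALSE])
    ag_accum(b, g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  }
  out
}

# ---- upsampling -----------------------------------------------------------

.upsample_cache <- new.env(parent = emptyenv())

# x2 interpolation matrix (2n x n). Bilinear uses half-pixel centers
# (out coord j maps to input j/2 - 0.25, clamped); nearest repeats each pixel.
upsample2_matrix <- function(n, mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  key <- paste0(mode, n)
  if (!is.null(.upsample_cache[[key]])) return(.upsample_cache[[key]])
  L <- matrix(0, 2L * n, n)
  if (mode == "nearest") {
    for (o in seq_len(2L * n)) L[o, ceiling(o / 2)] <- 1
  } else {
    for (o in seq_len(2L * n)) {
      src <- (o - 1) / 2 - 0.25
      i0 <- floor(src)
      w1 <- src - i0
      i0c <- min(max(i0, 0), n - 1) + 1L
      i1c <- min(max(i0 + 1, 0), n - 1) + 1L
      L[o, i0c] <- L[o, i0c] + (1 - w1)
      L[o, i1c] <- L[o, i1c] + w1
    }
  }
  .upsample_cache[[key]] <- L
  L
}

apply_axis1 <- function(v, L) {
  d <- dim(v)
  array(L %*% matrix(v, d[1]), c(nrow(L), d[-1]))
}

upsample2_value <- function(v, mode) {
  d <- dim(v)
  Lh <- upsample2_matrix(d[1], mode)
  Lw <- upsample2_matrix(d[2], mode)
  a <- apply_axis1(v, Lh)
  a <- aperm(a, c(2, 1, 3, 4))
  a <- apply_axis1(a, Lw)
  aperm(a, c(2, 1, 3, 4))
}

ag_upsample2 <- function(x, mode = "bilinear") {
  d <- dim(x$value)
  out <- ag_node(upsample2_value(x$value, mode), list(x))
  out$backward <- function(g) {
    Lh <- t(upsample2_matrix(d[1], mode))
    Lw <- t(upsample2_matrix(d[2], mode))
    a <- apply_axis1(g, Lh)
    a <- aperm(a, c(2, 1, 3, 4))
    a <- apply_axis1(a, Lw)
    ag_accum(x, aperm(a, c(2, 1, 3, 4)))
  }
  out
}

# ---- batch normalization --------------------------------------------------

bn_state <- function(channels, momentum = 0.1, eps = 1e-5) {
  s <- new.env(parent = emptyenv())
  s$running_mean <- numeric(channels)
  s$running_var <- rep(1, channels)
  s$momentum <- momentum
  s$eps <- eps
  s
}

# Batch norm over (H, W, N) per channel for 4-D activations. At batch size 1
# in training the running statistics are used instead (tiny-batch fallback).
ag_bn4 <- function(x, gamma, beta, state, training = FALSE) {
  d <- dim(x$value)
  C <- d[3]; m <- d[1] * d[2] * d[4]
  per_c <- function(v) matrix(aperm(v, c(1, 2, 4, 3)), ncol = C)
  from_c <- function(mat) aperm(array(mat, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  use_batch <- training && d[4] > 1L
  xm <- per_c(x$value)
  if (use_batch) {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2
    state$running_mean <- (1 - state$momentum) * state$running_mean + state$momentum * mu
    unb <- if (m > 1) va * m / (m - 1) else va
    state$running_var <- (1 - state$momentum) * state$running_var + state$momentum * unb
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  inv <- 1 / sqrt(va + state$eps)
  xhat <- sweep(sweep(xm, 2, mu, "-"), 2, inv, "*")
  y <- sweep(sweep(xhat, 2, gamma$value, "*"), 2, beta$value, "+")
  out <- ag_node(from_c(y), list(x, gamma, beta))
  out$backward <- function(g) {
    gm <- per_c(g)
    ag_accum(gamma, colSums(gm * xhat))
    ag_accum(beta, colSums(gm))
    gh <- sweep(gm, 2, gamma$value, "*")
    if (use_batch) {
      # standard training-mode batch-norm input gradient
      t1 <- sweep(gh, 2, colMeans(gh), "-")
      t2 <- sweep(xhat, 2, colMeans(gh * xhat), "*")
      gx <- sweep(t1 - t2, 2, inv, "*")
    } else {
      gx <- sweep(gh, 2, inv, "*")
    }
    ag_accum(x, from_c(gx))
  }
  out
}

# Batch norm on (C, N) channel descriptors: statistics over the batch axis.
ag_bn2 <- function(x, gamma, beta, state, training = FALSE) {
  v <- x$value
  N <- ncol(v)
  use_batch <- training && N > 1L
  if (use_batch) {
    mu <- rowMeans(v)
    va <- rowMeans(v^2) - mu^2
    state$running_mean <- (1 - state$momentum) * state$running_mean + state$momentum * mu
    unb <- if (N > 1) va * N / (N - 1) else va
    state$running_var <- (1 - state$momentum) * state$running_var + state$momentum * unb
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  inv <- 1 / sqrt(va + state$eps)
  xhat <- (v - mu) * inv
  out <- ag_node(xhat * gamma$value + beta$value, list(x, gamma, beta))
  out$backward <- function(g) {
    ag_accum(gamma, rowSums(g * xhat))
    ag_accum(beta, rowSums(g))
    gh <- g * gamma$value
    if (use_batch) {
      gx <- (gh - rowMeans(gh) - xhat * rowMeans(gh * xhat)) * inv
    } else {
      gx <- gh * inv
    }
    ag_accum(x, gx)
  }
  out
}

# ---- losses ---------------------------------------------------------------

# mean over all elements of (pred - target)^2; target is a plain array
ag_mse <- function(pred, target) {
  diff <- pred$value - target
  out <- ag_node(mean(diff^2), list(pred))
  out$backward <- function(g) ag_accum(pred, g * 2 * diff / length(diff))
  out
}

# ---- parameter utilities --------------------------------------------------

# Collect every ag_param node from an arbitrarily nested list structure.
collect_params <- function(x, prefix = "") {
  out <- list()
  if (inherits(x, "ag_node")) {
    if (isTRUE(x$is_param)) out[[prefix]] <- x
    return(out)
  }
  if (is.list(x)) {
    nms <- names(x)
    for (i in seq_along(x)) {
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      out <- c(out, collect_params(x[[i]], paste0(prefix, if (nzchar(prefix)) "." else "", nm)))
    }
  }
  out
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# Kaiming-style fan-in scaled uniform initialization; biases start at zero.
init_uniform <- function(dims, fan_in) {
  bound <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -bound, bound), dims)
}
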