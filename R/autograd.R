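# Minimal reverse-mode automatic differentiation.  A tape records nodes in
# creation (= topological) order; tp_backward() sweeps it in reverse.  Nodes
# are environments holding a value, an accumulated gradient, parent pointers
# and a backward closure returning one gradient per parent.  Leaves may carry
# a parameter environment, in which case gradients accumulate there instead.
# Tensor-valued nodes use the internal channel-first layout [C, H, W, N].
#
# Only the op vocabulary the networks and the loss oracle need is defined:
# convolutions, transposed convolutions, batch norm, ReLU/sigmoid, channel
# concat/scaling, bilinear resize, global pooling, dense layers, and a few
# scalar/elementwise ops used to differentiate the focal Tversky loss itself.

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

tp_node <- function(tape, value, parents = list(), backward = NULL, param = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  nd$param <- param
  if (!is.null(tape) && !is.null(backward)) {
    if (tape$n == length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    tape$n <- tape$n + 1L
    tape$nodes[[tape$n]] <- nd
  }
  nd
}

tp_leaf <- function(value, param = NULL) tp_node(NULL, value, param = param)

tp_accum <- function(node, g) {
  if (!is.null(node$param)) {
    node$param$grad <- node$param$grad + g
  } else {
    node$grad <- if (is.null(node$grad)) g else node$grad + g
  }
  invisible(NULL)
}

# seeds: list of list(node = <node>, grad = <array>) pairs (multiple roots
# support deep supervision, where several heads contribute to one loss).
tp_backward <- function(tape, seeds) {
  for (s in seeds) tp_accum(s$node, s$grad)
  if (tape$n == 0L) return(invisible(NULL))
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad)) next
    gs <- nd$backward(nd$grad)
    ps <- nd$parents
    for (k in seq_along(ps)) {
      if (!is.null(gs[[k]])) tp_accum(ps[[k]], gs[[k]])
    }
    nd$grad <- NULL  # free as we go
  }
  invisible(NULL)
}

## ---- tensor ops (channel-first values) ------------------------------------

op_conv2d <- function(tape, x, w, b, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  val <- conv2d_fwd(x$value, w$value, b$value, k, stride, pad)
  xv <- x$value; wv <- w$value
  tp_node(tape, val, parents = list(x, wleaf(tape, w), wleaf(tape, b)),
          backward = function(dy) {
            g <- conv2d_bwd(dy, xv, wv, k, stride, pad)
            list(g$dx, g$dw, g$db)
          })
}

op_convt2d <- function(tape, x, a, b, k = 4L, stride = 2L, pad = 1L) {
  val <- convt2d_fwd(x$value, a$value, b$value, k, stride, pad)
  xv <- x$value; av <- a$value
  tp_node(tape, val, parents = list(x, wleaf(tape, a), wleaf(tape, b)),
          backward = function(dy) {
            g <- convt2d_bwd(dy, xv, av, k, stride, pad)
            list(g$dx, g$da, g$db)
          })
}

# Parameter leaf bound to a param environment (see layers.R).
wleaf <- function(tape, p) tp_node(NULL, p$value, param = p)

op_relu <- function(tape, x) {
  val <- relu_fwd_cpp(x$value)
  tp_node(tape, val, parents = list(x),
          backward = function(dy) list(relu_bwd_cpp(dy, val)))
}

op_sigmoid <- function(tape, x) {
  val <- sigmoid_fwd_cpp(x$value)
  tp_node(tape, val, parents = list(x),
          backward = function(dy) list(sigmoid_bwd_cpp(dy, val)))
}

op_activation <- function(tape, x, act) {
  switch(act,
         relu = op_relu(tape, x),
         sigmoid = op_sigmoid(tape, x),
         linear = x,
         stop("unknown activation: ", act, call. = FALSE))
}

op_clamp <- function(tape, x, lo, hi) {
  inside <- x$value > lo & x$value < hi
  val <- pmin(pmax(x$value, lo), hi)
  if (!is.null(dim(x$value))) dim(val) <- dim(x$value)
  tp_node(tape, val, parents = list(x), backward = function(dy) list(dy * inside))
}

op_add <- function(tape, a, b) {
  tp_node(tape, a$value + b$value, parents = list(a, b),
          backward = function(dy) list(dy, dy))
}

# concatenate along the channel (first) dimension
op_concat_c <- function(tape, xs) {
  dims <- lapply(xs, function(x) cf_dims(x$value))
  h <- dims[[1]]$h; w <- dims[[1]]$w; n <- dims[[1]]$n
  for (d in dims) {
    if (d$h != h || d$w != w || d$n != n)
      stop("concat: spatial/batch mismatch (", d$h, "x", d$w, " vs ", h, "x", w, ")", call. = FALSE)
  }
  cs <- vapply(dims, function(d) d$c, numeric(1))
  val <- do.call(rbind, lapply(xs, function(x) matrix(x$value, nrow = dim(x$value)[1L])))
  dim(val) <- c(sum(cs), h, w, n)
  tp_node(tape, val, parents = xs, backward = function(dy) {
    dym <- matrix(dy, nrow = sum(cs))
    out <- vector("list", length(cs))
    at <- 0
    for (i in seq_along(cs)) {
      g <- dym[at + seq_len(cs[i]), , drop = FALSE]
      dim(g) <- c(cs[i], h, w, n)
      out[[i]] <- g
      at <- at + cs[i]
    }
    out
  })
}

op_bilinear <- function(tape, x, h_out, w_out) {
  d <- cf_dims(x$value)
  rh <- interp_matrix(h_out, d$h); rw <- interp_matrix(w_out, d$w)
  val <- resize_bilinear_chw(x$value, h_out, w_out, rh, rw)
  tp_node(tape, val, parents = list(x), backward = function(dy) {
    list(resize_bilinear_chw(dy, d$h, d$w, t(rh), t(rw)))
  })
}

# Batch norm over (H, W, N) per channel.  Training mode uses batch moments and
# updates the layer's running statistics in place; eval mode uses the stored
# running moments (so inference is deterministic and batch-size independent).
op_batchnorm <- function(tape, x, layer, training) {
  d <- cf_dims(x$value)
  m <- d$h * d$w * d$n
  if (training) {
    st <- channel_stats_cpp(x$value, d$c)
    mu <- st$mean; v <- st$var
    layer$state$mean <- (1 - layer$momentum) * layer$state$mean + layer$momentum * mu
    layer$state$var  <- (1 - layer$momentum) * layer$state$var  + layer$momentum * v
  } else {
    mu <- layer$state$mean
    v <- layer$state$var
  }
  inv <- 1 / sqrt(v + layer$eps)
  gamma <- layer$gamma; beta <- layer$beta
  # y = x * (gamma*inv) + (beta - gamma*inv*mu) in one pass
  gi <- gamma$value * inv
  val <- channel_affine_cpp(x$value, gi, beta$value - gi * mu)
  xv <- x$value
  tp_node(tape, val, parents = list(x, wleaf(tape, gamma), wleaf(tape, beta)),
          backward = function(dy) {
            xhat <- channel_affine_cpp(xv, inv, -mu * inv)
            dots <- channel_dots_cpp(dy, xhat, d$c)
            dgamma <- dots$dot
            dbeta <- dots$sum
            if (training) {
              dx <- bn_bwd_cpp(dy, xhat, gamma$value,
                               gamma$value * dots$sum / m,
                               gamma$value * dots$dot / m, inv)
            } else {
              dx <- channel_affine_cpp(dy, gamma$value * inv, numeric(d$c))
            }
            list(dx, dgamma, dbeta)
          })
}

# Global average / max pooling: [C, H, W, N] -> [C, N].
op_gap <- function(tape, x) {
  d <- cf_dims(x$value)
  hw <- d$h * d$w
  val <- matrix(0, d$c, d$n)
  for (n in seq_len(d$n)) val[, n] <- rowMeans(matrix(x$value[, , , n], d$c))
  tp_node(tape, val, parents = list(x), backward = function(dy) {
    g <- array(0, dim(x$value))
    for (n in seq_len(d$n)) g[, , , n] <- matrix(dy[, n] / hw, d$c, hw)
    list(g)
  })
}

op_gmp <- function(tape, x) {
  d <- cf_dims(x$value)
  hw <- d$h * d$w
  val <- matrix(0, d$c, d$n)
  idx <- matrix(0L, d$c, d$n)
  for (n in seq_len(d$n)) {
    m <- matrix(x$value[, , , n], d$c)
    idx[, n] <- max.col(m, ties.method = "first")
    val[, n] <- m[cbind(seq_len(d$c), idx[, n])]
  }
  tp_node(tape, val, parents = list(x), backward = function(dy) {
    g <- array(0, dim(x$value))
    for (n in seq_len(d$n)) {
      m <- matrix(0, d$c, hw)
      m[cbind(seq_len(d$c), idx[, n])] <- dy[, n]
      g[, , , n] <- m
    }
    list(g)
  })
}

# Dense layer on [C_in, N] matrices: y = W x + b.
op_dense <- function(tape, x, w, b) {
  val <- w$value %*% x$value + b$value
  xv <- x$value; wv <- w$value
  tp_node(tape, val, parents = list(x, wleaf(tape, w), wleaf(tape, b)),
          backward = function(dy) {
            list(crossprod(wv, dy), tcrossprod(dy, xv), rowSums(dy))
          })
}

# Multiply channel c of x by w[c, n] (attention reweighting).
op_scale_channels <- function(tape, x, w) {
  d <- cf_dims(x$value)
  if (nrow(w$value) != d$c)
    stop("attention weights have length ", nrow(w$value),
         " but the feature map has ", d$c, " channels", call. = FALSE)
  val <- scale_channels_cpp(x$value, w$value, d$h * d$w)
  xv <- x$value; wv <- w$value
  tp_node(tape, val, parents = list(x, w), backward = function(dy) {
    g <- scale_channels_bwd_cpp(dy, xv, wv, d$h * d$w)
    list(g$dx, g$dw)
  })
}

## ---- scalar / elementwise ops (loss-oracle vocabulary) --------------------

op_mul_const <- function(tape, x, k) {
  tp_node(tape, x$value * k, parents = list(x), backward = function(dy) list(dy * k))
}

op_sum <- function(tape, x) {
  d <- dim(x$value); len <- length(x$value)
  tp_node(tape, sum(x$value), parents = list(x), backward = function(dy) {
    g <- rep(dy, len); if (!is.null(d)) dim(g) <- d
    list(g)
  })
}

op_scalar_add <- function(tape, xs, weights = rep(1, length(xs)), const = 0) {
  val <- const + sum(mapply(function(x, w) w * x$value, xs, weights))
  tp_node(tape, val, parents = xs, backward = function(dy) {
    lapply(weights, function(w) dy * w)
  })
}

op_scalar_div <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  tp_node(tape, av / bv, parents = list(a, b), backward = function(dy) {
    list(dy / bv, -dy * av / bv^2)
  })
}

op_scalar_pow <- function(tape, x, p) {
  xv <- x$value
  tp_node(tape, xv^p, parents = list(x), backward = function(dy) list(dy * p * xv^(p - 1)))
}
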