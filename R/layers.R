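# Trainable parameters and the layer vocabulary of the networks.  A parameter
# is an environment (so SGD updates are visible everywhere it is referenced)
# holding value, gradient and momentum buffers.  Layer constructors draw
# their initial weights from the current RNG stream: callers seed once per
# model build, which makes initialisation reproducible.

new_param <- function(value, name = "") {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- value * 0
  p$mom <- value * 0
  p$name <- name
  class(p) <- "gcld_param"
  p
}

# He-normal fan-in initialisation, the standard choice for ReLU networks.
he_init <- function(nr, nc, fan_in) matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)

new_conv <- function(cin, cout, k = 3L, stride = 1L, name = "conv") {
  list(kind = "conv", k = k, stride = stride, pad = (k - 1L) %/% 2L,
       cin = cin, cout = cout,
       w = new_param(he_init(k * k * cin, cout, k * k * cin), paste0(name, ".w")),
       b = new_param(numeric(cout), paste0(name, ".b")))
}

# Transposed conv, kernel 4 stride 2 pad 1: exact spatial doubling.
new_convt <- function(cin, cout, k = 4L, name = "convt") {
  list(kind = "convt", k = k, stride = 2L, pad = 1L, cin = cin, cout = cout,
       w = new_param(he_init(k * k * cout, cin, k * k * cin), paste0(name, ".w")),
       b = new_param(numeric(cout), paste0(name, ".b")))
}

new_bn <- function(c, eps = 1e-5, momentum = 0.1, name = "bn") {
  st <- new.env(parent = emptyenv())
  st$mean <- numeric(c)
  st$var <- rep(1, c)
  list(kind = "bn", c = c, eps = eps, momentum = momentum, state = st,
       gamma = new_param(rep(1, c), paste0(name, ".gamma")),
       beta = new_param(numeric(c), paste0(name, ".beta")))
}

new_dense <- function(cin, cout, name = "dense") {
  list(kind = "dense", cin = cin, cout = cout,
       w = new_param(he_init(cout, cin, cin), paste0(name, ".w")),
       b = new_param(numeric(cout), paste0(name, ".b")))
}

# conv -> activation -> BN (the networks apply f inside the conv step and
# normalise its output; see the methods vignette for the ordering rationale).
new_conv_block <- function(cin, cout, k = 3L, stride = 1L, act = "relu",
                           bn = TRUE, name = "block") {
  list(kind = "conv_block", act = act,
       conv = new_conv(cin, cout, k, stride, paste0(name, ".conv")),
       bn = if (bn) new_bn(cout, name = paste0(name, ".bn")))
}

fwd_conv <- function(tape, x, ly) op_conv2d(tape, x, ly$w, ly$b, ly$k, ly$stride, ly$pad)
fwd_convt <- function(tape, x, ly) op_convt2d(tape, x, ly$w, ly$b, ly$k, ly$stride, ly$pad)
fwd_dense <- function(tape, x, ly) op_dense(tape, x, ly$w, ly$b)

fwd_conv_block <- function(tape, x, ly, training) {
  y <- fwd_conv(tape, x, ly$conv)
  y <- op_activation(tape, y, ly$act)
  if (!is.null(ly$bn)) y <- op_batchnorm(tape, y, ly$bn, training)
  y
}

# Recursively collect every gcld_param in a nested layer structure.
collect_params <- function(x) {
  if (inherits(x, "gcld_param")) return(list(x))
  if (is.list(x)) return(do.call(c, c(lapply(x, collect_params), list(list()))))
  list()
}

n_parameters <- function(params) sum(vapply(params, function(p) length(p$value), numeric(1)))

zero_grads <- function(params) {
  for (p in params) p$grad <- p$grad * 0
  invisible(NULL)
}

sgd_step <- function(params, lr, momentum = 0.9, weight_decay = 0) {
  for (p in params) {
    g <- p$grad
    if (weight_decay > 0) g <- g + weight_decay * p$value
    p$mom <- momentum * p$mom - lr * g
    p$value <- p$value + p$mom
  }
  invisible(NULL)
}
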