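# Shared test utilities: finite-difference gradient checking against the
# autodiff tape, and a naive direct-summation convolution oracle.

# Max abs difference between tape gradients and central finite differences
# for d(sum(out * g))/dx.
fd_grad_check <- function(make_out, x0, h = 1e-6) {
  tape <- gcldnet:::new_tape()
  xn <- gcldnet:::tp_leaf(x0)
  out <- make_out(tape, xn)
  set.seed(42)
  g <- array(rnorm(length(out$value)), dim(out$value) %||% length(out$value))
  gcldnet:::tp_backward(tape, list(list(node = out, grad = g)))
  f <- function(xv) sum(make_out(gcldnet:::new_tape(), gcldnet:::tp_leaf(xv))$value * g)
  num <- x0
  for (i in seq_along(x0)) {
    e1 <- x0; e1[i] <- e1[i] + h
    e2 <- x0; e2[i] <- e2[i] - h
    num[i] <- (f(e1) - f(e2)) / (2 * h)
  }
  max(abs(num - xn$grad))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Direct-summation 2-D convolution on a public-layout [H, W, C] array with a
# [k, k, Cin, Cout] kernel, stride/pad as given.  Deliberately slow and
# index-literal: the oracle for the GEMM-based implementation.
naive_conv <- function(x, w, bias, stride = 1L, pad = 1L) {
  k <- dim(w)[1]; cin <- dim(w)[3]; cout <- dim(w)[4]
  H <- dim(x)[1]; W <- dim(x)[2]
  ho <- (H + 2 * pad - k) %/% stride + 1L
  wo <- (W + 2 * pad - k) %/% stride + 1L
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, cin))
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  y <- array(0, c(ho, wo, cout))
  for (co in seq_len(cout)) for (i in seq_len(ho)) for (j in seq_len(wo)) {
    acc <- bias[co]
    for (ci in seq_len(cin)) for (ki in seq_len(k)) for (kj in seq_len(k)) {
      acc <- acc + xp[(i - 1) * stride + ki, (j - 1) * stride + kj, ci] * w[ki, kj, ci, co]
    }
    y[i, j, co] <- acc
  }
  y
}

# tiny encoder spec used across tests
tiny_spec <- function() encoder_spec(widths = c(8L, 16L, 24L, 32L, 48L, 64L))

# small, fast synthetic dataset
tiny_dataset <- function(n = 6, size = 64, seed = 5) {
  generate_dataset(synth_spec(size = size, seed = seed), n)
}
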