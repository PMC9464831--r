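# Every differentiable op is checked against central finite differences on
# small random tensors; layer parameters are checked through the tape too.

test_that("tensor op input-gradients agree with finite differences", {
  set.seed(10)
  x0 <- array(rnorm(2 * 6 * 6 * 2), c(2, 6, 6, 2))
  cv <- gcldnet:::new_conv(2L, 3L)
  cv2 <- gcldnet:::new_conv(2L, 3L, stride = 2L)
  ct <- gcldnet:::new_convt(2L, 3L)
  bn <- gcldnet:::new_bn(2L)
  at <- attention_params(2L, 2)
  wfix <- matrix(runif(4, 0.2, 0.8), 2, 2)
  checks <- list(
    conv = function(tp, xn) gcldnet:::fwd_conv(tp, xn, cv),
    conv_s2 = function(tp, xn) gcldnet:::fwd_conv(tp, xn, cv2),
    convt = function(tp, xn) gcldnet:::fwd_convt(tp, xn, ct),
    bn_train = function(tp, xn) gcldnet:::op_batchnorm(tp, xn, bn, TRUE),
    bn_eval = function(tp, xn) gcldnet:::op_batchnorm(tp, xn, bn, FALSE),
    relu = function(tp, xn) gcldnet:::op_relu(tp, xn),
    sigmoid = function(tp, xn) gcldnet:::op_sigmoid(tp, xn),
    bilinear = function(tp, xn) gcldnet:::op_bilinear(tp, xn, 9L, 11L),
    gap = function(tp, xn) gcldnet:::op_gap(tp, xn),
    gmp = function(tp, xn) gcldnet:::op_gmp(tp, xn),
    attention = function(tp, xn) gcldnet:::channel_attention_nodes(tp, xn, at),
    scale = function(tp, xn) gcldnet:::op_scale_channels(tp, xn, gcldnet:::tp_leaf(wfix)),
    concat = function(tp, xn) gcldnet:::op_concat_c(tp, list(xn, gcldnet:::op_relu(tp, xn))))
  for (nm in names(checks)) {
    expect_lt(fd_grad_check(checks[[nm]], x0), 1e-6, label = paste("op", nm))
  }
})

test_that("parameter gradients flow through the tape into param environments", {
  set.seed(11)
  x0 <- array(rnorm(2 * 6 * 6 * 2), c(2, 6, 6, 2))
  ly <- gcldnet:::new_conv(2L, 3L)
  fwd <- function() {
    tape <- gcldnet:::new_tape()
    out <- gcldnet:::fwd_conv(tape, gcldnet:::tp_leaf(x0), ly)
    list(tape = tape, out = out)
  }
  r <- fwd()
  g <- array(1, dim(r$out$value))
  gcldnet:::tp_backward(r$tape, list(list(node = r$out, grad = g)))
  an <- ly$w$grad
  i <- 17L
  h <- 1e-6
  v0 <- ly$w$value[i]
  ly$w$value[i] <- v0 + h; f1 <- sum(fwd()$out$value)
  ly$w$value[i] <- v0 - h; f2 <- sum(fwd()$out$value)
  ly$w$value[i] <- v0
  expect_equal(an[i], (f1 - f2) / (2 * h), tolerance = 1e-5)
})

test_that("multi-root backward accumulates gradients from several heads", {
  set.seed(12)
  x0 <- array(rnorm(2 * 4 * 4 * 1), c(2, 4, 4, 1))
  tape <- gcldnet:::new_tape()
  xn <- gcldnet:::tp_leaf(x0)
  mid <- gcldnet:::op_relu(tape, xn)
  h1 <- gcldnet:::op_sigmoid(tape, mid)
  h2 <- gcldnet:::op_mul_const(tape, mid, 2)
  g1 <- array(1, dim(h1$value)); g2 <- array(0.5, dim(h2$value))
  gcldnet:::tp_backward(tape, list(list(node = h1, grad = g1),
                                   list(node = h2, grad = g2)))
  s <- h1$value * (1 - h1$value)
  want <- (s * 1 + 2 * 0.5) * (x0 > 0)
  expect_equal(xn$grad, want, tolerance = 1e-12)
})

test_that("sgd with momentum follows the textbook update", {
  p <- gcldnet:::new_param(c(1, 2))
  p$grad <- c(0.5, -1)
  gcldnet:::sgd_step(list(p), lr = 0.1, momentum = 0.9)
  expect_equal(p$mom, c(-0.05, 0.1))
  expect_equal(p$value, c(0.95, 2.1))
  p$grad <- c(0, 0)
  gcldnet:::sgd_step(list(p), lr = 0.1, momentum = 0.9)
  expect_equal(p$value, c(0.95 - 0.045, 2.1 + 0.09))
})
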