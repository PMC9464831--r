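test_that("upsample_to_input honours size contracts and constants", {
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  up <- upsample_to_input(x, 32)
  expect_equal(dim(up), c(32L, 32L, 3L, 1L))
  same <- upsample_to_input(x, 8)
  expect_equal(same, as_feature_map(x))
  cst <- array(2.5, c(4, 4, 2))
  expect_equal(upsample_to_input(cst, 16), array(2.5, c(16, 16, 2, 1)))
  expect_error(upsample_to_input(x, 4), "target size")
})

test_that("conv_bn normalises with batch statistics", {
  set.seed(30)
  # hand-built block: identity-ish check via gamma = 0 -> constant beta
  blk <- gcldnet:::new_conv_block(1L, 1L)
  blk$bn$gamma$value <- 0
  blk$bn$beta$value <- 4.2
  x <- array(runif(6 * 6), c(6, 6, 1))
  expect_equal(conv_bn(x, blk), array(4.2, c(6, 6, 1, 1)))
  # delta kernel + zero bias passes the input through the ReLU unchanged,
  # so the block output is the batch-standardised input
  blk2 <- gcldnet:::new_conv_block(1L, 1L)
  blk2$conv$w$value[] <- 0
  blk2$conv$w$value[5, 1] <- 1                 # centre tap of the 3x3 kernel
  blk2$conv$b$value[] <- 0
  y <- conv_bn(array(c(1, 5, 3, 7), c(2, 2, 1)), blk2)
  expect_equal(as.numeric(y), (c(1, 5, 3, 7) - 4) / sqrt(5 + 1e-5),
               tolerance = 1e-12)
})

test_that("batch normalisation of [[1,3],[5,7]] standardises exactly", {
  bn <- gcldnet:::new_bn(1L)
  x <- array(c(1, 5, 3, 7), c(1, 2, 2, 1))    # [[1,3],[5,7]] channel-first
  nd <- gcldnet:::op_batchnorm(NULL, gcldnet:::tp_leaf(x), bn, TRUE)
  want <- (c(1, 5, 3, 7) - 4) / sqrt(5 + 1e-5) # mean 4, population var 5
  expect_equal(as.numeric(nd$value), want, tolerance = 1e-12)
})

test_that("channel attention weights lie strictly in (0,1)", {
  set.seed(31)
  for (rep in 1:25) {
    c <- sample(2:12, 1)
    at <- attention_params(c, r = sample(c(2, 4, 16), 1))
    x <- array(rnorm(c * 8 * 8, sd = runif(1, 0.1, 5)), c(8, 8, c))
    w <- channel_attention(x, at)
    expect_true(all(w > 0 & w < 1))
    expect_equal(dim(w), c(c, 1L))
  }
})

test_that("a zero-weight MLP yields attention exactly 0.5 per channel", {
  at <- attention_params(6L, r = 2)
  at$fc1$w$value[] <- 0; at$fc1$b$value[] <- 0
  at$fc2$w$value[] <- 0; at$fc2$b$value[] <- 0
  x <- array(rnorm(6 * 4 * 4), c(4, 4, 6))
  expect_equal(channel_attention(x, at), matrix(0.5, 6, 1))
})

test_that("constant maps pool to equal average and max descriptors", {
  x <- array(1.3, c(2, 5, 5, 1))              # channel-first constant map
  avg <- gcldnet:::op_gap(NULL, gcldnet:::tp_leaf(x))$value
  mx <- gcldnet:::op_gmp(NULL, gcldnet:::tp_leaf(x))$value
  expect_equal(avg, mx)
  # and the worked pooling example: [[1,3],[5,7]] -> mean 4, max 7
  y <- array(c(1, 5, 3, 7), c(1, 2, 2, 1))
  expect_equal(as.numeric(gcldnet:::op_gap(NULL, gcldnet:::tp_leaf(y))$value), 4)
  expect_equal(as.numeric(gcldnet:::op_gmp(NULL, gcldnet:::tp_leaf(y))$value), 7)
})

test_that("apply_attention reweights channels as an elementwise contraction", {
  x <- array(runif(3 * 4 * 4), c(4, 4, 3))
  expect_equal(apply_attention(rep(1, 3), x), as_feature_map(x))
  expect_equal(apply_attention(rep(0, 3), x), as_feature_map(x) * 0)
  two <- array(c(2, 4), c(1, 1, 2))
  expect_equal(as.numeric(apply_attention(c(0.5, 0.5), two)), c(1, 2))
  expect_error(apply_attention(c(1, 1), x), "channels")
  # contraction in magnitude for weights in (0,1)
  set.seed(32)
  w <- runif(3)
  expect_true(all(abs(apply_attention(w, x)) <= abs(as_feature_map(x))))
})

test_that("affm_fuse concatenates five attended maps at input resolution", {
  set.seed(33)
  widths <- c(4, 5, 6, 7, 8)
  agg <- lapply(1:5, function(i)
    array(rnorm(widths[i] * (32 / 2^(i - 1))^2), c(32 / 2^(i - 1), 32 / 2^(i - 1), widths[i])))
  affm <- gcldnet:::make_affm(widths, r = 2)
  xf <- affm_fuse(agg, affm)
  expect_equal(dim(xf), c(32L, 32L, sum(widths), 1L))
  # attention disabled: plain multiscale upsample-and-concatenate
  affm0 <- gcldnet:::make_affm(widths, r = 2, attention = FALSE)
  xf0 <- affm_fuse(agg, affm0)
  want <- aggregate_level(lapply(agg, function(m) upsample_to_input(m, 32)))
  expect_equal(xf0, want)
  # all-zero inputs propagate to an all-zero fusion (biases are zero)
  zeros <- lapply(agg, function(m) m * 0)
  expect_equal(affm_fuse(zeros, affm), xf * 0)
})

test_that("the segmentation head is a sigmoid probability map", {
  set.seed(34)
  head <- gcldnet:::make_head(4L)
  x <- array(rnorm(4 * 8 * 8), c(8, 8, 4))
  p <- segmentation_head(x, head)
  expect_equal(dim(p), c(8L, 8L, 1L, 1L))
  expect_true(all(p > 0 & p < 1))
  head$w$value[] <- 0; head$b$value[] <- 0
  expect_equal(segmentation_head(x, head), array(0.5, c(8, 8, 1, 1)))
})
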