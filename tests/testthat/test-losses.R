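# Focal Tversky loss: worked examples, the Dice special case, closed-form
# gradients against reverse-mode autodiff and finite differences, and the
# monotonicity/range properties.

test_that("the Tversky index reproduces hand-computed values", {
  p <- tversky_params(0.7, 0.3, 1)
  expect_equal(tversky_index(c(1, 0.5, 0), c(1, 1, 0), p),
               1.5 / (1.5 + 0.3 * 0.5), tolerance = 1e-6)
  # perfect binary prediction: no false mass, index 1 for any weights
  g <- c(1, 0, 1, 1, 0)
  expect_equal(tversky_index(g, g, tversky_params(0.9, 0.1, 2)), 1)
  # doubly-empty case is defined as 1 via smoothing
  expect_equal(tversky_index(rep(0, 8), rep(0, 8)), 1)
  expect_error(tversky_index(numeric(0), numeric(0)), "empty")
  expect_error(tversky_index(c(0.5), c(1, 0)), "length")
})

test_that("the focal exponent reshapes the loss as (1 - TI)^(1/lambda)", {
  p1 <- c(1, 0.5, 0); g1 <- c(1, 1, 0)
  l1 <- focal_tversky_loss(p1, g1, tversky_params(0.7, 0.3, 1))
  expect_equal(l1, 1 - 0.909091, tolerance = 1e-4)
  l3 <- focal_tversky_loss(p1, g1, tversky_params(0.7, 0.3, 3))
  expect_equal(l3, (1 - 0.909091)^(1 / 3), tolerance = 1e-4)
  expect_equal(focal_tversky_loss(g1, g1, tversky_params()), 0)
  expect_error(tversky_params(lambda = 0), "positive")
  expect_warning(tversky_params(lambda = 5), "recommended range")
})

test_that("at alpha = beta = 0.5, lambda = 1 the loss is exactly the Dice loss", {
  set.seed(40)
  pars <- tversky_params(0.5, 0.5, 1)
  for (i in 1:50) {
    p1 <- runif(64)
    g1 <- rbinom(64, 1, runif(1, 0.1, 0.9))
    expect_equal(focal_tversky_loss(p1, g1, pars), dice_loss(p1, g1),
                 tolerance = 1e-12)
  }
})

test_that("analytic gradients match autodiff and finite differences", {
  set.seed(41)
  grids <- list(tversky_params(0.5, 0.5, 1), tversky_params(0.7, 0.3, 4 / 3),
                suppressWarnings(tversky_params(0.3, 0.7, 3)))
  for (pars in grids) {
    for (i in 1:10) {
      p1 <- runif(16, 0.05, 0.95)
      g1 <- rbinom(16, 1, 0.5)
      an <- ftl_gradients(p1, g1, pars)
      ad <- gcldnet:::ftl_autodiff_gradients(p1, g1, pars)
      fd <- gcldnet:::ftl_numeric_gradients(p1, g1, pars)
      expect_lt(max(abs(an$dp1 - ad$dp1)) / max(abs(ad$dp1)), 1e-10)
      expect_lt(max(abs(an$dp0 - ad$dp0)) / max(abs(ad$dp1)), 1e-10)
      expect_lt(max(abs(an$dp1 - fd$dp1)) / max(abs(fd$dp1)), 1e-5)
      # background pixels carry no p0 gradient (factor g1)
      expect_true(all(an$dp0[g1 == 0] == 0))
    }
  }
})

test_that("the gradient singularity at TI = 1 is reported, not NaN", {
  g <- c(1, 0, 1)
  expect_error(ftl_gradients(g, g, tversky_params(0.7, 0.3, 2)),
               class = "gcld_ftl_singular")
  # lambda = 1 has no singularity: gradient defined everywhere
  out <- ftl_gradients(g, g, tversky_params(0.7, 0.3, 1))
  expect_true(all(is.finite(out$dp1)))
})

test_that("loss range and strict monotonicity in the Tversky index hold", {
  set.seed(42)
  for (lam in c(1, 4 / 3, 2, 3)) {
    ti_grid <- seq(0.01, 0.99, by = 0.01)
    loss <- (1 - ti_grid)^(1 / lam)
    expect_true(all(loss >= 0 & loss <= 1))
    expect_true(all(diff(loss) < 0))
  }
  for (i in 1:20) {
    p1 <- runif(32); g1 <- rbinom(32, 1, 0.5)
    l <- focal_tversky_loss(p1, g1, tversky_params())
    expect_gte(l, 0); expect_lte(l, 1)
  }
})

test_that("raising alpha never decreases the loss on imperfect predictions", {
  set.seed(43)
  for (i in 1:20) {
    p1 <- runif(32); g1 <- rbinom(32, 1, 0.5)
    if (!any(p1 < 1 & g1 == 1)) next        # ensure false-negative mass exists
    ls <- vapply(c(0.3, 0.5, 0.7, 0.9), function(a)
      focal_tversky_loss(p1, g1, tversky_params(a, 0.3, 4 / 3)), numeric(1))
    expect_true(all(diff(ls) >= 0))
  }
})

test_that("bce, dice and combined losses follow their definitions", {
  expect_equal(bce_loss(0.5, 1), log(2), tolerance = 1e-12)
  g <- c(1, 0, 1, 0)
  expect_equal(dice_loss(g, g), 0, tolerance = 1e-6)
  expect_equal(bce_loss(g, g), 0, tolerance = 1e-5)
  p <- c(0.9, 0.2, 0.7, 0.4)
  expect_equal(combined_loss(p, g), dice_loss(p, g) + bce_loss(p, g))
  expect_equal(combined_loss(p, g, c(0.5, 2)),
               0.5 * dice_loss(p, g) + 2 * bce_loss(p, g))
  # the trainer's gradient interface matches finite differences of the values
  for (nm in c("dice", "bce", "dice+bce")) {
    lf <- gcldnet:::loss_function(nm)
    an <- lf$grad(p, g)
    h <- 1e-6
    num <- vapply(seq_along(p), function(i) {
      e1 <- p; e1[i] <- e1[i] + h; e2 <- p; e2[i] <- e2[i] - h
      (lf$value(e1, g) - lf$value(e2, g)) / (2 * h)
    }, numeric(1))
    expect_equal(an, num, tolerance = 1e-4, label = paste("grad of", nm))
  }
  expect_error(gcldnet:::loss_function("huber"), "unknown loss")
})
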