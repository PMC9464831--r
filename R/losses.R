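# Segmentation losses.  The focal Tversky loss (FTL) is the package's
# centrepiece: an asymmetric overlap loss
#
#   TI = sum(p1*g1) / (sum(p1*g1) + alpha*sum(p1*g0) + beta*sum(p0*g1))
#   L  = (1 - TI)^(1/lambda)
#
# where p1/p0 are the per-pixel foreground/background probabilities, g1/g0
# the one-hot ground truth, alpha weights the false-positive mass p1*g0,
# beta the false-negative mass p0*g1, and lambda >= 1 focuses the loss on
# hard, low-overlap images.  At alpha = beta = 0.5, lambda = 1 the FTL is
# exactly the (soft) Dice loss.  A smoothing constant s added to numerator
# and denominator defines the empty-ground-truth / empty-prediction case as
# TI = 1.
#
# Analytic gradients are provided in closed form (treating p1 and p0 as
# independent inputs, as the pixel-form derivation does) and are verified in
# the test-suite against reverse-mode autodiff and central finite
# differences.

#' Tversky loss parameters
#'
#' @param alpha weight of the false-positive mass `sum(p1*g0)`.
#' @param beta weight of the false-negative mass `sum(p0*g1)`.
#' @param lambda focal exponent; the loss is `(1 - TI)^(1/lambda)`.  Values
#'   in \[1, 3\] are the useful range; `lambda = 1` disables focusing.
#' @param smooth smoothing constant added to numerator and denominator.
#' @return an object of class `tversky_params`.
#' @examples
#' tversky_params()                  # alpha 0.7, beta 0.3, lambda 4/3
#' tversky_params(0.5, 0.5, 1)      # the Dice-loss special case
#' @export
tversky_params <- function(alpha = 0.7, beta = 0.3, lambda = 4 / 3, smooth = 1e-6) {
  if (alpha < 0 || beta < 0 || alpha + beta <= 0)
    stop("alpha and beta must be non-negative with alpha + beta > 0", call. = FALSE)
  if (lambda <= 0) stop("lambda must be positive", call. = FALSE)
  if (lambda < 1 || lambda > 3)
    warning("lambda = ", signif(lambda, 3), " is outside the recommended range [1, 3]")
  structure(list(alpha = alpha, beta = beta, lambda = lambda, smooth = smooth),
            class = "tversky_params")
}

check_pg <- function(p1, g1) {
  if (length(p1) == 0L) stop("empty input", call. = FALSE)
  if (length(p1) != length(g1))
    stop("probability and ground-truth vectors differ in length", call. = FALSE)
  if (any(p1 < 0 | p1 > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (any(g1 != 0 & g1 != 1)) stop("ground truth must be binary", call. = FALSE)
  invisible(NULL)
}

ti_terms <- function(p1, g1, params) {
  tp <- sum(p1 * g1)
  fp <- sum(p1 * (1 - g1))
  fn <- sum((1 - p1) * g1)
  num <- tp + params$smooth
  den <- tp + params$alpha * fp + params$beta * fn + params$smooth
  list(tp = tp, fp = fp, fn = fn, num = num, den = den, ti = num / den)
}

#' Tversky index
#'
#' Smoothed asymmetric overlap between a probability map and a binary mask;
#' 1 for a perfect prediction (including the doubly-empty case) and 0 for a
#' fully disjoint one.
#'
#' @param p1 per-pixel foreground probabilities (any array shape).
#' @param g1 binary ground truth, same length.
#' @param params a [tversky_params()].
#' @return a number in \[0, 1\].
#' @examples
#' tversky_index(c(1, 0.5, 0), c(1, 1, 0), tversky_params(0.7, 0.3, 1))
#' @export
tversky_index <- function(p1, g1, params = tversky_params()) {
  p1 <- as.numeric(p1); g1 <- as.numeric(g1)
  check_pg(p1, g1)
  ti_terms(p1, g1, params)$ti
}

#' Focal Tversky loss
#'
#' `(1 - TI)^(1/lambda)`: zero for a perfect prediction, 1 for a disjoint
#' one, and with `lambda > 1` the loss decays more slowly near TI = 1, so
#' nearly-solved images keep contributing ("hard example mining").
#'
#' @inheritParams tversky_index
#' @return a number in \[0, 1\].
#' @export
focal_tversky_loss <- function(p1, g1, params = tversky_params()) {
  ti <- tversky_index(p1, g1, params)
  (1 - ti)^(1 / params$lambda)
}

#' Analytic gradients of the focal Tversky loss
#'
#' Closed-form partial derivatives of the pixel-form loss with respect to
#' the foreground and background probabilities, treating `p1` and `p0` as
#' independent inputs.  With `num = sum(p1*g1) + s` and
#' `den = num + alpha*sum(p1*g0) + beta*sum(p0*g1)`:
#' \deqn{\partial L/\partial p_{1i} =
#'   -\tfrac{1}{\lambda}(1 - TI)^{1/\lambda - 1}
#'   \frac{g_{1i}\,den - (g_{1i} + \alpha g_{0i})\,num}{den^2}}
#' \deqn{\partial L/\partial p_{0i} =
#'   \tfrac{1}{\lambda}(1 - TI)^{1/\lambda - 1}
#'   \frac{\beta g_{1i}\,num}{den^2}}
#' The factor `(1 - TI)^(1/lambda - 1)` is singular at TI = 1 for
#' `lambda > 1`; that case is reported via a condition rather than silent
#' NaNs.
#'
#' @inheritParams tversky_index
#' @param p0 optional background probabilities; defaults to `1 - p1`.
#' @return list with numeric vectors `dp1` and `dp0`.
#' @export
ftl_gradients <- function(p1, g1, params = tversky_params(), p0 = NULL) {
  p1 <- as.numeric(p1); g1 <- as.numeric(g1)
  check_pg(p1, g1)
  if (is.null(p0)) p0 <- 1 - p1
  g0 <- 1 - g1
  tp <- sum(p1 * g1)
  num <- tp + params$smooth
  den <- num + params$alpha * sum(p1 * g0) + params$beta * sum(p0 * g1)
  ti <- num / den
  lam <- params$lambda
  if (1 - ti <= 0) {
    if (lam > 1)
      stop(structure(class = c("gcld_ftl_singular", "error", "condition"),
                     list(message = paste0(
                       "focal Tversky gradient is singular at TI = 1 for lambda > 1 ",
                       "(the loss is at its minimum; use a zero gradient)"),
                       call = sys.call())))
    focal <- 1  # lambda = 1: (1-TI)^0
  } else {
    focal <- (1 - ti)^(1 / lam - 1)
  }
  common <- focal / lam
  dp1 <- -common * (g1 * den - (g1 + params$alpha * g0) * num) / den^2
  dp0 <- common * params$beta * g1 * num / den^2
  list(dp1 = dp1, dp0 = dp0)
}

# Total derivative wrt p1 with p0 = 1 - p1 substituted (training path).
ftl_grad_total <- function(p1, g1, params) {
  g <- ftl_gradients(p1, g1, params)
  g$dp1 - g$dp0
}

#' Dice, binary cross-entropy, and combined losses
#'
#' `dice_loss` is `1 - (2*sum(p1*g1) + 2s) / (sum(p1) + sum(g1) + 2s)`, the
#' soft Dice loss with the same smoothing as the focal Tversky loss (so the
#' FTL at `alpha = beta = 0.5, lambda = 1` reproduces it exactly).
#' `bce_loss` is the mean binary cross-entropy with probabilities clipped to
#' `[eps, 1 - eps]`.  `combined_loss` is a weighted sum, equal weights by
#' default.
#'
#' @inheritParams tversky_index
#' @param smooth smoothing constant for the Dice loss.
#' @param eps clipping constant for the BCE loss.
#' @param weights length-2 weights for `dice + bce`.
#' @return a single number.
#' @export
dice_loss <- function(p1, g1, smooth = 1e-6) {
  p1 <- as.numeric(p1); g1 <- as.numeric(g1)
  check_pg(p1, g1)
  1 - (2 * sum(p1 * g1) + 2 * smooth) / (sum(p1) + sum(g1) + 2 * smooth)
}

#' @rdname dice_loss
#' @export
bce_loss <- function(p1, g1, eps = 1e-7) {
  p1 <- as.numeric(p1); g1 <- as.numeric(g1)
  check_pg(p1, g1)
  p <- pmin(pmax(p1, eps), 1 - eps)
  -mean(g1 * log(p) + (1 - g1) * log(1 - p))
}

#' @rdname dice_loss
#' @export
combined_loss <- function(p1, g1, weights = c(1, 1)) {
  weights[1] * dice_loss(p1, g1) + weights[2] * bce_loss(p1, g1)
}

dice_grad_total <- function(p1, g1, smooth = 1e-6) {
  num <- 2 * sum(p1 * g1) + 2 * smooth
  den <- sum(p1) + sum(g1) + 2 * smooth
  -(2 * g1 * den - num) / den^2
}

bce_grad_total <- function(p1, g1, eps = 1e-7) {
  p <- pmin(pmax(p1, eps), 1 - eps)
  (p - g1) / (p * (1 - p)) / length(p1)
}

# Uniform interface used by the trainer: value + total gradient wrt p1.
# `name` is one of "ftl", "dice", "bce", "dice+bce".
loss_function <- function(name, params = tversky_params()) {
  switch(name,
    ftl = list(
      value = function(p1, g1) focal_tversky_loss(p1, g1, params),
      grad = function(p1, g1) {
        tryCatch(ftl_grad_total(p1, g1, params),
                 gcld_ftl_singular = function(e) numeric(length(p1)))
      }),
    dice = list(
      value = function(p1, g1) dice_loss(p1, g1),
      grad = function(p1, g1) dice_grad_total(p1, g1)),
    bce = list(
      value = function(p1, g1) bce_loss(p1, g1),
      grad = function(p1, g1) bce_grad_total(p1, g1)),
    `dice+bce` = list(
      value = function(p1, g1) combined_loss(p1, g1),
      grad = function(p1, g1) dice_grad_total(p1, g1) + bce_grad_total(p1, g1)),
    stop("unknown loss '", name, "' (use ftl, dice, bce or dice+bce)", call. = FALSE))
}

# Reverse-mode autodiff of the focal Tversky loss with p1 and p0 as
# independent leaves; the independent oracle the analytic gradients are
# checked against.
ftl_autodiff_gradients <- function(p1, g1, params = tversky_params(), p0 = NULL) {
  p1 <- as.numeric(p1); g1 <- as.numeric(g1)
  if (is.null(p0)) p0 <- 1 - p1
  g0 <- 1 - g1
  tape <- new_tape()
  n1 <- tp_leaf(p1)
  n0 <- tp_leaf(p0)
  num <- op_scalar_add(tape, list(op_sum(tape, op_mul_const(tape, n1, g1))),
                       const = params$smooth)
  den <- op_scalar_add(
    tape,
    list(num,
         op_sum(tape, op_mul_const(tape, n1, g0)),
         op_sum(tape, op_mul_const(tape, n0, g1))),
    weights = c(1, params$alpha, params$beta))
  ti <- op_scalar_div(tape, num, den)
  one_minus <- op_scalar_add(tape, list(ti), weights = -1, const = 1)
  loss <- op_scalar_pow(tape, one_minus, 1 / params$lambda)
  tp_backward(tape, list(list(node = loss, grad = 1)))
  list(value = loss$value, dp1 = n1$grad, dp0 = n0$grad)
}

# Central finite differences of the loss treating p1/p0 as independent.
ftl_numeric_gradients <- function(p1, g1, params = tversky_params(), h = 1e-5) {
  p1 <- as.numeric(p1); g1 <- as.numeric(g1)
  p0 <- 1 - p1
  f <- function(p1v, p0v) {
    tp <- sum(p1v * g1)
    num <- tp + params$smooth
    den <- num + params$alpha * sum(p1v * (1 - g1)) + params$beta * sum(p0v * g1)
    (1 - num / den)^(1 / params$lambda)
  }
  dp1 <- dp0 <- numeric(length(p1))
  for (i in seq_along(p1)) {
    e <- numeric(length(p1)); e[i] <- h
    dp1[i] <- (f(p1 + e, p0) - f(p1 - e, p0)) / (2 * h)
    dp0[i] <- (f(p1, p0 + e) - f(p1, p0 - e)) / (2 * h)
  }
  list(dp1 = dp1, dp0 = dp0)
}
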