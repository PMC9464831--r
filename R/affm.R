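# Attention feature fusion module (AFFM).  Each aggregated map is bilinearly
# upsampled to input resolution (X^{i,U}), passed through a 3x3 conv +
# activation + batch norm (X_C, X_B), pooled globally (average and max) into
# per-channel descriptors, squeezed through a shared two-layer MLP whose sum
# is squashed by a sigmoid into channel-attention weights W_A in (0,1), and
# the *upsampled* map is reweighted channel-wise: X^{i,A} = W_A (x) X^{i,U}.
# The five attended maps are concatenated into the fused feature X^F.
#
# The 3x3 conv preserves its channel count: the attention weights computed
# from X_B multiply X^{i,U}, so both must share C.

#' Channel-attention parameters
#'
#' A shared bottleneck MLP (hidden width `ceiling(c / r)`, ReLU) applied to
#' both pooled descriptors; the two outputs are summed and passed through a
#' sigmoid.
#'
#' @param c number of channels attended over.
#' @param r reduction rate of the hidden layer (default 16, the customary
#'   channel-attention setting).
#' @return an object of class `attention_params`.
#' @export
attention_params <- function(c, r = 16) {
  if (r < 1) stop("reduction rate r must be >= 1", call. = FALSE)
  hidden <- max(1L, as.integer(ceiling(c / r)))
  structure(list(c = as.integer(c), r = r, hidden = hidden,
                 fc1 = new_dense(c, hidden, "att.fc1"),
                 fc2 = new_dense(hidden, c, "att.fc2")),
            class = "attention_params")
}

make_affm <- function(in_widths, r = 16, attention = TRUE) {
  scales <- lapply(seq_along(in_widths), function(i) {
    c <- in_widths[i]
    list(block = new_conv_block(c, c, name = sprintf("affm.s%d", i)),
         att = attention_params(c, r))
  })
  list(kind = "affm", in_widths = as.integer(in_widths), r = r,
       attention = isTRUE(attention), scales = scales)
}

#' Bilinear upsampling to the input resolution
#'
#' @param x feature map array.
#' @param target_size integer length-1 or length-2 target spatial size; must
#'   be at least the source size.
#' @return array at the target size, channels unchanged.
#' @export
upsample_to_input <- function(x, target_size) {
  x <- as_feature_map(x)
  ts <- rep(as.integer(target_size), length.out = 2L)
  d <- fm_dims(x)
  if (ts[1] < d$h || ts[2] < d$w)
    stop("target size must be >= source size", call. = FALSE)
  resize_bilinear(x, ts[1], ts[2])
}

channel_attention_nodes <- function(tape, xb, att) {
  mlp <- function(v) fwd_dense(tape, op_relu(tape, fwd_dense(tape, v, att$fc1)), att$fc2)
  s <- op_add(tape, mlp(op_gap(tape, xb)), mlp(op_gmp(tape, xb)))
  # clamp away from exact 0/1 so the open-interval weight invariant survives
  # floating-point sigmoid saturation; the true derivative there is < 1e-17
  op_clamp(tape, op_sigmoid(tape, s), 1e-12, 1 - 1e-12)
}

#' 3x3 convolution + activation + batch normalisation
#'
#' The per-scale feature-enhancement step: `X_C = f(X * W + b)` followed by
#' `X_B = gamma * (X_C - E) / sqrt(Var + eps) + beta`.
#'
#' @param x feature map array.
#' @param block a conv block, e.g. `make_affm(...)$scales[[i]]$block` or
#'   `new_conv_block(cin, cout)` (internal constructor, reachable via the
#'   model object).
#' @param training logical; `TRUE` normalises with batch statistics.
#' @return array of the block's output width.
#' @export
conv_bn <- function(x, block, training = TRUE) {
  nd <- fwd_conv_block(NULL, tp_leaf(to_chw(x)), block, training)
  to_hwc(nd$value)
}

#' Dual-pooled channel attention weights
#'
#' `W_A = sigmoid(MLP(P_Avg) + MLP(P_Max))` with per-channel global average
#' and max pooling descriptors and a shared bottleneck MLP.  Every entry lies
#' strictly in (0, 1).
#'
#' @param xb feature map array (typically the [conv_bn()] output).
#' @param params an [attention_params()].
#' @return matrix `[C, N]` of attention weights.
#' @export
channel_attention <- function(xb, params) {
  nd <- channel_attention_nodes(NULL, tp_leaf(to_chw(xb)), params)
  nd$value
}

#' Reweight feature-map channels
#'
#' Channel c of the output is `w[c] * x[, , c]`, broadcast over pixels.
#'
#' @param w attention weights: vector of length C or matrix `[C, N]`.
#' @param x feature map array with C channels.
#' @return array like `x`.
#' @export
apply_attention <- function(w, x) {
  x <- as_feature_map(x)
  d <- fm_dims(x)
  if (is.null(dim(w))) w <- matrix(w, length(w), d$n)
  nd <- op_scale_channels(NULL, tp_leaf(to_chw(x)), tp_leaf(w))
  to_hwc(nd$value)
}

affm_fuse_nodes <- function(tape, affm, aggregated, target_hw, training) {
  attended <- vector("list", length(aggregated))
  for (i in seq_along(aggregated)) {
    res <- tryCatch({
      xu <- op_bilinear(tape, aggregated[[i]], target_hw[1], target_hw[2])
      if (affm$attention) {
        xb <- fwd_conv_block(tape, xu, affm$scales[[i]]$block, training)
        wa <- channel_attention_nodes(tape, xb, affm$scales[[i]]$att)
        op_scale_channels(tape, xu, wa)
      } else xu
    }, error = function(e)
      stop("AFFM scale ", i, ": ", conditionMessage(e), call. = FALSE))
    attended[[i]] <- res
  }
  op_concat_c(tape, attended)
}

#' Attention feature fusion
#'
#' Upsamples the five aggregated decoder maps to the input resolution,
#' computes per-scale channel attention, reweights each upsampled map and
#' concatenates the results into the fused feature X^F.  With
#' `attention = FALSE` at construction the module reduces to plain
#' multiscale upsample-and-concatenate.
#'
#' @param aggregated list of five arrays from [lfa_forward()] (level order
#'   1..5, level 1 at input resolution).
#' @param affm module built by `make_affm()` (or taken from a model built
#'   with [build_model()]).
#' @param training logical; batch-norm mode.
#' @return fused array at input resolution with `sum(affm$in_widths)`
#'   channels.
#' @export
affm_fuse <- function(aggregated, affm, training = TRUE) {
  nodes <- lapply(aggregated, function(m) tp_leaf(to_chw(m)))
  d1 <- cf_dims(nodes[[1]]$value)
  nd <- affm_fuse_nodes(NULL, affm, nodes, c(d1$h, d1$w), training)
  to_hwc(nd$value)
}

make_head <- function(cin, name = "head") new_conv(cin, 1L, k = 1L, name = name)

segmentation_head_nodes <- function(tape, xf, head) {
  op_sigmoid(tape, fwd_conv(tape, xf, head))
}

#' Probability head
#'
#' 1x1 convolution to a single channel followed by a sigmoid; returns the
#' per-pixel lesion probability p1 (the background probability is 1 - p1).
#'
#' @param xf fused feature array.
#' @param head head layer (from a built model, or `make_head(cin)`).
#' @return array `[H, W, 1, N]` with values in (0, 1).
#' @export
segmentation_head <- function(xf, head) {
  nd <- segmentation_head_nodes(NULL, tp_leaf(to_chw(xf)), head)
  to_hwc(nd$value)
}
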