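# Dense-tensor primitives.  Public interfaces use the natural image layout
# [H, W, C, N]; internally every network op runs channel-first, [C, H, W, N]
# (column-major), so a convolution's GEMM output is already in tensor order
# and per-channel affine ops reduce to vector recycling over matrix rows.
# Convolutions are im2col + BLAS GEMM; the transposed convolution reuses
# col2im as its forward scatter.

#' Coerce an image-like array to the [H, W, C, N] feature-map layout
#'
#' 2-D arrays become single-channel single-image tensors, 3-D arrays a
#' single-image batch. 4-D arrays pass through unchanged.
#'
#' @param x numeric array with 2 to 4 dimensions.
#' @return numeric array with dim \code{c(H, W, C, N)}.
#' @export
as_feature_map <- function(x) {
  if (is.null(dim(x))) stop("expected an array with 2-4 dimensions", call. = FALSE)
  nd <- length(dim(x))
  if (nd == 2L) dim(x) <- c(dim(x), 1L, 1L)
  else if (nd == 3L) dim(x) <- c(dim(x), 1L)
  else if (nd != 4L) stop("expected an array with 2-4 dimensions", call. = FALSE)
  x
}

# layout shuttles between the public [H,W,C,N] and internal [C,H,W,N]
to_chw <- function(x) aperm(as_feature_map(x), c(3L, 1L, 2L, 4L))
to_hwc <- function(x) aperm(x, c(2L, 3L, 1L, 4L))

# dims of an internal channel-first tensor
cf_dims <- function(x) {
  d <- dim(x)
  list(c = d[1L], h = d[2L], w = d[3L], n = d[4L])
}

# dims of a public [H,W,C,N] tensor
fm_dims <- function(x) {
  d <- dim(x)
  list(h = d[1L], w = d[2L], c = d[3L], n = d[4L])
}

conv_out_size <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

# y = W' patches(x) + b.  w_mat is [k*k*Cin, Cout]; rows follow the
# column-major flattening of a [Cin, k, k] tap block.
conv2d_fwd <- function(x, w_mat, bias, k, stride, pad) {
  d <- cf_dims(x)
  stopifnot(d$c == nrow(w_mat) / (k * k))
  conv_fwd_cpp(x, w_mat, bias %||% numeric(0), d$c, d$h, d$w, d$n, k, stride, pad)
}

conv2d_bwd <- function(dy, x, w_mat, k, stride, pad) {
  d <- cf_dims(x)
  conv_bwd_cpp(dy, x, w_mat, d$c, d$h, d$w, d$n, k, stride, pad)
}

# Transposed convolution (kernel k, stride 2, pad 1: exact spatial
# doubling).  a_mat is the adjoint conv's weight, [k*k*Cout, Cin]: the
# forward pass here is the input-gradient of a stride-2 convolution mapping
# [2H] -> [H].
convt2d_fwd <- function(x, a_mat, bias, k = 4L, stride = 2L, pad = 1L) {
  d <- cf_dims(x)
  stopifnot(d$c == ncol(a_mat))
  convt_fwd_cpp(x, a_mat, bias %||% numeric(0), d$c, d$h, d$w, d$n, k, stride, pad)
}

convt2d_bwd <- function(dy, x, a_mat, k = 4L, stride = 2L, pad = 1L) {
  d <- cf_dims(x)
  convt_bwd_cpp(dy, x, a_mat, d$c, d$h, d$w, d$n, k, stride, pad)
}

# 1-D linear-interpolation operator (half-pixel centres, clamped edges).
interp_matrix <- function(n_out, n_in) {
  if (n_out == n_in) return(diag(n_in))
  s <- pmin(pmax((seq_len(n_out) - 0.5) * n_in / n_out - 0.5, 0), n_in - 1)
  i0 <- floor(s)
  w <- s - i0
  m <- matrix(0, n_out, n_in)
  m[cbind(seq_len(n_out), i0 + 1)] <- m[cbind(seq_len(n_out), i0 + 1)] + (1 - w)
  i1 <- pmin(i0 + 1, n_in - 1)
  m[cbind(seq_len(n_out), i1 + 1)] <- m[cbind(seq_len(n_out), i1 + 1)] + w
  m
}

# channel-first bilinear resize: interpolate H then W via small GEMMs.
resize_bilinear_chw <- function(x, h_out, w_out, rh = NULL, rw = NULL) {
  d <- cf_dims(x)
  if (is.null(rh)) rh <- interp_matrix(h_out, d$h)
  if (is.null(rw)) rw <- interp_matrix(w_out, d$w)
  y <- aperm(x, c(2L, 1L, 3L, 4L))                  # [h, c, w, n]
  y <- rh %*% matrix(y, d$h)                        # [h_out, c*w*n]
  dim(y) <- c(h_out, d$c, d$w, d$n)
  y <- aperm(y, c(3L, 2L, 1L, 4L))                  # [w, c, h_out, n]
  y <- rw %*% matrix(y, d$w)                        # [w_out, c*h_out*n]
  dim(y) <- c(w_out, d$c, h_out, d$n)
  aperm(y, c(2L, 3L, 1L, 4L))                       # [c, h_out, w_out, n]
}

# public-layout bilinear resize (used for images and sample pairs)
resize_bilinear <- function(x, h_out, w_out) {
  to_hwc(resize_bilinear_chw(to_chw(x), h_out, w_out))
}

resize_nearest <- function(x, h_out, w_out) {
  d <- fm_dims(x)
  ri <- pmin(pmax(round((seq_len(h_out) - 0.5) * d$h / h_out + 0.5), 1), d$h)
  ci <- pmin(pmax(round((seq_len(w_out) - 0.5) * d$w / w_out + 0.5), 1), d$w)
  x[ri, ci, , , drop = FALSE]
}
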