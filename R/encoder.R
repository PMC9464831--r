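# Backbone encoder: six feature maps X^{i,1}, i = 1..6, at successively
# halved resolution.  Level 1 is produced at full resolution by a stride-1
# double-conv block (the decoder's aggregation equations need a
# full-resolution X^{1,1}); levels 2..6 each halve the grid once with a
# stride-2 conv followed by a stride-1 conv.

#' Encoder specification
#'
#' Describes the backbone that produces the six encoder feature maps.  The
#' bundled backbone is `"smallconv"`, a plain double-conv pyramid with
#' configurable per-level widths; it needs no pretrained weights and trains
#' on CPU.  Requesting `"efficientnet-b4"` raises a configuration error:
#' pretrained large-scale backbones are not bundled with this package.
#'
#' @param backbone character backbone name; `"smallconv"` is implemented.
#' @param widths integer vector of six per-level channel widths C1..C6.
#' @param pretrained logical; must be `FALSE` for `"smallconv"`.
#' @return an object of class `encoder_spec`.
#' @examples
#' sp <- encoder_spec(widths = c(8, 16, 24, 32, 48, 64))
#' @export
encoder_spec <- function(backbone = "smallconv",
                         widths = c(16L, 24L, 32L, 48L, 64L, 96L),
                         pretrained = FALSE) {
  if (identical(backbone, "efficientnet-b4"))
    stop("configuration error: backbone 'efficientnet-b4' is not bundled ",
         "(no pretrained weights ship with this package); use 'smallconv'",
         call. = FALSE)
  if (!identical(backbone, "smallconv"))
    stop("configuration error: unknown backbone '", backbone, "'", call. = FALSE)
  if (length(widths) != 6L || any(widths <= 0))
    stop("configuration error: 'widths' must be six positive channel counts", call. = FALSE)
  if (isTRUE(pretrained))
    stop("configuration error: no pretrained weights are available for 'smallconv'", call. = FALSE)
  structure(list(backbone = backbone, widths = as.integer(widths),
                 pretrained = FALSE),
            class = "encoder_spec")
}

check_input_size <- function(h, w) {
  if (h %% 32L != 0L || w %% 32L != 0L)
    stop("dimension error: input spatial size ", h, "x", w,
         " is not divisible by 32 (five exact halvings are required)",
         call. = FALSE)
  invisible(NULL)
}

make_encoder <- function(spec) {
  w <- spec$widths
  levels <- vector("list", 6L)
  cin <- 3L
  for (i in 1:6) {
    stride <- if (i == 1L) 1L else 2L
    levels[[i]] <- list(
      a = new_conv_block(cin, w[i], stride = stride, name = sprintf("enc%d.a", i)),
      b = new_conv_block(w[i], w[i], name = sprintf("enc%d.b", i)))
    cin <- w[i]
  }
  list(kind = "encoder", spec = spec, levels = levels)
}

encoder_forward <- function(tape, enc, x, training) {
  out <- vector("list", 6L)
  h <- x
  for (i in 1:6) {
    h <- fwd_conv_block(tape, h, enc$levels[[i]]$a, training)
    h <- fwd_conv_block(tape, h, enc$levels[[i]]$b, training)
    out[[i]] <- h
  }
  out
}

#' Encode an image into six pyramid feature maps
#'
#' Runs a freshly initialised backbone (seeded, hence reproducible) over an
#' image and returns the six encoder maps \eqn{X^{i,1}}; map \eqn{i} has
#' spatial size `input / 2^(i-1)` and `spec$widths[i]` channels.  Intended
#' for inspection and testing; training uses the encoder embedded in a model
#' built with [build_model()].
#'
#' @param image array `[H, W, 3]` or `[H, W, 3, N]`; H and W divisible by 32.
#' @param spec an [encoder_spec()].
#' @param seed integer seed for weight initialisation.
#' @return list of six arrays `[H_i, W_i, C_i, N]`.
#' @export
encode <- function(image, spec = encoder_spec(), seed = 1L) {
  x <- as_feature_map(image)
  d <- fm_dims(x)
  check_input_size(d$h, d$w)
  if (d$c != 3L) stop("dimension error: expected a 3-channel RGB image", call. = FALSE)
  if (any(!is.finite(x))) stop("dimension error: non-finite values in input", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  enc <- make_encoder(spec)
  maps <- encoder_forward(NULL, enc, tp_leaf(to_chw(x)), training = TRUE)
  lapply(maps, function(nd) to_hwc(nd$value))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
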