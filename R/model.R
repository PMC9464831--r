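# Model factory.  Three variants share the encoder contract and the
# probability-map output contract (the ablation ladder):
#   "baseline"           encoder + plain U-Net-style decoder
#   "baseline+lfa"       encoder + level-feature-aggregation decoder,
#                        head on the full-resolution aggregated map
#   "baseline+lfa+affm"  as above, plus attention feature fusion before the
#                        head
# LFA variants can attach deep-supervision heads: one auxiliary 1x1-conv +
# sigmoid head per aggregated map, compared against the mask after bilinear
# upsampling to full resolution.  Auxiliary heads only ever contribute to
# the training loss; inference uses the main head alone.

#' Model configuration
#'
#' @param variant `"baseline"`, `"baseline+lfa"` or `"baseline+lfa+affm"`.
#' @param encoder an [encoder_spec()].
#' @param chain_widths LFA chain widths d1..d5 (scalar recycled); default
#'   half the encoder widths.
#' @param r channel-attention reduction rate.
#' @param attention logical; `FALSE` turns the AFFM into plain multiscale
#'   concatenation (used by ablations).
#' @param deep_supervision logical; attach auxiliary heads to the aggregated
#'   maps (LFA variants only).
#' @return an object of class `model_config`.
#' @export
model_config <- function(variant = c("baseline+lfa+affm", "baseline+lfa", "baseline"),
                         encoder = encoder_spec(),
                         chain_widths = NULL, r = 16,
                         attention = TRUE, deep_supervision = TRUE) {
  variant <- match.arg(variant)
  structure(list(variant = variant, encoder = encoder,
                 chain_widths = chain_widths, r = r,
                 attention = isTRUE(attention),
                 deep_supervision = isTRUE(deep_supervision)),
            class = "model_config")
}

#' Build a lesion-detection model
#'
#' Initialises all weights (seeded, hence reproducible) for the requested
#' variant.  All variants map an RGB image whose sides are divisible by 32
#' to a same-size probability map.
#'
#' @param cfg a [model_config()].
#' @param seed integer initialisation seed.
#' @return an object of class `gcld_model`.
#' @export
build_model <- function(cfg, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  enc <- make_encoder(cfg$encoder)
  w <- cfg$encoder$widths
  m <- list(cfg = cfg, seed = seed, encoder = enc)
  if (cfg$variant == "baseline") {
    stages <- vector("list", 5L)
    cin <- w[6L]
    for (i in 5:1) {
      stages[[i]] <- list(
        up = new_convt(cin, w[i], name = sprintf("dec%d.up", i)),
        bn = new_bn(w[i], name = sprintf("dec%d.up.bn", i)),
        fuse = new_conv_block(2L * w[i], w[i], name = sprintf("dec%d.fuse", i)))
      cin <- w[i]
    }
    m$decoder <- stages
    m$head <- make_head(w[1L])
  } else {
    dec <- if (is.null(cfg$chain_widths)) lfa_decoder(w)
           else lfa_decoder(w, cfg$chain_widths)
    m$lfa <- dec
    if (cfg$variant == "baseline+lfa+affm") {
      m$affm <- make_affm(dec$agg_widths, r = cfg$r, attention = cfg$attention)
      m$head <- make_head(sum(dec$agg_widths))
      if (cfg$deep_supervision)
        m$aux_heads <- lapply(1:5, function(i)
          make_head(dec$agg_widths[i], sprintf("aux%d", i)))
    } else {
      m$head <- make_head(dec$agg_widths[1L])
      if (cfg$deep_supervision)
        m$aux_heads <- lapply(2:5, function(i)
          make_head(dec$agg_widths[i], sprintf("aux%d", i)))
    }
  }
  m$params <- collect_params(m[setdiff(names(m), c("cfg", "seed"))])
  class(m) <- "gcld_model"
  m
}

#' @export
print.gcld_model <- function(x, ...) {
  cat("<gcld_model> variant:", x$cfg$variant,
      "| encoder widths:", paste(x$cfg$encoder$widths, collapse = "/"),
      "| parameters:", format(n_parameters(x$params), big.mark = ","), "\n")
  invisible(x)
}

# Full forward pass on nodes.  Returns main probability node, auxiliary
# probability nodes (already upsampled to full resolution), and optionally
# the decoder lattice.
model_forward_nodes <- function(tape, model, x, training, keep_lattice = FALSE,
                                with_aux = TRUE) {
  d <- cf_dims(x$value)
  check_input_size(d$h, d$w)
  enc_maps <- encoder_forward(tape, model$encoder, x, training)
  aux <- list()
  lattice <- NULL
  if (model$cfg$variant == "baseline") {
    h <- enc_maps[[6L]]
    for (i in 5:1) {
      st <- model$decoder[[i]]
      h <- op_batchnorm(tape, op_relu(tape, fwd_convt(tape, h, st$up)), st$bn, training)
      h <- op_concat_c(tape, list(h, enc_maps[[i]]))
      h <- fwd_conv_block(tape, h, st$fuse, training)
    }
    feat <- h
  } else {
    out <- lfa_forward_nodes(tape, model$lfa, enc_maps, training)
    if (keep_lattice) lattice <- out$lattice
    agg <- out$aggregated
    feat <- if (model$cfg$variant == "baseline+lfa+affm")
      affm_fuse_nodes(tape, model$affm, agg, c(d$h, d$w), training)
    else agg[[1L]]
    if (with_aux && model$cfg$deep_supervision && !is.null(model$aux_heads)) {
      lv <- if (model$cfg$variant == "baseline+lfa+affm") 1:5 else 2:5
      aux <- lapply(seq_along(lv), function(k) {
        p <- segmentation_head_nodes(tape, agg[[lv[k]]], model$aux_heads[[k]])
        if (lv[k] > 1L) op_bilinear(tape, p, d$h, d$w) else p
      })
    }
  }
  prob <- segmentation_head_nodes(tape, feat, model$head)
  list(prob = prob, aux = aux, lattice = lattice)
}

# Stack a list of sample pairs into channel-first batched tensors
# ([3,H,W,N] images, [1,H,W,N] masks).
stack_pairs <- function(pairs, center = TRUE) {
  n <- length(pairs)
  hw <- dim(pairs[[1]]$mask)
  x <- array(0, c(3L, hw[1], hw[2], n))
  g <- array(0, c(1L, hw[1], hw[2], n))
  for (i in seq_len(n)) {
    p <- if (center) augment(pairs[[i]], "center") else pairs[[i]]
    x[, , , i] <- aperm(p$image, c(3L, 1L, 2L))
    g[1L, , , i] <- p$mask
  }
  list(x = x, g = g)
}

#' Predict lesion probability maps
#'
#' Runs the model in inference mode (batch-norm running statistics).
#'
#' @param object a trained [build_model()] object.
#' @param images list of sample pairs, a single image array, or a batched
#'   `[H, W, 3, N]` array.
#' @param center subtract per-channel means before the forward pass (must
#'   match how the model was trained; default `TRUE`).
#' @param ... unused.
#' @return array `[H, W, 1, N]` of probabilities in (0, 1).
#' @export
predict.gcld_model <- function(object, images, center = TRUE, ...) {
  if (is.list(images) && !is.null(images[[1]]$image)) {
    b <- stack_pairs(images, center = center)
    x <- b$x
  } else {
    x <- to_chw(as_feature_map(images))
    if (center) {
      d <- cf_dims(x)
      for (i in seq_len(d$n)) for (ch in seq_len(d$c))
        x[ch, , , i] <- x[ch, , , i] - mean(x[ch, , , i])
    }
  }
  out <- model_forward_nodes(NULL, object, tp_leaf(x), training = FALSE,
                             with_aux = FALSE)
  to_hwc(out$prob$value)
}
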