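# Level feature aggregation (LFA) decoder.  Starting from the deepest
# encoder map, chains of transposed convolutions (each exactly doubling the
# grid) climb back to full resolution; at each level, all maps that have
# arrived there so far are concatenated channel-wise ("from bottom to top and
# from left to right").  Indexing follows the lattice X^{i,j}: level i in
# 1..6 (spatial size input/2^(i-1)), position j in 1..6, with X^{i,1} the
# encoder output, chain nodes at j = c+1 for chain c, and the aggregated map
# of level i at j = 8-i (j = 6 for level 1).
#
# Chain c (c = 1..5) starts from the deepest not-yet-consumed map: chain 1
# from X^{6,1}, chain c >= 2 from the aggregated map of level 7-c.  Its steps
# produce one node per level from 6-c down to 1.

#' Level-feature-aggregation decoder constructor
#'
#' @param widths six encoder channel widths C1..C6.
#' @param chain_widths five per-level transposed-convolution output widths
#'   d1..d5 (width of every chain node landing on level i).  Default
#'   `ceiling(widths[1:5] / 2)`; a single number is recycled.
#' @return an object of class `lfa_decoder` holding the step layers and the
#'   implied aggregated widths.
#' @export
lfa_decoder <- function(widths, chain_widths = ceiling(widths[1:5] / 2)) {
  widths <- as.integer(widths)
  if (length(widths) != 6L) stop("'widths' must have length 6", call. = FALSE)
  if (length(chain_widths) == 1L) chain_widths <- rep(chain_widths, 5L)
  d <- as.integer(chain_widths)
  if (length(d) != 5L || any(d <= 0)) stop("'chain_widths' must be five positive widths", call. = FALSE)
  agg <- widths[1:5] + (6L - 1:5) * d           # C_i plus (6 - i) chain arrivals
  src <- c(widths[6L], rev(agg[2:5]))           # chain sources: X^{6,1}, then agg 5..2
  chains <- vector("list", 5L)
  for (ch in 1:5) {
    top <- 6L - ch                              # highest level this chain reaches... produced levels top..1
    steps <- vector("list", top)
    cin <- src[ch]
    for (i in rev(seq_len(top))) {              # i = top, top-1, ..., 1
      steps[[i]] <- list(
        up = new_convt(cin, d[i], name = sprintf("lfa.c%d.l%d", ch, i)),
        bn = new_bn(d[i], name = sprintf("lfa.c%d.l%d.bn", ch, i)))
      cin <- d[i]
    }
    chains[[ch]] <- steps
  }
  structure(list(widths = widths, chain_widths = d, agg_widths = agg,
                 chains = chains),
            class = "lfa_decoder")
}

upsample_step_nodes <- function(tape, x, step, training) {
  y <- fwd_convt(tape, x, step$up)
  y <- op_relu(tape, y)
  op_batchnorm(tape, y, step$bn, training)
}

#' Single decoder upsampling step
#'
#' One transposed convolution (kernel 4, stride 2: exact spatial doubling)
#' followed by ReLU and batch normalisation.
#'
#' @param x feature map array (`[H, W, C]` or `[H, W, C, N]`).
#' @param step one step of an [lfa_decoder()] chain, e.g.
#'   `dec$chains[[1]][[5]]`.
#' @param training logical; batch-norm mode.
#' @return array with doubled spatial size and `step$up$cout` channels.
#' @export
upsample_step <- function(x, step, training = TRUE) {
  nd <- upsample_step_nodes(NULL, tp_leaf(to_chw(x)), step, training)
  to_hwc(nd$value)
}

#' Concatenate same-level feature maps channel-wise
#'
#' The aggregation primitive of the decoder: continuous concatenation in the
#' given order.  All maps must share spatial size and batch size; output
#' channels are the sum of input channels.  A single-element list returns the
#' map unchanged.
#'
#' @param maps ordered list of feature-map arrays.
#' @return a single array.
#' @export
aggregate_level <- function(maps) {
  stopifnot(length(maps) >= 1L)
  maps <- lapply(maps, as_feature_map)
  if (length(maps) == 1L) return(maps[[1L]])
  nd <- op_concat_c(NULL, lapply(maps, function(m) tp_leaf(to_chw(m))))
  to_hwc(nd$value)
}

# Node-level forward.  encoder_maps: list of 6 nodes.  Returns aggregated
# nodes (levels 1..5) and the full lattice (list keyed "i,j"; the chain-5
# node at level 1 is stored under "1,6U", the aggregated map under "1,6").
lfa_forward_nodes <- function(tape, dec, encoder_maps, training) {
  lat <- list()
  for (i in 1:6) lat[[paste(i, 1L, sep = ",")]] <- encoder_maps[[i]]
  agg <- vector("list", 5L)
  src <- encoder_maps[[6L]]
  for (ch in 1:5) {
    top <- 6L - ch
    j <- ch + 1L
    node <- src
    for (i in rev(seq_len(top))) {
      node <- upsample_step_nodes(tape, node, dec$chains[[ch]][[i]], training)
      key <- if (i == 1L && j == 6L) "1,6U" else paste(i, j, sep = ",")
      lat[[key]] <- node
    }
    lev <- top                                   # level aggregated after this chain
    agg_j <- if (lev == 1L) 6L else 8L - lev     # Eq. numbering: j = 8-i for i >= 2, j = 6 for i = 1
    parts <- lapply(seq_len(8L - lev - 1L), function(kk) {
      key <- if (lev == 1L && kk == 6L) "1,6U" else paste(lev, kk, sep = ",")
      lat[[key]]
    })
    agg_node <- tryCatch(op_concat_c(tape, parts), error = function(e)
      stop("aggregation failed at node (", lev, ",", agg_j, "): ",
           conditionMessage(e), call. = FALSE))
    lat[[paste(lev, agg_j, sep = ",")]] <- agg_node
    agg[[lev]] <- agg_node
    if (ch < 5L) src <- agg_node
  }
  list(aggregated = agg, lattice = lat)
}

#' Run the level-feature-aggregation decoder
#'
#' Computes the full decoding lattice from six encoder maps and returns the
#' five aggregated maps \eqn{X^{1,6}, X^{2,6}, X^{3,5}, X^{4,4}, X^{5,3}}
#' (levels 1..5) together with the lattice of every intermediate node.
#'
#' @param encoder_maps list of six feature-map arrays from [encode()].
#' @param decoder an [lfa_decoder()].
#' @param training logical; batch-norm mode.
#' @return list with `aggregated` (five arrays, level order 1..5) and
#'   `lattice` (named list of arrays keyed `"i,j"`, plus `"1,6U"` for the
#'   upsampled chain node entering the level-1 aggregation).
#' @export
lfa_forward <- function(encoder_maps, decoder, training = TRUE) {
  nodes <- lapply(encoder_maps, function(m) tp_leaf(to_chw(m)))
  out <- lfa_forward_nodes(NULL, decoder, nodes, training)
  list(aggregated = lapply(out$aggregated, function(nd) to_hwc(nd$value)),
       lattice = lapply(out$lattice, function(nd) to_hwc(nd$value)))
}

#' Inventory of the decoding lattice
#'
#' One row per lattice node with its level, position, role and shape —
#' convenient for asserting the completeness and size contracts.
#'
#' @param lattice the `lattice` element returned by [lfa_forward()].
#' @return a tibble with columns `i`, `j`, `role`, `height`, `width`,
#'   `channels`.
#' @export
lattice_inventory <- function(lattice) {
  keys <- names(lattice)
  rows <- lapply(keys, function(k) {
    up <- grepl("U$", k)
    ij <- as.integer(strsplit(sub("U$", "", k), ",")[[1]])
    d <- fm_dims(lattice[[k]])
    role <- if (up) "upsampled"
    else if (ij[2] == 1L) "encoder"
    else if (ij[2] == 8L - ij[1] || (ij[1] == 1L && ij[2] == 6L)) "aggregated"
    else "chain"
    tibble::tibble(i = ij[1], j = ij[2], role = role,
                   height = d$h, width = d$w, channels = d$c)
  })
  do.call(rbind, rows)
}
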