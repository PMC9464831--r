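# Pixel-level evaluation: Dice similarity coefficient (DSC), Jaccard index
# (JI), accuracy (ACC) and precision (PRE) from confusion counts.
# Degenerate denominators follow the documented convention: an empty ground
# truth met by an empty prediction scores 1 on every metric; an empty
# prediction against a non-empty ground truth scores DSC = JI = PRE = 0.

#' Threshold a probability map into a binary mask
#'
#' A pixel is foreground iff its probability is `>= threshold` (ties go to
#' foreground).
#'
#' @param p array or vector of probabilities.
#' @param threshold scalar in (0, 1); default 0.5.
#' @return integer array of 0/1 with the shape of `p`.
#' @export
binarize <- function(p, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)", call. = FALSE)
  out <- (p >= threshold) + 0L
  dim(out) <- dim(p)
  out
}

check_mask <- function(m, what = "mask") {
  if (any(m != 0L & m != 1L))
    stop(what, " must be strictly binary (0/1)", call. = FALSE)
  invisible(NULL)
}

#' Confusion counts between predicted and reference masks
#'
#' @param pred,gt binary masks of identical shape.
#' @return named list with integer `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)) || length(pred) != length(gt))
    stop("mask shapes differ", call. = FALSE)
  check_mask(pred, "prediction"); check_mask(gt, "ground truth")
  tp <- sum(pred == 1L & gt == 1L)
  tn <- sum(pred == 0L & gt == 0L)
  fp <- sum(pred == 1L & gt == 0L)
  fn <- sum(pred == 0L & gt == 1L)
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

div_or <- function(num, den, empty) if (den == 0) empty else num / den

#' Segmentation metrics from confusion counts
#'
#' `DSC = 2TP / (2TP + FP + FN)`, `JI = TP / (TP + FP + FN)`,
#' `ACC = (TP + TN) / total`, `PRE = TP / (TP + FP)`.  When both masks are
#' empty the overlap metrics are defined as 1; an empty prediction against a
#' non-empty reference gives `PRE = 0`.
#'
#' @param counts a list as returned by [confusion_counts()].
#' @return one-row tibble with columns `dsc`, `ji`, `acc`, `pre`.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty masks", call. = FALSE)
  tibble::tibble(
    dsc = div_or(2 * tp, 2 * tp + fp + fn, 1),
    ji  = div_or(tp, tp + fp + fn, 1),
    acc = (tp + tn) / total,
    pre = if (tp + fp == 0) (if (fn == 0) 1 else 0) else tp / (tp + fp))
}

#' Evaluate predicted masks against references
#'
#' Per-image metrics plus a dataset summary.  `aggregate = "mean"` (the
#' default) averages per-image metrics; `aggregate = "pooled"` sums the
#' confusion counts over all images first.
#'
#' @param preds,gts lists of binary masks (or single masks).
#' @param ids optional image identifiers.
#' @param aggregate `"mean"` or `"pooled"`.
#' @return list with `per_image` (tibble, one row per image) and `summary`
#'   (one-row tibble).
#' @export
evaluate_masks <- function(preds, gts, ids = NULL, aggregate = c("mean", "pooled")) {
  aggregate <- match.arg(aggregate)
  if (!is.list(preds)) preds <- list(preds)
  if (!is.list(gts)) gts <- list(gts)
  stopifnot(length(preds) == length(gts))
  if (is.null(ids)) ids <- sprintf("img%03d", seq_along(preds))
  counts <- Map(confusion_counts, preds, gts)
  per <- do.call(rbind, lapply(counts, compute_metrics))
  per <- tibble::tibble(id = ids, per)
  summ <- if (aggregate == "mean") {
    tibble::tibble(dsc = mean(per$dsc), ji = mean(per$ji),
                   acc = mean(per$acc), pre = mean(per$pre))
  } else {
    pooled <- Reduce(function(a, b) Map(`+`, a, b), counts)
    compute_metrics(pooled)
  }
  list(per_image = per, summary = summ)
}
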