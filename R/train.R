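# Training protocol: SGD with momentum, batch size 6, reduce-on-plateau
# learning-rate schedule monitoring the validation Dice coefficient (halve
# after 5 consecutive epochs without strict improvement, floor 1e-6), and
# deep supervision ("joint collaborative training"): the main head and the
# auxiliary heads contribute equally-weighted loss terms, 1/(k+1) each.

#' Reduce-on-plateau learning-rate schedule
#'
#' A pure state machine, exposed so the halving rule is unit-testable: a
#' strict improvement of the monitored Dice resets the counter; after
#' `patience` consecutive non-improving epochs the rate is multiplied by
#' `factor` (never below `floor`) and the counter resets.
#'
#' @param lr initial learning rate.
#' @param factor multiplicative decay on plateau.
#' @param patience consecutive non-improving epochs tolerated.
#' @param floor minimum learning rate.
#' @return scheduler state (a list); advance it with [plateau_step()].
#' @examples
#' s <- plateau_scheduler(1e-2)
#' for (d in c(.50, .60, .60, .59, .60, .58, .60)) s <- plateau_step(s, d)
#' s$lr   # halved once, after the seventh epoch
#' @export
plateau_scheduler <- function(lr = 1e-2, factor = 0.5, patience = 5L, floor = 1e-6) {
  if (patience < 1L) stop("patience must be >= 1", call. = FALSE)
  if (floor > lr) stop("floor must not exceed the initial learning rate", call. = FALSE)
  list(lr = lr, factor = factor, patience = as.integer(patience), floor = floor,
       best = -Inf, wait = 0L, n_halved = 0L)
}

#' @param state scheduler state.
#' @param dice monitored validation Dice for the epoch just finished.
#' @rdname plateau_scheduler
#' @export
plateau_step <- function(state, dice) {
  if (dice > state$best) {
    state$best <- dice
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= state$patience) {
      state$lr <- max(state$floor, state$lr * state$factor)
      state$n_halved <- state$n_halved + 1L
      state$wait <- 0L
    }
  }
  state
}

#' Training configuration
#'
#' Defaults follow the reference protocol: batch size 6, 150 epochs, SGD
#' (momentum 0.9) from learning rate 1e-2, halved after a 5-epoch Dice
#' plateau down to a floor of 1e-6, focal Tversky loss, deep supervision
#' with equal weights.
#'
#' @param batch_size images per gradient step.
#' @param epochs training epochs.
#' @param lr initial learning rate.
#' @param patience,factor,lr_floor plateau schedule (see
#'   [plateau_scheduler()]).
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty coefficient.
#' @param loss `"ftl"`, `"dice"`, `"bce"` or `"dice+bce"`.
#' @param tversky a [tversky_params()] (used when `loss = "ftl"`).
#' @param aux_weight relative weight of each auxiliary (deep-supervision)
#'   head before normalisation; the main head has relative weight 1 and all
#'   weights are normalised to sum to 1.  `aux_weight = 1` gives the equal
#'   `1/(k+1)` scheme; the default 0.25 keeps the main head dominant.
#' @param random_flips random horizontal/vertical flips during training.
#' @param center subtract per-channel image means (sample centering).
#' @param seed seed for shuffling/augmentation.
#' @param verbose print per-epoch progress.
#' @return an object of class `train_config`.
#' @export
train_config <- function(batch_size = 6L, epochs = 150L, lr = 1e-2,
                         patience = 5L, factor = 0.5, lr_floor = 1e-6,
                         momentum = 0.9, weight_decay = 0,
                         loss = "ftl", tversky = tversky_params(),
                         aux_weight = 0.25,
                         random_flips = TRUE, center = TRUE,
                         seed = 1L, verbose = FALSE) {
  structure(list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 lr = lr, patience = as.integer(patience), factor = factor,
                 lr_floor = lr_floor, momentum = momentum,
                 weight_decay = weight_decay, loss = loss, tversky = tversky,
                 aux_weight = aux_weight,
                 random_flips = isTRUE(random_flips), center = isTRUE(center),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Train a lesion-detection model
#'
#' Full-batch-loop SGD training with deep supervision and the plateau
#' schedule; the validation Dice that drives the schedule is computed on
#' `val_pairs` after every epoch (mean per-image Dice at threshold 0.5).
#' Training is deterministic given the model seed and `tc$seed`.
#'
#' @param model a [build_model()] object (modified in place and returned).
#' @param train_pairs,val_pairs lists of sample pairs.
#' @param tc a [train_config()].
#' @return the model, with a `history` tibble (`epoch`, `loss`, `val_dice`,
#'   `lr`) attached.
#' @export
train_model <- function(model, train_pairs, val_pairs, tc = train_config()) {
  if (!length(train_pairs) || !length(val_pairs))
    stop("training and validation sets must be non-empty", call. = FALSE)
  lf <- loss_function(tc$loss, tc$tversky)
  sched <- plateau_scheduler(tc$lr, tc$factor, tc$patience, tc$lr_floor)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(tc$seed)
  hist <- vector("list", tc$epochs)
  for (epoch in seq_len(tc$epochs)) {
    ord <- sample.int(length(train_pairs))
    ep_loss <- 0; n_batches <- 0L
    for (start in seq(1L, length(ord), by = tc$batch_size)) {
      idx <- ord[start:min(start + tc$batch_size - 1L, length(ord))]
      pairs <- train_pairs[idx]
      if (tc$random_flips)
        pairs <- lapply(pairs, function(p)
          augment(p, c("hflip", "vflip")[runif(2) < 0.5]))
      b <- stack_pairs(pairs, center = tc$center)
      nb <- length(idx)
      tape <- new_tape()
      out <- model_forward_nodes(tape, model, tp_leaf(b$x), training = TRUE)
      if (!all(is.finite(out$prob$value)))
        stop("training diverged: non-finite prediction at epoch ", epoch, call. = FALSE)
      heads <- c(list(out$prob), out$aux)
      wts <- c(1, rep(tc$aux_weight %||% 1, length(out$aux)))
      wts <- wts / sum(wts)
      loss <- 0
      seeds <- vector("list", length(heads))
      for (h in seq_along(heads)) {
        pv <- heads[[h]]$value
        gr <- array(0, dim(pv))
        for (i in seq_len(nb)) {
          p1 <- as.numeric(pv[1L, , , i])
          g1 <- as.numeric(b$g[1L, , , i])
          loss <- loss + wts[h] * lf$value(p1, g1) / nb
          gr[1L, , , i] <- wts[h] * lf$grad(p1, g1) / nb
        }
        seeds[[h]] <- list(node = heads[[h]], grad = gr)
      }
      if (!is.finite(loss))
        stop("training diverged: non-finite loss at epoch ", epoch, call. = FALSE)
      tp_backward(tape, seeds)
      sgd_step(model$params, sched$lr, tc$momentum, tc$weight_decay)
      zero_grads(model$params)
      ep_loss <- ep_loss + loss; n_batches <- n_batches + 1L
    }
    vd <- validation_dice(model, val_pairs, tc)
    lr_used <- sched$lr
    sched <- plateau_step(sched, vd)
    hist[[epoch]] <- tibble::tibble(epoch = epoch, loss = ep_loss / n_batches,
                                    val_dice = vd, lr = lr_used)
    if (tc$verbose)
      message(sprintf("epoch %3d  loss %.4f  val dice %.4f  lr %.2e",
                      epoch, ep_loss / n_batches, vd, lr_used))
  }
  model$history <- do.call(rbind, hist)
  model
}

validation_dice <- function(model, pairs, tc) {
  dices <- predict_metrics(model, pairs, center = tc$center,
                           batch_size = tc$batch_size)$per_image$dsc
  mean(dices)
}

predict_metrics <- function(model, pairs, threshold = 0.5, center = TRUE,
                            batch_size = 6L, aggregate = "mean") {
  preds <- list(); gts <- list(); ids <- character(0)
  for (start in seq(1L, length(pairs), by = batch_size)) {
    chunk <- pairs[start:min(start + batch_size - 1L, length(pairs))]
    prob <- predict(model, chunk, center = center)
    for (i in seq_along(chunk)) {
      preds[[length(preds) + 1L]] <- binarize(prob[, , 1L, i], threshold)
      gts[[length(gts) + 1L]] <- chunk[[i]]$mask
      ids <- c(ids, chunk[[i]]$id)
    }
  }
  evaluate_masks(preds, gts, ids, aggregate = aggregate)
}

#' Evaluate a trained model on a test set
#'
#' @param model a trained model.
#' @param test_pairs list of sample pairs.
#' @param threshold binarisation threshold.
#' @param aggregate `"mean"` (per-image average) or `"pooled"`.
#' @param center match the training-time centering.
#' @return list with `per_image` and `summary` tibbles (DSC, JI, ACC, PRE).
#' @export
evaluate_model <- function(model, test_pairs, threshold = 0.5,
                           aggregate = "mean", center = TRUE) {
  predict_metrics(model, test_pairs, threshold = threshold, center = center,
                  aggregate = aggregate)
}

#' Summarise repeated runs
#'
#' Mirrors the mean-plus-minus-standard-deviation reporting of repeated
#' training runs: each model is evaluated on the same test set and the
#' per-run summary metrics are averaged.
#'
#' @param models list of trained models (one per seed/run).
#' @param test_pairs list of sample pairs.
#' @param ... passed to [evaluate_model()].
#' @return list with `per_run` (one row per run) and `summary` (mean and sd
#'   columns for each metric; sd is 0 for a single run).
#' @export
evaluate_runs <- function(models, test_pairs, ...) {
  per_run <- do.call(rbind, lapply(seq_along(models), function(i) {
    s <- evaluate_model(models[[i]], test_pairs, ...)$summary
    tibble::tibble(run = i, s)
  }))
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  summary <- tibble::tibble(
    dsc_mean = mean(per_run$dsc), dsc_sd = sd0(per_run$dsc),
    ji_mean = mean(per_run$ji), ji_sd = sd0(per_run$ji),
    acc_mean = mean(per_run$acc), acc_sd = sd0(per_run$acc),
    pre_mean = mean(per_run$pre), pre_sd = sd0(per_run$pre))
  list(per_run = per_run, summary = summary)
}

#' Predict binary masks and write them as PNG files
#'
#' @param model a trained model.
#' @param pairs list of sample pairs (images; masks ignored if present).
#' @param dir output directory; one `<id>.png` (values 0/255) per input.
#' @param threshold binarisation threshold.
#' @param center match the training-time centering.
#' @return invisibly, the vector of written paths.
#' @export
predict_masks <- function(model, pairs, dir, threshold = 0.5, center = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(pairs))
  for (start in seq(1L, length(pairs), by = 6L)) {
    chunk <- pairs[start:min(start + 5L, length(pairs))]
    prob <- predict(model, chunk, center = center)
    for (i in seq_along(chunk)) {
      m <- binarize(prob[, , 1L, i], threshold)
      paths[start + i - 1L] <- file.path(dir, paste0(chunk[[i]]$id, ".png"))
      png::writePNG(m * 1.0, paths[start + i - 1L])
    }
  }
  invisible(paths)
}
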