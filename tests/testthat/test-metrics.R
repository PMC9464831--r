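test_that("binarize thresholds with ties going to foreground", {
  expect_equal(as.numeric(binarize(c(0.4, 0.6), 0.5)), c(0, 1))
  expect_true(all(binarize(matrix(0.5, 3, 3), 0.5) == 1))
  b <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(binarize(b, 0.5), b + 0L)
  expect_error(binarize(b, 0), "threshold")
})

test_that("confusion counts enumerate pixels exhaustively", {
  # 4x4 masks constructed to give TP=2, FP=2, FN=2, TN=10
  gt <- matrix(0L, 4, 4); gt[1, 1:4] <- 1L
  pred <- matrix(0L, 4, 4); pred[1, 1:2] <- 1L; pred[2, 1:2] <- 1L
  cc <- confusion_counts(pred, gt)
  expect_equal(cc, list(tp = 2L, tn = 10L, fp = 2L, fn = 2L))
  expect_equal(Reduce(`+`, cc), 16L)
  # perfect agreement and perfect disagreement
  expect_equal(confusion_counts(gt, gt)[c("tp", "fp", "fn")],
               list(tp = 4L, fp = 0L, fn = 0L))
  inv <- 1L - gt
  cc2 <- confusion_counts(inv, gt)
  expect_equal(cc2$tp + cc2$tn, 0L)
  expect_error(confusion_counts(matrix(0L, 2, 2), gt), "shapes differ")
  expect_error(confusion_counts(matrix(0.5, 4, 4), gt), "binary")
})

test_that("metric formulas and degenerate conventions hold", {
  m <- compute_metrics(list(tp = 2, tn = 10, fp = 2, fn = 2))
  expect_equal(m$dsc, 0.5)
  expect_equal(m$ji, 1 / 3)
  expect_equal(m$acc, 0.75)
  expect_equal(m$pre, 0.5)
  perfect <- compute_metrics(list(tp = 5, tn = 11, fp = 0, fn = 0))
  expect_equal(unlist(perfect), c(dsc = 1, ji = 1, acc = 1, pre = 1))
  both_empty <- compute_metrics(list(tp = 0, tn = 16, fp = 0, fn = 0))
  expect_equal(unlist(both_empty), c(dsc = 1, ji = 1, acc = 1, pre = 1))
  missed <- compute_metrics(list(tp = 0, tn = 12, fp = 0, fn = 4))
  expect_equal(unlist(missed[c("dsc", "ji", "pre")]), c(dsc = 0, ji = 0, pre = 0))
})

test_that("counting metrics equal literal set arithmetic on random masks", {
  set.seed(50)
  for (i in 1:100) {
    n <- 8L
    gt <- matrix(rbinom(n * n, 1, runif(1, 0, 0.7)), n)
    pred <- matrix(rbinom(n * n, 1, runif(1, 0, 0.7)), n)
    m <- compute_metrics(confusion_counts(pred, gt))
    sgt <- which(gt == 1); spr <- which(pred == 1)
    inter <- length(intersect(sgt, spr))
    uni <- length(union(sgt, spr))
    if (length(sgt) + length(spr) > 0) {
      expect_equal(m$dsc, 2 * inter / (length(sgt) + length(spr)))
      expect_equal(m$ji, inter / uni)
      # DSC and Jaccard are the same information
      expect_equal(m$dsc, 2 * m$ji / (1 + m$ji))
    } else {
      expect_equal(m$dsc, 1); expect_equal(m$ji, 1)
    }
  }
})

test_that("metrics are invariant under joint flips of both masks", {
  set.seed(51)
  gt <- matrix(rbinom(64, 1, 0.3), 8)
  pred <- matrix(rbinom(64, 1, 0.3), 8)
  m0 <- compute_metrics(confusion_counts(pred, gt))
  flip <- function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m)))]
  m1 <- compute_metrics(confusion_counts(flip(pred), flip(gt)))
  expect_equal(m0, m1)
})

test_that("evaluate_masks reports per-image rows and the chosen aggregate", {
  gt <- matrix(0L, 4, 4); gt[1:2, 1:2] <- 1L
  pred1 <- gt
  pred2 <- matrix(0L, 4, 4); pred2[1:2, 1] <- 1L
  out <- evaluate_masks(list(pred1, pred2), list(gt, gt), c("a", "b"))
  expect_equal(nrow(out$per_image), 2L)
  expect_equal(out$per_image$dsc, c(1, 2 * 2 / (2 + 4)))
  expect_equal(out$summary$dsc, mean(out$per_image$dsc))
  pooled <- evaluate_masks(list(pred1, pred2), list(gt, gt), aggregate = "pooled")
  expect_equal(pooled$summary$dsc, 2 * 6 / (6 + 8))
})
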