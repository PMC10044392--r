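test_that("confusion counts match hand-enumerated cases", {
  ones <- matrix(1L, 4, 4)
  zeros <- matrix(0L, 4, 4)
  cc <- confusion_counts(ones, ones)
  expect_equal(unclass(cc), list(TP = 16L, FP = 0L, FN = 0L, TN = 0L),
               ignore_attr = TRUE)
  cc <- confusion_counts(zeros, ones)
  expect_equal(cc$FN, 16)
  expect_equal(cc$TP + cc$FP + cc$TN, 0)
  # pred rows (1,1 / 0,0), truth rows (1,0 / 1,0): one of each cell
  pred <- matrix(c(1, 0, 1, 0), 2, 2, byrow = FALSE)
  pred <- rbind(c(1, 1), c(0, 0))
  truth <- rbind(c(1, 0), c(1, 0))
  cc <- confusion_counts(pred, truth)
  expect_equal(unclass(cc), list(TP = 1L, FP = 1L, FN = 1L, TN = 1L),
               ignore_attr = TRUE)
  expect_error(confusion_counts(matrix(0L, 2, 2), matrix(0L, 3, 3)), "shape")
  expect_error(confusion_counts(matrix(0.5, 2, 2), matrix(0L, 2, 2)), "0/1")
})

test_that("vectorized confusion counts equal a per-pixel loop oracle", {
  set.seed(11)
  for (i in 1:100) {
    pred <- matrix(rbinom(64, 1, runif(1, 0.2, 0.8)), 8, 8)
    truth <- matrix(rbinom(64, 1, runif(1, 0.2, 0.8)), 8, 8)
    expect_identical(unclass(confusion_counts(pred, truth)),
                     lapply(loop_confusion(pred, truth), as.integer),
                     ignore_attr = TRUE)
  }
})

test_that("metric report follows the stated formulas and conventions", {
  r <- metric_report(list(TP = 8, FP = 1, FN = 1))
  expect_equal(r$precision, 8 / 9)
  expect_equal(r$recall, 8 / 9)
  expect_equal(r$f1, 8 / 9)
  expect_equal(r$iou, 0.8)
  # paired headline scores: iou 0.96 pairs with f1 0.98 under the identity
  expect_equal(round(2 * 0.96 / 1.96, 2), 0.98)
  # zero-overlap: all metrics 0
  r0 <- metric_report(list(TP = 0, FP = 5, FN = 5))
  expect_equal(unlist(r0[c("precision", "recall", "f1", "iou")]),
               c(precision = 0, recall = 0, f1 = 0, iou = 0))
  # both entirely empty: a perfect empty prediction scores 1
  r1 <- metric_report(list(TP = 0, FP = 0, FN = 0, TN = 10))
  expect_equal(r1$f1, 1)
  expect_equal(r1$iou, 1)
  expect_error(metric_report(list(TP = -1, FP = 0, FN = 0)), "non-negative")
})

test_that("f1 = 2*iou/(1+iou) on randomized counts; metrics bounded", {
  set.seed(7)
  for (i in 1:1000) {
    cnt <- list(TP = rpois(1, 20), FP = rpois(1, 5), FN = rpois(1, 5))
    r <- metric_report(cnt)
    vals <- unlist(r[c("precision", "recall", "f1", "iou")])
    expect_true(all(vals >= 0 & vals <= 1))
    expect_equal(r$f1, 2 * r$iou / (1 + r$iou), tolerance = 1e-12)
    expect_gte(r$f1, r$iou)
  }
})

test_that("binary focal loss matches its closed form and limits", {
  one <- matrix(1L, 1, 1)
  # y = 1, p = 0.5, alpha 0.25, gamma 2 -> 0.25 * 0.25 * log(2)
  expect_equal(binary_focal_loss(one, matrix(0.5, 1, 1)),
               0.25 * 0.25 * log(2), tolerance = 1e-12)
  # perfect prediction limit
  expect_lt(binary_focal_loss(one, matrix(1 - 1e-9, 1, 1)), 1e-10)
  # non-negative on random rasters, and zero only near perfection
  set.seed(3)
  y <- matrix(rbinom(64, 1, 0.4), 8, 8)
  p <- matrix(runif(64), 8, 8)
  expect_gte(binary_focal_loss(y, p), 0)
  # gamma 0, alpha 0.5 reduces to half the binary cross-entropy
  bce <- function(y, p) {
    p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
    mean(-y * log(p) - (1 - y) * log(1 - p))
  }
  for (i in 1:5) {
    y <- matrix(rbinom(64, 1, 0.5), 8, 8)
    p <- matrix(runif(64), 8, 8)
    expect_equal(
      binary_focal_loss(y, p, focal_loss_params(alpha = 0.5, gamma = 0)),
      0.5 * bce(y, p), tolerance = 1e-6)
  }
  expect_error(binary_focal_loss(one, matrix(0.5, 2, 2)), "shape")
  expect_error(focal_loss_params(alpha = 0), "alpha")
  expect_error(focal_loss_params(gamma = -1), "gamma")
})

test_that("focal loss increases as prediction moves away from truth", {
  y <- matrix(1L, 2, 2)
  ps <- seq(0.9, 0.1, by = -0.1)
  losses <- sapply(ps, function(p) binary_focal_loss(y, matrix(p, 2, 2)))
  expect_true(all(diff(losses) > 0))
  y0 <- matrix(0L, 2, 2)
  losses0 <- sapply(rev(ps), function(p) binary_focal_loss(y0, matrix(p, 2, 2)))
  expect_true(all(diff(losses0) > 0))
})

test_that("binarize uses the >= convention and is monotone in threshold", {
  half <- matrix(0.5, 3, 3)
  expect_equal(binarize(half, 0.5), matrix(1L, 3, 3))
  low <- matrix(0.1, 3, 3)
  expect_equal(sum(binarize(low, 0.5)), 0)
  set.seed(5)
  m <- matrix(runif(100), 10, 10)
  counts <- sapply(c(0.3, 0.5, 0.7), function(t) sum(binarize(m, t)))
  expect_true(all(diff(counts) <= 0))
  expect_error(binarize(m, 0), "threshold")
  expect_error(binarize(m, 1), "threshold")
})

test_that("evaluate_masks averages per image and can pool counts", {
  p1 <- matrix(c(1, 1, 0, 0), 2, 2); t1 <- matrix(1L, 2, 2)   # recall 0.5
  p2 <- matrix(1L, 2, 2); t2 <- matrix(1L, 2, 2)              # recall 1
  per <- evaluate_masks(list(p1, p2), list(t1, t2))
  expect_equal(per$recall, mean(c(0.5, 1)))
  pooled <- evaluate_masks(list(p1, p2), list(t1, t2), pooled = TRUE)
  expect_equal(pooled$recall, 6 / 8)
})
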