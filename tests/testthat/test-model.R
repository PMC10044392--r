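# small shared fixtures: 32x32 easy samples and a 32-px tiny backbone keep
# these tests in the seconds range
spec32 <- backbone_spec("tiny", input_size = 32)

easy32 <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_dataset(synthetic_config(
        24, image_size = 32, background_palette = c("skin", "flat"),
        hard_fraction = 0, seed = 515))
    cache
  }
})

test_that("model output is a probability raster aligned with the input", {
  m <- build_model(spec32, seed = 4)
  s <- easy32()$samples[[1]]
  p <- predict_prob(m, s)
  expect_identical(dim(p), c(32L, 32L))
  expect_true(all(p > 0 & p < 1))
  # same spec and seed: identical initial predictions
  m2 <- build_model(spec32, seed = 4)
  expect_identical(predict_prob(m2, s), p)
  # different seed: different weights
  m3 <- build_model(spec32, seed = 5)
  expect_false(identical(predict_prob(m3, s), p))
  expect_error(backbone_spec("resnet50"), "unknown")
})

test_that("parameter counts are ordered tiny < mobilenet_v2 < efficientnet_b3", {
  n_tiny <- n_parameters(backbone_spec("tiny"))
  n_mob <- n_parameters(backbone_spec("mobilenet_v2"))
  n_eff <- n_parameters(backbone_spec("efficientnet_b3", input_size = 64))
  expect_lt(n_tiny, n_mob)
  expect_lt(n_mob, n_eff)
})

test_that("a zero-weight model predicts probability one half everywhere", {
  m <- build_model(spec32, seed = 1)
  m$weights <- lapply(m$weights, function(w) { w[] <- 0; w })
  s <- easy32()$samples[[1]]
  expect_true(all(predict_prob(m, s) == 0.5))
  # and the >= convention binarizes it to an all-ones mask
  expect_equal(sum(predict_masks(m, list(s), 0.5)[[1]]), 32 * 32)
})

test_that("training reduces the loss and is reproducible given the seed", {
  ds <- easy32()
  tr <- ds$samples[1:16]
  msk <- lapply(tr, `[[`, "truth_mask")
  m <- build_model(spec32, seed = 7)
  cfg <- training_config(epochs = 12, learning_rate = 1e-3, seed = 3)
  fit1 <- train_model(m, tr, msk, cfg = cfg)
  expect_lt(tail(fit1$history$train_loss, 1), fit1$history$train_loss[1])
  fit2 <- train_model(m, tr, msk, cfg = cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(weight_fingerprint(fit1$model), weight_fingerprint(fit2$model))
  expect_error(train_model(m, list(), list(), cfg = cfg), "empty")
  expect_error(train_model(m, tr[1], list(NULL), cfg = cfg), "missing masks")
})

test_that("a tiny model trained on easy samples segments held-out ones", {
  ds <- easy32()
  tr <- ds$samples[1:16]; te <- ds$samples[17:24]
  fit <- train_model(build_model(spec32, seed = 7), tr,
                     lapply(tr, `[[`, "truth_mask"),
                     cfg = training_config(epochs = 40, learning_rate = 1e-3,
                                           seed = 3))
  thr <- focal_neutral_threshold()  # the loss-matched operating point
  rep <- evaluate_masks(predict_masks(fit$model, te, thr),
                        lapply(te, `[[`, "truth_mask"))
  expect_gte(rep$f1, 0.9)
  # inference is deterministic
  p1 <- predict_masks(fit$model, te[1:2])
  p2 <- predict_masks(fit$model, te[1:2])
  expect_identical(p1, p2)
})

test_that("save/load and reset reproduce predictions bit-exactly", {
  ds <- easy32()
  m <- build_model(spec32, seed = 11)
  fit <- train_model(m, ds$samples[1:8],
                     lapply(ds$samples[1:8], `[[`, "truth_mask"),
                     cfg = training_config(epochs = 3, learning_rate = 1e-3,
                                           seed = 1))
  trained <- fit$model
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(trained, f)
  back <- load_model(f)
  s <- ds$samples[[9]]
  expect_identical(predict_prob(back, s), predict_prob(trained, s))
  expect_true(file.exists(paste0(f, ".json")))
  # reset restores the pretrained predictions on arbitrary inputs
  reset <- reset_weights(trained, m)
  for (i in 9:12)
    expect_identical(predict_prob(reset, ds$samples[[i]]),
                     predict_prob(m, ds$samples[[i]]))
  # idempotent
  expect_identical(reset_weights(reset, m)$weights, reset$weights)
  # spec mismatch is an error
  other <- build_model(backbone_spec("tiny", input_size = 64), seed = 1)
  expect_error(reset_weights(trained, other), "spec")
})

test_that("train -> reset -> train reproduces the first history", {
  ds <- easy32()
  pre <- build_model(spec32, seed = 2)
  cfg <- training_config(epochs = 4, learning_rate = 1e-3, seed = 6)
  tr <- ds$samples[1:8]; msk <- lapply(tr, `[[`, "truth_mask")
  fit1 <- train_model(reset_weights(pre, pre), tr, msk, cfg = cfg)
  fit2 <- train_model(reset_weights(fit1$model, pre), tr, msk, cfg = cfg)
  expect_identical(fit1$history, fit2$history)
})

test_that("the C++ focal loss agrees with the reference implementation", {
  ds <- easy32()
  m <- build_model(spec32, seed = 8)
  s <- ds$samples[[1]]
  y <- s$truth_mask
  p <- predict_prob(m, s)
  x <- woundassl:::prepare_image(s$pixels, 32)
  for (prm in list(c(0.25, 2), c(0.5, 0), c(0.75, 1))) {
    cpp <- woundassl:::cpp_unet_loss(m$weights, spec32$widths, 3L,
                                     list(x), list(y * 1.0), prm[1], prm[2])
    ref <- binary_focal_loss(y, p, focal_loss_params(alpha = prm[1],
                                                     gamma = prm[2]))
    expect_equal(cpp, ref, tolerance = 1e-10)
  }
})

test_that("analytic gradients match finite differences", {
  spec16 <- backbone_spec("tiny", input_size = 16)
  m <- build_model(spec16, seed = 3)
  set.seed(42)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  y <- matrix(rbinom(256, 1, 0.3), 16, 16) * 1.0
  g <- woundassl:::cpp_unet_grad(m$weights, spec16$widths, 3L, x, y, 0.25, 2)
  expect_equal(g$loss,
               woundassl:::cpp_unet_loss(m$weights, spec16$widths, 3L,
                                         list(x), list(y), 0.25, 2))
  set.seed(9)
  for (nm in names(m$weights)) {
    for (i in sample(length(m$weights[[nm]]), min(2, length(m$weights[[nm]])))) {
      eps <- 1e-6
      wp <- m$weights; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- m$weights; wm[[nm]][i] <- wm[[nm]][i] - eps
      num <- (woundassl:::cpp_unet_loss(wp, spec16$widths, 3L, list(x), list(y), 0.25, 2) -
              woundassl:::cpp_unet_loss(wm, spec16$widths, 3L, list(x), list(y), 0.25, 2)) / (2 * eps)
      ana <- g$grads[[nm]][i]
      expect_lt(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 1e-4)
    }
  }
})

test_that("flip augmentation applies the same flip to image and mask", {
  s <- easy32()$samples[[1]]
  img <- s$pixels; msk <- s$truth_mask
  flips <- list(
    none = function(a) a,
    v = function(a) if (length(dim(a)) == 3) a[nrow(a):1, , , drop = FALSE] else a[nrow(a):1, ],
    h = function(a) if (length(dim(a)) == 3) a[, ncol(a):1, , drop = FALSE] else a[, ncol(a):1],
    hv = function(a) if (length(dim(a)) == 3) a[nrow(a):1, ncol(a):1, , drop = FALSE] else a[nrow(a):1, ncol(a):1]
  )
  combo_of <- function(pair) {
    for (nm in names(flips))
      if (identical(pair$mask, flips[[nm]](msk)) &&
          identical(pair$image, flips[[nm]](img))) return(nm)
    NA_character_
  }
  tally <- c(none = 0, v = 0, h = 0, hv = 0)
  withr::with_seed(77, {
    for (i in 1:1000) {
      pair <- augment_pair(img, msk)
      nm <- combo_of(pair)
      expect_false(is.na(nm))  # image and mask always flipped together
      expect_equal(sum(pair$mask), sum(msk))  # area conserved
      tally[nm] <- tally[nm] + 1
    }
  })
  expect_true(all(abs(tally / 1000 - 0.25) <= 0.05))
  # flips are involutions
  expect_identical(flips$v(flips$v(img)), img)
  expect_identical(flips$h(flips$h(msk)), msk)
  expect_error(augment_pair(img, msk[1:10, ]), "shape")
})

test_that("prediction is spatially aligned with the input", {
  # train on half-plane masks; the predicted boundary must sit at the centre
  set.seed(33)
  imgs <- list(); msks <- list()
  for (i in 1:8) {
    img <- array(0L, c(32, 32, 3))
    top <- matrix(0L, 32, 32); top[1:16, ] <- 1L
    img[, , 1] <- as.integer(120 + 100 * top + sample(-5:5, 1))
    img[, , 2] <- 60L; img[, , 3] <- 60L
    imgs[[i]] <- img; msks[[i]] <- top
  }
  fit <- train_model(build_model(spec32, seed = 21), imgs, msks,
                     cfg = training_config(epochs = 30, learning_rate = 3e-3,
                                           seed = 2, horizontal_flip = FALSE,
                                           vertical_flip = FALSE))
  pred <- predict_masks(fit$model, imgs[1])[[1]]
  row_means <- rowMeans(pred)
  expect_gt(mean(row_means[1:12]), 0.9)   # well inside the foreground half
  expect_lt(mean(row_means[21:32]), 0.1)  # well inside the background half
})

test_that("masks are upsampled back to the original image resolution", {
  ds64 <- tiny_dataset()
  m <- build_model(spec32, seed = 5)     # 32-px model, 64-px images
  out <- predict_masks(m, ds64$samples[1])[[1]]
  expect_identical(dim(out), dim(ds64$samples[[1]]$truth_mask))
  expect_true(all(out %in% c(0L, 1L)))
})
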