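#' Backbone specification for the encoder-decoder segmentation model
#'
#' The model family is a U-Net style encoder-decoder: 3x3 convolutions with
#' ReLU, 2x2 average pooling, nearest-neighbour upsampling with skip
#' concatenation, and a 1x1 sigmoid head producing one foreground probability
#' per pixel. Named presets set the depth and channel widths:
#'
#' * `tiny` (default): 3 resolution levels, base width 8 - trains end-to-end
#'   on one CPU at 64x64 in minutes and is the intended desk-scale backbone.
#' * `mobilenet_v2`: 3 levels, base width 16 - a mid-capacity preset sized to
#'   echo the relative capacity of a mobile-grade backbone.
#' * `efficientnet_b3`: 4 levels, base width 24 - the high-capacity preset.
#'
#' The two larger presets are capacity stand-ins within the same convolutional
#' family, not reproductions of the original MobileNet/EfficientNet
#' architectures; parameter counts are ordered tiny < mobilenet_v2 <
#' efficientnet_b3.
#'
#' @param name one of `"tiny"`, `"mobilenet_v2"`, `"efficientnet_b3"`.
#' @param input_size square input side in pixels, divisible by `2^levels`.
#'   Default 64.
#' @param base_width channel count of the first encoder level (tiny preset
#'   only; the named larger presets fix their own widths).
#' @return A list of class `backbone_spec` with a `widths` vector (encoder
#'   levels plus bottleneck).
#' @export
backbone_spec <- function(name = "tiny", input_size = 64, base_width = 8) {
  presets <- list(
    tiny = list(levels = 3, base = base_width),
    mobilenet_v2 = list(levels = 3, base = 16),
    efficientnet_b3 = list(levels = 4, base = 24)
  )
  if (!is.character(name) || length(name) != 1 || !name %in% names(presets))
    abort_wa("unknown backbone name: ", name)
  p <- presets[[name]]
  if (input_size %% (2^p$levels) != 0)
    abort_wa("input_size must be divisible by ", 2^p$levels)
  widths <- as.integer(p$base * 2^(0:p$levels))
  structure(list(name = name, input_size = as.integer(input_size),
                 base_width = as.integer(p$base), levels = p$levels,
                 widths = widths),
            class = "backbone_spec")
}

#' Training configuration
#'
#' Defaults follow the reference training protocol: 100 epochs per round,
#' Adam with learning rate 1e-5, binary focal loss (alpha 0.25, gamma 2), and
#' augmentation restricted to horizontal and vertical flips. Desk-scale runs
#' on the tiny backbone typically reduce `epochs` and raise `learning_rate`
#' (the 1e-5 default assumes a strongly pretrained full-scale backbone).
#'
#' @param epochs training epochs. Default 100.
#' @param learning_rate Adam learning rate. Default 1e-5.
#' @param loss a [focal_loss_params()].
#' @param horizontal_flip,vertical_flip enable the two flip augmentations
#'   (each applied independently with probability 0.5). Defaults `TRUE`.
#' @param batch_size minibatch size. Default 8.
#' @param seed RNG seed for shuffling and augmentation.
#' @return A list of class `training_config`.
#' @export
training_config <- function(epochs = 100, learning_rate = 1e-5,
                            loss = focal_loss_params(),
                            horizontal_flip = TRUE, vertical_flip = TRUE,
                            batch_size = 8, seed = 1L) {
  if (epochs < 1) abort_wa("epochs must be >= 1")
  if (learning_rate <= 0) abort_wa("learning_rate must be positive")
  if (batch_size < 1) abort_wa("batch_size must be >= 1")
  if (!inherits(loss, "focal_loss_params")) loss <- do.call(focal_loss_params, loss)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 loss = loss, horizontal_flip = horizontal_flip,
                 vertical_flip = vertical_flip,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "training_config")
}

#' Build a segmentation model with seeded random initialisation
#'
#' @param spec a [backbone_spec()].
#' @param seed integer seed; two builds with the same spec and seed produce
#'   identical initial weights (He initialisation, zero biases).
#' @param provenance free-text provenance tag stored with the state.
#' @return A list of class `wound_model` with fields `spec`, `weights`,
#'   `provenance`.
#' @export
build_model <- function(spec = backbone_spec(), seed = 1L,
                        provenance = "random-init") {
  if (!inherits(spec, "backbone_spec"))
    abort_wa("spec must be created with backbone_spec()")
  weights <- cpp_unet_init(spec$widths, 3L, as.integer(seed))
  structure(list(spec = spec, weights = weights, provenance = provenance),
            class = "wound_model")
}

#' Number of trainable parameters of a model or backbone spec
#' @param x a `wound_model` or `backbone_spec`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(x) {
  if (inherits(x, "backbone_spec")) x <- build_model(x, seed = 0L)
  if (!inherits(x, "wound_model")) abort_wa("x must be a model or backbone spec")
  sum(vapply(x$weights, length, 0L))
}

# 8-bit HxWx3 integer array -> [0,1] double array at the model input size
prepare_image <- function(pixels, input_size) {
  if (length(dim(pixels)) == 2) pixels <- array(rep(pixels, 3), c(dim(pixels), 3))
  img <- pixels / 255
  if (nrow(img) != input_size || ncol(img) != input_size)
    img <- as.array(EBImage::resize(img, w = input_size, h = input_size))
  pmin(pmax(img, 0), 1)
}

as_pixel_list <- function(images) {
  lapply(images, function(x) if (inherits(x, "wound_sample")) x$pixels else x)
}

#' Train a segmentation model
#'
#' Optimises the binary focal loss with Adam over flip-augmented image/mask
#' pairs. The Adam state is fresh at each call (per-round retraining always
#' restarts the optimiser). Fully deterministic given the config seed.
#'
#' @param state a `wound_model`.
#' @param images list of 8-bit RGB arrays (or `wound_sample`s) at the model
#'   input size.
#' @param masks list of binary masks aligned with `images`.
#' @param val_images,val_masks optional held-out pairs; per-epoch validation
#'   loss is recorded when given.
#' @param cfg a [training_config()].
#' @return A list with `model` (trained `wound_model`) and `history` (data
#'   frame with `epoch`, `train_loss`, `val_loss`).
#' @export
train_model <- function(state, images, masks, val_images = NULL,
                        val_masks = NULL, cfg = training_config()) {
  if (!inherits(state, "wound_model")) abort_wa("state must be a wound_model")
  if (length(images) == 0) abort_wa("empty training set")
  if (length(images) != length(masks)) abort_wa("images/masks length mismatch")
  if (any(vapply(masks, is.null, TRUE))) abort_wa("training samples missing masks")
  sz <- state$spec$input_size
  xs <- lapply(as_pixel_list(images), prepare_image, input_size = sz)
  ys <- lapply(masks, function(m) {
    assert_mask(m)
    if (nrow(m) != sz || ncol(m) != sz)
      m <- as.matrix(EBImage::resize(m, w = sz, h = sz, filter = "none"))
    storage.mode(m) <- "double"
    m
  })
  vx <- list(); vy <- list()
  if (!is.null(val_images)) {
    vx <- lapply(as_pixel_list(val_images), prepare_image, input_size = sz)
    vy <- lapply(val_masks, function(m) {
      storage.mode(m) <- "double"
      if (nrow(m) != sz) m <- as.matrix(EBImage::resize(m, w = sz, h = sz, filter = "none"))
      m
    })
  }
  res <- cpp_unet_train(state$weights, state$spec$widths, 3L, xs, ys, vx, vy,
                        cfg$epochs, cfg$learning_rate, cfg$batch_size,
                        cfg$loss$alpha, cfg$loss$gamma,
                        cfg$horizontal_flip, cfg$vertical_flip, cfg$seed)
  trained <- state
  trained$weights <- res$weights
  trained$provenance <- paste0(state$provenance, "+trained")
  history <- data.frame(epoch = seq_len(cfg$epochs),
                        train_loss = as.numeric(res$train_loss),
                        val_loss = as.numeric(res$val_loss))
  list(model = trained, history = history)
}

#' Predict per-pixel foreground probabilities for one image
#'
#' @param state a `wound_model`.
#' @param image 8-bit RGB array or `wound_sample`.
#' @return Probability matrix at the model input size.
#' @export
predict_prob <- function(state, image) {
  if (!inherits(state, "wound_model")) abort_wa("state must be a wound_model")
  px <- as_pixel_list(list(image))[[1]]
  x <- prepare_image(px, state$spec$input_size)
  cpp_unet_predict(state$weights, state$spec$widths, 3L, x)
}

#' Predict binary masks for a set of images
#'
#' Images are resized to the model input size (bilinear), the probability map
#' is binarized with [binarize()], and the binary mask is returned at the
#' original image resolution (nearest-neighbour upsampling).
#'
#' @param state a `wound_model`.
#' @param images list of 8-bit RGB arrays or `wound_sample`s.
#' @param threshold binarization threshold in `(0, 1)`. Default 0.5.
#' @return List of binary masks, one per image, at original resolution.
#' @export
predict_masks <- function(state, images, threshold = 0.5) {
  pxs <- as_pixel_list(images)
  lapply(pxs, function(px) {
    prob <- predict_prob(state, px)
    m <- binarize(prob, threshold)
    if (nrow(m) != nrow(px) || ncol(m) != ncol(px)) {
      m <- as.matrix(EBImage::resize(m, w = nrow(px), h = ncol(px),
                                     filter = "none"))
      storage.mode(m) <- "integer"
    }
    m
  })
}

#' Restore a model to a pretrained weight configuration
#'
#' Returns a state whose predictions are bit-identical to `pretrained`'s on
#' any input. Idempotent. The backbone specs must match.
#'
#' @param state,pretrained `wound_model`s with identical `backbone_spec`s.
#' @return A `wound_model`.
#' @export
reset_weights <- function(state, pretrained) {
  if (!inherits(state, "wound_model") || !inherits(pretrained, "wound_model"))
    abort_wa("both arguments must be wound_models")
  if (!identical(state$spec, pretrained$spec))
    abort_wa("backbone specs do not match")
  state$weights <- pretrained$weights
  state$provenance <- pretrained$provenance
  state
}

#' Compact fingerprint of a model's weights
#'
#' Summary statistics over the flattened parameter vector, used to assert that
#' two states carry identical weights (e.g. the per-round reset contract).
#'
#' @param state a `wound_model`.
#' @return Named numeric vector.
#' @export
weight_fingerprint <- function(state) {
  v <- unlist(state$weights, use.names = FALSE)
  c(n = length(v), sum = sum(v), sumsq = sum(v^2), min = min(v), max = max(v))
}

#' Apply the flip augmentation to an aligned image/mask pair
#'
#' Horizontal and vertical flips are each applied with probability 0.5, and
#' the identical flip is applied to image and mask. Draws from the current R
#' RNG state; seed with `set.seed()` or `withr::with_seed()` for
#' reproducibility.
#'
#' @param image H x W x 3 array.
#' @param mask H x W binary mask.
#' @return A list with flipped `image` and `mask`.
#' @export
augment_pair <- function(image, mask) {
  assert_same_shape(image, mask, "image and mask")
  fh <- runif(1) < 0.5
  fv <- runif(1) < 0.5
  if (fv) { image <- image[nrow(image):1, , , drop = FALSE]; mask <- mask[nrow(mask):1, , drop = FALSE] }
  if (fh) { image <- image[, ncol(image):1, , drop = FALSE]; mask <- mask[, ncol(mask):1, drop = FALSE] }
  list(image = image, mask = mask)
}

#' Save / load a model state
#'
#' The weights are written to `path` and a JSON sidecar (`<path>.json`)
#' records the backbone spec and provenance. The round trip reproduces
#' bit-identical predictions.
#'
#' @param state a `wound_model`.
#' @param path weights file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   `wound_model`.
#' @export
save_model <- function(state, path) {
  if (!inherits(state, "wound_model")) abort_wa("state must be a wound_model")
  saveRDS(state$weights, path)
  sidecar <- list(
    backbone = state$spec$name,
    input_size = state$spec$input_size,
    base_width = state$spec$base_width,
    provenance = state$provenance
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spec <- backbone_spec(side$backbone, input_size = side$input_size,
                        base_width = side$base_width)
  structure(list(spec = spec, weights = readRDS(path),
                 provenance = side$provenance),
            class = "wound_model")
}
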