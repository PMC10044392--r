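#' Read and write 8-bit RGB images
#'
#' PNG files are read with the png package, everything else (JPEG) through
#' EBImage. Grayscale inputs are promoted to three identical channels. Images
#' are held in memory as H x W x 3 integer arrays with values in 0..255.
#' PNG write/read round trips are bit-identical; JPEG is lossy by nature
#' (written at quality 90).
#'
#' @param path file path.
#' @return `read_image` returns a `wound_sample` (no mask); `write_image`
#'   returns `path` invisibly.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort_wa("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
  } else {
    img <- EBImage::readImage(path)
    arr <- as.array(img)
    # EBImage stores x (width) first; transpose to row = y convention
    arr <- if (length(dim(arr)) == 2) t(arr) else aperm(arr, c(2, 1, 3))
  }
  if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), c(dim(arr), 3))
  if (dim(arr)[3] > 3) arr <- arr[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(arr)[3] == 1) arr <- array(rep(arr, 3), c(dim(arr)[1:2], 3))
  pixels <- array(as.integer(round(arr * 255)), dim(arr))
  structure(list(
    sample_id = tools::file_path_sans_ext(basename(path)),
    pixels = pixels, truth_mask = NULL, camera_tag = NA_character_
  ), class = "wound_sample")
}

#' @rdname read_image
#' @param sample a `wound_sample` or an H x W x 3 integer array (0..255).
#' @param quality JPEG quality (ignored for PNG). Default 90.
#' @export
write_image <- function(sample, path, quality = 90) {
  px <- if (inherits(sample, "wound_sample")) sample$pixels else sample
  if (any(px < 0) || any(px > 255)) abort_wa("pixel values must be in [0, 255]")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(px / 255, path)
  } else {
    arr <- aperm(px / 255, c(2, 1, 3))
    EBImage::writeImage(EBImage::Image(arr, colormode = "Color"), path,
                        quality = quality)
  }
  invisible(path)
}

#' Read and write binary masks as single-channel PNG
#'
#' Masks are stored with values {0, 255} (PNG only, never JPEG, so labels are
#' never corrupted by lossy compression). On read, values above 127 map to
#' foreground; if any pixel is neither 0 nor 255 a warning reports how many
#' were coerced.
#'
#' @param path PNG file path.
#' @return `read_mask` returns a 0/1 integer matrix; `write_mask` returns
#'   `path` invisibly.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) abort_wa("cannot read mask: ", path)
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  raw <- round(arr * 255)
  odd <- sum(raw != 0 & raw != 255)
  if (odd > 0)
    warning(odd, " mask pixel(s) were neither 0 nor 255; coerced by >127 rule")
  m <- matrix(as.integer(raw > 127), nrow(raw), ncol(raw))
  m
}

#' @rdname read_mask
#' @param mask a 0/1 binary mask matrix.
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  if (tolower(tools::file_ext(path)) != "png")
    abort_wa("masks must be written as PNG")
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' Overlay a mask on its image for visual review
#'
#' Draws the mask contour in green (a 2-px band) and tints the interior with
#' a translucent green fill, the standard presentation for accept/discard
#' review of a segmentation. Pixels outside the contour band and the fill are
#' never altered; an empty mask returns the image unchanged. Pure function of
#' its inputs.
#'
#' @param sample a `wound_sample` or H x W x 3 integer array.
#' @param mask binary mask aligned with the image.
#' @param alpha fill opacity in `[0, 1]`. Default 0.25.
#' @return An H x W x 3 integer array (0..255).
#' @export
render_overlay <- function(sample, mask, alpha = 0.25) {
  px <- if (inherits(sample, "wound_sample")) sample$pixels else sample
  assert_mask(mask)
  assert_same_shape(px, mask, "image and mask")
  if (sum(mask) == 0) return(px)
  er2 <- as.matrix(EBImage::erode(mask, EBImage::makeBrush(5, "disc")))
  contour <- mask == 1 & er2 == 0          # ~2-px inner band
  fill <- mask == 1 & !contour
  out <- px / 255
  green <- c(0, 1, 0)
  for (c in 1:3) {
    ch <- out[, , c]
    ch[contour] <- green[c]
    ch[fill] <- (1 - alpha) * ch[fill] + alpha * green[c]
    out[, , c] <- ch
  }
  array(as.integer(round(out * 255)), dim(px))
}

#' Write / read a dataset directory
#'
#' Writes `images/<id>.png`, `masks/<id>.png` (when a mask is present) and
#' `manifest.csv` with columns `sample_id`, `image_path`, `mask_path`,
#' `camera_tag`, `split_status`. `read_dataset` reconstructs the
#' `wound_dataset` from such a directory.
#'
#' @param dataset a `wound_dataset`.
#' @param dir target directory (created if missing).
#' @return `write_dataset` returns the manifest data frame invisibly;
#'   `read_dataset` returns a `wound_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  man <- dataset$manifest
  for (i in seq_along(dataset$samples)) {
    s <- dataset$samples[[i]]
    ip <- file.path("images", paste0(s$sample_id, ".png"))
    write_image(s, file.path(dir, ip))
    man$image_path[i] <- ip
    if (!is.null(s$truth_mask)) {
      mp <- file.path("masks", paste0(s$sample_id, ".png"))
      write_mask(s$truth_mask, file.path(dir, mp))
      man$mask_path[i] <- mp
    }
  }
  write_manifest(man, file.path(dir, "manifest.csv"))
  invisible(man)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  man <- read_manifest(file.path(dir, "manifest.csv"))
  samples <- lapply(seq_len(nrow(man)), function(i) {
    s <- read_image(file.path(dir, man$image_path[i]))
    s$sample_id <- man$sample_id[i]
    s$camera_tag <- man$camera_tag[i]
    if (!is.na(man$mask_path[i]) && nzchar(man$mask_path[i]))
      s$truth_mask <- read_mask(file.path(dir, man$mask_path[i]))
    s
  })
  structure(list(samples = samples, manifest = man), class = "wound_dataset")
}

#' Read / write a dataset manifest
#'
#' @param manifest data frame with columns `sample_id`, `image_path`,
#'   `mask_path`, `camera_tag`, `split_status`.
#' @param path CSV file path.
#' @return `read_manifest` returns the manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  need <- c("sample_id", "image_path", "mask_path", "camera_tag", "split_status")
  if (!all(need %in% names(manifest)))
    abort_wa("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(manifest$sample_id))
    abort_wa("manifest sample_id values must be unique")
  write.csv(manifest[need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  man <- read.csv(path, stringsAsFactors = FALSE)
  if (anyDuplicated(man$sample_id)) abort_wa("duplicate sample_id in manifest")
  man
}

#' Read / write accept-discard decisions
#'
#' The decisions table records one row per reviewed mask: the three criteria,
#' the overall decision, and whether it came from the simulated oracle or a
#' human reviewer.
#'
#' @param decisions data frame with columns `sample_id`, `covers_wound`,
#'   `only_wound`, `boundary_ok`, `accepted`, `mode`.
#' @param path CSV file path.
#' @export
write_decisions <- function(decisions, path) {
  write.csv(decisions, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_decisions
#' @export
read_decisions <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Validate a directory of predicted masks against reference masks
#'
#' Runs the simulated oracle over matching mask files and returns (and
#' optionally writes) a decisions table.
#'
#' @param pred_dir,truth_dir directories of mask PNGs with matching names.
#' @param thresholds a [validation_thresholds()].
#' @param out optional CSV output path.
#' @return Decisions data frame.
#' @export
validate_mask_dir <- function(pred_dir, truth_dir,
                              thresholds = validation_thresholds(),
                              out = NULL) {
  files <- sort(list.files(pred_dir, pattern = "\\.png$"))
  if (length(files) == 0) abort_wa("no predicted masks in ", pred_dir)
  rows <- lapply(files, function(f) {
    pred <- read_mask(file.path(pred_dir, f))
    truth <- read_mask(file.path(truth_dir, f))
    v <- oracle_validate(pred, truth, thresholds)
    data.frame(sample_id = tools::file_path_sans_ext(f),
               covers_wound = v$covers_wound, only_wound = v$only_wound,
               boundary_ok = v$boundary_ok, accepted = v$accepted,
               mode = "oracle", stringsAsFactors = FALSE)
  })
  dec <- do.call(rbind, rows)
  if (!is.null(out)) write_decisions(dec, out)
  dec
}

# ---------------------------------------------------------------------------
# configuration files
# ---------------------------------------------------------------------------

#' Load / save an ASSL configuration as YAML
#'
#' An empty file yields all defaults (target 0.80, val_fraction 0.10, 100
#' epochs, learning rate 1e-5, focal alpha 0.25 and gamma 2). Unknown keys are
#' rejected with an error listing them. `thresholds`, `training` and `loss`
#' are nested maps with the field names of [validation_thresholds()],
#' [training_config()] and [focal_loss_params()].
#'
#' @param path YAML file path.
#' @return `load_config` returns an [assl_config()].
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  top_keys <- c("target_correct_fraction", "max_rounds", "plateau_patience",
                "val_fraction", "seed", "thresholds", "training",
                "binarize_threshold")
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad) > 0)
      abort_wa("unknown config key(s) in ", where, ": ",
               paste(bad, collapse = ", "))
  }
  check_keys(raw, top_keys, "top level")
  th <- raw$thresholds %||% list()
  check_keys(th, names(formals(validation_thresholds)), "thresholds")
  tr <- raw$training %||% list()
  check_keys(tr, names(formals(training_config)), "training")
  if (!is.null(tr$loss)) {
    check_keys(tr$loss, names(formals(focal_loss_params)), "training$loss")
    tr$loss <- do.call(focal_loss_params, tr$loss)
  }
  args <- raw[setdiff(names(raw), c("thresholds", "training"))]
  args$thresholds <- do.call(validation_thresholds, th)
  args$training <- do.call(training_config, tr)
  do.call(assl_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname load_config
#' @param cfg an [assl_config()].
#' @export
save_config <- function(cfg, path) {
  if (!inherits(cfg, "assl_config")) abort_wa("cfg must be an assl_config")
  x <- unclass(cfg)
  x$thresholds <- unclass(x$thresholds)
  x$training <- unclass(x$training)
  x$training$loss <- unclass(x$training$loss)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

# ---------------------------------------------------------------------------
# round history
# ---------------------------------------------------------------------------

#' Persist / restore an ASSL round history as JSON
#'
#' The full round history (one entry per `round_state`, including pool ids
#' and split ids) round-trips losslessly.
#'
#' @param history an `assl_run` or list of `round_state`s.
#' @param path JSON file path.
#' @export
write_history <- function(history, path) {
  if (inherits(history, "assl_run")) history <- history$history
  ser <- lapply(history, function(r) {
    list(round_index = r$round_index, n_train = r$n_train, n_val = r$n_val,
         n_correct = r$n_correct, f1 = r$f1, iou = r$iou,
         pool = list(labeled = as.list(r$pool$labeled),
                     unlabeled = as.list(r$pool$unlabeled),
                     total = r$pool$total),
         train_ids = as.list(r$train_ids), val_ids = as.list(r$val_ids),
         start_fingerprint = as.list(r$start_fingerprint))
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_history
#' @export
read_history <- function(path) {
  raw <- jsonlite::read_json(path)
  as_chr <- function(x) as.character(unlist(x, use.names = FALSE))
  lapply(raw, function(r) {
    fp <- unlist(r$start_fingerprint)
    structure(list(
      round_index = as.integer(r$round_index),
      n_train = as.integer(r$n_train), n_val = as.integer(r$n_val),
      n_correct = as.integer(r$n_correct),
      f1 = if (is.null(r$f1)) NA_real_ else as.numeric(r$f1),
      iou = if (is.null(r$iou)) NA_real_ else as.numeric(r$iou),
      pool = list(labeled = as_chr(r$pool$labeled),
                  unlabeled = as_chr(r$pool$unlabeled),
                  total = as.integer(r$pool$total)),
      train_ids = as_chr(r$train_ids), val_ids = as_chr(r$val_ids),
      start_fingerprint = stats::setNames(as.numeric(fp), names(fp))
    ), class = "round_state")
  })
}
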