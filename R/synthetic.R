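#' Configuration for the synthetic wound-image generator
#'
#' The generator emulates the statistical structure of a heterogeneous
#' clinical wound-photo collection: variable backgrounds (skin-like,
#' fabric-like, flat-colour), per-image lighting (global gain and gamma,
#' emulating illumination and exposure differences between devices), and a
#' reddish wound blob with exact binary ground truth. A configurable fraction
#' of "hard" samples has low wound/background contrast, which controls how
#' many images a source-domain model segments correctly at the start of an
#' ASSL run.
#'
#' @param n_images number of samples to generate.
#' @param image_size square image side in pixels (must be divisible by 8).
#'   Default 64.
#' @param wound_area_fraction_range wound area as a fraction of the image,
#'   `0 < min < max < 1`. Default `c(0.05, 0.25)`.
#' @param background_palette subset of `c("skin", "fabric", "flat")`.
#' @param lighting_gain_range multiplicative gain range. Default `c(0.7, 1.3)`.
#' @param lighting_gamma_range gamma range. Default `c(0.8, 1.25)`.
#' @param hard_fraction fraction of low-contrast samples in `[0, 1]`.
#'   Default 0.5.
#' @param hard_contrast_range blend factor of wound colour toward the
#'   background for hard samples, a continuum from moderately to severely
#'   low-contrast so that a model trained on accepted samples can bootstrap
#'   its way down the difficulty scale across rounds. Default `c(0.25, 0.65)`.
#' @param seed integer RNG seed; identical configurations (including seed)
#'   produce identical output.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_images,
                             image_size = 64,
                             wound_area_fraction_range = c(0.05, 0.25),
                             background_palette = c("skin", "fabric", "flat"),
                             lighting_gain_range = c(0.7, 1.3),
                             lighting_gamma_range = c(0.8, 1.25),
                             hard_fraction = 0.5,
                             hard_contrast_range = c(0.25, 0.65),
                             seed = 1L) {
  if (!is.numeric(n_images) || length(n_images) != 1 || n_images < 0)
    abort_wa("n_images must be a non-negative count")
  r <- wound_area_fraction_range
  if (length(r) != 2 || r[1] <= 0 || r[2] >= 1 || r[1] >= r[2])
    abort_wa("wound_area_fraction_range must satisfy 0 < min < max < 1")
  if (!all(background_palette %in% c("skin", "fabric", "flat")) ||
      length(background_palette) == 0)
    abort_wa("background_palette must be a non-empty subset of skin/fabric/flat")
  if (image_size < 16 || image_size %% 8 != 0)
    abort_wa("image_size must be >= 16 and divisible by 8")
  if (hard_fraction < 0 || hard_fraction > 1)
    abort_wa("hard_fraction must be in [0, 1]")
  structure(list(
    n_images = as.integer(n_images),
    image_size = as.integer(image_size),
    wound_area_fraction_range = as.numeric(r),
    background_palette = background_palette,
    lighting_gain_range = as.numeric(lighting_gain_range),
    lighting_gamma_range = as.numeric(lighting_gamma_range),
    hard_fraction = hard_fraction,
    hard_contrast_range = as.numeric(hard_contrast_range),
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# rasterize a union of ellipses, uniformly scaled by sqrt(s) around the first
# centre; later centres sit inside the first ellipse at every scale, so the
# union is always a single connected component
ellipse_union <- function(S, ells, s) {
  xs <- matrix(rep(seq_len(S), S), S, S)         # row index
  ys <- matrix(rep(seq_len(S), each = S), S, S)  # col index
  m <- matrix(FALSE, S, S)
  sc <- sqrt(s)
  c1 <- ells[[1]]$center
  for (e in ells) {
    cx <- c1[1] + (e$center[1] - c1[1]) * sc
    cy <- c1[2] + (e$center[2] - c1[2]) * sc
    dx <- xs - cx; dy <- ys - cy
    u <- dx * cos(e$theta) + dy * sin(e$theta)
    v <- -dx * sin(e$theta) + dy * cos(e$theta)
    m <- m | ((u / (e$a * sc))^2 + (v / (e$b * sc))^2 <= 1)
  }
  m
}

# single wound mask with area fraction inside [lo, hi]; draws from the
# current RNG state
make_wound_mask <- function(S, range) {
  target <- runif(1, range[1] + 0.1 * diff(range), range[2] - 0.1 * diff(range))
  n_ell <- sample(1:3, 1)
  c1 <- c(S / 2 + runif(1, -S / 8, S / 8), S / 2 + runif(1, -S / 8, S / 8))
  r1 <- sqrt(target * S^2 / pi)
  ells <- list()
  for (k in seq_len(n_ell)) {
    if (k == 1) {
      ctr <- c1
      base <- r1
    } else {
      ang <- runif(1, 0, 2 * pi)
      off <- runif(1, 0.2, 0.6) * r1
      ctr <- c1 + off * c(cos(ang), sin(ang))
      base <- r1 * runif(1, 0.4, 0.8)
    }
    aspect <- runif(1, 0.55, 1)
    ells[[k]] <- list(center = ctr, a = base / sqrt(aspect),
                      b = base * sqrt(aspect), theta = runif(1, 0, pi))
  }
  lo <- 0; hi <- 16
  m <- NULL
  for (it in 1:40) {
    s <- (lo + hi) / 2
    m <- ellipse_union(S, ells, s)
    a <- mean(m)
    if (a >= range[1] && a <= range[2] &&
        abs(a - target) < 0.02) break
    if (a < target) lo <- s else hi <- s
  }
  storage.mode(m) <- "integer"
  m
}

hsv_rgb <- function(h, s, v) as.numeric(grDevices::col2rgb(grDevices::hsv(h, s, v))) / 255

smooth_noise <- function(S, sigma) {
  x <- EBImage::gblur(matrix(rnorm(S * S), S, S), sigma)
  x / stats::sd(x)
}

make_background <- function(family, S) {
  img <- array(0, c(S, S, 3))
  if (family == "skin") {
    base <- c(0.80, 0.62, 0.48) + runif(3, -0.08, 0.08)
    field <- smooth_noise(S, 4)
    for (c in 1:3) img[, , c] <- base[c] + 0.06 * field * c(1, 0.85, 0.7)[c]
  } else if (family == "fabric") {
    base <- hsv_rgb(runif(1, 0.25, 0.65), runif(1, 0.3, 0.7), runif(1, 0.4, 0.8))
    phi <- runif(1, 0, pi)
    freq <- runif(1, 3, 8)
    xs <- matrix(rep(seq_len(S), S), S, S)
    ys <- matrix(rep(seq_len(S), each = S), S, S)
    stripes <- sin(2 * pi * freq * (xs * cos(phi) + ys * sin(phi)) / S)
    field <- smooth_noise(S, 3)
    for (c in 1:3) img[, , c] <- base[c] + 0.05 * stripes + 0.03 * field
  } else { # flat
    base <- hsv_rgb(runif(1, 0.2, 0.8), runif(1, 0.1, 0.5), runif(1, 0.35, 0.9))
    field <- smooth_noise(S, 2)
    for (c in 1:3) img[, , c] <- base[c] + 0.012 * field
  }
  pmin(pmax(img, 0), 1)
}

# one synthetic sample; draws from the current RNG state
synth_one <- function(cfg, id) {
  S <- cfg$image_size
  family <- if (length(cfg$background_palette) == 1) cfg$background_palette else
    sample(cfg$background_palette, 1)
  bg <- make_background(family, S)
  mask <- make_wound_mask(S, cfg$wound_area_fraction_range)

  hard <- runif(1) < cfg$hard_fraction
  blend <- if (hard) runif(1, cfg$hard_contrast_range[1], cfg$hard_contrast_range[2])
           else runif(1, 0, 0.15)

  wound_base <- c(0.50, 0.10, 0.10) + runif(3, -0.06, 0.06) * c(1, 0.5, 0.5)
  depth <- as.matrix(EBImage::distmap(mask))
  if (max(depth) > 0) depth <- depth / max(depth)
  speckle <- smooth_noise(S, 1.2) * 0.04
  # narrow soft edge: the photometric wound extent matches the binary truth
  alpha_edge <- pmin(pmax(as.matrix(EBImage::gblur(mask * 1.0, 0.4)), 0), 1)

  img <- bg
  for (c in 1:3) {
    wound_layer <- wound_base[c] * (1 - 0.25 * depth) + speckle
    w_eff <- (1 - blend) * wound_layer + blend * bg[, , c]
    img[, , c] <- alpha_edge * w_eff + (1 - alpha_edge) * bg[, , c]
  }

  img <- pmin(pmax(img, 0), 1)  # clamp before gamma: negatives have no root
  gain <- runif(1, cfg$lighting_gain_range[1], cfg$lighting_gain_range[2])
  gam <- runif(1, cfg$lighting_gamma_range[1], cfg$lighting_gamma_range[2])
  img <- pmin(pmax(gain * img^gam, 0), 1)
  pixels <- array(as.integer(round(img * 255)), dim(img))

  structure(list(
    sample_id = id,
    pixels = pixels,
    truth_mask = mask,
    camera_tag = sample(c("cam_A", "cam_B", "cam_C", "cam_D"), 1),
    hard = hard
  ), class = "wound_sample")
}

#' Generate a synthetic wound-image dataset with exact ground truth
#'
#' Each sample carries an 8-bit RGB raster, a single-connected-component
#' binary wound mask with area fraction inside the configured range, and a
#' camera tag emulating device heterogeneity. Generation is a pure function of
#' the configuration: rerunning with the same config (including seed) yields
#' identical output.
#'
#' @param config a [synthetic_config()].
#' @return A list of class `wound_dataset` with elements `samples` (list of
#'   `wound_sample`) and `manifest` (data frame with columns `sample_id`,
#'   `image_path`, `mask_path`, `camera_tag`, `split_status`).
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config"))
    abort_wa("config must be created with synthetic_config()")
  n <- config$n_images
  samples <- withr::with_seed(config$seed, {
    lapply(seq_len(n), function(i)
      synth_one(config, sprintf("synth_%04d", i)))
  })
  manifest <- data.frame(
    sample_id = vapply(samples, `[[`, "", "sample_id"),
    image_path = rep(NA_character_, n),
    mask_path = rep(NA_character_, n),
    camera_tag = vapply(samples, `[[`, "", "camera_tag"),
    split_status = rep("unlabeled", n),
    stringsAsFactors = FALSE
  )
  structure(list(samples = samples, manifest = manifest),
            class = "wound_dataset")
}

#' Specification of a systematic mask corruption
#'
#' Corruptions target the three clinical acceptance criteria:
#' `under_coverage` (mask misses wound area), `holes` and `spurious` (mask
#' has holes or disjoint extra parts), and `boundary_jitter` (mask boundary
#' departs from the true wound contour while preserving area).
#'
#' @param mode one of `"under_coverage"`, `"holes"`, `"spurious"`,
#'   `"boundary_jitter"`.
#' @param severity effect size in `[0, 1]`; 0 leaves the mask unchanged in
#'   every mode, and the effect scales monotonically with severity.
#' @param seed RNG seed for the stochastic modes.
#' @return A list of class `corruption_spec`.
#' @export
corruption_spec <- function(mode, severity, seed = 1L) {
  modes <- c("under_coverage", "holes", "spurious", "boundary_jitter")
  if (!is.character(mode) || length(mode) != 1 || !mode %in% modes)
    abort_wa("unknown corruption mode: ", mode)
  if (!is.numeric(severity) || severity < 0 || severity > 1)
    abort_wa("severity must be in [0, 1]")
  structure(list(mode = mode, severity = severity, seed = as.integer(seed)),
            class = "corruption_spec")
}

disc_brush <- function(r) EBImage::makeBrush(2 * r + 1, shape = "disc")

largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) <= 1) return(mask)
  counts <- tabulate(lab[lab > 0])
  matrix(as.integer(lab == which.max(counts)), nrow(mask), ncol(mask))
}

corrupt_under_coverage <- function(mask, sev) {
  r_eq <- sqrt(sum(mask) / pi)
  d <- max(1L, round(sev * 0.5 * r_eq))
  out <- EBImage::erode(mask, disc_brush(d))
  matrix(as.integer(out > 0), nrow(mask), ncol(mask))
}

corrupt_holes <- function(mask, sev) {
  D <- as.matrix(EBImage::distmap(mask))
  mx <- max(D)
  d_h <- min(max(2, ceiling(mx * (1 - 0.9 * sev))), mx)
  hole <- D >= d_h
  matrix(as.integer(mask == 1 & !hole), nrow(mask), ncol(mask))
}

corrupt_spurious <- function(mask, sev) {
  S1 <- nrow(mask); S2 <- ncol(mask)
  k <- ceiling(sev * 4)
  rb <- max(2L, round(2 + sev * 3))
  Dbg <- as.matrix(EBImage::distmap(1L - mask))  # distance of background to mask
  xs <- matrix(rep(seq_len(S1), S2), S1, S2)
  ys <- matrix(rep(seq_len(S2), each = S1), S1, S2)
  out <- mask
  placed <- 0
  margin <- rb + 3
  while (placed < k && margin >= 1) {
    ok <- Dbg > margin & xs > rb & xs <= S1 - rb & ys > rb & ys <= S2 - rb
    idx <- which(ok)
    if (length(idx) == 0) { margin <- margin - 1; next }
    pick <- idx[sample.int(length(idx), 1)]
    px <- xs[pick]; py <- ys[pick]
    blob <- (xs - px)^2 + (ys - py)^2 <= rb^2
    out[blob] <- 1L
    # keep future blobs disjoint from this one and from the mask
    Dbg[(xs - px)^2 + (ys - py)^2 <= (2 * rb + 2)^2] <- 0
    placed <- placed + 1
  }
  if (placed == 0) abort_wa("no background space to place a spurious component")
  out
}

corrupt_boundary_jitter <- function(mask, sev) {
  S1 <- nrow(mask); S2 <- ncol(mask)
  area0 <- sum(mask)
  # displacement amplitude scales with the image diagonal so the violation
  # tracks the diagonal-relative boundary tolerance of the oracle
  amp <- 3 * sqrt(S1^2 + S2^2) / sqrt(2 * 64^2)
  base <- as.matrix(EBImage::gblur(mask * 1.0, 2))
  one_attempt <- function() {
    noise <- EBImage::gblur(matrix(rnorm(S1 * S2), S1, S2), 3)
    noise <- as.matrix(noise) / stats::sd(noise)
    f <- base + sev * amp * noise
    clean <- function(t) {
      m <- matrix(as.integer(f >= t), S1, S2)
      if (sum(m) == 0) return(m)
      as.matrix(EBImage::fillHull(largest_component(m))) * 1L
    }
    lo <- min(f); hi <- max(f)
    best <- NULL; best_err <- Inf
    for (it in 1:30) {
      t <- (lo + hi) / 2
      m <- clean(t)
      err <- abs(sum(m) - area0) / area0
      if (err < best_err) { best <- m; best_err <- err }
      if (err < 0.02) break
      if (sum(m) > area0) lo <- t else hi <- t
    }
    list(mask = best, err = best_err)
  }
  # the largest-component/fill-hull cleanup can make the area response
  # non-monotone; retry with fresh noise until the area is preserved
  best <- NULL; best_err <- Inf
  for (attempt in 1:5) {
    a <- one_attempt()
    if (a$err < best_err) { best <- a$mask; best_err <- a$err }
    if (best_err <= 0.08) break
  }
  storage.mode(best) <- "integer"
  best
}

#' Apply a systematic corruption to a binary mask
#'
#' `under_coverage` strictly shrinks the foreground (morphological erosion);
#' `holes` removes interior pixels while preserving the outer contour;
#' `spurious` adds at least one connected component disjoint from the
#' original; `boundary_jitter` displaces the boundary while preserving the
#' foreground area to within 10 percent. Severity 0 returns the input
#' unchanged. Pure function of `(mask, spec)`.
#'
#' @param mask non-empty binary mask (0/1 matrix).
#' @param spec a [corruption_spec()].
#' @return A corrupted binary mask with the same dimensions.
#' @export
corrupt_mask <- function(mask, spec) {
  assert_mask(mask)
  if (!inherits(spec, "corruption_spec"))
    abort_wa("spec must be created with corruption_spec()")
  if (sum(mask) == 0) abort_wa("cannot corrupt an empty mask")
  storage.mode(mask) <- "integer"
  if (spec$severity == 0) return(mask)
  withr::with_seed(spec$seed, {
    switch(spec$mode,
      under_coverage = corrupt_under_coverage(mask, spec$severity),
      holes = corrupt_holes(mask, spec$severity),
      spurious = corrupt_spurious(mask, spec$severity),
      boundary_jitter = corrupt_boundary_jitter(mask, spec$severity)
    )
  })
}
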