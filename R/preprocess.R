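#' Preprocessing configuration
#'
#' Controls deterministic image standardization: resize to a square
#' `target_size` (stretching by default; optional zero-padding preserves
#' aspect ratio) and per-channel standardization after scaling to
#' \[0, 1\]. The default mean/std are the fixed per-channel constants
#' derived from the ImageNet-1K corpus.
#'
#' @param target_size Output side length in pixels (> 0). Default 224;
#'   the desk-scale tiny CNN uses 32.
#' @param mean,std Per-channel (R, G, B) normalization constants; all `std`
#'   components must be positive.
#' @param preserve_aspect If `TRUE`, resize with zero-padding instead of
#'   stretching.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(target_size = 224L,
                              mean = c(0.485, 0.456, 0.406),
                              std = c(0.229, 0.224, 0.225),
                              preserve_aspect = FALSE) {
  target_size <- as.integer(target_size)
  if (target_size <= 0) stopf("fb_bad_params", "target_size must be > 0")
  if (any(std <= 0)) stopf("fb_bad_params", "std components must be > 0")
  structure(list(target_size = target_size, mean = mean, std = std,
                 preserve_aspect = preserve_aspect),
            class = "preprocess_config")
}

#' Training-time augmentation configuration
#'
#' Stochastic augmentations applied during training only, each with an
#' independent application probability, in the fixed order
#' rotate, horizontal flip, vertical flip, brightness/contrast, cutout.
#' Defaults: rotation with probability 0.8 and angle uniform in
#' \[-90, 90\] degrees; horizontal and vertical flips each with
#' probability 0.5; random brightness/contrast with probability 0.5
#' (brightness limit 0.1, contrast limit 0.15); cutout with probability
#' 0.5 (20 holes, maximum hole height and width 11 px).
#'
#' @param rotate_prob,angle_range Rotation probability and symmetric angle
#'   range in degrees.
#' @param hflip_prob,vflip_prob Flip probabilities.
#' @param bc_prob,brightness_limit,contrast_limit Brightness/contrast jitter:
#'   output is `x * (1 + c) + b * 255` with `b ~ U(-brightness_limit,
#'   brightness_limit)`, `c ~ U(-contrast_limit, contrast_limit)`, clipped.
#' @param cutout_prob,cutout_holes,cutout_max_h,cutout_max_w Cutout
#'   regularization: `cutout_holes` rectangles with side lengths uniform in
#'   `1:cutout_max_*`, positions uniform, filled with 0.
#' @return An `augmentation_config` list.
#' @export
augmentation_config <- function(rotate_prob = 0.8, angle_range = c(-90, 90),
                                hflip_prob = 0.5, vflip_prob = 0.5,
                                bc_prob = 0.5, brightness_limit = 0.1,
                                contrast_limit = 0.15,
                                cutout_prob = 0.5, cutout_holes = 20L,
                                cutout_max_h = 11L, cutout_max_w = 11L) {
  probs <- c(rotate_prob, hflip_prob, vflip_prob, bc_prob, cutout_prob)
  if (any(probs < 0 | probs > 1)) {
    stopf("fb_bad_params", "probabilities must lie in [0, 1]")
  }
  if (abs(angle_range[1] + angle_range[2]) > 1e-9) {
    stopf("fb_bad_params", "angle_range must be symmetric about 0")
  }
  if (cutout_max_h < 1 || cutout_max_w < 1) {
    stopf("fb_bad_params", "cutout hole dimensions must be >= 1")
  }
  structure(list(rotate_prob = rotate_prob, angle_range = angle_range,
                 hflip_prob = hflip_prob, vflip_prob = vflip_prob,
                 bc_prob = bc_prob, brightness_limit = brightness_limit,
                 contrast_limit = contrast_limit,
                 cutout_prob = cutout_prob,
                 cutout_holes = as.integer(cutout_holes),
                 cutout_max_h = as.integer(cutout_max_h),
                 cutout_max_w = as.integer(cutout_max_w)),
            class = "augmentation_config")
}

# bilinear resize of an H x W x C array to out_h x out_w
resize_bilinear <- function(img, out_h, out_w) {
  d <- dim(img)
  h <- d[1]; w <- d[2]; nc <- d[3]
  if (h == out_h && w == out_w) return(img)
  # pixel-center alignment: output center i maps to (i - 0.5) * scale + 0.5
  ys <- (seq_len(out_h) - 0.5) * h / out_h + 0.5
  xs <- (seq_len(out_w) - 0.5) * w / out_w + 0.5
  y0 <- pmin(pmax(floor(ys), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(xs), 1), w); x1 <- pmin(x0 + 1, w)
  wy <- pmin(pmax(ys - y0, 0), 1); wx <- pmin(pmax(xs - x0, 0), 1)
  out <- array(0, dim = c(out_h, out_w, nc))
  for (ch in seq_len(nc)) {
    p <- img[, , ch]
    a <- p[y0, x0, drop = FALSE]; b <- p[y0, x1, drop = FALSE]
    cc <- p[y1, x0, drop = FALSE]; dd <- p[y1, x1, drop = FALSE]
    top <- a * outer(rep(1, out_h), 1 - wx) + b * outer(rep(1, out_h), wx)
    bot <- cc * outer(rep(1, out_h), 1 - wx) + dd * outer(rep(1, out_h), wx)
    out[, , ch] <- top * outer(1 - wy, rep(1, out_w)) +
      bot * outer(wy, rep(1, out_w))
  }
  out
}

#' Resize and normalize an RGB image
#'
#' Deterministically resizes an RGB image (0-255 scale) to
#' `target_size x target_size` with bilinear interpolation (stretched by
#' default, zero-padded if `preserve_aspect`), scales channels to
#' \[0, 1\], and standardizes each channel by `(x - mean) / std`.
#'
#' @param image H x W x 3 numeric array on the 0-255 scale.
#' @param cfg A [preprocess_config()].
#' @return `target_size x target_size x 3` numeric tensor.
#' @export
resize_normalize <- function(image, cfg = preprocess_config()) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3 || d[3] != 3 || d[1] < 1 || d[2] < 1) {
    stopf("fb_not_rgb", "resize_normalize() expects an H x W x 3 RGB array")
  }
  ts <- cfg$target_size
  if (cfg$preserve_aspect && d[1] != d[2]) {
    side <- max(d[1], d[2])
    padded <- array(0, dim = c(side, side, 3))
    ro <- (side - d[1]) %/% 2; co <- (side - d[2]) %/% 2
    padded[ro + seq_len(d[1]), co + seq_len(d[2]), ] <- image
    image <- padded
  }
  image <- resize_bilinear(image, ts, ts)
  out <- image / 255
  for (ch in 1:3) {
    out[, , ch] <- (out[, , ch] - cfg$mean[ch]) / cfg$std[ch]
  }
  out
}

# rotate an H x W x C image by `angle` degrees about its center,
# bilinear interpolation, zero fill outside the frame
rotate_image <- function(img, angle) {
  d <- dim(img)
  out <- cpp_rotate_bilinear(as.vector(img), as.integer(d), angle)
  dim(out) <- d
  out
}

#' Apply stochastic training-time augmentation
#'
#' Applies each configured transform independently with its probability, in
#' the fixed order rotate, horizontal flip, vertical flip,
#' brightness/contrast, cutout. Consumes the ambient RNG stream, so results
#' are deterministic under [set.seed()]. The output has the same shape as
#' the input. Evaluation-time pipelines never call this function.
#'
#' @param image H x W x 3 numeric array on the 0-255 scale.
#' @param cfg An [augmentation_config()].
#' @return Augmented H x W x 3 array, clipped to \[0, 255\].
#' @export
augment <- function(image, cfg = augmentation_config()) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3 || d[3] != 3) {
    stopf("fb_not_rgb", "augment() expects an H x W x 3 RGB array")
  }
  h <- d[1]; w <- d[2]
  if (stats::runif(1) < cfg$rotate_prob) {
    angle <- stats::runif(1, cfg$angle_range[1], cfg$angle_range[2])
    image <- rotate_image(image, angle)
  }
  if (stats::runif(1) < cfg$hflip_prob) {
    image <- image[, w:1, , drop = FALSE]
  }
  if (stats::runif(1) < cfg$vflip_prob) {
    image <- image[h:1, , , drop = FALSE]
  }
  if (stats::runif(1) < cfg$bc_prob) {
    b <- stats::runif(1, -cfg$brightness_limit, cfg$brightness_limit)
    cc <- stats::runif(1, -cfg$contrast_limit, cfg$contrast_limit)
    image <- clip255(image * (1 + cc) + b * 255)
  }
  if (stats::runif(1) < cfg$cutout_prob) {
    for (hole in seq_len(cfg$cutout_holes)) {
      hh <- sample.int(min(cfg$cutout_max_h, h), 1)
      ww <- sample.int(min(cfg$cutout_max_w, w), 1)
      top <- sample.int(h - hh + 1L, 1)
      left <- sample.int(w - ww + 1L, 1)
      image[top:(top + hh - 1L), left:(left + ww - 1L), ] <- 0
    }
  }
  image
}
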