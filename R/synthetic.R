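#' Synthesis parameters for the synthetic fundus generator
#'
#' Controls the rendered geometry and the acquisition artifacts of the
#' synthetic corpus. Images are 8-bit RGB (values 0-255) showing a circular
#' bright "retina field" on a dark background with an elliptical optic disc
#' and inner cup, dark vessel walks, and class-conditional lesions:
#' glaucoma draws its cup-to-disc area ratio from a high range disjoint
#' from normal's; diabetic retinopathy scatters small bright exudate blobs
#' and dark hemorrhage dots; AMD places mid-intensity yellowish drusen
#' near the field center. A global multiplicative exposure factor and
#' additive Gaussian pixel noise emulate the under-/over-exposure and noise
#' artifacts of heterogeneous clinical corpora, and a fraction of images is
#' rendered at a different resolution to emulate multi-camera corpora.
#'
#' @param image_size Pixels per side (square), >= 32. Default 64
#'   (desk scale); up to 224.
#' @param field_radius_fraction Fraction of the half-width occupied by the
#'   circular retina field, in (0, 1].
#' @param exposure_range Range of the per-image multiplicative brightness
#'   factor. `c(1, 1)` disables the artifact.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise on
#'   the 0-255 scale; >= 0.
#' @param alt_resolution_prob Probability that an image is rendered at a
#'   different resolution (then resized by the preprocessing stage),
#'   emulating resolution heterogeneity.
#' @param alt_resolution_range Multiplicative range for the alternative
#'   resolution.
#' @param class_features Per-class feature ranges as produced by
#'   [default_class_features()]. Setting all four entries equal collapses
#'   the classes to indistinguishable (null-signal configuration).
#' @return A `synthesis_params` list.
#' @export
synthesis_params <- function(image_size = 64L,
                             field_radius_fraction = 0.9,
                             exposure_range = c(0.5, 1.5),
                             noise_sd = 8,
                             alt_resolution_prob = 0.1,
                             alt_resolution_range = c(0.75, 1.5),
                             class_features = default_class_features()) {
  image_size <- as.integer(image_size)
  if (image_size < 32L) stopf("fb_bad_params", "image_size must be >= 32")
  if (field_radius_fraction <= 0 || field_radius_fraction > 1) {
    stopf("fb_bad_params", "field_radius_fraction must be in (0, 1]")
  }
  if (noise_sd < 0) stopf("fb_bad_params", "noise_sd must be >= 0")
  stopifnot(length(exposure_range) == 2, exposure_range[1] <= exposure_range[2])
  missing_cls <- setdiff(FUNDUS_CLASSES, names(class_features))
  if (length(missing_cls) > 0) {
    stopf("fb_bad_params", "class_features lacks entries for: %s",
          paste(missing_cls, collapse = ", "))
  }
  structure(list(
    image_size = image_size,
    field_radius_fraction = field_radius_fraction,
    exposure_range = exposure_range,
    noise_sd = noise_sd,
    alt_resolution_prob = alt_resolution_prob,
    alt_resolution_range = alt_resolution_range,
    class_features = class_features
  ), class = "synthesis_params")
}

#' Default per-class feature ranges
#'
#' Cup-to-disc area ratio (`cdr_range`) is drawn from disjoint ranges for
#' normal (0.10-0.30) and glaucoma (0.55-0.85), the fundus hallmark of
#' glaucomatous cupping. `n_bright`/`n_dark` give the count ranges of
#' bright exudate blobs and dark hemorrhage dots (diabetic retinopathy,
#' minimum 3 of each); `n_drusen` the count range of central yellowish
#' deposits (AMD).
#'
#' @return Named list over [FUNDUS_CLASSES], each a list with elements
#'   `cdr_range`, `n_bright`, `n_dark`, `n_drusen`.
#' @export
default_class_features <- function() {
  base <- list(cdr_range = c(0.10, 0.30), n_bright = c(0L, 0L),
               n_dark = c(0L, 0L), n_drusen = c(0L, 0L))
  feats <- list(NORMAL = base, GLAUCOMA = base, AMD = base, DR = base)
  feats$GLAUCOMA$cdr_range <- c(0.55, 0.85)
  feats$DR$n_bright <- c(4L, 10L)
  feats$DR$n_dark <- c(4L, 10L)
  feats$AMD$n_drusen <- c(6L, 14L)
  feats
}

# paint a filled disk of given color into img (H x W x 3), restricted to
# pixels where `within` is TRUE
paint_disk <- function(img, xg, yg, cx, cy, rad, color, within = NULL) {
  m <- (xg - cx)^2 + (yg - cy)^2 <= rad^2
  if (!is.null(within)) m <- m & within
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[m] <- color[ch]
    img[, , ch] <- plane
  }
  img
}

paint_ellipse <- function(img, xg, yg, cx, cy, a, b, color) {
  m <- ((xg - cx) / a)^2 + ((yg - cy) / b)^2 <= 1
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[m] <- color[ch]
    img[, , ch] <- plane
  }
  img
}

#' Generate one synthetic fundus image
#'
#' Renders a labeled fundus-like RGB image from the ambient RNG stream
#' (seed it with [set.seed()] or use [generate_corpus()] for a seeded
#' corpus). Shared anatomy (field, disc position, vessels) is drawn before
#' class-specific features, so images of different classes generated from
#' the same seed share their anatomical template and differ only in the
#' class-conditional structure.
#'
#' @param label One of [FUNDUS_CLASSES].
#' @param params A [synthesis_params()] object.
#' @param id Identifier stored in the record.
#' @return An `image_record` list: `id`, `label`, `source` ("synthetic"),
#'   `width`, `height`, `pixels` (H x W x 3 array, 0-255), and a `truth`
#'   list with the rendered ground-truth geometry (disc/cup axes, cup-to-
#'   disc area ratio, lesion centers, exposure factor) for oracle checks.
#' @export
generate_image <- function(label, params = synthesis_params(), id = NA_character_) {
  assert_label(label)
  feats <- params$class_features[[label]]

  s <- params$image_size
  if (stats::runif(1) < params$alt_resolution_prob) {
    s <- as.integer(round(s * stats::runif(1, params$alt_resolution_range[1],
                                           params$alt_resolution_range[2])))
  }
  scale <- s / 64

  c0 <- (s + 1) / 2
  r <- params$field_radius_fraction * s / 2
  xg <- matrix(rep(seq_len(s), each = s), nrow = s)   # column index
  yg <- matrix(rep(seq_len(s), times = s), nrow = s)  # row index
  d2 <- (xg - c0)^2 + (yg - c0)^2
  field <- d2 <= r^2

  img <- array(12, dim = c(s, s, 3))
  shade <- 1 - 0.25 * d2 / r^2
  base_col <- c(192, 98, 46)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[field] <- base_col[ch] * shade[field]
    img[, , ch] <- plane
  }

  # optic disc geometry (shared anatomy, drawn before class features)
  side <- sample(c(-1, 1), 1)
  dcx <- c0 + side * 0.45 * r
  dcy <- c0 + stats::runif(1, -0.12, 0.12) * r
  a <- 0.30 * r * (1 + stats::runif(1, -0.1, 0.1))
  b <- 0.26 * r * (1 + stats::runif(1, -0.1, 0.1))

  # vessel random walks emanating from the disc
  vessel_col <- c(125, 32, 22)
  for (v in 1:4) {
    ang <- stats::runif(1, 0, 2 * pi)
    px <- dcx; py <- dcy
    for (step in seq_len(round(1.8 * r))) {
      ang <- ang + stats::rnorm(1, 0, 0.25)
      px <- px + cos(ang); py <- py + sin(ang)
      xi <- round(px); yi <- round(py)
      if (xi < 1 || xi > s || yi < 1 || yi > s) break
      if ((xi - c0)^2 + (yi - c0)^2 > r^2) break
      img[yi, xi, ] <- vessel_col
      if (yi < s) img[yi + 1, xi, ] <- vessel_col
    }
  }

  img <- paint_ellipse(img, xg, yg, dcx, dcy, a, b, c(232, 198, 130))
  cdr <- stats::runif(1, feats$cdr_range[1], feats$cdr_range[2])
  cup_a <- sqrt(cdr) * a
  cup_b <- sqrt(cdr) * b
  img <- paint_ellipse(img, xg, yg, dcx, dcy, cup_a, cup_b, c(250, 232, 178))

  rand_in_field <- function(max_frac) {
    repeat {
      px <- stats::runif(1, c0 - r, c0 + r)
      py <- stats::runif(1, c0 - r, c0 + r)
      if ((px - c0)^2 + (py - c0)^2 <= (max_frac * r)^2) return(c(px, py))
    }
  }

  n_bright <- if (feats$n_bright[2] > 0)
    sample(feats$n_bright[1]:feats$n_bright[2], 1) else 0L
  bright_centers <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n_bright)) {
    p <- rand_in_field(0.85)
    rad <- stats::runif(1, 2.2, 4.0) * scale
    img <- paint_disk(img, xg, yg, p[1], p[2], rad, c(255, 252, 205), field)
    bright_centers <- rbind(bright_centers, p)
  }

  n_dark <- if (feats$n_dark[2] > 0)
    sample(feats$n_dark[1]:feats$n_dark[2], 1) else 0L
  dark_centers <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n_dark)) {
    p <- rand_in_field(0.85)
    rad <- stats::runif(1, 1.6, 3.0) * scale
    img <- paint_disk(img, xg, yg, p[1], p[2], rad, c(45, 12, 8), field)
    dark_centers <- rbind(dark_centers, p)
  }

  n_drusen <- if (feats$n_drusen[2] > 0)
    sample(feats$n_drusen[1]:feats$n_drusen[2], 1) else 0L
  drusen_centers <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n_drusen)) {
    p <- rand_in_field(0.30)  # macular region: confined near field center
    rad <- stats::runif(1, 1.6, 3.2) * scale
    img <- paint_disk(img, xg, yg, p[1], p[2], rad, c(240, 222, 120), field)
    drusen_centers <- rbind(drusen_centers, p)
  }

  exposure <- stats::runif(1, params$exposure_range[1], params$exposure_range[2])
  img <- img * exposure
  if (params$noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, params$noise_sd)
  }
  img <- round(clip255(img))

  structure(list(
    id = id, label = label, source = "synthetic",
    width = s, height = s, pixels = img,
    truth = list(size = s, field_center = c(c0, c0), field_radius = r,
                 disc_center = c(dcx, dcy), disc_axes = c(a, b),
                 cdr = cdr, cup_axes = c(cup_a, cup_b),
                 n_bright = n_bright, bright_centers = bright_centers,
                 n_dark = n_dark, dark_centers = dark_centers,
                 n_drusen = n_drusen, drusen_centers = drusen_centers,
                 exposure = exposure)
  ), class = "image_record")
}

#' Generate a labeled synthetic corpus
#'
#' Generates exactly the requested number of images per class (canonical
#' class order, seeded), writes them as PNG files under
#' `file.path(out_dir, "images")` together with `manifest.csv`, and
#' returns the manifest. The same `(counts, params, seed)` triple always
#' yields a byte-identical corpus.
#'
#' @param counts Named vector of per-class image counts over (a subset of)
#'   [FUNDUS_CLASSES]; total must be >= 1.
#' @param params A [synthesis_params()] object.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer RNG seed.
#' @return A [corpus_manifest()] whose paths point at the written PNGs.
#' @examples
#' \donttest{
#' m <- generate_corpus(c(NORMAL = 4, GLAUCOMA = 2, AMD = 1, DR = 3),
#'                      out_dir = tempfile(), seed = 7)
#' class_counts(m)
#' }
#' @export
generate_corpus <- function(counts, params = synthesis_params(),
                            out_dir, seed = 1L) {
  counts <- normalize_counts(counts)
  if (sum(counts) < 1) {
    stopf("fb_empty_corpus", "all class counts are zero")
  }
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)

  rows <- vector("list", sum(counts))
  i <- 0L
  withr::with_seed(as.integer(seed), {
    for (cls in FUNDUS_CLASSES) {
      for (j in seq_len(counts[[cls]])) {
        i <- i + 1L
        id <- sprintf("syn%05d", i)
        rec <- generate_image(cls, params, id = id)
        png::writePNG(rec$pixels / 255, file.path(img_dir, paste0(id, ".png")))
        rows[[i]] <- tibble::tibble(
          id = id, path = file.path(img_dir, paste0(id, ".png")),
          label = cls, source = "synthetic",
          width = rec$width, height = rec$height)
      }
    }
  })
  manifest <- corpus_manifest(do.call(rbind, rows))
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

# validate + order a counts vector over the canonical classes
normalize_counts <- function(counts) {
  bad <- setdiff(names(counts), FUNDUS_CLASSES)
  if (length(bad) > 0 || is.null(names(counts))) {
    stopf("fb_bad_params", "counts must be named by classes %s",
          paste(FUNDUS_CLASSES, collapse = ", "))
  }
  if (any(counts < 0)) stopf("fb_bad_params", "counts must be nonnegative")
  full <- stats::setNames(integer(4), FUNDUS_CLASSES)
  full[names(counts)] <- as.integer(counts)
  full
}

#' Class counts proportional to the merged-corpus census
#'
#' Scales the merged public-corpus census (86,415 normal / 3,787 glaucoma /
#' 632 AMD / 34,379 diabetic retinopathy) by `scale` and rounds, preserving
#' the imbalance ratios at a tractable size. `scale = 1/100` gives
#' 864/38/6/344.
#'
#' @param scale Multiplicative scale factor.
#' @return Named integer vector over [FUNDUS_CLASSES].
#' @export
census_ratio_counts <- function(scale = 1 / 100) {
  census <- c(NORMAL = 86415, GLAUCOMA = 3787, AMD = 632, DR = 34379)
  stats::setNames(as.integer(round(census * scale)), names(census))
}

#' Read an image referenced by a manifest row as a 0-255 RGB array
#'
#' @param path PNG file path.
#' @return H x W x 3 numeric array on the 0-255 scale.
#' @export
read_image <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), dim = c(dim(px), 3))
  if (dim(px)[3] > 3) px <- px[, , 1:3, drop = FALSE]
  px * 255
}
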