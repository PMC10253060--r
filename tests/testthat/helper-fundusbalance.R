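# shared fixtures and brute-force oracles, built in code at test time

# counts-level manifest: labels only, no image files behind the paths
counts_manifest <- function(counts, source = "test") {
  labels <- rep(names(counts), times = counts)
  n <- length(labels)
  corpus_manifest(tibble::tibble(
    id = sprintf("%s-%06d", source, seq_len(n)),
    path = sprintf("%s/%06d.png", source, seq_len(n)),
    label = labels, source = source, width = 64L, height = 64L))
}

# fast low-artifact synthesis settings for unit tests that need pixels
quiet_params <- function(image_size = 64L) {
  synthesis_params(image_size = image_size, noise_sd = 0,
                   exposure_range = c(1, 1), alt_resolution_prob = 0)
}

# brute-force connected components (4-connectivity) of a logical mask
flood_fill_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  n_comp <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j] || seen[i, j]) next
    n_comp <- n_comp + 1L
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue) > 0) {
      p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        y <- p[1] + d[1]; x <- p[2] + d[2]
        if (y >= 1 && y <= h && x >= 1 && x <= w &&
            mask[y, x] && !seen[y, x]) {
          seen[y, x] <- TRUE
          queue[[length(queue) + 1L]] <- c(y, x)
        }
      }
    }
  }
  n_comp
}

# exhaustive pair-counting AUC oracle (ties half-weighted), percent scale
auc_pair_oracle <- function(scores, truths) {
  pos <- scores[as.logical(truths)]
  neg <- scores[!as.logical(truths)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  100 * total / (length(pos) * length(neg))
}

# one-vs-rest metric oracle computed directly from label vectors
ovr_oracle <- function(pred, truth, cls) {
  tp <- sum(truth == cls & pred == cls)
  fn <- sum(truth == cls & pred != cls)
  fp <- sum(truth != cls & pred == cls)
  tn <- sum(truth != cls & pred != cls)
  list(
    accuracy = 100 * (tp + tn) / length(truth),
    f1 = if (2 * tp + fp + fn == 0) 0 else 100 * 2 * tp / (2 * tp + fp + fn),
    sensitivity = if (tp + fn == 0) 0 else 100 * tp / (tp + fn),
    specificity = if (tn + fp == 0) 100 else 100 * tn / (tn + fp))
}

# nearest class-mean classifier on exposure-normalized 16x16 thumbnails;
# the "trivial pixel-statistics classifier" used for learnability checks
thumbnail_features <- function(manifest) {
  t(vapply(manifest$path, function(p) {
    v <- as.vector(resize_bilinear_for_test(read_image(p), 16, 16))
    v / mean(v)
  }, numeric(16 * 16 * 3)))
}

resize_bilinear_for_test <- function(img, h, w) {
  fundusbalance:::resize_bilinear(img, h, w)
}

nearest_mean_accuracy <- function(train_manifest, test_manifest) {
  ftr <- thumbnail_features(train_manifest)
  fte <- thumbnail_features(test_manifest)
  classes <- sort(unique(train_manifest$label))
  centers <- t(vapply(classes, function(cls) {
    colMeans(ftr[train_manifest$label == cls, , drop = FALSE])
  }, numeric(ncol(ftr))))
  d2 <- outer(rowSums(fte^2), rep(1, nrow(centers))) -
    2 * fte %*% t(centers) +
    outer(rep(1, nrow(fte)), rowSums(centers^2))
  pred <- classes[apply(d2, 1, which.min)]
  mean(pred == test_manifest$label)
}
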