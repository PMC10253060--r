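#' Random minority oversampling (ROS)
#'
#' Upsamples every class of a training manifest to the maximum class count
#' by drawing records with replacement. All original records are retained;
#' added records are copies of originals (same file path) with ids
#' disambiguated by a `#dup<n>` suffix, so the training loop sees the same
#' image multiple times without any pixel duplication on disk.
#'
#' @param train A [corpus_manifest()] with >= 1 record in every class
#'   present.
#' @param seed Integer seed.
#' @return Oversampled `corpus_manifest` in which every class present has
#'   the maximum class count.
#' @export
ros <- function(train, seed = 1L) {
  counts <- class_counts(train)
  present <- names(counts)[counts > 0]
  if (length(present) == 0) stopf("fb_empty_corpus", "empty training manifest")
  target <- max(counts[present])
  extras <- list()
  withr::with_seed(as.integer(seed), {
    for (cls in present) {
      deficit <- target - counts[[cls]]
      if (deficit > 0) {
        idx <- which(train$label == cls)
        picked <- sample_from(idx, deficit, replace = TRUE)
        dup <- tibble::as_tibble(train[picked, ])
        dup$id <- paste0(dup$id, "#dup", seq_len(deficit))
        extras[[cls]] <- dup
      }
    }
  })
  corpus_manifest(rbind(tibble::as_tibble(train), do.call(rbind, extras)))
}

#' Random majority undersampling (RUS)
#'
#' Downsamples every class of a training manifest without replacement to
#' the minimum class count. The output is an injective sample of the
#' input.
#'
#' @inheritParams ros
#' @return Undersampled `corpus_manifest` in which every class present has
#'   the minimum class count.
#' @export
rus <- function(train, seed = 1L) {
  counts <- class_counts(train)
  present <- names(counts)[counts > 0]
  if (length(present) == 0) stopf("fb_empty_corpus", "empty training manifest")
  target <- min(counts[present])
  keep <- integer(0)
  withr::with_seed(as.integer(seed), {
    for (cls in present) {
      idx <- which(train$label == cls)
      keep <- c(keep, if (length(idx) > target) sample_from(idx, target) else idx)
    }
  })
  corpus_manifest(train[sort(keep), ])
}

#' Threshold an evaluation fold to the fine-tuning class ratios
#'
#' Caps the NORMAL and DR counts of a validation/test fold at the fold's
#' threshold-class (glaucoma) count by uniform seeded downsampling, leaving
#' glaucoma and AMD untouched. This aligns the class ratios of evaluation
#' folds with the fine-tuning subset so the resampling arms are compared on
#' identical evaluation data.
#'
#' @param fold A [corpus_manifest()] containing the threshold class.
#' @param threshold_class Class defining the cap; default `"GLAUCOMA"`.
#' @param seed Integer seed.
#' @return Thresholded `corpus_manifest`.
#' @export
threshold_eval_fold <- function(fold, threshold_class = "GLAUCOMA",
                                seed = 1L) {
  assert_label(threshold_class)
  counts <- class_counts(fold)
  t <- counts[[threshold_class]]
  if (t == 0) {
    stopf("fb_threshold_absent",
          "threshold class %s absent from fold", threshold_class)
  }
  keep <- rep(TRUE, nrow(fold))
  withr::with_seed(as.integer(seed), {
    for (cls in c("NORMAL", "DR")) {
      idx <- which(fold$label == cls)
      if (length(idx) > t) {
        keep[setdiff(idx, sample_from(idx, t))] <- FALSE
      }
    }
  })
  corpus_manifest(fold[keep, ])
}
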