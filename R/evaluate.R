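#' Stratified k-fold plan with rotating validation/test folds
#'
#' Partitions a manifest into `k` near-equal folds, stratified by class:
#' within each class, shuffled records are distributed so every fold
#' receives either `floor(n_c / k)` or `ceiling(n_c / k)` records of class
#' `c`. Iteration `i` uses fold `i` as the test set, fold `i %% k + 1` as
#' the validation set and the remaining folds for training, so every fold
#' serves as the test set exactly once.
#'
#' @param manifest A [corpus_manifest()].
#' @param k Number of folds, >= 3.
#' @param seed Integer seed.
#' @return A `fold_plan` list: `k`, `assignment` (tibble `id`, `fold`),
#'   `iterations` (tibble `iteration`, `test`, `validation`).
#' @export
make_folds <- function(manifest, k = 10L, seed = 1L) {
  k <- as.integer(k)
  if (k < 3) stopf("fb_bad_params", "k must be >= 3")
  counts <- class_counts(manifest)
  short <- names(counts)[counts > 0 & counts < k]
  if (length(short) > 0) {
    stopf("fb_class_too_small",
          "class %s has fewer than k = %d records; cannot stratify",
          paste(short, collapse = ", "), k)
  }
  fold <- integer(nrow(manifest))
  withr::with_seed(as.integer(seed), {
    for (cls in names(counts)[counts > 0]) {
      idx <- sample_from(which(manifest$label == cls), counts[[cls]])
      n <- length(idx)
      base <- n %/% k
      extra_folds <- sample.int(k, n %% k)
      sizes <- rep(base, k)
      sizes[extra_folds] <- sizes[extra_folds] + 1L
      fold[idx] <- rep(seq_len(k), times = sizes)
    }
  })
  structure(list(
    k = k,
    assignment = tibble::tibble(id = manifest$id, fold = fold),
    iterations = tibble::tibble(iteration = seq_len(k),
                                test = seq_len(k),
                                validation = seq_len(k) %% k + 1L)
  ), class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> k = %d over %d records\n", x$k,
              nrow(x$assignment)))
  invisible(x)
}

#' Confusion matrix in canonical class order
#'
#' @param predictions,truths Equal-length vectors of class labels from
#'   [FUNDUS_CLASSES] (or factors over a common class set).
#' @param classes Class vocabulary defining row/column order.
#' @return K x K integer matrix, rows = true class, columns = predicted.
#' @export
confusion <- function(predictions, truths, classes = FUNDUS_CLASSES) {
  if (length(predictions) != length(truths) || length(truths) < 1) {
    stopf("fb_length_mismatch",
          "predictions and truths must have equal length >= 1")
  }
  tab <- table(true = as_class_factor(truths, classes),
               predicted = as_class_factor(predictions, classes))
  cm <- matrix(as.integer(tab), nrow = length(classes),
               dimnames = list(true = classes, predicted = classes))
  cm
}

#' One-vs-rest metrics for one class of a confusion matrix
#'
#' Treating class `c` as positive and all others as negative:
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), accuracy =
#' (TP+TN)/total, F1 = 2TP/(2TP+FP+FN), all on the percent scale.
#' Degenerate 0/0 ratios are returned as 0 (sensitivity, F1) or 100
#' (specificity, when no negatives exist) together with a `degenerate`
#' flag rather than NaN.
#'
#' @param cm Confusion matrix from [confusion()].
#' @param class Class name (must be a row of `cm`).
#' @return List with `accuracy`, `f1`, `sensitivity`, `specificity`
#'   (percent) and `degenerate` (logical).
#' @export
ovr_metrics <- function(cm, class) {
  if (!class %in% rownames(cm)) {
    stopf("fb_unknown_label", "class '%s' not in confusion matrix", class)
  }
  total <- sum(cm)
  if (total < 1) stopf("fb_bad_params", "empty confusion matrix")
  tp <- cm[class, class]
  fn <- sum(cm[class, ]) - tp
  fp <- sum(cm[, class]) - tp
  tn <- total - tp - fn - fp
  degenerate <- FALSE
  ratio <- function(num, den, convention) {
    if (den == 0) { degenerate <<- TRUE; return(convention) }
    100 * num / den
  }
  list(accuracy = 100 * (tp + tn) / total,
       f1 = ratio(2 * tp, 2 * tp + fp + fn, 0),
       sensitivity = ratio(tp, tp + fn, 0),
       specificity = ratio(tn, tn + fp, 100),
       degenerate = degenerate)
}

#' One-vs-rest AUC by rank statistic
#'
#' AUC as the fraction of (positive, negative) pairs in which the positive
#' sample outscores the negative one, ties counted half — the Mann-Whitney
#' statistic, equal to the trapezoidal area under the ROC curve. Percent
#' scale.
#'
#' @param scores Numeric per-sample scores for the positive class
#'   (typically softmax probabilities).
#' @param truths Logical (or 0/1) one-vs-rest labels, TRUE = positive.
#' @return AUC in \[0, 100\].
#' @export
auc_ovr <- function(scores, truths) {
  truths <- as.logical(truths)
  n_pos <- sum(truths); n_neg <- sum(!truths)
  if (n_pos == 0 || n_neg == 0) {
    stopf("fb_single_class", "AUC needs both positive and negative samples")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[truths]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  100 * auc
}

#' One-vs-rest ROC curve
#'
#' Curve of (FPR, TPR) points obtained by sweeping the decision threshold
#' over the sorted unique scores, from the all-negative corner (0, 0) to
#' the all-positive corner (1, 1).
#'
#' @inheritParams auc_ovr
#' @return Tibble with columns `fpr`, `tpr`, both nondecreasing.
#' @export
roc_curve <- function(scores, truths) {
  truths <- as.logical(truths)
  n_pos <- sum(truths); n_neg <- sum(!truths)
  if (n_pos == 0 || n_neg == 0) {
    stopf("fb_single_class", "ROC needs both positive and negative samples")
  }
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(truths[ord])
  fp <- cumsum(!truths[ord])
  # collapse tied scores to one operating point
  last_of_tie <- c(diff(scores[ord]) != 0, TRUE)
  tibble::tibble(fpr = c(0, fp[last_of_tie] / n_neg),
                 tpr = c(0, tp[last_of_tie] / n_pos))
}

#' Per-fold evaluation report
#'
#' Builds the confusion matrix from argmax predictions, one-vs-rest
#' metrics and AUC per class, macro averages (unweighted means over the
#' four classes), the overall accuracy, and per-class ROC curves.
#'
#' @param probs N x 4 matrix of class probabilities with columns in
#'   canonical class order (as from [predict_manifest()]).
#' @param truths Length-N vector of true labels.
#' @return A `fold_report` list: `confusion`, `per_class` (tibble `class`,
#'   `accuracy`, `f1`, `sensitivity`, `specificity`, `auc`), `macro`
#'   (named vector), `overall_accuracy`, `roc` (named list of ROC
#'   tibbles).
#' @export
fold_report <- function(probs, truths) {
  classes <- colnames(probs)
  if (is.null(classes)) classes <- FUNDUS_CLASSES
  pred <- classes[max.col(probs, ties.method = "first")]
  cm <- confusion(pred, truths, classes)
  rows <- list(); roc <- list()
  for (cls in classes) {
    m <- ovr_metrics(cm, cls)
    pos <- truths == cls
    auc <- if (any(pos) && any(!pos)) auc_ovr(probs[, cls], pos) else NA_real_
    rows[[cls]] <- tibble::tibble(class = cls, accuracy = m$accuracy,
                                  f1 = m$f1, sensitivity = m$sensitivity,
                                  specificity = m$specificity, auc = auc)
    roc[[cls]] <- if (any(pos) && any(!pos)) roc_curve(probs[, cls], pos)
  }
  per_class <- do.call(rbind, rows)
  macro <- c(accuracy = mean(per_class$accuracy), f1 = mean(per_class$f1),
             sensitivity = mean(per_class$sensitivity),
             specificity = mean(per_class$specificity),
             auc = mean(per_class$auc))
  structure(list(confusion = cm, per_class = per_class, macro = macro,
                 overall_accuracy = 100 * sum(diag(cm)) / sum(cm),
                 roc = roc),
            class = "fold_report")
}

#' Aggregate fold reports into a cross-validation summary
#'
#' Mean and standard deviation of every per-class metric, the macro
#' averages and the overall accuracy across folds. The standard deviation
#' uses the population convention (divide by k) by default, matching
#' descriptive mean-and-spread reporting over a fixed set of folds;
#' `sd_type = "sample"` switches to the n-1 convention.
#'
#' @param fold_reports List of >= 2 [fold_report()] objects over the same
#'   class set.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return A `cv_summary` list: `per_class` (tibble `class`, `metric`,
#'   `mean`, `sd`), `macro`, `overall_accuracy` (mean, sd), `k`.
#' @export
aggregate_folds <- function(fold_reports, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(fold_reports) < 2) {
    stopf("fb_bad_params", "need at least 2 fold reports")
  }
  class_sets <- lapply(fold_reports, function(r) r$per_class$class)
  if (length(unique(vapply(class_sets, paste, character(1),
                           collapse = ","))) != 1) {
    stopf("fb_bad_params", "fold reports have inconsistent class sets")
  }
  pop_sd <- function(x) {
    if (sd_type == "sample") return(stats::sd(x))
    sqrt(mean((x - mean(x))^2))
  }
  classes <- class_sets[[1]]
  metrics <- c("accuracy", "f1", "sensitivity", "specificity", "auc")
  rows <- list()
  for (cls in classes) {
    for (met in metrics) {
      v <- vapply(fold_reports,
                  function(r) r$per_class[[met]][r$per_class$class == cls],
                  numeric(1))
      rows[[paste(cls, met)]] <- tibble::tibble(
        class = cls, metric = met, mean = mean(v), sd = pop_sd(v))
    }
  }
  macro_rows <- list()
  for (met in metrics) {
    v <- vapply(fold_reports, function(r) r$macro[[met]], numeric(1))
    macro_rows[[met]] <- tibble::tibble(class = "Average", metric = met,
                                        mean = mean(v), sd = pop_sd(v))
  }
  ov <- vapply(fold_reports, function(r) r$overall_accuracy, numeric(1))
  structure(list(per_class = do.call(rbind, rows),
                 macro = do.call(rbind, macro_rows),
                 overall_accuracy = c(mean = mean(ov), sd = pop_sd(ov)),
                 k = length(fold_reports)),
            class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat(sprintf("<cv_summary> over %d folds; overall accuracy %.2f +/- %.2f\n",
              x$k, x$overall_accuracy["mean"], x$overall_accuracy["sd"]))
  invisible(x)
}

#' Mean ROC curve with pointwise standard-deviation band
#'
#' Interpolates each fold's ROC curve onto a fixed 101-point FPR grid
#' (0 to 1) and reports the pointwise mean and standard deviation of the
#' TPR, as used for ROC plots with a std band.
#'
#' @param curves List of >= 2 ROC tibbles (`fpr`, `tpr`), each with >= 2
#'   points.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return Tibble with `fpr`, `tpr_mean`, `tpr_sd` (101 rows).
#' @export
roc_band <- function(curves, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(curves) < 2) stopf("fb_bad_params", "need at least 2 curves")
  grid <- seq(0, 1, length.out = 101)
  mat <- vapply(curves, function(cv) {
    if (nrow(cv) < 2) stopf("fb_bad_params", "ROC curve with < 2 points")
    stats::approx(cv$fpr, cv$tpr, xout = grid, ties = max, rule = 2)$y
  }, numeric(101))
  pop_sd <- function(x) {
    if (sd_type == "sample") return(stats::sd(x))
    sqrt(mean((x - mean(x))^2))
  }
  tibble::tibble(fpr = grid,
                 tpr_mean = rowMeans(mat),
                 tpr_sd = apply(mat, 1, pop_sd))
}
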