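#' Cross-validated training and evaluation of one imbalance-handling arm
#'
#' Runs k-fold cross-validation of a single method on a pooled corpus.
#' Per iteration, the test and validation folds are first thresholded to
#' the fine-tuning class ratios ([threshold_eval_fold()]); the training
#' folds are then handled per arm:
#' \describe{
#'   \item{twostage}{[threshold_split()] of the training folds, binary
#'     pre-training on the excess subset, 4-class fine-tuning on the
#'     balanced remainder.}
#'   \item{ros}{[ros()] oversampling of the training folds, one 4-class
#'     training stage from a fresh model.}
#'   \item{rus}{[rus()] undersampling, likewise.}
#'   \item{none}{training folds used unchanged.}
#' }
#' All arms share identical (thresholded) evaluation folds and the same
#' 4-class hyperparameters.
#'
#' @param corpus A [corpus_manifest()].
#' @param method One of `"twostage"`, `"ros"`, `"rus"`, `"none"`.
#' @param k Number of folds (>= 3); ignored when `plan` is given.
#' @param plan Optional [make_folds()] plan shared across arms.
#' @param spec [backbone_spec()] for the 4-class model.
#' @param pretrain_cfg,finetune_cfg [train_config()]s for the two stages;
#'   stage-default class weights apply when `class_weights` is `NULL`.
#' @param aug_cfg Training-time [augmentation_config()].
#' @param threshold_class Class defining thresholds; default `"GLAUCOMA"`.
#' @param seed Integer seed controlling folds, splits and training.
#' @param verbose Print per-fold progress.
#' @return A `cv_result` list: `method`, `summary` ([aggregate_folds()]),
#'   `reports` (per-fold [fold_report()]s), `plan`, and `predictions`
#'   (pooled test-fold tibble: `id`, `truth`, `predicted`, per-class
#'   probability columns).
#' @export
run_cv <- function(corpus, method = c("twostage", "ros", "rus", "none"),
                   k = 10L, plan = NULL, spec = backbone_spec(),
                   pretrain_cfg = train_config(),
                   finetune_cfg = train_config(),
                   aug_cfg = augmentation_config(),
                   threshold_class = "GLAUCOMA", seed = 1L,
                   verbose = FALSE) {
  method <- match.arg(method)
  if (is.null(plan)) plan <- make_folds(corpus, k, seed = seed)
  fold_of <- plan$assignment$fold[match(corpus$id, plan$assignment$id)]
  if (anyNA(fold_of)) {
    stopf("fb_bad_params", "fold plan does not cover the corpus")
  }
  reports <- vector("list", plan$k)
  preds <- vector("list", plan$k)
  bin_spec <- spec
  bin_spec$n_outputs <- 2L

  for (i in seq_len(plan$k)) {
    it <- plan$iterations[i, ]
    test_m <- corpus_manifest(corpus[fold_of == it$test, ])
    val_m <- corpus_manifest(corpus[fold_of == it$validation, ])
    train_m <- corpus_manifest(corpus[!fold_of %in% c(it$test, it$validation), ])
    test_t <- threshold_eval_fold(test_m, threshold_class,
                                  seed = seed + 101L * i)
    val_t <- threshold_eval_fold(val_m, threshold_class,
                                 seed = seed + 211L * i)

    ft_cfg <- finetune_cfg
    ft_cfg$seed <- as.integer(seed + 17L * i)
    if (method == "twostage") {
      sp <- threshold_split(train_m, threshold_class,
                            seed = seed + 307L * i)
      if (nrow(sp$pretrain) > 0) {
        pt_cfg <- pretrain_cfg
        pt_cfg$seed <- as.integer(seed + 23L * i)
        base <- pretrain(sp$pretrain, bin_spec, pt_cfg,
                         aug_cfg = aug_cfg, verbose = verbose)$model
      } else {
        base <- build_model(bin_spec, seed = seed + 23L * i)
      }
      stage <- finetune(base, sp$finetune, val_t, ft_cfg,
                        aug_cfg = aug_cfg, verbose = verbose)
    } else {
      train_r <- switch(method,
        ros = ros(train_m, seed = seed + 401L * i),
        rus = rus(train_m, seed = seed + 401L * i),
        none = train_m)
      base <- build_model(spec, seed = seed + 23L * i)
      stage <- finetune(base, train_r, val_t, ft_cfg,
                        aug_cfg = aug_cfg, verbose = verbose)
    }
    probs <- predict_manifest(stage$model, test_t)
    reports[[i]] <- fold_report(probs, test_t$label)
    pr <- tibble::as_tibble(as.data.frame(probs))
    preds[[i]] <- tibble::tibble(
      id = test_t$id, iteration = i, truth = test_t$label,
      predicted = colnames(probs)[max.col(probs, ties.method = "first")])
    preds[[i]] <- cbind(preds[[i]], pr)
    if (verbose) {
      message(sprintf("[%s] fold %d/%d: overall accuracy %.2f",
                      method, i, plan$k, reports[[i]]$overall_accuracy))
    }
  }
  structure(list(method = method,
                 summary = aggregate_folds(reports),
                 reports = reports, plan = plan,
                 predictions = tibble::as_tibble(do.call(rbind, preds))),
            class = "cv_result")
}

#' Macro-F1 of a prediction vector
#'
#' Unweighted mean of the four per-class one-vs-rest F1 scores (percent).
#'
#' @param predictions,truths Label vectors.
#' @param classes Class vocabulary.
#' @return Macro-averaged F1 in \[0, 100\].
#' @export
macro_f1 <- function(predictions, truths, classes = FUNDUS_CLASSES) {
  cm <- confusion(predictions, truths, classes)
  mean(vapply(classes, function(cls) ovr_metrics(cm, cls)$f1, numeric(1)))
}

#' Permuted-label chance band for macro-F1
#'
#' Distribution of macro-F1 obtained by permuting the true labels against
#' the fixed predictions; a model carrying real class signal must exceed
#' the upper quantile of this band.
#'
#' @param predictions,truths Label vectors from pooled test folds.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with `mean`, `sd`, `q95`, `q99` and the permuted `values`.
#' @export
chance_band_macro_f1 <- function(predictions, truths, n_perm = 200L,
                                 seed = 1L) {
  vals <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(b) {
      macro_f1(predictions, sample(truths))
    }, numeric(1))
  })
  list(mean = mean(vals), sd = stats::sd(vals),
       q95 = unname(stats::quantile(vals, 0.95)),
       q99 = unname(stats::quantile(vals, 0.99)),
       values = vals)
}

#' Compare imbalance-handling arms under a shared fold plan
#'
#' Runs [run_cv()] for each requested method on one corpus using a single
#' fold plan (hence identical thresholded evaluation folds), and tabulates
#' the macro metrics and overall accuracy per arm, each with its
#' permuted-label chance band.
#'
#' @inheritParams run_cv
#' @param methods Character vector of arms to run.
#' @return A `method_comparison` list: `results` (named list of
#'   `cv_result`s), `table` (tibble: method, macro metric means/sds,
#'   overall accuracy, elapsed seconds), `chance` (named list of
#'   [chance_band_macro_f1()] outputs).
#' @export
compare_methods <- function(corpus, methods = c("twostage", "ros", "rus"),
                            k = 3L, spec = backbone_spec(),
                            pretrain_cfg = train_config(),
                            finetune_cfg = train_config(),
                            aug_cfg = augmentation_config(),
                            threshold_class = "GLAUCOMA", seed = 1L,
                            verbose = FALSE) {
  plan <- make_folds(corpus, k, seed = seed)
  results <- list(); chance <- list(); rows <- list()
  for (m in methods) {
    t0 <- proc.time()[["elapsed"]]
    res <- run_cv(corpus, m, plan = plan, spec = spec,
                  pretrain_cfg = pretrain_cfg, finetune_cfg = finetune_cfg,
                  aug_cfg = aug_cfg, threshold_class = threshold_class,
                  seed = seed, verbose = verbose)
    elapsed <- proc.time()[["elapsed"]] - t0
    results[[m]] <- res
    chance[[m]] <- chance_band_macro_f1(res$predictions$predicted,
                                        res$predictions$truth,
                                        seed = seed)
    mac <- res$summary$macro
    rows[[m]] <- tibble::tibble(
      method = m,
      macro_f1_mean = mac$mean[mac$metric == "f1"],
      macro_f1_sd = mac$sd[mac$metric == "f1"],
      macro_sensitivity_mean = mac$mean[mac$metric == "sensitivity"],
      macro_specificity_mean = mac$mean[mac$metric == "specificity"],
      macro_auc_mean = mac$mean[mac$metric == "auc"],
      overall_accuracy_mean = res$summary$overall_accuracy[["mean"]],
      overall_accuracy_sd = res$summary$overall_accuracy[["sd"]],
      chance_macro_f1_q99 = chance[[m]]$q99,
      runtime_s = elapsed)
  }
  structure(list(results = results, table = do.call(rbind, rows),
                 chance = chance, plan = plan),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison>\n")
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}
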