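test_that("fold plans partition the manifest with stratified balance", {
  m <- counts_manifest(c(NORMAL = 20))
  plan <- make_folds(m, k = 10, seed = 1)
  expect_equal(sort(table(plan$assignment$fold)), sort(rep(2L, 10)),
               ignore_attr = TRUE)
  expect_setequal(plan$assignment$id, m$id)
  # every fold is the test fold exactly once; validation rotates
  expect_equal(sort(plan$iterations$test), 1:10)
  expect_true(all(plan$iterations$test != plan$iterations$validation))

  ftm <- counts_manifest(c(NORMAL = 379, GLAUCOMA = 379, AMD = 63, DR = 379))
  plan2 <- make_folds(ftm, k = 10, seed = 2)
  amd_ids <- ftm$id[ftm$label == "AMD"]
  per_fold <- table(factor(
    plan2$assignment$fold[plan2$assignment$id %in% amd_ids], levels = 1:10))
  expect_true(all(per_fold %in% c(6L, 7L)))

  expect_identical(make_folds(ftm, k = 10, seed = 2)$assignment,
                   plan2$assignment)
  expect_error(make_folds(ftm, k = 2), class = "fb_bad_params")
  small <- counts_manifest(c(NORMAL = 20, AMD = 3))
  expect_error(make_folds(small, k = 5), class = "fb_class_too_small",
               regexp = "AMD")
})

test_that("confusion matrices tally truth against prediction", {
  labs <- c("NORMAL", "GLAUCOMA", "AMD", "DR")
  cm <- confusion(labs, labs)
  expect_equal(diag(cm), rep(1L, 4), ignore_attr = TRUE)
  expect_equal(sum(cm), 4L)

  cm1 <- confusion("DR", "NORMAL")
  expect_equal(cm1["NORMAL", "DR"], 1L)
  expect_equal(sum(cm1), 1L)

  set.seed(31)
  truth <- sample(FUNDUS_CLASSES, 1000, replace = TRUE)
  pred <- sample(FUNDUS_CLASSES, 1000, replace = TRUE)
  cm2 <- confusion(pred, truth)
  expect_equal(sum(cm2), 1000L)
  for (cls in FUNDUS_CLASSES) {
    expect_equal(sum(cm2[cls, ]), sum(truth == cls))
    expect_equal(sum(cm2[, cls]), sum(pred == cls))
  }
  expect_error(confusion(c("DR", "DR"), "DR"), class = "fb_length_mismatch")
})

test_that("one-vs-rest metrics match hand arithmetic and conventions", {
  perfect <- confusion(rep(FUNDUS_CLASSES, 5), rep(FUNDUS_CLASSES, 5))
  for (cls in FUNDUS_CLASSES) {
    m <- ovr_metrics(perfect, cls)
    expect_equal(c(m$accuracy, m$f1, m$sensitivity, m$specificity),
                 rep(100, 4))
    expect_false(m$degenerate)
  }

  # binary reduction [[50, 10], [5, 35]]
  pred <- c(rep("A", 50), rep("B", 10), rep("A", 5), rep("B", 35))
  truth <- c(rep("A", 60), rep("B", 40))
  cm <- confusion(pred, truth, classes = c("A", "B"))
  m <- ovr_metrics(cm, "A")
  expect_equal(m$sensitivity, 100 * 50 / 60, tolerance = 1e-10)
  expect_equal(m$specificity, 87.5)
  expect_equal(m$f1, 100 * 100 / 115, tolerance = 1e-10)
  expect_equal(m$accuracy, 85)
  # sensitivity of one binary class equals specificity of the other
  m_b <- ovr_metrics(cm, "B")
  expect_equal(m$sensitivity, m_b$specificity)
  expect_equal(m$specificity, m_b$sensitivity)

  # absent class: no true members, no predictions
  cm0 <- confusion(rep("NORMAL", 5), rep("NORMAL", 5))
  deg <- ovr_metrics(cm0, "AMD")
  expect_equal(deg$sensitivity, 0)
  expect_equal(deg$specificity, 100)
  expect_true(deg$degenerate)
})

test_that("rank-based AUC equals exhaustive pair counting", {
  expect_equal(auc_ovr(c(0.9, 0.8, 0.7, 0.1), c(TRUE, TRUE, FALSE, FALSE)),
               100)
  expect_equal(auc_ovr(rep(0.5, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)),
               50)
  expect_equal(auc_ovr(c(0.8, 0.4, 0.6, 0.2), c(TRUE, TRUE, FALSE, FALSE)),
               75)
  expect_error(auc_ovr(c(0.1, 0.2), c(TRUE, TRUE)),
               class = "fb_single_class")

  set.seed(37)
  for (rep in 1:50) {
    n <- sample(4:30, 1)
    scores <- round(runif(n), sample(1:3, 1))  # induce ties
    truths <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    expect_equal(auc_ovr(scores, truths), auc_pair_oracle(scores, truths))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  for (rep in 1:5) {
    scores <- runif(60)
    truths <- runif(60) > 0.6
    if (!any(truths) || all(truths)) next
    ref <- as.numeric(pROC::auc(pROC::roc(as.integer(truths), scores,
                                          quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc_ovr(scores, truths), 100 * ref, tolerance = 1e-10)
  }
})

test_that("the ROC curve integrates to the rank AUC", {
  set.seed(43)
  for (rep in 1:20) {
    n <- sample(6:40, 1)
    scores <- round(runif(n), 2)
    truths <- c(TRUE, FALSE, runif(n - 2) > 0.4)
    cv <- roc_curve(scores, truths)
    expect_true(all(diff(cv$fpr) >= 0))
    expect_true(all(diff(cv$tpr) >= 0))
    trap <- sum(diff(cv$fpr) * (head(cv$tpr, -1) + cv$tpr[-1]) / 2)
    expect_equal(100 * trap, auc_ovr(scores, truths), tolerance = 1e-10)
  }
})

test_that("fold reports satisfy the confusion-trace identities", {
  set.seed(47)
  n <- 200
  truth <- sample(FUNDUS_CLASSES, n, replace = TRUE)
  probs <- matrix(runif(n * 4), n)
  probs <- probs / rowSums(probs)
  colnames(probs) <- FUNDUS_CLASSES
  rep1 <- fold_report(probs, truth)
  tps <- vapply(FUNDUS_CLASSES,
                function(cls) rep1$confusion[cls, cls], numeric(1))
  expect_equal(sum(tps), sum(diag(rep1$confusion)))
  expect_equal(rep1$overall_accuracy,
               100 * sum(diag(rep1$confusion)) / n)
  expect_equal(rep1$macro[["f1"]], mean(rep1$per_class$f1))
  # permutation invariance to sample order
  perm <- sample(n)
  rep2 <- fold_report(probs[perm, ], truth[perm])
  expect_equal(rep1$per_class, rep2$per_class)
  expect_equal(rep1$overall_accuracy, rep2$overall_accuracy)
})

test_that("aggregation reports mean and population std across folds", {
  set.seed(53)
  n <- 80
  truth <- sample(FUNDUS_CLASSES, n, replace = TRUE)
  probs <- matrix(runif(n * 4), n)
  probs <- probs / rowSums(probs)
  colnames(probs) <- FUNDUS_CLASSES
  r <- fold_report(probs, truth)
  same <- aggregate_folds(list(r, r, r))
  expect_true(all(same$per_class$sd == 0))
  expect_equal(same$overall_accuracy[["mean"]], r$overall_accuracy)

  # two folds with AUC 90 and 94 -> mean 92, population sd 2
  r90 <- r; r94 <- r
  r90$per_class$auc <- rep(90, 4); r90$macro[["auc"]] <- 90
  r94$per_class$auc <- rep(94, 4); r94$macro[["auc"]] <- 94
  agg <- aggregate_folds(list(r90, r94))
  auc_rows <- agg$per_class[agg$per_class$metric == "auc", ]
  expect_equal(auc_rows$mean, rep(92, 4))
  expect_equal(auc_rows$sd, rep(2, 4))
  agg_s <- aggregate_folds(list(r90, r94), sd_type = "sample")
  expect_equal(agg_s$per_class$sd[agg_s$per_class$metric == "auc"],
               rep(sqrt(8), 4))
  expect_error(aggregate_folds(list(r)), class = "fb_bad_params")
})

test_that("ROC bands interpolate onto the common grid", {
  c1 <- tibble::tibble(fpr = c(0, 1), tpr = c(0, 1))
  band0 <- roc_band(list(c1, c1))
  expect_equal(band0$tpr_mean, band0$fpr)
  expect_true(all(band0$tpr_sd == 0))

  c2 <- tibble::tibble(fpr = c(0, 0.5, 1), tpr = c(0, 1, 1))
  band <- roc_band(list(c1, c2))
  at_half <- band[abs(band$fpr - 0.5) < 1e-9, ]
  expect_equal(at_half$tpr_mean, 0.75)
  expect_equal(at_half$tpr_sd, 0.25)
  expect_error(roc_band(list(c1)), class = "fb_bad_params")
  expect_error(roc_band(list(c1, c1[1, ])), class = "fb_bad_params")
})

test_that("macro F1 and its permutation chance band behave sanely", {
  set.seed(59)
  truth <- sample(FUNDUS_CLASSES, 400, replace = TRUE)
  expect_equal(macro_f1(truth, truth), 100)
  band <- chance_band_macro_f1(sample(truth), truth, n_perm = 100, seed = 3)
  expect_lt(band$q99, 60)
  expect_gt(band$mean, 0)
})
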