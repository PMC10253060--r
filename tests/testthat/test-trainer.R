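test_that("freeze fraction marks the leading layer groups non-trainable", {
  spec0 <- backbone_spec(freeze_fraction = 0)
  expect_false(any(build_model(spec0)$frozen))
  spec1 <- backbone_spec(freeze_fraction = 1)
  expect_true(all(build_model(spec1)$frozen))
  spec_half <- backbone_spec(freeze_fraction = 0.5)
  expect_equal(build_model(spec_half)$frozen, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("cosine schedule matches its closed form at every epoch", {
  sched <- list(T_max = 20, eta_min = 1e-5, eta_max = 3e-4)
  expect_identical(cosine_lr(0, sched), 3e-4)
  expect_identical(cosine_lr(20, sched), 1e-5)
  expect_equal(cosine_lr(10, sched), (3e-4 + 1e-5) / 2)
  t <- 0:20
  closed <- 1e-5 + 0.5 * (3e-4 - 1e-5) * (1 + cos(pi * t / 20))
  expect_equal(cosine_lr(t, sched), closed)
  expect_true(all(diff(cosine_lr(t, sched)) <= 0))
  # held at eta_min beyond T_max
  expect_equal(cosine_lr(25, sched), 1e-5)
})

test_that("weighted cross-entropy follows the weighted-mean reduction", {
  # certain prediction -> zero loss whatever the weights
  expect_equal(as.numeric(weighted_cross_entropy(c(0, 1, 0, 0), 2L,
                                                 c(1, 0.9, 1.5, 1.2))), 0)
  # binary pre-training weights: p = (.5, .5), true DR, w = (1, 2)
  l <- weighted_cross_entropy(matrix(c(0.5, 0.5), 1), 2L, c(1, 2))
  expect_equal(attr(l, "per_sample"), 2 * log(2))
  expect_equal(as.numeric(l), log(2))
  # fine-tuning weights: single AMD sample at p = .5 -> 1.5 ln2 / 1.5
  l2 <- weighted_cross_entropy(matrix(c(0.2, 0.2, 0.5, 0.1), 1), 3L,
                               c(1, 0.9, 1.5, 1.2))
  expect_equal(as.numeric(l2), log(2))
  # unit weights reduce to plain mean cross-entropy
  set.seed(2)
  p <- matrix(runif(40), 10)
  p <- p / rowSums(p)
  y <- sample(1:4, 10, replace = TRUE)
  expect_equal(as.numeric(weighted_cross_entropy(p, y, rep(1, 4))),
               mean(-log(p[cbind(1:10, y)])))
})

test_that("backpropagated gradients match central finite differences", {
  set.seed(42)
  model <- fundusbalance:::new_tiny_cnn(4, freeze_fraction = 0,
                                        input_size = 8L,
                                        channels = c(4L, 6L, 8L, 8L),
                                        seed = 2)
  x <- array(rnorm(2 * 8 * 8 * 3), dim = c(2, 8, 8, 3))
  y <- c(1L, 3L)
  w <- c(1, 0.9, 1.5, 1.2)
  loss_at <- function(params) {
    m <- model; m$params <- params
    fwd <- fundusbalance:::tiny_cnn_forward(m, x)
    fundusbalance:::wce_loss_grad(fwd$logits, y, w)$loss
  }
  fwd <- fundusbalance:::tiny_cnn_forward(model, x)
  lg <- fundusbalance:::wce_loss_grad(fwd$logits, y, w)
  gr <- fundusbalance:::tiny_cnn_backward(model, fwd, lg$dlogits)
  eps <- 1e-5
  for (layer in names(gr)) {
    for (slot in c("W", "b")) {
      g <- gr[[layer]][[slot]]
      for (trial in 1:4) {
        i <- sample(length(g), 1)
        p <- model$params
        p[[layer]][[slot]][i] <- p[[layer]][[slot]][i] + eps
        lp <- loss_at(p)
        p[[layer]][[slot]][i] <- p[[layer]][[slot]][i] - 2 * eps
        lm <- loss_at(p)
        expect_equal(g[i], (lp - lm) / (2 * eps), tolerance = 1e-4)
      }
    }
  }
})

test_that("one SGD step on the head matches the softmax-regression oracle", {
  set.seed(3)
  model <- fundusbalance:::new_tiny_cnn(4, freeze_fraction = 1,
                                        input_size = 8L,
                                        channels = c(4L, 4L, 4L, 6L),
                                        seed = 5)
  x <- array(rnorm(1 * 8 * 8 * 3), dim = c(1, 8, 8, 3))
  y <- 2L
  fwd <- fundusbalance:::tiny_cnn_forward(model, x)
  feats <- fwd$caches[[4]]$gap$out          # 1 x C feature embedding
  probs <- fundusbalance:::softmax_rows(fwd$logits)
  onehot <- matrix(0, 1, 4); onehot[1, y] <- 1
  lr <- 0.1
  oracle_W <- model$params$head$W - lr * (t(feats) %*% (probs - onehot))
  oracle_b <- model$params$head$b - lr * as.vector(probs - onehot)

  lg <- fundusbalance:::wce_loss_grad(fwd$logits, y, rep(1, 4))
  gr <- fundusbalance:::tiny_cnn_backward(model, fwd, lg$dlogits)
  st <- fundusbalance:::optimizer_init("sgd")
  step <- fundusbalance:::optimizer_step(st, model$params, gr, lr,
                                         weight_decay = 0)
  expect_equal(step$params$head$W, oracle_W, tolerance = 1e-12)
  expect_equal(step$params$head$b, oracle_b, tolerance = 1e-12)
})

test_that("early stopping halts within patience of the best epoch", {
  # validation loss strictly increasing from epoch 2, patience 5:
  # training must halt by epoch 6 ( <= 7 ) with best epoch 1
  losses <- c(1.0)
  stopped_at <- NA
  for (epoch in 2:10) {
    losses <- c(losses, 1.0 + 0.1 * (epoch - 1))
    es <- fundusbalance:::early_stop_state(losses, patience = 5)
    if (es$stop) { stopped_at <- epoch; break }
  }
  expect_lte(stopped_at, 7)
  es <- fundusbalance:::early_stop_state(losses, patience = 5)
  expect_equal(es$best_epoch, 1L)
  # no stop while within patience
  expect_false(fundusbalance:::early_stop_state(c(1, 1.1, 1.2),
                                                patience = 5)$stop)
})

test_that("pretrain enforces its contract and trains above chance", {
  bad <- generate_corpus(c(NORMAL = 4, GLAUCOMA = 4, DR = 4),
                         quiet_params(), withr::local_tempdir(), seed = 1)
  expect_error(pretrain(bad), class = "fb_bad_pretrain_labels")

  small <- generate_corpus(c(NORMAL = 40, DR = 40), quiet_params(),
                           withr::local_tempdir(), seed = 50)
  one <- pretrain(small, cfg = train_config(max_epochs = 1, seed = 7))
  expect_equal(nrow(one$history), 1L)
  expect_false(one$stopped_early)

  d <- withr::local_tempdir()
  corpus <- generate_corpus(c(NORMAL = 160, DR = 160), quiet_params(), d,
                            seed = 51)
  # scratch-training rate (see vignette): eta_max 1e-2 annealed over the
  # stage's epoch span
  cfg <- train_config(learning_rate = 1e-2,
                      scheduler = list(T_max = NULL, eta_min = 1e-4,
                                       eta_max = 1e-2),
                      max_epochs = 20, seed = 7)
  res <- pretrain(corpus, cfg = cfg)
  expect_lte(nrow(res$history), 20)
  expect_equal(res$best_epoch, which.min(res$history$val_loss))

  d_te <- withr::local_tempdir()
  test <- generate_corpus(c(NORMAL = 30, DR = 30), quiet_params(), d_te,
                          seed = 52)
  probs <- predict_manifest(res$model, test)
  pred <- colnames(probs)[max.col(probs, ties.method = "first")]
  acc <- mean(pred == test$label)
  expect_gt(acc, 0.5 + 3 * sqrt(0.25 / nrow(test)))

  # frozen feature-extractor blocks are bit-identical to initialization
  init <- build_model(backbone_spec(n_outputs = 2), seed = cfg$seed)
  expect_identical(res$model$params$conv1, init$params$conv1)
  expect_identical(res$model$params$conv2, init$params$conv2)
  expect_false(identical(res$model$params$conv3, init$params$conv3))
})

test_that("training is deterministic under identical seeds", {
  d <- withr::local_tempdir()
  corpus <- generate_corpus(c(NORMAL = 30, DR = 30), quiet_params(), d,
                            seed = 61)
  cfg <- train_config(max_epochs = 2, seed = 19)
  r1 <- pretrain(corpus, cfg = cfg)
  r2 <- pretrain(corpus, cfg = cfg)
  expect_identical(r1$history$train_loss[1], r2$history$train_loss[1])
  expect_equal(r1$history, r2$history)
  expect_identical(r1$model$params, r2$model$params)
})

test_that("finetune validates weights, head replacement and validation data", {
  model <- build_model(backbone_spec(n_outputs = 2), seed = 1)
  m4 <- replace_head(model, 4L, seed = 2)
  expect_equal(m4$n_outputs, 4L)
  expect_equal(ncol(m4$params$head$W), 4L)
  expect_equal(m4$frozen, c(TRUE, TRUE, FALSE, FALSE))

  d <- withr::local_tempdir()
  train <- generate_corpus(c(NORMAL = 6, GLAUCOMA = 6, AMD = 6, DR = 6),
                           quiet_params(), d, seed = 71)
  expect_error(finetune(model, train, train[0, ]),
               class = "fb_empty_validation")
  expect_error(finetune(model, train, train,
                        train_config(class_weights = c(1, 2))),
               class = "fb_bad_weights")
})

test_that("evaluation consumes no augmentation randomness", {
  corpus <- generate_corpus(c(NORMAL = 8, DR = 8), quiet_params(),
                            withr::local_tempdir(), seed = 91)
  res <- pretrain(corpus, cfg = train_config(max_epochs = 1, seed = 3))
  set.seed(1)
  p1 <- predict_manifest(res$model, corpus)
  set.seed(999)
  p2 <- predict_manifest(res$model, corpus)
  expect_identical(p1, p2)
})

test_that("checkpoints round-trip the trained model and its history", {
  corpus <- generate_corpus(c(NORMAL = 8, DR = 8), quiet_params(),
                            withr::local_tempdir(), seed = 92)
  res <- pretrain(corpus, cfg = train_config(max_epochs = 2, seed = 3))
  d <- withr::local_tempdir()
  save_checkpoint(res, d)
  expect_true(all(file.exists(file.path(d, c("model.rds", "history.csv",
                                             "stage.json")))))
  back <- load_checkpoint(d)
  expect_identical(back$params, res$model$params)
  hist <- utils::read.csv(file.path(d, "history.csv"))
  expect_equal(nrow(hist), 2L)
  meta <- jsonlite::read_json(file.path(d, "stage.json"))
  expect_equal(meta$n_outputs, 2L)
  expect_equal(unlist(meta$classes), c("NORMAL", "DR"))
})

test_that("the backbone registry accepts custom constructors and rejects unknowns", {
  expect_error(backbone_spec(family = "alexnet"),
               class = "fb_unknown_backbone")
  expect_error(build_model(backbone_spec(family = "resnet50")),
               class = "fb_unknown_backbone")
  register_backbone("toy-linear", function(spec, seed) {
    structure(list(spec = spec, seed = seed), class = "toy_linear")
  })
  m <- build_model(backbone_spec(family = "toy-linear"), seed = 9)
  expect_s3_class(m, "toy_linear")
  expect_equal(m$seed, 9)
})
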