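#' Backbone specification and registry
#'
#' A backbone spec names a feature-extractor family, the number of
#' classifier outputs, and the fraction of feature-extractor layer groups
#' frozen (counted from the input side, by depth). The desk-scale default
#' family is `tiny-cnn`, a compact 4-block convolutional network trained
#' from random initialization that ships with the package. Other families
#' (`resnet50`, `convnext-tiny`, `regnet-y-3.2gf`) are accepted names but
#' require a user-registered constructor via [register_backbone()] (large
#' ImageNet-pretrained backbones need externally supplied weights).
#'
#' @param family Backbone family name.
#' @param pretrained Whether the constructor should load pretrained
#'   feature-extractor weights (ignored by `tiny-cnn`, which is always
#'   randomly initialized).
#' @param n_outputs Number of classifier outputs: 2 (pre-training) or 4.
#' @param freeze_fraction Fraction of feature-extractor layer groups
#'   frozen, in \[0, 1\]; the first `ceiling(freeze_fraction * L)` of the
#'   `L` groups become non-trainable. Default 0.5.
#' @param input_size Input side length the backbone expects; `tiny-cnn`
#'   defaults to 32.
#' @param channels Channel widths of the `tiny-cnn` blocks.
#' @return A `backbone_spec` list.
#' @export
backbone_spec <- function(family = "tiny-cnn", pretrained = FALSE,
                          n_outputs = 4L, freeze_fraction = 0.5,
                          input_size = 32L, channels = c(8L, 16L, 32L, 64L)) {
  known <- c("tiny-cnn", "resnet50", "convnext-tiny", "regnet-y-3.2gf")
  if (!family %in% c(known, names(.backbones$constructors))) {
    stopf("fb_unknown_backbone", "unknown backbone family '%s'", family)
  }
  if (!n_outputs %in% c(2L, 4L)) {
    stopf("fb_bad_params", "n_outputs must be 2 or 4")
  }
  if (freeze_fraction < 0 || freeze_fraction > 1) {
    stopf("fb_bad_params", "freeze_fraction must be in [0, 1]")
  }
  structure(list(family = family, pretrained = pretrained,
                 n_outputs = as.integer(n_outputs),
                 freeze_fraction = freeze_fraction,
                 input_size = as.integer(input_size),
                 channels = as.integer(channels)),
            class = "backbone_spec")
}

.backbones <- new.env(parent = emptyenv())
.backbones$constructors <- list()

#' @rdname backbone_spec
#' @param constructor Function `(spec, seed)` returning a model object that
#'   implements the `nn_forward()`, `nn_backward()`, `nn_proba()` and
#'   `replace_head()` generics.
#' @export
register_backbone <- function(family, constructor) {
  stopifnot(is.function(constructor))
  .backbones$constructors[[family]] <- constructor
  invisible(family)
}

#' Build a model from a backbone spec
#'
#' Constructs the feature extractor, attaches a randomly initialized
#' classification head with `spec$n_outputs` outputs, and marks the first
#' `ceiling(freeze_fraction * L)` feature-extractor layer groups
#' non-trainable.
#'
#' @param spec A [backbone_spec()].
#' @param seed Integer seed for weight initialization.
#' @return A model object (class `tiny_cnn` for the built-in family).
#' @export
build_model <- function(spec, seed = 1L) {
  if (spec$family == "tiny-cnn") {
    return(new_tiny_cnn(spec$n_outputs, spec$freeze_fraction,
                        spec$input_size, spec$channels, seed = seed))
  }
  ctor <- .backbones$constructors[[spec$family]]
  if (is.null(ctor)) {
    stopf("fb_unknown_backbone",
          "no constructor registered for backbone family '%s'; see register_backbone()",
          spec$family)
  }
  ctor(spec, seed)
}

# S3 surface a backbone must implement ---------------------------------

nn_forward <- function(model, x) UseMethod("nn_forward")
nn_backward <- function(model, fwd, dlogits) UseMethod("nn_backward")

#' Class probabilities for a batch tensor
#' @param model A trained model.
#' @param x Batch tensor (N, S, S, 3).
#' @return N x n_outputs matrix of softmax probabilities.
#' @export
nn_proba <- function(model, x) UseMethod("nn_proba")

#' Replace the classification head of a model
#'
#' Installs a new randomly initialized head with `n_outputs` outputs and
#' re-applies the freeze rule to the feature extractor, as done between the
#' pre-training and fine-tuning stages.
#'
#' @param model A model object.
#' @param n_outputs New number of outputs.
#' @param seed Seed for the head initialization.
#' @return The modified model.
#' @export
replace_head <- function(model, n_outputs, seed = 1L) UseMethod("replace_head")

#' @export
nn_forward.tiny_cnn <- function(model, x) tiny_cnn_forward(model, x)
#' @export
nn_backward.tiny_cnn <- function(model, fwd, dlogits) {
  tiny_cnn_backward(model, fwd, dlogits)
}
#' @export
nn_proba.tiny_cnn <- function(model, x) tiny_cnn_proba(model, x)
#' @export
replace_head.tiny_cnn <- function(model, n_outputs, seed = 1L) {
  ci <- model$channels[length(model$channels)]
  model$params$head <- withr::with_seed(as.integer(seed), list(
    W = matrix(stats::rnorm(ci * n_outputs, 0, sqrt(1 / ci)), ci, n_outputs),
    b = numeric(n_outputs)))
  model$n_outputs <- as.integer(n_outputs)
  nb <- length(model$channels)
  model$frozen <- seq_len(nb) <= ceiling(model$freeze_fraction * nb)
  model$classes <- NULL
  model
}

#' Training-stage configuration
#'
#' Hyperparameters of one training stage. Defaults follow the training
#' recipe used for both stages: rectified-Adam with learning rate
#' 3e-4, batch size 32, weight decay 1e-5, a cosine-annealed learning rate
#' (T_max = 20 epochs, eta_min = 1e-5, eta_max = 3e-4, stepped per epoch),
#' and early stopping on validation loss with patience 5 epochs (the
#' best-epoch weights are restored).
#'
#' @param learning_rate Maximum learning rate (eta_max).
#' @param batch_size Minibatch size, >= 1.
#' @param weight_decay L2 penalty coupled into the gradient.
#' @param scheduler List with `T_max`, `eta_min`, `eta_max`. A `NULL`
#'   `T_max` anneals over the stage's planned epoch count.
#' @param patience Early-stopping patience in epochs, >= 1.
#' @param class_weights Positive weights aligned to the class order used by
#'   the stage (`NULL` = stage default: `c(1, 2)` for binary pre-training
#'   over (NORMAL, DR); `c(1, 0.9, 1.5, 1.2)` for 4-class fine-tuning in
#'   canonical order).
#' @param max_epochs Maximum number of epochs.
#' @param step_budget Optional target number of optimizer steps for the
#'   stage; when set, the epoch count becomes
#'   `min(max_epochs, ceiling(step_budget / batches_per_epoch))`, so
#'   stages with very different training-set sizes (e.g. oversampled vs
#'   thresholded) receive comparable optimization effort. `NULL` (default)
#'   disables the budget.
#' @param val_fraction Internal validation fraction used by [pretrain()]'s
#'   stratified split.
#' @param optimizer `"radam"` (default) or `"sgd"`.
#' @param seed Integer seed for shuffling, augmentation and head init.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 3e-4, batch_size = 32L,
                         weight_decay = 1e-5,
                         scheduler = list(T_max = 20, eta_min = 1e-5,
                                          eta_max = 3e-4),
                         patience = 5L, class_weights = NULL,
                         max_epochs = 20L, step_budget = NULL,
                         val_fraction = 0.1,
                         optimizer = c("radam", "sgd"), seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (scheduler$eta_min >= scheduler$eta_max) {
    stopf("fb_bad_params", "scheduler eta_min must be < eta_max")
  }
  if (patience < 1) stopf("fb_bad_params", "patience must be >= 1")
  if (batch_size < 1) stopf("fb_bad_params", "batch_size must be >= 1")
  if (!is.null(class_weights) && any(class_weights <= 0)) {
    stopf("fb_bad_params", "class_weights must be > 0")
  }
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, scheduler = scheduler,
                 patience = as.integer(patience),
                 class_weights = class_weights,
                 max_epochs = as.integer(max_epochs),
                 step_budget = step_budget,
                 val_fraction = val_fraction, optimizer = optimizer,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Cosine-annealed learning rate
#'
#' Closed form `eta_min + (eta_max - eta_min) / 2 * (1 + cos(pi * t /
#' T_max))`, stepped per epoch: `t = 0` gives `eta_max`, `t = T_max` gives
#' `eta_min`, monotone nonincreasing in between. Beyond `T_max` the rate is
#' held at `eta_min` (no warm restarts).
#'
#' @param t Epoch index, >= 0 (vectorized).
#' @param sched List with `T_max`, `eta_min`, `eta_max`.
#' @return Learning rate(s).
#' @export
cosine_lr <- function(t, sched = list(T_max = 20, eta_min = 1e-5,
                                      eta_max = 3e-4)) {
  stopifnot(all(t >= 0))
  tt <- pmin(t, sched$T_max)
  sched$eta_min + 0.5 * (sched$eta_max - sched$eta_min) *
    (1 + cos(pi * tt / sched$T_max))
}

#' Weighted cross-entropy loss
#'
#' Per-sample loss `-w[y] * log(p[y])`; the batch loss is the sum of
#' per-sample losses divided by the sum of the samples' weights (weighted
#' mean), so with all weights 1 it reduces to ordinary mean cross-entropy.
#' Probabilities are floored at 1e-12 rather than erroring on zero.
#'
#' @param p N x K matrix of class probabilities (rows sum to 1), or a
#'   single probability vector.
#' @param y Integer class indices in `1:K` (length N).
#' @param w Positive class weights of length K, aligned to the column
#'   order of `p`.
#' @return Scalar batch loss with attribute `per_sample`.
#' @export
weighted_cross_entropy <- function(p, y, w = rep(1, ncol(p))) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  stopifnot(length(y) == nrow(p), length(w) == ncol(p), all(w > 0))
  py <- pmax(p[cbind(seq_len(nrow(p)), y)], 1e-12)
  per <- -w[y] * log(py)
  structure(sum(per) / sum(w[y]), per_sample = per)
}

# loss + dlogits for one batch under weighted CE (weighted-mean reduction)
wce_loss_grad <- function(logits, y, w) {
  p <- softmax_rows(logits)
  n <- nrow(p)
  wy <- w[y]
  sw <- sum(wy)
  py <- pmax(p[cbind(seq_len(n), y)], 1e-12)
  loss <- sum(-wy * log(py)) / sw
  onehot <- matrix(0, n, ncol(p))
  onehot[cbind(seq_len(n), y)] <- 1
  dlogits <- (p - onehot) * (wy / sw)
  list(loss = loss, dlogits = dlogits, wsum = sw)
}

# early stopping bookkeeping: given the validation-loss history so far,
# the best epoch and whether training should halt now
early_stop_state <- function(val_losses, patience) {
  best <- which.min(val_losses)
  list(best_epoch = best,
       stop = (length(val_losses) - best) >= patience)
}

# ---- training loop ----------------------------------------------------

# read + cache raw images for a manifest (unique paths read once)
load_pixel_cache <- function(paths) {
  cache <- new.env(parent = emptyenv())
  for (p in unique(paths)) assign(p, read_image(p), envir = cache)
  cache
}

# assemble a preprocessed batch tensor; augmenting consumes the ambient RNG
make_batch_tensor <- function(paths, cache, pre_cfg, aug_cfg = NULL) {
  ts <- pre_cfg$target_size
  x <- array(0, dim = c(length(paths), ts, ts, 3))
  for (i in seq_along(paths)) {
    img <- get(paths[i], envir = cache)
    if (!is.null(aug_cfg)) img <- augment(img, aug_cfg)
    x[i, , , ] <- resize_normalize(img, pre_cfg)
  }
  x
}

batched_eval_loss <- function(model, x, y, w, chunk = 256L) {
  n <- dim(x)[1]
  tot <- 0; totw <- 0
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fwd <- nn_forward(model, x[idx, , , , drop = FALSE])
    lg <- wce_loss_grad(fwd$logits, y[idx], w)
    tot <- tot + lg$loss * lg$wsum
    totw <- totw + lg$wsum
  }
  tot / totw
}

# core stage runner shared by pretrain() and finetune().
# `classes` gives the label -> output-unit mapping for this stage.
train_stage <- function(model, train_manifest, val_manifest, cfg, classes,
                        aug_cfg = augmentation_config(),
                        pre_cfg = NULL, verbose = FALSE) {
  if (is.null(pre_cfg)) {
    pre_cfg <- preprocess_config(target_size = model$input_size)
  }
  y_tr <- match(train_manifest$label, classes)
  y_va <- match(val_manifest$label, classes)
  if (anyNA(y_tr) || anyNA(y_va)) {
    stopf("fb_bad_stage_labels",
          "stage expects labels in {%s}", paste(classes, collapse = ", "))
  }
  w <- cfg$class_weights
  if (is.null(w)) w <- rep(1, length(classes))
  if (length(w) != length(classes)) {
    stopf("fb_bad_weights", "class_weights must have %d entries, got %d",
          length(classes), length(w))
  }

  cache <- load_pixel_cache(c(train_manifest$path, val_manifest$path))
  x_val <- make_batch_tensor(val_manifest$path, cache, pre_cfg)

  opt <- optimizer_init(cfg$optimizer)
  n <- nrow(train_manifest)
  n_epochs <- cfg$max_epochs
  if (!is.null(cfg$step_budget)) {
    batches_per_epoch <- ceiling(n / cfg$batch_size)
    n_epochs <- min(n_epochs,
                    max(1L, ceiling(cfg$step_budget / batches_per_epoch)))
  }
  sched <- cfg$scheduler
  # an unset annealing horizon follows the stage's planned epoch count, so
  # stages with very different epoch counts anneal over the same fraction
  # of their schedule
  if (is.null(sched$T_max)) sched$T_max <- n_epochs
  history <- vector("list", n_epochs)
  val_losses <- numeric(0)
  best_params <- model$params
  best_epoch <- 0L
  stopped_early <- FALSE

  withr::with_seed(cfg$seed, {
    for (epoch in seq_len(n_epochs)) {
      lr <- cosine_lr(epoch - 1, sched)
      ord <- sample.int(n)
      tot <- 0; totw <- 0
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        xb <- make_batch_tensor(train_manifest$path[idx], cache, pre_cfg,
                                aug_cfg = aug_cfg)
        fwd <- nn_forward(model, xb)
        lg <- wce_loss_grad(fwd$logits, y_tr[idx], w)
        grads <- nn_backward(model, fwd, lg$dlogits)
        grads <- grads[setdiff(names(grads),
                               paste0("conv", which(model$frozen)))]
        step <- optimizer_step(opt, model$params, grads, lr,
                               cfg$weight_decay)
        opt <- step$state
        model$params <- step$params
        tot <- tot + lg$loss * lg$wsum
        totw <- totw + lg$wsum
      }
      train_loss <- tot / totw
      val_loss <- batched_eval_loss(model, x_val, y_va, w)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, lr = lr, train_loss = train_loss,
        val_loss = val_loss)
      if (verbose) {
        message(sprintf("epoch %d: lr %.2e train %.4f val %.4f",
                        epoch, lr, train_loss, val_loss))
      }
      val_losses <- c(val_losses, val_loss)
      es <- early_stop_state(val_losses, cfg$patience)
      if (es$best_epoch == epoch) best_params <- model$params
      best_epoch <- es$best_epoch
      if (es$stop) { stopped_early <- TRUE; break }
    }
  })
  model$params <- best_params
  model$classes <- classes
  structure(list(model = model,
                 history = do.call(rbind, history[!vapply(history, is.null,
                                                          logical(1))]),
                 best_epoch = best_epoch,
                 stopped_early = stopped_early),
            class = "stage_result")
}

#' @export
print.stage_result <- function(x, ...) {
  cat(sprintf("<stage_result> %d epoch(s), best epoch %d%s\n",
              nrow(x$history), x$best_epoch,
              if (x$stopped_early) " (early stop)" else ""))
  invisible(x)
}

#' Binary pre-training on the excess majority-class subset
#'
#' Trains a 2-output model (normal vs diabetic retinopathy) on the
#' pre-training subset produced by [threshold_split()]. The corpus is
#' internally split into stratified train/validation parts
#' (`cfg$val_fraction`, default 10%); augmentation is applied to the
#' training part only; early stopping monitors validation loss and the
#' best-epoch weights are restored.
#'
#' @param corpus A [corpus_manifest()] containing only NORMAL and DR
#'   records.
#' @param spec A [backbone_spec()] with `n_outputs = 2`.
#' @param cfg A [train_config()]; `class_weights` defaults to `c(1, 2)`
#'   for (NORMAL, DR).
#' @param aug_cfg,pre_cfg Augmentation and preprocessing configs.
#' @param verbose Print per-epoch progress.
#' @return A `stage_result`: trained model, per-epoch history tibble
#'   (`epoch`, `lr`, `train_loss`, `val_loss`), best epoch, early-stop
#'   flag.
#' @export
pretrain <- function(corpus, spec = backbone_spec(n_outputs = 2L),
                     cfg = train_config(), aug_cfg = augmentation_config(),
                     pre_cfg = NULL, verbose = FALSE) {
  extra <- setdiff(unique(corpus$label), c("NORMAL", "DR"))
  if (length(extra) > 0) {
    stopf("fb_bad_pretrain_labels",
          "pre-training corpus must contain only NORMAL and DR records; found %s",
          paste(extra, collapse = ", "))
  }
  if (spec$n_outputs != 2L) {
    stopf("fb_bad_params", "pre-training requires n_outputs = 2")
  }
  if (is.null(cfg$class_weights)) cfg$class_weights <- c(1, 2)
  model <- build_model(spec, seed = cfg$seed)
  parts <- withr::with_seed(cfg$seed, {
    val_idx <- integer(0)
    for (cls in unique(corpus$label)) {
      idx <- which(corpus$label == cls)
      n_val <- max(1L, round(length(idx) * cfg$val_fraction))
      if (length(idx) < 2) {
        stopf("fb_bad_params",
              "class %s has < 2 records; cannot hold out validation", cls)
      }
      val_idx <- c(val_idx, sample_from(idx, n_val))
    }
    list(train = corpus[-val_idx, ], val = corpus[val_idx, ])
  })
  train_stage(model, parts$train, parts$val, cfg,
              classes = c("NORMAL", "DR"), aug_cfg = aug_cfg,
              pre_cfg = pre_cfg, verbose = verbose)
}

#' Four-class fine-tuning
#'
#' Replaces the classification head of a (typically pre-trained) model with
#' a randomly initialized 4-output head, re-applies the freeze rule, and
#' trains on the fine-tuning fold with weighted cross-entropy (default
#' weights 1, 0.9, 1.5, 1.2 for normal, glaucoma, AMD, diabetic
#' retinopathy).
#'
#' @param model A model from [pretrain()] (its `stage_result$model`) or
#'   [build_model()].
#' @param train_manifest,val_manifest Fine-tuning training and validation
#'   manifests (4-class); the validation manifest must be nonempty.
#' @param cfg A [train_config()]; `class_weights` must have 4 entries.
#' @param aug_cfg,pre_cfg Augmentation and preprocessing configs.
#' @param verbose Print per-epoch progress.
#' @return A `stage_result`.
#' @export
finetune <- function(model, train_manifest, val_manifest,
                     cfg = train_config(), aug_cfg = augmentation_config(),
                     pre_cfg = NULL, verbose = FALSE) {
  if (nrow(val_manifest) == 0) {
    stopf("fb_empty_validation", "fine-tuning validation set is empty")
  }
  if (is.null(cfg$class_weights)) cfg$class_weights <- c(1, 0.9, 1.5, 1.2)
  if (length(cfg$class_weights) != 4) {
    stopf("fb_bad_weights", "fine-tuning class_weights must have 4 entries")
  }
  model <- replace_head(model, 4L, seed = cfg$seed)
  train_stage(model, train_manifest, val_manifest, cfg,
              classes = FUNDUS_CLASSES, aug_cfg = aug_cfg,
              pre_cfg = pre_cfg, verbose = verbose)
}

#' Persist a training-stage result as a checkpoint
#'
#' Writes the trained model (`model.rds`), the per-epoch training log
#' (`history.csv`: epoch, learning rate, train loss, validation loss) and
#' a sidecar JSON (`stage.json`: backbone family, class order, frozen
#' blocks, best epoch, early-stop flag) into `dir`.
#' [load_checkpoint()] restores the model.
#'
#' @param stage A `stage_result` from [pretrain()] or [finetune()].
#' @param dir Checkpoint directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_checkpoint <- function(stage, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(stage$model, file.path(dir, "model.rds"))
  utils::write.csv(as.data.frame(stage$history),
                   file.path(dir, "history.csv"), row.names = FALSE)
  meta <- list(family = stage$model$family,
               input_size = stage$model$input_size,
               channels = stage$model$channels,
               n_outputs = stage$model$n_outputs,
               classes = stage$model$classes,
               frozen_blocks = which(stage$model$frozen),
               best_epoch = stage$best_epoch,
               stopped_early = stage$stopped_early)
  jsonlite::write_json(meta, file.path(dir, "stage.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  readRDS(file.path(dir, "model.rds"))
}

#' Predict class probabilities for every record of a manifest
#'
#' @param model A trained model carrying a `classes` attribute (set by the
#'   training stages).
#' @param manifest A [corpus_manifest()].
#' @param pre_cfg Preprocessing config; defaults to the model's input size.
#' @param chunk Evaluation batch size.
#' @return N x K probability matrix with column names = model classes.
#' @export
predict_manifest <- function(model, manifest, pre_cfg = NULL, chunk = 256L) {
  if (is.null(pre_cfg)) {
    pre_cfg <- preprocess_config(target_size = model$input_size)
  }
  cache <- load_pixel_cache(manifest$path)
  n <- nrow(manifest)
  out <- matrix(0, n, model$n_outputs)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    x <- make_batch_tensor(manifest$path[idx], cache, pre_cfg)
    out[idx, ] <- nn_proba(model, x)
  }
  colnames(out) <- model$classes
  out
}
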