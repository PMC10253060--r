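test_that("pooling adds class counts and preserves sources", {
  m1 <- counts_manifest(c(NORMAL = 2, GLAUCOMA = 1), source = "a")
  m2 <- counts_manifest(c(AMD = 3, DR = 4), source = "b")
  pooled <- pool_manifests(list(m1, m2))
  expect_equal(as.vector(class_counts(pooled)), c(2L, 1L, 3L, 4L))
  expect_true(all(startsWith(pooled$id[1:3], "a/")))

  single <- pool_manifests(list(m1))
  expect_equal(class_counts(single), class_counts(m1))
  expect_equal(nrow(single), nrow(m1))

  empty <- corpus_manifest(m1[0, ])
  with_empty <- pool_manifests(list(m1, empty))
  expect_equal(class_counts(with_empty), class_counts(m1))

  clash <- counts_manifest(c(NORMAL = 2), source = "a")
  expect_error(pool_manifests(list(m1[, ], clash)),
               class = "fb_duplicate_id")
})

test_that("pooling the per-dataset glaucoma counts reproduces the corpus total", {
  gl_per_dataset <- c(396, 101, 10, 756, 40, 312, 1711, 289, 172)
  manifests <- lapply(seq_along(gl_per_dataset), function(i) {
    counts_manifest(c(GLAUCOMA = gl_per_dataset[i]),
                    source = paste0("ds", i))
  })
  pooled <- pool_manifests(manifests)
  expect_equal(class_counts(pooled)[["GLAUCOMA"]], 3787L)
})

test_that("threshold split reproduces the published split arithmetic", {
  corpus <- counts_manifest(c(NORMAL = 86415, GLAUCOMA = 3787, AMD = 632,
                              DR = 34379))
  sp <- threshold_split(corpus, seed = 1)
  expect_equal(sp$threshold, 3787L)
  ft <- class_counts(sp$finetune)
  expect_equal(as.vector(ft), c(3787L, 3787L, 632L, 3787L))
  expect_equal(attr(ft, "total"), 11993L)
  pt <- class_counts(sp$pretrain)
  expect_equal(pt[["DR"]], 30592L)
  expect_equal(pt[["GLAUCOMA"]], 0L)
  expect_equal(pt[["AMD"]], 0L)
  expect_equal(pt[["NORMAL"]], 86415L - 3787L)
})

test_that("threshold split conserves, keeps pretrain pure, and balances", {
  set.seed(7)
  for (rep in 1:20) {
    counts <- c(NORMAL = sample(5:200, 1), GLAUCOMA = sample(1:50, 1),
                AMD = sample(0:30, 1), DR = sample(5:200, 1))
    corpus <- counts_manifest(counts)
    sp <- threshold_split(corpus, seed = rep)
    # conservation, overall and per class
    expect_equal(nrow(sp$pretrain) + nrow(sp$finetune), nrow(corpus))
    expect_equal(class_counts(sp$pretrain) + class_counts(sp$finetune),
                 class_counts(corpus), ignore_attr = TRUE)
    # purity: no glaucoma or AMD ever pre-trains
    expect_false(any(sp$pretrain$label %in% c("GLAUCOMA", "AMD")))
    # disjointness
    expect_length(intersect(sp$pretrain$id, sp$finetune$id), 0)
    # balance whenever the majority classes exceed the threshold
    ft <- class_counts(sp$finetune)
    t <- sp$threshold
    expect_equal(ft[["NORMAL"]], min(t, counts[["NORMAL"]]))
    expect_equal(ft[["DR"]], min(t, counts[["DR"]]))
    expect_equal(ft[["AMD"]], counts[["AMD"]])
    # reproducibility
    sp2 <- threshold_split(corpus, seed = rep)
    expect_identical(sp$finetune$id, sp2$finetune$id)
  }
})

test_that("threshold split handles degenerate corpora", {
  balanced <- counts_manifest(c(NORMAL = 5, GLAUCOMA = 5, AMD = 5, DR = 5))
  sp <- threshold_split(balanced, seed = 1)
  expect_equal(nrow(sp$pretrain), 0L)
  expect_equal(nrow(sp$finetune), nrow(balanced))

  no_gl <- counts_manifest(c(NORMAL = 5, AMD = 2, DR = 5))
  expect_error(threshold_split(no_gl, seed = 1),
               class = "fb_threshold_absent")
  expect_error(threshold_split(counts_manifest(c(NORMAL = 0))[0, ]),
               class = "fb_empty_corpus")
})

test_that("class_counts matches an independent one-pass tally", {
  expect_equal(as.vector(class_counts(counts_manifest(c(NORMAL = 0)))),
               rep(0L, 4))
  m <- counts_manifest(c(DR = 3))
  expect_equal(as.vector(class_counts(m)), c(0L, 0L, 0L, 3L))

  set.seed(13)
  labels <- sample(FUNDUS_CLASSES, 500, replace = TRUE,
                   prob = c(0.6, 0.15, 0.05, 0.2))
  m <- corpus_manifest(tibble::tibble(
    id = sprintf("r%03d", 1:500), path = "x.png", label = labels,
    source = "r", width = 64L, height = 64L))
  tally <- integer(4); names(tally) <- FUNDUS_CLASSES
  for (lab in labels) tally[lab] <- tally[lab] + 1L
  expect_equal(as.vector(class_counts(m)), as.vector(tally))
})

test_that("manifests round-trip through CSV", {
  m <- counts_manifest(c(NORMAL = 3, DR = 2))
  d <- withr::local_tempdir()
  write_manifest(m, file.path(d, "m.csv"))
  back <- read_manifest(file.path(d, "m.csv"))
  expect_equal(back$id, m$id)
  expect_equal(back$label, m$label)
  expect_equal(back$width, m$width)
})
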