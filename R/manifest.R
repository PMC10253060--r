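#' Corpus manifests
#'
#' A corpus manifest is the unit of data passed between every stage of the
#' pipeline: a tibble with one row per labeled fundus image and columns
#' `id` (unique within the manifest), `path` (image file location), `label`
#' (one of [FUNDUS_CLASSES]), `source` (dataset tag) and `width`/`height`
#' in pixels. `corpus_manifest()` validates a data frame and stamps the
#' `corpus_manifest` class on it.
#'
#' @param records Data frame with columns `id`, `path`, `label`, `source`,
#'   `width`, `height`.
#' @return A `corpus_manifest` tibble.
#' @examples
#' m <- corpus_manifest(tibble::tibble(
#'   id = c("a", "b"), path = c("a.png", "b.png"),
#'   label = c("NORMAL", "DR"), source = "demo", width = 64L, height = 64L))
#' class_counts(m)
#' @export
corpus_manifest <- function(records) {
  required <- c("id", "path", "label", "source", "width", "height")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stopf("fb_bad_manifest", "manifest lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  records <- tibble::as_tibble(records)[required]
  bad <- setdiff(unique(records$label), FUNDUS_CLASSES)
  if (length(bad) > 0) {
    stopf("fb_unknown_label", "manifest contains unknown label(s): %s",
          paste(bad, collapse = ", "))
  }
  if (anyDuplicated(records$id)) {
    stopf("fb_duplicate_id", "manifest contains duplicated id(s), e.g. '%s'",
          records$id[duplicated(records$id)][1])
  }
  class(records) <- c("corpus_manifest", class(records))
  records
}

#' @export
print.corpus_manifest <- function(x, ...) {
  cts <- class_counts(x)
  cat(sprintf("<corpus_manifest> %d records (%s)\n", nrow(x),
              paste(sprintf("%s=%d", names(cts), cts), collapse = ", ")))
  NextMethod()
}

#' Per-class census of a manifest
#'
#' @param manifest A [corpus_manifest()].
#' @return Named integer vector over the canonical four classes (zero for
#'   absent classes), with a `total` attribute.
#' @export
class_counts <- function(manifest) {
  tab <- table(as_class_factor(manifest$label))
  counts <- stats::setNames(as.integer(tab), names(tab))
  attr(counts, "total") <- sum(counts)
  counts
}

#' Pool per-source manifests into one corpus
#'
#' Concatenates manifests in order, preserving source tags. Record ids are
#' disambiguated by prefixing the source tag (`source/id`); a collision
#' after prefixing is an error. Per-class counts of the result are the sums
#' of the inputs' counts.
#'
#' @param manifests List of [corpus_manifest()] objects (at least one).
#' @return Pooled `corpus_manifest`.
#' @export
pool_manifests <- function(manifests) {
  if (length(manifests) < 1) {
    stopf("fb_empty_pool", "pool_manifests() needs at least one manifest")
  }
  pooled <- do.call(rbind, lapply(manifests, function(m) {
    m <- tibble::as_tibble(m)
    m$id <- paste(m$source, m$id, sep = "/")
    m
  }))
  if (anyDuplicated(pooled$id)) {
    stopf("fb_duplicate_id",
          "id collision after source prefixing, e.g. '%s'",
          pooled$id[duplicated(pooled$id)][1])
  }
  corpus_manifest(pooled)
}

#' Threshold split into pre-training and fine-tuning subsets
#'
#' Implements the two-stage data split: the cardinality of the threshold
#' class (glaucoma by default) defines a threshold `t`. All glaucoma and
#' AMD records go to the fine-tuning subset. For each of the two majority
#' classes (normal, DR), a uniform random sample of `min(t, class count)`
#' records is retained for fine-tuning and the excess is routed to the
#' binary pre-training subset. The two subsets are disjoint and exhaustive.
#'
#' @param corpus A [corpus_manifest()].
#' @param threshold_class Class whose cardinality defines the threshold;
#'   default `"GLAUCOMA"`.
#' @param seed Integer seed controlling which excess records are sampled.
#' @return A `split_result` list with elements `threshold` (integer),
#'   `pretrain` and `finetune` (both `corpus_manifest`).
#' @examples
#' \donttest{
#' corp <- generate_corpus(c(NORMAL = 12, GLAUCOMA = 4, AMD = 2, DR = 9),
#'                         out_dir = tempfile(), seed = 1)
#' sp <- threshold_split(corp, seed = 1)
#' class_counts(sp$finetune)
#' }
#' @export
threshold_split <- function(corpus, threshold_class = "GLAUCOMA", seed = 1L) {
  assert_label(threshold_class)
  if (nrow(corpus) == 0) {
    stopf("fb_empty_corpus", "cannot split an empty corpus")
  }
  counts <- class_counts(corpus)
  t <- counts[[threshold_class]]
  if (t == 0) {
    stopf("fb_threshold_absent",
          "threshold class %s has zero records; split undefined",
          threshold_class)
  }
  to_finetune <- rep(TRUE, nrow(corpus))
  withr::with_seed(seed, {
    for (cls in c("NORMAL", "DR")) {
      idx <- which(corpus$label == cls)
      if (length(idx) > t) {
        keep <- sample_from(idx, t)
        to_finetune[setdiff(idx, keep)] <- FALSE
      }
    }
  })
  structure(list(
    threshold = as.integer(t),
    pretrain  = corpus_manifest(corpus[!to_finetune, ]),
    finetune  = corpus_manifest(corpus[to_finetune, ])
  ), class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> threshold = %d\n", x$threshold))
  cat("pretrain: "); print(class_counts(x$pretrain))
  cat("finetune: "); print(class_counts(x$finetune))
  invisible(x)
}

#' Read and write manifest CSV files
#'
#' Manifests are persisted as plain CSV with columns
#' `id, relative_path, label, source, width, height`; paths are stored
#' relative to the CSV's directory and resolved on read.
#'
#' @param manifest A [corpus_manifest()].
#' @param file CSV path.
#' @return `write_manifest()` returns `file` invisibly; `read_manifest()`
#'   returns a `corpus_manifest`.
#' @export
write_manifest <- function(manifest, file) {
  dir.create(dirname(file), recursive = TRUE, showWarnings = FALSE)
  out <- tibble::as_tibble(manifest)
  base <- normalizePath(dirname(file), mustWork = FALSE)
  rel <- vapply(out$path, function(p) {
    p_norm <- suppressWarnings(normalizePath(p, mustWork = FALSE))
    if (startsWith(p_norm, paste0(base, "/"))) {
      substring(p_norm, nchar(base) + 2L)
    } else p
  }, character(1), USE.NAMES = FALSE)
  utils::write.csv(
    data.frame(id = out$id, relative_path = rel, label = out$label,
               source = out$source, width = out$width, height = out$height),
    file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  base <- dirname(normalizePath(file))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", df$relative_path),
                df$relative_path, file.path(base, df$relative_path))
  corpus_manifest(tibble::tibble(
    id = as.character(df$id), path = abs, label = df$label,
    source = df$source, width = as.integer(df$width),
    height = as.integer(df$height)))
}
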