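# internal helpers shared across modules

stopf <- function(class, fmt, ...) {
  rlang::abort(sprintf(fmt, ...), class = c(class, "fundusbalance_error"))
}

assert_label <- function(label) {
  if (length(label) != 1L || !label %in% FUNDUS_CLASSES) {
    stopf("fb_unknown_label", "unknown class label '%s' (expected one of %s)",
          paste(label, collapse = ","), paste(FUNDUS_CLASSES, collapse = ", "))
  }
  label
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

clip255 <- function(x) pmin(pmax(x, 0), 255)

# sample() without the scalar-x surprise: always samples from the set `x`
sample_from <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# label vector -> factor in canonical order
as_class_factor <- function(x, classes = FUNDUS_CLASSES) {
  bad <- setdiff(unique(x), classes)
  if (length(bad) > 0) {
    stopf("fb_unknown_label", "unknown class label(s): %s",
          paste(bad, collapse = ", "))
  }
  factor(x, levels = classes)
}
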