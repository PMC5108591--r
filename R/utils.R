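# Internal helpers shared across modules.

# Derive an independent sub-stream seed from a scene seed. Streams are fixed
# by convention: geometry = 0, markers = 1, noise = 2. Kept below 2^31 - 1.
sub_seed <- function(seed, stream) {
  seed <- as.integer(seed) %% 1000003L
  (seed * 2047L + as.integer(stream) * 7919L + 17L) %% 2147483647L
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1], got %s",
                  name, paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

check_raster <- function(x, name = "image") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a 2-D numeric matrix", name))
  }
  invisible(x)
}

check_same_shape <- function(a, b, name_a, name_b) {
  if (!identical(dim(a), dim(b))) {
    abort(sprintf("`%s` (%s) and `%s` (%s) must share dimensions",
                  name_a, paste(dim(a), collapse = "x"),
                  name_b, paste(dim(b), collapse = "x")))
  }
  invisible(NULL)
}

# Relabel a positive-integer label matrix so labels are 1..K in raster-scan
# (row-major) order of each component's first pixel.
relabel_raster_scan <- function(labels) {
  pos <- which(t(labels) > 0)  # row-major order
  vals <- t(labels)[pos]
  first <- vals[!duplicated(vals)]
  map <- integer(max(labels))
  map[first] <- seq_along(first)
  out <- labels
  out[labels > 0] <- map[labels[labels > 0]]
  out
}
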