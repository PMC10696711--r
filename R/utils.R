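# Internal helpers shared across modules.

# Validate a grayscale image matrix: finite, non-negative, 2D.
assert_gray_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  if (nrow(image) < 1L || ncol(image) < 1L)
    stop(sprintf("`%s` must have positive dimensions", arg), call. = FALSE)
  if (anyNA(image) || any(!is.finite(image)))
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  if (min(image) < 0)
    stop(sprintf("`%s` contains negative intensities", arg), call. = FALSE)
  invisible(TRUE)
}

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

# Lower median: for even counts take the lower of the two central order
# statistics, keeping the result an attained (integer-stable) intensity.
lower_median <- function(x) {
  n <- length(x)
  sort(x, partial = ceiling(n / 2))[ceiling(n / 2)]
}

# Shannon entropy in bits of a non-negative weight vector, 0 log2 0 := 0.
entropy_bits <- function(p) {
  p <- p[p > 0]
  if (!length(p)) return(0)
  -sum(p * log2(p))
}
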