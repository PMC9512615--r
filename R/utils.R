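#' @importFrom stats median rnorm sd
NULL

#' Clip intensities to the unit interval
#'
#' @param x Numeric matrix or vector.
#' @return `x` with every element forced into \[0, 1\].
#' @export
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

## Validate a grayscale image: numeric matrix, >= 8 x 8, finite.
## Range is only enforced where a caller asks for it (coefficient grids
## share the same plumbing but are unbounded).
check_image <- function(img, min_dim = 8L, unit_range = FALSE,
                        arg = deparse(substitute(img))) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (nrow(img) < min_dim || ncol(img) < min_dim) {
    stop(sprintf("`%s` must be at least %dx%d pixels, got %dx%d",
                 arg, min_dim, min_dim, nrow(img), ncol(img)), call. = FALSE)
  }
  if (!all(is.finite(img))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  if (unit_range && (min(img) < 0 || max(img) > 1)) {
    stop(sprintf("`%s` has intensities outside [0, 1]", arg), call. = FALSE)
  }
  invisible(img)
}

check_same_shape <- function(ref, test) {
  if (!identical(dim(ref), dim(test))) {
    stop(sprintf("image shapes differ: %dx%d vs %dx%d",
                 nrow(ref), ncol(ref), nrow(test), ncol(test)), call. = FALSE)
  }
  invisible(NULL)
}

## Symmetric (half-point, edge-duplicating) padding of a matrix by `r`
## rows/columns on every side; the boundary rule shared by the bilateral,
## NLM and wavelet stages.
pad_symmetric <- function(x, r) {
  n <- nrow(x); m <- ncol(x)
  if (r < 1) return(x)
  if (r > n || r > m) {
    stop(sprintf("padding radius %d exceeds image extent %dx%d", r, n, m),
         call. = FALSE)
  }
  x <- rbind(x[r:1, , drop = FALSE], x, x[n:(n - r + 1), , drop = FALSE])
  cbind(x[, r:1, drop = FALSE], x, x[, m:(m - r + 1), drop = FALSE])
}

## Run `code` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
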