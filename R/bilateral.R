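#' Bilateral filter parameters
#'
#' @param sigma_d Spatial (domain) Gaussian kernel width in pixels; > 0.
#' @param sigma_r Range (photometric) Gaussian kernel width in intensity
#'   units; > 0.
#' @param radius Half-width of the square neighborhood in pixels;
#'   defaults to `ceiling(2 * sigma_d)`.
#' @return An object of class `bilateral_params`.
#' @export
bilateral_params <- function(sigma_d = 1.8, sigma_r = 0.1,
                             radius = ceiling(2 * sigma_d)) {
  if (sigma_d <= 0 || sigma_r <= 0) {
    stop("`sigma_d` and `sigma_r` must be > 0", call. = FALSE)
  }
  radius <- as.integer(radius)
  if (radius < 1L) stop("`radius` must be >= 1", call. = FALSE)
  structure(list(sigma_d = sigma_d, sigma_r = sigma_r, radius = radius),
            class = "bilateral_params")
}

#' @export
print.bilateral_params <- function(x, ...) {
  cat(sprintf("<bilateral_params> sigma_d=%g px, sigma_r=%g, radius=%d\n",
              x$sigma_d, x$sigma_r, x$radius))
  invisible(x)
}

#' Edge-preserving bilateral filter
#'
#' Each output pixel is the normalized weighted mean of its
#' `(2 radius + 1)^2` neighborhood, the weight of neighbor `(k, l)` seen
#' from `(i, j)` being the product of a spatial Gaussian
#' `exp(-((i-k)^2 + (j-l)^2) / (2 sigma_d^2))` and a range Gaussian
#' `exp(-(f(i,j) - f(k,l))^2 / (2 sigma_r^2))`.  Flat regions are
#' smoothed like a plain Gaussian blur while strong intensity steps
#' suppress the range weight and survive.  Boundaries use symmetric
#' reflection so the normalization never sees missing mass.
#'
#' The output at every pixel is a convex combination of its window, so it
#' is bounded by the local min and max (no over/undershoot) and a
#' constant image is a fixed point.
#'
#' @param img Numeric matrix; an image in \[0, 1\] or any real-valued
#'   coefficient grid (e.g. a wavelet approximation band).
#' @param params A [bilateral_params()], or `NULL` to use the other
#'   arguments.
#' @param sigma_d,sigma_r,radius Used when `params` is `NULL`.
#' @return Filtered matrix, same shape; not clipped.
#' @examples
#' x <- shepp_logan(64)
#' y <- bilateral_filter(x, bilateral_params(sigma_d = 1.5, sigma_r = 0.1))
#' @export
bilateral_filter <- function(img, params = NULL, sigma_d = 1.8,
                             sigma_r = 0.1, radius = ceiling(2 * sigma_d)) {
  if (is.null(params)) params <- bilateral_params(sigma_d, sigma_r, radius)
  if (!inherits(params, "bilateral_params")) {
    stop("`params` must be a bilateral_params", call. = FALSE)
  }
  check_image(img, min_dim = 2L)
  r <- params$radius
  P <- pad_symmetric(img, r)
  n <- nrow(img); m <- ncol(img)
  num <- matrix(0, n, m); den <- num
  inv2sd <- 1 / (2 * params$sigma_d^2)
  inv2sr <- 1 / (2 * params$sigma_r^2)
  for (dy in -r:r) {
    for (dx in -r:r) {
      sw <- exp(-(dy * dy + dx * dx) * inv2sd)
      nb <- P[(r + 1 + dy):(r + n + dy), (r + 1 + dx):(r + m + dx), drop = FALSE]
      w <- sw * exp(-(nb - img)^2 * inv2sr)
      num <- num + w * nb
      den <- den + w
    }
  }
  num / den
}
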