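#' Noise specification
#'
#' Bundles a noise model with its parameters and the seed of the
#' pseudo-random stream, so that a corrupted image is a pure function of
#' `(image, spec)`.
#'
#' Three models are supported:
#' \describe{
#'   \item{gaussian}{additive, `g = x + n`, `n ~ N(mean, variance)` i.i.d.}
#'   \item{salt_pepper}{impulse noise: a fraction `density` of pixels is
#'     replaced, half by 1 (salt) and half by 0 (pepper)}
#'   \item{speckle}{multiplicative, `g = x * (1 + n)`, `n ~ N(0, variance)`}
#' }
#'
#' @param kind One of `"gaussian"`, `"salt_pepper"`, `"speckle"`.
#' @param mean Mean of the additive Gaussian component (gaussian only).
#' @param variance Variance of the Gaussian component on the \[0,1\]
#'   intensity scale (gaussian/speckle). Must be nonnegative.
#' @param density Fraction of pixels corrupted (salt_pepper only), in \[0,1\].
#' @param seed Integer seed for the pseudo-random stream.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("gaussian", "salt_pepper", "speckle"),
                       mean = 0, variance = NULL, density = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "salt_pepper") {
    if (is.null(density)) stop("salt_pepper noise requires `density`", call. = FALSE)
    if (density < 0 || density > 1) {
      stop("`density` must lie in [0, 1]", call. = FALSE)
    }
    if (!is.null(variance)) stop("`variance` does not apply to salt_pepper noise", call. = FALSE)
  } else {
    if (is.null(variance)) stop(sprintf("%s noise requires `variance`", kind), call. = FALSE)
    if (variance < 0) stop("`variance` must be >= 0", call. = FALSE)
    if (!is.null(density)) stop("`density` only applies to salt_pepper noise", call. = FALSE)
    if (kind == "speckle" && mean != 0) stop("speckle noise is zero-mean", call. = FALSE)
  }
  structure(list(kind = kind, mean = mean, variance = variance,
                 density = density, seed = as.integer(seed)),
            class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  pars <- switch(x$kind,
    gaussian    = sprintf("mean=%g, variance=%g", x$mean, x$variance),
    salt_pepper = sprintf("density=%g", x$density),
    speckle     = sprintf("variance=%g", x$variance))
  cat(sprintf("<noise_spec> %s (%s, seed=%d)\n", x$kind, pars, x$seed))
  invisible(x)
}

#' Inject noise into an image
#'
#' Applies the noise model described by a [noise_spec()] to a grayscale
#' image and clips the result back to \[0, 1\].  Deterministic given
#' `(img, spec)` including the seed; the caller's RNG state is left
#' untouched.
#'
#' @param img Numeric matrix with intensities in \[0, 1\].
#' @param spec A [noise_spec()].
#' @return A matrix of the same shape, clipped to \[0, 1\].
#' @examples
#' ph <- shepp_logan(64)
#' noisy <- add_noise(ph, noise_spec("gaussian", variance = 0.04, seed = 7))
#' @export
add_noise <- function(img, spec) {
  if (!inherits(spec, "noise_spec")) stop("`spec` must be a noise_spec", call. = FALSE)
  check_image(img, unit_range = TRUE)
  switch(spec$kind,
    gaussian    = add_gaussian_noise(img, spec$variance, mean = spec$mean, seed = spec$seed),
    salt_pepper = add_salt_pepper_noise(img, spec$density, seed = spec$seed),
    speckle     = add_speckle_noise(img, spec$variance, seed = spec$seed))
}

#' Additive Gaussian noise
#'
#' `g = clip(x + n, 0, 1)` with `n` i.i.d. normal.
#'
#' @inheritParams add_noise
#' @param variance Noise variance on the \[0,1\] intensity scale.
#' @param mean Noise mean (default 0).
#' @param seed Integer seed.
#' @return Noisy image, same shape, clipped to \[0, 1\].
#' @export
add_gaussian_noise <- function(img, variance, mean = 0, seed = 1L) {
  check_image(img)
  if (variance < 0) stop("`variance` must be >= 0", call. = FALSE)
  if (variance == 0 && mean == 0) return(img)
  n <- with_seed(seed, rnorm(length(img), mean = mean, sd = sqrt(variance)))
  clip01(img + matrix(n, nrow(img), ncol(img)))
}

#' Salt-and-pepper (impulse) noise
#'
#' A seeded random fraction `density` of pixel sites (chosen without
#' replacement) is overwritten: half of them (rounded) with 1.0 ("salt",
#' the bright extreme `b`), the rest with 0.0 ("pepper", the dark extreme
#' `a`).  All remaining pixels are untouched.
#'
#' @inheritParams add_noise
#' @param density Fraction of corrupted pixels, in \[0, 1\].
#' @param seed Integer seed.
#' @return Corrupted image, same shape.
#' @export
add_salt_pepper_noise <- function(img, density, seed = 1L) {
  check_image(img)
  if (density < 0 || density > 1) stop("`density` must lie in [0, 1]", call. = FALSE)
  if (density == 0) return(img)
  npix <- length(img)
  ncorrupt <- round(density * npix)
  if (ncorrupt == 0) return(img)
  out <- img
  with_seed(seed, {
    sites <- sample.int(npix, ncorrupt)
    nsalt <- round(ncorrupt / 2)
    out[sites[seq_len(nsalt)]] <- 1
    if (ncorrupt > nsalt) out[sites[(nsalt + 1):ncorrupt]] <- 0
  })
  out
}

#' Multiplicative speckle noise
#'
#' `g = clip(x * (1 + n), 0, 1)` with `n` i.i.d. zero-mean normal; the
#' perturbation is proportional to the local signal, so dark regions are
#' barely touched and an all-zero image is a fixed point.
#'
#' @inheritParams add_noise
#' @param variance Variance of the multiplier noise `n`.
#' @param seed Integer seed.
#' @return Noisy image, same shape, clipped to \[0, 1\].
#' @export
add_speckle_noise <- function(img, variance, seed = 1L) {
  check_image(img)
  if (variance < 0) stop("`variance` must be >= 0", call. = FALSE)
  if (variance == 0) return(img)
  n <- with_seed(seed, rnorm(length(img), sd = sqrt(variance)))
  clip01(img * (1 + matrix(n, nrow(img), ncol(img))))
}
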