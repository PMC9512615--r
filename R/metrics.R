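#' Mean squared error
#'
#' @param ref,test Numeric matrices of identical shape.
#' @return Mean over all pixels of the squared intensity difference.
#' @export
img_mse <- function(ref, test) {
  check_same_shape(ref, test)
  mean((ref - test)^2)
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` in decibels; `Inf` for identical images.
#' Higher is better; on \[0, 1\] images `peak = 1`.
#'
#' @inheritParams img_mse
#' @param peak Peak signal value (default 1, the unit intensity scale).
#' @return PSNR in dB.
#' @examples
#' img_psnr(matrix(0, 8, 8), matrix(0.1, 8, 8))  # 20 dB
#' @export
img_psnr <- function(ref, test, peak = 1) {
  if (peak <= 0) stop("`peak` must be > 0", call. = FALSE)
  m <- img_mse(ref, test)
  if (m == 0) return(Inf)
  10 * log10(peak^2 / m)
}

## 1D Gaussian window, unit sum.
gaussian_window <- function(size = 11L, sigma = 1.5) {
  half <- (size - 1) / 2
  w <- exp(-((-half):half)^2 / (2 * sigma^2))
  w / sum(w)
}

## Separable 'valid' correlation of X with an outer-product window w x w.
filter_valid <- function(X, w) {
  k <- length(w)
  n <- nrow(X) - k + 1L; m <- ncol(X) - k + 1L
  A <- matrix(0, n, ncol(X))
  for (j in seq_len(k)) A <- A + w[j] * X[j:(j + n - 1L), , drop = FALSE]
  B <- matrix(0, n, m)
  for (j in seq_len(k)) B <- B + w[j] * A[, j:(j + m - 1L), drop = FALSE]
  B
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM in the canonical configuration: 11x11 Gaussian
#' weighting window with sigma 1.5, stability constants
#' `C1 = (0.01 * peak)^2` and `C2 = (0.03 * peak)^2`, local statistics
#' compared through
#' `((2 mu_x mu_y + C1)(2 cov_xy + C2)) / ((mu_x^2 + mu_y^2 + C1)(var_x + var_y + C2))`
#' and averaged over all fully interior window positions.  Ranges over
#' \[-1, 1\]; 1 means structurally identical, negative values
#' anticorrelated structure.
#'
#' @inheritParams img_psnr
#' @param window_size Odd window side (default 11).
#' @param window_sigma Gaussian window width (default 1.5).
#' @return Mean SSIM.
#' @export
img_ssim <- function(ref, test, peak = 1, window_size = 11L,
                     window_sigma = 1.5) {
  check_same_shape(ref, test)
  if (min(dim(ref)) < window_size) {
    stop(sprintf("images must be at least %dx%d for SSIM",
                 window_size, window_size), call. = FALSE)
  }
  w <- gaussian_window(window_size, window_sigma)
  C1 <- (0.01 * peak)^2
  C2 <- (0.03 * peak)^2
  mu1 <- filter_valid(ref, w)
  mu2 <- filter_valid(test, w)
  s11 <- filter_valid(ref * ref, w) - mu1^2
  s22 <- filter_valid(test * test, w) - mu2^2
  s12 <- filter_valid(ref * test, w) - mu1 * mu2
  ssim_map <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  mean(ssim_map)
}

#' Full-reference quality report
#'
#' Computes MSE, PSNR and SSIM of a test image against its reference in
#' one call.
#'
#' @inheritParams img_psnr
#' @return A one-row tibble with columns `mse`, `psnr`, `ssim`.
#' @examples
#' ph <- shepp_logan(64)
#' quality_report(ph, add_gaussian_noise(ph, 0.01, seed = 1))
#' @export
quality_report <- function(ref, test, peak = 1) {
  tibble::tibble(
    mse  = img_mse(ref, test),
    psnr = img_psnr(ref, test, peak),
    ssim = img_ssim(ref, test, peak)
  )
}
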