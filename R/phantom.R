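## Modified Shepp-Logan head phantom: ten ellipses, each a row of
## (additive intensity A, semi-axis a along x, semi-axis b along y,
## centre x0, centre y0, rotation phi in degrees).  The canonical
## "modified" intensity set keeps soft-tissue contrast visible on a
## linear grayscale.
shepp_logan_ellipses <- function() {
  matrix(c(
    #   A       a       b       x0      y0     phi
     1.00,  0.6900, 0.9200,  0.000,  0.0000,   0,
    -0.80,  0.6624, 0.8740,  0.000, -0.0184,   0,
    -0.20,  0.1100, 0.3100,  0.220,  0.0000, -18,
    -0.20,  0.1600, 0.4100, -0.220,  0.0000,  18,
     0.10,  0.2100, 0.2500,  0.000,  0.3500,   0,
     0.10,  0.0460, 0.0460,  0.000,  0.1000,   0,
     0.10,  0.0460, 0.0460,  0.000, -0.1000,   0,
     0.10,  0.0460, 0.0230, -0.080, -0.6050,   0,
     0.10,  0.0230, 0.0230,  0.000, -0.6060,   0,
     0.10,  0.0230, 0.0460,  0.060, -0.6050,   0
  ), ncol = 6, byrow = TRUE,
  dimnames = list(NULL, c("A", "a", "b", "x0", "y0", "phi")))
}

#' Generate the Shepp-Logan head phantom
#'
#' Renders the modified Shepp-Logan phantom -- ten analytically defined
#' ellipses on the unit square -- onto a `size` x `size` pixel grid and
#' linearly rescales intensities to span \[0, 1\].  This is the standard
#' synthetic test image for CT algorithms: a skull-like outer ellipse,
#' brain-like interior, two dark "ventricles" and several small
#' high-contrast features.
#'
#' @param size Side length in pixels (integer, at least 8).
#' @return A `size` x `size` numeric matrix with values in \[0, 1\].
#'   Row 1 is the top of the head; columns run left to right.
#' @examples
#' ph <- shepp_logan(128)
#' range(ph)
#' @export
shepp_logan <- function(size = 512L) {
  size <- as.integer(size)
  if (length(size) != 1L || is.na(size) || size < 8L) {
    stop("`size` must be a single integer >= 8", call. = FALSE)
  }
  ell <- shepp_logan_ellipses()
  xs <- seq(-1, 1, length.out = size)
  ys <- seq(1, -1, length.out = size)          # row 1 = top (y = +1)
  X <- matrix(xs, size, size, byrow = TRUE)
  Y <- matrix(ys, size, size)
  img <- matrix(0, size, size)
  for (k in seq_len(nrow(ell))) {
    phi <- ell[k, "phi"] * pi / 180
    xr <- (X - ell[k, "x0"]) * cos(phi) + (Y - ell[k, "y0"]) * sin(phi)
    yr <- -(X - ell[k, "x0"]) * sin(phi) + (Y - ell[k, "y0"]) * cos(phi)
    inside <- (xr / ell[k, "a"])^2 + (yr / ell[k, "b"])^2 <= 1
    img[inside] <- img[inside] + ell[k, "A"]
  }
  rng <- range(img)
  if (rng[2] > rng[1]) img <- (img - rng[1]) / (rng[2] - rng[1])
  img
}
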