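## Orthogonal wavelet filter bank.  Only the scaling (low-pass
## decomposition) filter is stored; the quadrature-mirror relations give
## the other three: dec_hi[j] = (-1)^j * dec_lo[L+1-j], rec = reversed dec.
## Daubechies / Symlet coefficients are the published values.
wavelet_filter_table <- list(
  haar = c(1, 1) / sqrt(2),
  db1  = c(1, 1) / sqrt(2),
  db2  = c(-0.12940952255126037, 0.22414386804201339,
            0.83651630373780790, 0.48296291314453416),
  db4  = c(-0.010597401785069032, 0.032883011666885169,
            0.030841381835560764, -0.187034811719093085,
           -0.027983769416859854, 0.630880767929858908,
            0.714846570552915647, 0.230377813308896501),
  sym4 = c(-0.075765714789273330, -0.029635527645998510,
            0.497618667632015450, 0.803738751805916078,
            0.297857795605277362, -0.099219543576847216,
           -0.012603967262037833, 0.032223100604042700)
)

#' Orthogonal wavelet filters
#'
#' @param wavelet Filter family name: `"haar"` (= `"db1"`), `"db2"`,
#'   `"db4"` or `"sym4"`.
#' @return A list with decomposition and reconstruction low/high-pass
#'   filters (`dec_lo`, `dec_hi`, `rec_lo`, `rec_hi`) and the filter
#'   length `length`.
#' @export
wavelet_filters <- function(wavelet = "db4") {
  dec_lo <- wavelet_filter_table[[wavelet]]
  if (is.null(dec_lo)) {
    stop(sprintf("unknown wavelet '%s'; available: %s", wavelet,
                 paste(names(wavelet_filter_table), collapse = ", ")),
         call. = FALSE)
  }
  L <- length(dec_lo)
  dec_hi <- (-1)^(1:L) * rev(dec_lo)
  list(wavelet = wavelet, length = L,
       dec_lo = dec_lo, dec_hi = dec_hi,
       rec_lo = rev(dec_lo), rec_hi = rev(dec_hi))
}

#' Maximum feasible decomposition depth
#'
#' Follows the subband-size cascade of the chosen boundary mode and
#' counts how many analysis steps are possible: a symmetric-mode step
#' needs the current extent to be at least `L - 1` (the extension
#' length), a periodic step needs an even extent of at least `L`.  The
#' depth is additionally capped at `floor(log2(n))`, beyond which
#' symmetric-mode subbands stop shrinking and further levels carry no
#' new scale information.
#'
#' @param n_min Smaller of the two image dimensions (pixels).
#' @param wavelet Filter name, see [wavelet_filters()].
#' @param boundary_mode `"symmetric"` or `"periodic"`.
#' @return Integer depth (possibly 0 for tiny images).
#' @export
max_wavelet_levels <- function(n_min, wavelet = "db4",
                               boundary_mode = "symmetric") {
  L <- wavelet_filters(wavelet)$length
  n <- as.integer(n_min)
  depth <- 0L
  cap <- max(floor(log2(max(n, 1))), 0)
  while (depth < cap) {
    if (boundary_mode == "periodic") {
      if (n < L || n %% 2L != 0L) break
      n <- n %/% 2L
    } else {
      if (n < L - 1L) break
      n <- (n + L - 1L) %/% 2L
    }
    depth <- depth + 1L
  }
  depth
}

## --- 1D analysis/synthesis applied to every column of a matrix ----------
##
## Symmetric mode: half-point symmetric extension by L-1 samples each
## side; subband length floor((n + L - 1) / 2); synthesis is the valid
## part of the upsampled full convolution.  Periodic mode: circular
## convolution (requires even n); subband length n/2; synthesis is the
## adjoint, exact because the periodized filter matrix is orthonormal.

dwt_cols <- function(X, f, mode) {
  n <- nrow(X); L <- f$length
  if (mode == "periodic") {
    if (n %% 2L != 0L) {
      stop("periodic boundary mode requires even extents at every level",
           call. = FALSE)
    }
    m <- n %/% 2L
    lo <- matrix(0, m, ncol(X)); hi <- lo
    for (j in 1:L) {
      rows <- ((2 * (1:m) + L - j - 1) %% n) + 1L
      S <- X[rows, , drop = FALSE]
      lo <- lo + f$dec_lo[j] * S
      hi <- hi + f$dec_hi[j] * S
    }
  } else {
    if (n < L - 1) {
      stop(sprintf("extent %d too small for filter length %d", n, L),
           call. = FALSE)
    }
    Xe <- rbind(X[(L - 1):1, , drop = FALSE], X,
                X[n:(n - L + 2), , drop = FALSE])
    m <- (n + L - 1) %/% 2L
    lo <- matrix(0, m, ncol(X)); hi <- lo
    for (j in 1:L) {
      S <- Xe[L + 2 * (1:m) - j, , drop = FALSE]
      lo <- lo + f$dec_lo[j] * S
      hi <- hi + f$dec_hi[j] * S
    }
  }
  list(lo = lo, hi = hi)
}

idwt_cols <- function(lo, hi, f, n_out, mode) {
  nc <- nrow(lo); L <- f$length
  if (mode == "periodic") {
    n <- 2L * nc
    out <- matrix(0, n, ncol(lo))
    for (j in 1:L) {
      rows <- ((2 * (1:nc) + L - j - 1) %% n) + 1L
      out[rows, ] <- out[rows, ] + f$dec_lo[j] * lo + f$dec_hi[j] * hi
    }
    out[seq_len(n_out), , drop = FALSE]
  } else {
    up <- matrix(0, 2L * nc + L - 1L, ncol(lo))
    odd <- seq(1L, 2L * nc, by = 2L)
    for (j in 1:L) {
      up[odd + j - 1L, ] <- up[odd + j - 1L, ] +
        f$rec_lo[j] * lo + f$rec_hi[j] * hi
    }
    up[(L - 1L):(L - 2L + n_out), , drop = FALSE]
  }
}

## One 2D analysis step: rows first, then columns, 2:1 decimation on each
## axis; returns the four subbands of this level.
dwt2_step <- function(X, f, mode) {
  rows <- dwt_cols(t(X), f, mode)            # transform along rows
  Lo <- t(rows$lo); Hi <- t(rows$hi)         # n x m2 each
  colsL <- dwt_cols(Lo, f, mode)
  colsH <- dwt_cols(Hi, f, mode)
  list(a = colsL$lo,   # low/low
       h = colsL$hi,   # horizontal detail: low along rows, high across rows
       v = colsH$lo,   # vertical detail: high along rows, low across rows
       d = colsH$hi)   # diagonal detail: high/high
}

idwt2_step <- function(a, h, v, d, f, shape, mode) {
  Lo <- idwt_cols(a, h, f, shape[1], mode)
  Hi <- idwt_cols(v, d, f, shape[1], mode)
  t(idwt_cols(t(Lo), t(Hi), f, shape[2], mode))
}

#' Multilevel 2D discrete wavelet decomposition
#'
#' Separable orthogonal analysis: each level filters rows then columns
#' with 2:1 decimation, producing an approximation band and horizontal /
#' vertical / diagonal detail bands; the cascade recurses on the
#' approximation band.  With `boundary_mode = "symmetric"` the signal is
#' extended by half-point reflection and subbands have
#' `floor((n + L - 1)/2)` samples per axis; with `"periodic"` extension is
#' circular, extents must be even at every level, and subbands have
#' exactly `n/2` samples.  Both modes reconstruct perfectly (to ~1e-12)
#' through [wave_reconstruct()].
#'
#' @param img Numeric matrix (image or coefficient grid).
#' @param wavelet Orthogonal filter name, see [wavelet_filters()].
#' @param levels Decomposition depth `L >= 1`.
#' @param boundary_mode `"symmetric"` (default) or `"periodic"`.
#' @return An object of class `wave_decomposition`: a list with
#'   `approximation` (deepest low-frequency band), `details` (list of
#'   length `levels`, finest first, each with matrices `h`, `v`, `d`),
#'   `wavelet`, `levels`, `boundary_mode` and `original_shape`.
#' @examples
#' dec <- wave_decompose(shepp_logan(64), "db4", levels = 2)
#' sapply(dec$details, function(l) dim(l$d)[1])
#' @export
wave_decompose <- function(img, wavelet = "db4", levels = 3L,
                           boundary_mode = c("symmetric", "periodic")) {
  boundary_mode <- match.arg(boundary_mode)
  check_image(img, min_dim = 2L)
  levels <- as.integer(levels)
  if (levels < 1L) stop("`levels` must be >= 1", call. = FALSE)
  lmax <- max_wavelet_levels(min(dim(img)), wavelet, boundary_mode)
  if (levels > lmax) {
    stop(sprintf("levels = %d too deep for a %dx%d image with '%s' (max %d)",
                 levels, nrow(img), ncol(img), wavelet, lmax), call. = FALSE)
  }
  f <- wavelet_filters(wavelet)
  details <- vector("list", levels)
  shapes <- vector("list", levels)
  cA <- img
  for (l in seq_len(levels)) {
    shapes[[l]] <- dim(cA)
    s <- dwt2_step(cA, f, boundary_mode)
    details[[l]] <- list(h = s$h, v = s$v, d = s$d)
    cA <- s$a
  }
  structure(list(approximation = cA, details = details,
                 wavelet = wavelet, levels = levels,
                 boundary_mode = boundary_mode,
                 original_shape = dim(img), level_shapes = shapes),
            class = "wave_decomposition")
}

#' @export
print.wave_decomposition <- function(x, ...) {
  cat(sprintf("<wave_decomposition> %s, %d level(s), %s boundary, source %dx%d\n",
              x$wavelet, x$levels, x$boundary_mode,
              x$original_shape[1], x$original_shape[2]))
  cat(sprintf("  approximation: %dx%d\n",
              nrow(x$approximation), ncol(x$approximation)))
  for (l in seq_len(x$levels)) {
    cat(sprintf("  level %d details: %dx%d (h, v, d)\n", l,
                nrow(x$details[[l]]$h), ncol(x$details[[l]]$h)))
  }
  invisible(x)
}

#' Inverse multilevel 2D wavelet transform
#'
#' Runs the synthesis cascade from the deepest approximation band back to
#' the original resolution and crops to the stored source shape.  Output
#' values are not clipped; clipping to \[0, 1\] is the final step of a
#' denoising pipeline, not of the transform.
#'
#' @param dec A `wave_decomposition` from [wave_decompose()], possibly
#'   with modified coefficient bands.
#' @return Numeric matrix with the decomposition's `original_shape`.
#' @export
wave_reconstruct <- function(dec) {
  if (!inherits(dec, "wave_decomposition")) {
    stop("`dec` must be a wave_decomposition", call. = FALSE)
  }
  f <- wavelet_filters(dec$wavelet)
  cA <- dec$approximation
  for (l in rev(seq_len(dec$levels))) {
    dl <- dec$details[[l]]
    ref <- dim(dl$h)
    for (b in c("h", "v", "d")) {
      if (!identical(dim(dl[[b]]), ref) || !is.matrix(dl[[b]])) {
        stop(sprintf("inconsistent subband shapes at level %d", l), call. = FALSE)
      }
    }
    if (!identical(dim(cA), ref)) {
      stop(sprintf("approximation/detail shape mismatch at level %d", l),
           call. = FALSE)
    }
    cA <- idwt2_step(cA, dl$h, dl$v, dl$d, f,
                     dec$level_shapes[[l]], dec$boundary_mode)
  }
  cA
}
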