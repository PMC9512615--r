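## Box-sum of an (n + 2f) x (m + 2f) matrix over (2f+1)^2 windows,
## evaluated at the n x m window centres, via a summed-area table.
box_sum <- function(Q, f) {
  n <- nrow(Q) - 2L * f; m <- ncol(Q) - 2L * f
  S <- apply(apply(Q, 2, cumsum), 1, cumsum)   # transposed SAT
  S <- t(S)
  S <- rbind(0, cbind(0, S))                   # (nr+1) x (nc+1), S[i+1,j+1] = sum Q[1:i,1:j]
  w <- 2L * f + 1L
  S[(w + 1):(w + n), (w + 1):(w + m)] -
    S[1:n, (w + 1):(w + m)] -
    S[(w + 1):(w + n), 1:m] +
    S[1:n, 1:m]
}

#' Non-local means denoising
#'
#' Buades-style patch-based averaging: pixel `(i, j)` is replaced by a
#' weighted mean of the pixels in its `(2 search_radius + 1)^2` search
#' window, the weight of candidate `(k, l)` being
#' `exp(-D / h^2)` where `D` is the mean squared difference between the
#' `patch_size` x `patch_size` patches centred on `(i, j)` and `(k, l)`.
#' Boundaries use symmetric reflection.  The centre pixel participates
#' with weight 1 (`D = 0`), so the output is always a convex combination
#' of window values.
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param patch_size Odd patch side length, >= 3.
#' @param search_radius Search window half-width, >= 1.
#' @param h Filtering strength (intensity units), > 0; larger values
#'   average more aggressively.
#' @return Denoised matrix, same shape, clipped to \[0, 1\].
#' @export
denoise_nlm <- function(img, patch_size = 7L, search_radius = 10L, h = 0.1) {
  patch_size <- as.integer(patch_size)
  search_radius <- as.integer(search_radius)
  if (patch_size < 3L || patch_size %% 2L == 0L) {
    stop("`patch_size` must be an odd integer >= 3", call. = FALSE)
  }
  if (search_radius < 1L) stop("`search_radius` must be >= 1", call. = FALSE)
  if (h <= 0) stop("`h` must be > 0", call. = FALSE)
  check_image(img, min_dim = 2L)
  f <- (patch_size - 1L) %/% 2L
  r <- search_radius
  pr <- r + f
  P <- pad_symmetric(img, pr)
  n <- nrow(img); m <- ncol(img)
  ## patch-extended center block, (n + 2f) x (m + 2f)
  C <- P[(r + 1):(r + n + 2L * f), (r + 1):(r + m + 2L * f), drop = FALSE]
  num <- matrix(0, n, m); den <- num
  npatch <- patch_size^2
  for (dy in -r:r) {
    for (dx in -r:r) {
      Tt <- P[(r + 1 + dy):(r + n + 2L * f + dy),
              (r + 1 + dx):(r + m + 2L * f + dx), drop = FALSE]
      D <- box_sum((C - Tt)^2, f) / npatch
      w <- exp(-D / h^2)
      nb <- P[(pr + 1 + dy):(pr + n + dy), (pr + 1 + dx):(pr + m + dx), drop = FALSE]
      num <- num + w * nb
      den <- den + w
    }
  }
  clip01(num / den)
}
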