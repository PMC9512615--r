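# Independent brute-force reference implementations used as oracles.
# Deliberately written as plain loops with their own boundary handling so
# they share no code path with the package.

# Edge-duplicating symmetric reflection of index i onto 1..n.
mirror_index <- function(i, n) {
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i
    if (i > n) i <- 2L * n + 1L - i
  }
  i
}

oracle_bilateral <- function(img, sigma_d, sigma_r, radius) {
  n <- nrow(img); m <- ncol(img)
  out <- matrix(0, n, m)
  for (i in 1:n) {
    for (j in 1:m) {
      num <- 0; den <- 0
      for (k in (i - radius):(i + radius)) {
        for (l in (j - radius):(j + radius)) {
          fkl <- img[mirror_index(k, n), mirror_index(l, m)]
          w <- exp(-((i - k)^2 + (j - l)^2) / (2 * sigma_d^2)) *
            exp(-(img[i, j] - fkl)^2 / (2 * sigma_r^2))
          num <- num + w * fkl
          den <- den + w
        }
      }
      out[i, j] <- num / den
    }
  }
  out
}

# Plain truncated-Gaussian spatial smoothing (bilateral limit sigma_r -> Inf).
oracle_gaussian_blur <- function(img, sigma_d, radius) {
  n <- nrow(img); m <- ncol(img)
  out <- matrix(0, n, m)
  for (i in 1:n) {
    for (j in 1:m) {
      num <- 0; den <- 0
      for (k in (i - radius):(i + radius)) {
        for (l in (j - radius):(j + radius)) {
          w <- exp(-((i - k)^2 + (j - l)^2) / (2 * sigma_d^2))
          num <- num + w * img[mirror_index(k, n), mirror_index(l, m)]
          den <- den + w
        }
      }
      out[i, j] <- num / den
    }
  }
  out
}

oracle_nlm <- function(img, patch_size, search_radius, h) {
  n <- nrow(img); m <- ncol(img)
  f <- (patch_size - 1L) %/% 2L
  out <- matrix(0, n, m)
  patch_of <- function(i, j) {
    p <- matrix(0, patch_size, patch_size)
    for (a in -f:f) for (b in -f:f) {
      p[a + f + 1L, b + f + 1L] <- img[mirror_index(i + a, n), mirror_index(j + b, m)]
    }
    p
  }
  for (i in 1:n) {
    for (j in 1:m) {
      p0 <- patch_of(i, j)
      num <- 0; den <- 0
      for (di in -search_radius:search_radius) {
        for (dj in -search_radius:search_radius) {
          p1 <- patch_of(i + di, j + dj)
          D <- mean((p0 - p1)^2)
          w <- exp(-D / h^2)
          num <- num + w * img[mirror_index(i + di, n), mirror_index(j + dj, m)]
          den <- den + w
        }
      }
      out[i, j] <- num / den
    }
  }
  pmin(pmax(out, 0), 1)
}

oracle_mse <- function(ref, test) {
  acc <- 0
  for (i in seq_len(nrow(ref))) {
    for (j in seq_len(ncol(ref))) acc <- acc + (ref[i, j] - test[i, j])^2
  }
  acc / (nrow(ref) * ncol(ref))
}

oracle_ssim <- function(ref, test, peak = 1, size = 11L, sigma = 1.5) {
  half <- (size - 1L) %/% 2L
  g1 <- exp(-((-half):half)^2 / (2 * sigma^2))
  W <- outer(g1, g1)
  W <- W / sum(W)
  C1 <- (0.01 * peak)^2; C2 <- (0.03 * peak)^2
  n <- nrow(ref); m <- ncol(ref)
  vals <- c()
  for (i in (half + 1):(n - half)) {
    for (j in (half + 1):(m - half)) {
      x <- ref[(i - half):(i + half), (j - half):(j + half)]
      y <- test[(i - half):(i + half), (j - half):(j + half)]
      mx <- sum(W * x); my <- sum(W * y)
      vx <- sum(W * x^2) - mx^2
      vy <- sum(W * y^2) - my^2
      cxy <- sum(W * x * y) - mx * my
      vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                      ((mx^2 + my^2 + C1) * (vx + vy + C2)))
    }
  }
  mean(vals)
}

# Shared small fixtures
random_image <- function(n, m = n, seed = 1) {
  withr::with_seed(seed, matrix(stats::runif(n * m), n, m))
}
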