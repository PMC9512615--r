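test_that("perfect reconstruction holds across wavelets, sizes and boundary modes", {
  set.seed(7)
  for (w in c("haar", "db2", "db4", "sym4")) {
    for (mode in c("symmetric", "periodic")) {
      for (shape in list(c(32, 32), c(64, 48), c(37, 53), c(8, 8))) {
        if (mode == "periodic" && any(shape %% 2 != 0)) next
        lv <- min(2L, max_wavelet_levels(min(shape), w, mode))
        if (lv < 1L) next
        img <- matrix(runif(prod(shape)), shape[1], shape[2])
        rec <- wave_reconstruct(wave_decompose(img, w, lv, mode))
        expect_lt(max(abs(rec - img)), 1e-8)
      }
    }
  }
})

test_that("Haar analysis of a 2x2 block gives the orthonormal closed form", {
  X <- matrix(c(1, 5, 3, 7), 2, 2, byrow = TRUE)  # rows (1,5), (3,7)
  a <- X[1, 1]; b <- X[1, 2]; cc <- X[2, 1]; d <- X[2, 2]
  dec <- wave_decompose(X, "haar", 1)
  expect_equal(as.vector(dec$approximation), (a + b + cc + d) / 2)
  expect_equal(as.vector(dec$details[[1]]$h), (a + b - cc - d) / 2)
  expect_equal(as.vector(dec$details[[1]]$v), (a - b + cc - d) / 2)
  expect_equal(as.vector(dec$details[[1]]$d), (a - b - cc + d) / 2)
})

test_that("separable analysis reproduces an independent reference decomposition", {
  # frozen from an independent implementation of the same symmetric-mode
  # orthogonal filter bank (db2, one level, 4x4 input)
  X <- matrix(c(0.773956, 0.094177, 0.128114, 0.643865, 0.438878, 0.975622,
                0.450386, 0.822762, 0.858598, 0.76114, 0.370798, 0.443414,
                0.697368, 0.786064, 0.926765, 0.227239), 4, 4)
  cA <- matrix(c(1.192548875000, 0.783637855363, 1.137224875000,
                 1.223245444444, 1.137265041106, 1.276117223667,
                 1.496429750000, 1.624629878695, 0.815810750000), 3, 3)
  cH <- matrix(c(0.325320927387, -0.449459273674, 0.415611869960,
                 -0.053499514104, -0.497934583295, 0.408690601358,
                 -0.036509465960, 0.357624927868, -0.438633639775), 3, 3)
  cV <- matrix(c(0.026801104677, -0.382486098664, -0.185970944728,
                 0.203256761460, 0.053954717369, -0.097099142721,
                 -0.099325752598, 0.058526221372, -0.020039394831), 3, 3)
  cD <- matrix(c(0.456196125000, -0.017744690470, 0.053765625000,
                 0.095958812696, -0.239636616165, 0.152101491190,
                 -0.069807750000, 0.358089743915, -0.289553250000), 3, 3)
  dec <- wave_decompose(X, "db2", 1)
  expect_equal(dec$approximation, cA, tolerance = 1e-9)
  expect_equal(dec$details[[1]]$h, cH, tolerance = 1e-9)
  expect_equal(dec$details[[1]]$v, cV, tolerance = 1e-9)
  expect_equal(dec$details[[1]]$d, cD, tolerance = 1e-9)
})

test_that("constants are annihilated by every detail filter", {
  flat <- matrix(0.37, 32, 32)
  for (w in c("haar", "db2", "db4", "sym4")) {
    dec <- wave_decompose(flat, w, 1)
    expect_lt(max(abs(dec$details[[1]]$h)), 1e-10)
    expect_lt(max(abs(dec$details[[1]]$v)), 1e-10)
    expect_lt(max(abs(dec$details[[1]]$d)), 1e-10)
    expect_lt(max(abs(dec$approximation - dec$approximation[1, 1])), 1e-10)
  }
})

test_that("the synthesis bank is linear", {
  img <- random_image(33, 41, seed = 2)
  dec <- wave_decompose(img, "db4", 2)
  dec2 <- dec
  dec2$approximation <- 2 * dec2$approximation
  for (l in 1:2) for (b in c("h", "v", "d")) {
    dec2$details[[l]][[b]] <- 2 * dec2$details[[l]][[b]]
  }
  expect_lt(max(abs(wave_reconstruct(dec2) - 2 * img)), 1e-8)
  zero <- dec
  zero$approximation <- 0 * zero$approximation
  for (l in 1:2) for (b in c("h", "v", "d")) {
    zero$details[[l]][[b]] <- 0 * zero$details[[l]][[b]]
  }
  expect_lt(max(abs(wave_reconstruct(zero))), 1e-12)
})

test_that("subband shapes follow the halving cascade of each boundary mode", {
  for (w in c("db2", "db4")) {
    L <- wavelet_filters(w)$length
    for (n in c(64L, 57L, 100L)) {
      lv <- min(3L, max_wavelet_levels(n, w))
      dec <- wave_decompose(matrix(0, n, n), w, lv)
      expect_length(dec$details, lv)
      sz <- n
      for (l in seq_len(lv)) {
        sz <- (sz + L - 1L) %/% 2L
        expect_identical(dim(dec$details[[l]]$d), c(sz, sz))
      }
      expect_identical(dim(dec$approximation), c(sz, sz))
    }
    dec <- wave_decompose(matrix(0, 64, 64), w, 2, "periodic")
    expect_identical(dim(dec$details[[2]]$d), c(16L, 16L))
  }
})

test_that("infeasible depth errors name the maximum level; inconsistent bands are rejected", {
  expect_error(wave_decompose(matrix(0, 16, 16), "db4", 8), "max")
  dec <- wave_decompose(random_image(32, seed = 3), "db4", 1)
  dec$details[[1]]$h <- dec$details[[1]]$h[-1, , drop = FALSE]
  expect_error(wave_reconstruct(dec), "shape")
})
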