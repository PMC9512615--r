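test_that("a minimal one-cell grid is fully populated", {
  b <- run_benchmark("gaussian", levels = 0.04, methods = "q1",
                     seeds = 101L, size = 64)
  expect_s3_class(b, "ct_benchmark")
  r <- tidy(b)
  expect_identical(nrow(r), 3L)  # one cell x three metrics
  expect_true(all(r$n_seeds == 1L))
  expect_true(all(is.finite(r$mean)))
})

test_that("the identity hook recovers the injected noise variance as its MSE", {
  flat <- matrix(0.5, 64, 64)
  b <- run_benchmark("gaussian", levels = 0.01, methods = "identity",
                     seeds = 1:5, image = flat)
  m <- tidy(b)
  got <- m$mean[m$metric == "mse"]
  expect_equal(got, 0.01, tolerance = 0.05)
})

test_that("benchmark reruns are bit-identical and noisy inputs are shared across methods", {
  a <- run_benchmark("salt_pepper", levels = c(0.1, 0.2), methods = c("q1", "q5"),
                     seeds = c(11L, 12L), size = 64)
  b <- run_benchmark("salt_pepper", levels = c(0.1, 0.2), methods = c("q1", "q5"),
                     seeds = c(11L, 12L), size = 64)
  expect_identical(tidy(a), tidy(b))
  expect_identical(tidy(a, per_seed = TRUE), tidy(b, per_seed = TRUE))
})

test_that("level semantics follow the documented proportion reading", {
  flat <- matrix(0.5, 64, 64)
  # speckle at proportion p: residual variance = x^2 p^2 = 0.25 p^2
  b <- run_benchmark("speckle", levels = 0.2, methods = "identity",
                     seeds = 1:5, image = flat)
  m <- tidy(b)
  expect_equal(m$mean[m$metric == "mse"], 0.25 * 0.04, tolerance = 0.10)
})

test_that("external method hooks join the grid", {
  blur <- function(img) (img + img[c(1, 1:(nrow(img) - 1)), ]) / 2
  b <- run_benchmark("gaussian", levels = 0.02, methods = c("identity", "blur"),
                     seeds = 1L, size = 64, configs = list(blur = blur))
  expect_identical(sort(unique(tidy(b)$method)), c("blur", "identity"))
})

test_that("grid export is tidy, stable and round-trips through CSV", {
  b <- run_benchmark("gaussian", levels = c(0.02, 0.04), methods = c("q1", "q5"),
                     seeds = c(5L, 6L), size = 64)
  path <- withr::local_tempfile(fileext = ".csv")
  export_grid(b, path)
  back <- read_grid(path)
  expect_identical(names(back),
                   c("noise_kind", "level", "method", "metric", "mean", "sd", "n_seeds"))
  expect_identical(nrow(back), 2L * 2L * 3L)
  expect_equal(back$mean, tidy(b)$mean)
  expect_equal(back$sd, tidy(b)$sd)
})

test_that("degenerate grids are refused", {
  expect_error(run_benchmark("gaussian", levels = numeric(0), methods = "q1",
                             seeds = 1L, size = 64), "level")
  expect_error(run_benchmark("gaussian", levels = 0.02, methods = character(0),
                             seeds = 1L, size = 64), "method")
  expect_error(run_benchmark("gaussian", levels = 0.02, methods = "q1",
                             seeds = integer(0), size = 64), "seed")
})

test_that("tidy/glance/autoplot expose the grid the tidyverse way", {
  b <- run_benchmark("gaussian", levels = c(0.02, 0.04), methods = c("q1", "q5"),
                     seeds = 3L, size = 64)
  expect_s3_class(tidy(b), "tbl_df")
  g <- glance(b)
  expect_identical(nrow(g), 1L)
  expect_true(g$best_method %in% c("q1", "q5"))
  p <- autoplot(b)
  expect_s3_class(p, "ggplot")
})
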