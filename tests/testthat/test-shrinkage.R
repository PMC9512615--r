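test_that("shrinkage functions match their closed forms at spot values", {
  expect_equal(shrink_coefficients(2, 1, shrinkage_rule("soft")), 1)
  expect_equal(shrink_coefficients(2, 1, shrinkage_rule("hard")), 2)
  expect_equal(shrink_coefficients(0.5, 1, shrinkage_rule("improved", a = 0.4)), 0.2)
  expect_equal(
    shrink_coefficients(-0.5, 1, shrinkage_rule("improved", a = 0.4,
                                                improved_small = "constant")),
    -0.4)
  expect_equal(shrink_coefficients(1, 1, shrinkage_rule("soft")), 0)  # tie
  expect_error(shrink_coefficients(1, -0.1), "lambda")
  expect_error(shrinkage_rule(a = 1.5), "a")
  expect_error(shrinkage_rule(selector = "manual"), "manual_lambda")
})

test_that("shrinkage algebra holds on dense coefficient grids", {
  w <- seq(-3, 3, by = 0.05)
  for (lam in c(0, 0.5, 1, 2)) {
    soft <- shrink_coefficients(w, lam, shrinkage_rule("soft"))
    hard <- shrink_coefficients(w, lam, shrinkage_rule("hard"))
    for (a in c(0, 0.25, 0.5, 0.75, 1)) {
      comp <- shrink_coefficients(w, lam, shrinkage_rule("compromise", a = a))
      impr <- shrink_coefficients(w, lam, shrinkage_rule("improved", a = a))
      # odd symmetry
      expect_equal(comp, -rev(comp))
      expect_equal(impr, -rev(impr))
      # never amplifies
      expect_true(all(abs(comp) <= abs(w) + 1e-12))
      expect_true(all(abs(impr) <= abs(w) + 1e-12))
      expect_true(all(abs(soft) <= abs(w) + 1e-12))
    }
    # limit identities: compromise interpolates hard (a=0) and soft (a=1);
    # improved collapses to soft at a=0
    expect_equal(shrink_coefficients(w, lam, shrinkage_rule("compromise", a = 1)), soft)
    expect_equal(shrink_coefficients(w, lam, shrinkage_rule("compromise", a = 0)), hard)
    expect_equal(shrink_coefficients(w, lam, shrinkage_rule("improved", a = 0)), soft)
    # soft is continuous at the threshold and vanishes there
    if (lam > 0) {
      eps <- 1e-9
      below <- shrink_coefficients(lam - eps, lam, shrinkage_rule("soft"))
      above <- shrink_coefficients(lam + eps, lam, shrinkage_rule("soft"))
      expect_lt(abs(above - below), 1e-8)
      expect_equal(shrink_coefficients(lam, lam, shrinkage_rule("soft")), 0)
    }
  }
})

test_that("sigma estimator implements MAD/0.674 and recovers a known noise level", {
  expect_equal(estimate_sigma(c(-0.674, 0.674, 0.674)), 1)
  expect_equal(estimate_sigma(matrix(0, 4, 4)), 0)
  x <- withr::with_seed(99, stats::rnorm(1e6))
  expect_equal(estimate_sigma(x), 1, tolerance = 0.01)
  expect_error(estimate_sigma(numeric(0)), "empty")
})

test_that("universal threshold follows sigma * sqrt(2 log N) and is monotone", {
  expect_equal(universal_threshold(0, 100), 0)
  expect_equal(universal_threshold(1, 1), 0)
  expect_equal(universal_threshold(2, 1024), 2 * sqrt(2 * log(1024)))
  expect_equal(universal_threshold(2, 1024), 7.44659, tolerance = 1e-5)
  tt <- sapply(c(1, 10, 100, 1000), function(n) universal_threshold(1, n))
  expect_true(all(diff(tt) >= 0))
  ss <- sapply(c(0, 0.5, 1, 2), function(s) universal_threshold(s, 256))
  expect_true(all(diff(ss) >= 0))
  expect_error(universal_threshold(-1, 10), "sigma")
  expect_error(universal_threshold(1, 0), "n_coeffs")
})

test_that("Bayes threshold matches sigma^2 / sigma_x with a degenerate kill branch", {
  expect_equal(bayes_threshold(c(1, 2, 3), 0), 0)
  # mean square exactly sigma^2 -> no detected signal -> max |subband|
  sb <- c(1, -1, 1, -1)
  expect_equal(bayes_threshold(sb, 1), 1)
  x <- withr::with_seed(42, stats::rnorm(1e6, sd = sqrt(4 + 1)))
  expect_equal(bayes_threshold(x, 1), 0.5, tolerance = 0.02 * 0.5 + 0.01)
  expect_error(bayes_threshold(numeric(0), 1), "empty")
})

test_that("decomposition-level shrinkage leaves the approximation band untouched and respects manual thresholds", {
  img <- random_image(64, seed = 5)
  dec <- wave_decompose(img, "db4", 2)
  rule0 <- shrinkage_rule("soft", selector = "manual", manual_lambda = 0)
  out0 <- shrink_decomposition(dec, rule0)
  expect_identical(out0$approximation, dec$approximation)
  expect_equal(out0$details, dec$details)
  # threshold above every detail magnitude kills all details
  big <- max(abs(unlist(dec$details))) + 1
  ruleB <- shrinkage_rule("hard", selector = "manual", manual_lambda = big)
  outB <- shrink_decomposition(dec, ruleB)
  expect_true(all(abs(unlist(outB$details)) == 0))
  approx_only <- dec
  for (l in 1:2) for (b in c("h", "v", "d")) {
    approx_only$details[[l]][[b]] <- 0 * approx_only$details[[l]][[b]]
  }
  expect_equal(wave_reconstruct(outB), wave_reconstruct(approx_only))
})

test_that("Bayes-selected soft shrinkage reduces MSE on the noisy phantom", {
  ph <- shepp_logan(128)
  rule <- shrinkage_rule("soft", selector = "bayes")
  gains <- sapply(1:10, function(s) {
    noisy <- add_gaussian_noise(ph, 0.04, seed = s)
    dec <- shrink_decomposition(wave_decompose(noisy, "db4", 3), rule)
    img_mse(ph, noisy) - img_mse(ph, clip01(wave_reconstruct(dec)))
  })
  expect_gt(mean(gains), 0)
  expect_true(all(gains > 0))
})
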