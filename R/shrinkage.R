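#' Shrinkage rule
#'
#' Describes how detail-band wavelet coefficients are thresholded: which
#' shrinkage function to apply and how the threshold `lambda` is chosen
#' per subband.
#'
#' Modes (with `s = sign(w)` and adjustment coefficient `a` in \[0, 1\]):
#' \describe{
#'   \item{hard}{`w` if `|w| >= lambda`, else 0 — keeps magnitudes, leaves
#'     a discontinuity at the threshold.}
#'   \item{soft}{`s * (|w| - lambda)` if `|w| >= lambda`, else 0 —
#'     continuous but biases every kept coefficient toward zero.}
#'   \item{compromise}{`s * (|w| - a * lambda)` if `|w| >= lambda`, else 0;
#'     `a = 1` reproduces soft, `a = 0` hard.}
#'   \item{improved}{`s * (|w| - (1 - a) * lambda)` if `|w| >= lambda`,
#'     else `a * w`: sub-threshold coefficients are attenuated rather than
#'     killed, retaining part of the weak signal; `a = 0` reproduces
#'     soft.  `improved_small = "constant"` switches the sub-threshold
#'     branch to the literal `s * a * lambda`.}
#' }
#'
#' Selectors: `"bayes"` (BayesShrink, `lambda = sigma^2 / sigma_x` per
#' subband), `"fixed_universal"` (`lambda = sigma * sqrt(2 log N)` with
#' `N` the subband size) and `"manual"` (a caller-supplied `lambda`).
#'
#' @param mode Shrinkage function, see Details.
#' @param a Adjustment coefficient in \[0, 1\] (compromise/improved).
#' @param selector Threshold selector.
#' @param manual_lambda Nonnegative threshold used when
#'   `selector = "manual"`.
#' @param improved_small Sub-threshold branch of the improved rule:
#'   `"attenuate"` (`a * w`, default) or `"constant"` (`sign(w) * a * lambda`).
#' @return An object of class `shrinkage_rule`.
#' @export
shrinkage_rule <- function(mode = c("improved", "soft", "hard", "compromise"),
                           a = 0.5,
                           selector = c("bayes", "fixed_universal", "manual"),
                           manual_lambda = NULL,
                           improved_small = c("attenuate", "constant")) {
  mode <- match.arg(mode)
  selector <- match.arg(selector)
  improved_small <- match.arg(improved_small)
  if (a < 0 || a > 1) stop("`a` must lie in [0, 1]", call. = FALSE)
  if (selector == "manual") {
    if (is.null(manual_lambda) || manual_lambda < 0) {
      stop("manual selector requires `manual_lambda` >= 0", call. = FALSE)
    }
  } else if (!is.null(manual_lambda)) {
    stop("`manual_lambda` only applies when selector = 'manual'", call. = FALSE)
  }
  structure(list(mode = mode, a = a, selector = selector,
                 manual_lambda = manual_lambda,
                 improved_small = improved_small),
            class = "shrinkage_rule")
}

#' @export
print.shrinkage_rule <- function(x, ...) {
  lam <- if (x$selector == "manual") sprintf(", lambda=%g", x$manual_lambda) else ""
  cat(sprintf("<shrinkage_rule> %s (a=%g), selector=%s%s\n",
              x$mode, x$a, x$selector, lam))
  invisible(x)
}

#' Apply a shrinkage function to coefficients
#'
#' Elementwise thresholding map; see [shrinkage_rule()] for the four
#' functional forms.  Ties at `|w| == lambda` take the keep/shrink
#' branch.
#'
#' @param w Numeric vector or matrix of wavelet coefficients.
#' @param lambda Nonnegative threshold.
#' @param rule A [shrinkage_rule()] (its selector is ignored here; only
#'   `mode`, `a` and `improved_small` matter).
#' @return Shrunk coefficients, same shape as `w`.
#' @examples
#' shrink_coefficients(c(-2, -0.5, 0.5, 2), 1, shrinkage_rule("soft"))
#' @export
shrink_coefficients <- function(w, lambda, rule = shrinkage_rule("soft")) {
  if (length(lambda) != 1L || is.na(lambda) || lambda < 0) {
    stop("`lambda` must be a single nonnegative number", call. = FALSE)
  }
  keep <- abs(w) >= lambda
  s <- sign(w)
  out <- switch(rule$mode,
    hard       = ifelse(keep, w, 0),
    soft       = ifelse(keep, s * (abs(w) - lambda), 0),
    compromise = ifelse(keep, s * (abs(w) - rule$a * lambda), 0),
    improved   = {
      small <- if (rule$improved_small == "attenuate") rule$a * w
               else s * rule$a * lambda
      ifelse(keep, s * (abs(w) - (1 - rule$a) * lambda), small)
    })
  if (is.matrix(w)) out <- matrix(out, nrow(w), ncol(w))
  out
}

#' Robust noise-level estimate from a detail band
#'
#' Median absolute coefficient of the finest diagonal band divided by
#' 0.674, the (rounded) normal consistency constant: under pure Gaussian
#' noise `median(|w|) ~ 0.6745 * sigma`, and the diagonal band of a
#' natural image is dominated by noise.
#'
#' @param coeffs Numeric matrix or vector of detail coefficients
#'   (typically the level-1 diagonal band).
#' @return Nonnegative noise standard deviation estimate.
#' @export
estimate_sigma <- function(coeffs) {
  if (length(coeffs) == 0L) stop("empty coefficient grid", call. = FALSE)
  median(abs(coeffs)) / 0.674
}

#' Universal (fixed) threshold
#'
#' Donoho's `lambda = sigma * sqrt(2 * log(N))` with the natural
#' logarithm; nondecreasing in both arguments.
#'
#' @param sigma Nonnegative noise standard deviation.
#' @param n_coeffs Signal scale `N >= 1` (number of coefficients).
#' @return Nonnegative threshold.
#' @export
universal_threshold <- function(sigma, n_coeffs) {
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (n_coeffs < 1) stop("`n_coeffs` must be >= 1", call. = FALSE)
  sigma * sqrt(2 * log(n_coeffs))
}

#' BayesShrink subband threshold
#'
#' Models subband coefficients as signal + noise with
#' `E[w^2] = sigma_x^2 + sigma^2` and returns `lambda = sigma^2 / sigma_x`
#' where `sigma_x = sqrt(max(mean(w^2) - sigma^2, 0))`.  When no signal
#' variance is detected (`sigma_x = 0`) the threshold is `max(|w|)`,
#' which zeroes the whole subband under any of the shrinkage modes'
#' kill branches.
#'
#' @param subband Numeric matrix or vector of detail coefficients.
#' @param sigma Nonnegative noise standard deviation.
#' @return Nonnegative threshold.
#' @export
bayes_threshold <- function(subband, sigma) {
  if (length(subband) == 0L) stop("empty subband", call. = FALSE)
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  sigma_x <- sqrt(max(mean(subband^2) - sigma^2, 0))
  if (sigma_x > 0) sigma^2 / sigma_x else max(abs(subband))
}

## Threshold for one subband under a rule.
select_lambda <- function(subband, rule, sigma) {
  switch(rule$selector,
    manual          = rule$manual_lambda,
    fixed_universal = universal_threshold(sigma, length(subband)),
    bayes           = bayes_threshold(subband, sigma))
}

#' Shrink every detail band of a decomposition
#'
#' Applies [shrink_coefficients()] to all detail subbands at all levels
#' with a per-subband threshold chosen by the rule's selector; the
#' approximation band is never touched.  The noise level `sigma` is
#' estimated once from the finest diagonal band (see [estimate_sigma()])
#' when not supplied.
#'
#' @param dec A `wave_decomposition`.
#' @param rule A [shrinkage_rule()].
#' @param sigma Optional noise standard deviation; estimated if `NULL`.
#' @return A new `wave_decomposition` with shrunk detail bands.
#' @export
shrink_decomposition <- function(dec, rule = shrinkage_rule(), sigma = NULL) {
  if (!inherits(dec, "wave_decomposition")) {
    stop("`dec` must be a wave_decomposition", call. = FALSE)
  }
  if (is.null(sigma)) sigma <- estimate_sigma(dec$details[[1]]$d)
  out <- dec
  for (l in seq_len(dec$levels)) {
    for (b in c("h", "v", "d")) {
      sb <- dec$details[[l]][[b]]
      lambda <- select_lambda(sb, rule, sigma)
      out$details[[l]][[b]] <- shrink_coefficients(sb, lambda, rule)
    }
  }
  out
}
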