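#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom dplyr group_by summarise arrange across all_of
#' @importFrom tidyr pivot_longer
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

## Map a benchmark noise level to a noise_spec under the package's
## reading of "noise proportion": sigma on the [0,1] intensity scale for
## gaussian/speckle, corrupted-pixel density for salt-and-pepper.
level_to_spec <- function(noise_kind, level, level_type, seed) {
  switch(noise_kind,
    gaussian = {
      v <- if (level_type == "variance") level else level^2
      noise_spec("gaussian", variance = v, seed = seed)
    },
    speckle = {
      v <- if (level_type == "variance") level else level^2
      noise_spec("speckle", variance = v, seed = seed)
    },
    salt_pepper = noise_spec("salt_pepper", density = level, seed = seed))
}

#' Benchmark denoisers over a grid of noise levels
#'
#' For every `(method, level, seed)` cell: generate the phantom (or use
#' a supplied clean image), inject noise, denoise, and score with MSE,
#' PSNR and SSIM against the clean image.  The noisy image for a given
#' `(level, seed)` is shared across methods, so the comparison is paired.
#' Fully deterministic given the seed list.
#'
#' @param noise_kind `"gaussian"`, `"salt_pepper"` or `"speckle"`.
#' @param levels Numeric vector of noise levels (meaning set by
#'   `level_type`).
#' @param methods Character vector of method names understood by
#'   [denoise_config()] (`"q1"`, `"q2"`, `"q4"`, `"q5"`, `"identity"`),
#'   or names of entries in `configs`.
#' @param seeds Integer vector of noise seeds; one replicate per seed.
#' @param size Phantom side length when `image` is `NULL`.
#' @param image Optional clean reference image; defaults to
#'   [shepp_logan()] at `size`.
#' @param level_type How to read `levels`: `"variance"` or
#'   `"proportion"` (= noise standard deviation) for gaussian/speckle;
#'   ignored for salt_pepper (always a pixel density).  Defaults to
#'   `"variance"` for gaussian and `"proportion"` for speckle.
#' @param configs Optional named list of [denoise_config()] objects (or
#'   functions `function(img) -> img` for external methods) keyed by
#'   method name, overriding the defaults.
#' @param verbose Emit one structured log line per cell to stderr.
#' @return An object of class `ct_benchmark`; see [tidy.ct_benchmark()],
#'   [glance.ct_benchmark()], [autoplot.ct_benchmark()] and
#'   [export_grid()].
#' @examples
#' b <- run_benchmark("gaussian", levels = 0.04, methods = c("q1", "q5"),
#'                    seeds = 1:2, size = 64)
#' tidy(b)
#' @export
run_benchmark <- function(noise_kind = c("gaussian", "salt_pepper", "speckle"),
                          levels = c(0.02, 0.04, 0.06, 0.08, 0.10),
                          methods = c("q1", "q2", "q4", "q5"),
                          seeds = default_benchmark_seeds(),
                          size = 512L, image = NULL,
                          level_type = NULL, configs = NULL,
                          verbose = FALSE) {
  noise_kind <- match.arg(noise_kind)
  if (length(methods) < 1L) stop("need at least one method", call. = FALSE)
  if (length(levels) < 1L) stop("need at least one noise level", call. = FALSE)
  if (length(seeds) < 1L) stop("need at least one seed", call. = FALSE)
  if (is.null(level_type)) {
    level_type <- if (noise_kind == "gaussian") "variance" else "proportion"
  }
  clean <- if (is.null(image)) shepp_logan(size) else check_image(image, unit_range = TRUE)
  rows <- vector("list", length(levels) * length(seeds) * length(methods))
  k <- 0L
  for (lev in levels) {
    for (s in seeds) {
      noisy <- add_noise(clean, level_to_spec(noise_kind, lev, level_type, s))
      for (mth in methods) {
        t0 <- proc.time()[["elapsed"]]
        out <- tryCatch({
          cfg <- if (!is.null(configs) && mth %in% names(configs)) configs[[mth]] else mth
          if (is.function(cfg)) clip01(cfg(noisy)) else denoise(noisy, cfg)
        }, error = function(e) {
          stop(sprintf("benchmark cell failed (method=%s, level=%g, seed=%d): %s",
                       mth, lev, s, conditionMessage(e)), call. = FALSE)
        })
        q <- quality_report(clean, out)
        k <- k + 1L
        rows[[k]] <- tibble::tibble(noise_kind = noise_kind, level = lev,
                                    method = mth, seed = as.integer(s),
                                    mse = q$mse, psnr = q$psnr, ssim = q$ssim)
        if (verbose) {
          message(sprintf(
            "benchmark method=%s level=%g seed=%d mse=%.6g psnr=%.4f ssim=%.4f elapsed=%.2fs",
            mth, lev, s, q$mse, q$psnr, q$ssim,
            proc.time()[["elapsed"]] - t0))
        }
      }
    }
  }
  per_seed <- dplyr::bind_rows(rows)
  results <- per_seed |>
    tidyr::pivot_longer(c("mse", "psnr", "ssim"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$noise_kind, .data$level, .data$method, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     n_seeds = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$level, .data$method, .data$metric)
  structure(list(results = results, per_seed = per_seed,
                 noise_kind = noise_kind, level_type = level_type,
                 levels = levels, methods = methods,
                 seeds = as.integer(seeds), size = nrow(clean)),
            class = "ct_benchmark")
}

#' Default benchmark replication seeds
#'
#' Ten fixed integers used for all published benchmark tables.
#' @return Integer vector of length 10.
#' @export
default_benchmark_seeds <- function() {
  c(101L, 202L, 303L, 404L, 505L, 606L, 707L, 808L, 909L, 1010L)
}

#' @export
print.ct_benchmark <- function(x, ...) {
  cat(sprintf("<ct_benchmark> %s noise (%s levels), %d method(s) x %d level(s) x %d seed(s), %dx%d phantom\n",
              x$noise_kind, x$level_type, length(x$methods), length(x$levels),
              length(x$seeds), x$size, x$size))
  print(x$results, n = 20)
  invisible(x)
}

#' Tidy a benchmark grid
#'
#' @param x A `ct_benchmark`.
#' @param per_seed Return the per-seed rows instead of the
#'   mean/sd aggregation.
#' @param ... Unused.
#' @return A tibble; one row per (level, method, metric) with `mean`,
#'   `sd`, `n_seeds`, or per (level, method, seed) when
#'   `per_seed = TRUE`.
#' @export
tidy.ct_benchmark <- function(x, per_seed = FALSE, ...) {
  if (per_seed) x$per_seed else x$results
}

#' One-line benchmark summary
#'
#' @param x A `ct_benchmark`.
#' @param ... Unused.
#' @return A one-row tibble: grid dimensions and the method with the
#'   highest overall mean PSNR.
#' @export
glance.ct_benchmark <- function(x, ...) {
  psnr <- x$results[x$results$metric == "psnr", ]
  overall <- psnr |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(mean_psnr = mean(.data$mean), .groups = "drop")
  best <- overall$method[which.max(overall$mean_psnr)]
  tibble::tibble(noise_kind = x$noise_kind,
                 n_levels = length(x$levels), n_methods = length(x$methods),
                 n_seeds = length(x$seeds), size = x$size,
                 best_method = best,
                 best_mean_psnr = max(overall$mean_psnr))
}

#' Plot a benchmark grid
#'
#' Mean metric (with +/- 1 sd ribbon) against noise level, one line per
#' method.
#'
#' @param object A `ct_benchmark`.
#' @param metric `"psnr"`, `"ssim"` or `"mse"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ct_benchmark <- function(object, metric = "psnr", ...) {
  stopifnot(metric %in% c("psnr", "ssim", "mse"))
  d <- object$results[object$results$metric == metric, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$level, y = .data$mean,
                                  colour = .data$method, fill = .data$method)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("%s noise level (%s)", object$noise_kind,
                              object$level_type),
                  y = toupper(metric),
                  title = sprintf("Denoising performance on the %dx%d phantom",
                                  object$size, object$size)) +
    ggplot2::theme_minimal()
}

#' Export a benchmark grid to CSV
#'
#' Tidy layout, one row per (noise_kind, level, method, metric) with
#' columns `noise_kind, level, method, metric, mean, sd, n_seeds` in
#' that order.  Refuses to write an incomplete grid (any requested
#' (method, level) cell missing or non-finite mean).
#'
#' @param x A `ct_benchmark`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_grid <- function(x, path) {
  if (!inherits(x, "ct_benchmark")) stop("`x` must be a ct_benchmark", call. = FALSE)
  res <- x$results
  expected <- length(x$levels) * length(x$methods) * 3L
  if (nrow(res) != expected || any(!is.finite(res$mean))) {
    stop("benchmark grid is incomplete; refusing to write", call. = FALSE)
  }
  res <- res[, c("noise_kind", "level", "method", "metric", "mean", "sd", "n_seeds")]
  utils::write.csv(res, path, row.names = FALSE)
  invisible(path)
}

#' Read a benchmark grid CSV back into a tibble
#'
#' @param path CSV written by [export_grid()].
#' @return A tibble with the exported columns.
#' @export
read_grid <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
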