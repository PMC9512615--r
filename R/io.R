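#' Read a grayscale image
#'
#' Supports PNG (8/16-bit) and TIFF (including 32-bit float).  Intensities
#' are returned on \[0, 1\]; multi-channel rasters are collapsed to their
#' channel mean.  DICOM is not supported and raises a format error.
#'
#' @param path Image file; format inferred from the extension.
#' @return Numeric matrix in \[0, 1\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    dcm = ,
    dicom = stop("DICOM input is not supported; convert to PNG or TIFF first",
                 call. = FALSE),
    stop(sprintf("unsupported image format '.%s' (use PNG or TIFF)", ext),
         call. = FALSE))
  if (length(dim(img)) == 3L) {
    img <- apply(img, c(1, 2), mean)
  }
  clip01(img)
}

#' Write a grayscale image
#'
#' PNG output is 8-bit (quantized to the 256-level lattice); TIFF output
#' is 16-bit integer or lossless 32-bit float.
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param path Output file; format inferred from the extension.
#' @param bits TIFF bit depth: 32 (float, lossless round trip, default)
#'   or 16 (integer). Ignored for PNG.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bits = 32L) {
  check_image(img, min_dim = 1L, unit_range = TRUE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = {
      if (!bits %in% c(16L, 32L)) stop("`bits` must be 16 or 32", call. = FALSE)
      tiff::writeTIFF(img, path, bits.per.sample = as.integer(bits),
                      reduce = FALSE)
    },
    stop(sprintf("unsupported output format '.%s' (use PNG or TIFF)", ext),
         call. = FALSE))
  invisible(path)
}
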