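# Image reading and region-of-interest colour extraction, mimicking the
# ImageJ step that turns a cuvette photograph into mean R, G, B and
# weighted-intensity values.

#' Read an 8-bit RGB image
#'
#' Decodes a PNG or JPEG file (detected from its magic bytes) into a
#' `rows x cols x 3` numeric array on the 0-255 scale. Greyscale images are
#' expanded to three equal channels; an alpha channel is discarded.
#'
#' @param path Path to a PNG or JPEG file.
#' @return Numeric array of dimension `c(rows, cols, 3)`, values in
#'   `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  magic <- readBin(path, "raw", n = 3)
  img <- if (length(magic) >= 3 &&
             identical(magic[1:2], as.raw(c(0xff, 0xd8)))) {
    jpeg::readJPEG(path)
  } else if (length(magic) >= 3 &&
             identical(magic, as.raw(c(0x89, 0x50, 0x4e)))) {
    png::readPNG(path)
  } else {
    stop("'", path, "' is neither a PNG nor a JPEG file")
  }
  if (length(dim(img)) == 2) {                       # greyscale
    img <- array(rep(img, 3), dim = c(dim(img), 3))
  } else if (dim(img)[3] == 2) {                     # grey + alpha
    img <- array(rep(img[, , 1], 3), dim = c(dim(img)[1:2], 3))
  } else if (dim(img)[3] >= 4) {                     # drop alpha
    img <- img[, , 1:3, drop = FALSE]
  }
  img * 255
}

#' Rectangular region of interest
#'
#' Coordinates are 0-based with half-open extents: the region covers pixel
#' columns `x0 .. x0 + width - 1` and rows `y0 .. y0 + height - 1`.
#'
#' @param x0,y0 Pixel offsets of the top-left corner (0-based; `x` indexes
#'   columns, `y` rows).
#' @param width,height Extent in pixels (>= 1).
#' @return An object of class `roi`.
#' @export
roi <- function(x0, y0, width, height) {
  if (width < 1 || height < 1) stop("roi width and height must be >= 1")
  if (x0 < 0 || y0 < 0) stop("roi offsets must be >= 0")
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width), height = as.integer(height)),
            class = "roi")
}

#' Default centred ROI: a square covering 25 % of the shorter image side
#' @noRd
default_roi <- function(image) {
  d <- dim(image)
  side <- max(1L, floor(0.25 * min(d[1], d[2])))
  roi(x0 = floor((d[2] - side) / 2), y0 = floor((d[1] - side) / 2),
      width = side, height = side)
}

#' Mean channel values over a region of interest
#'
#' Arithmetic per-channel means over the ROI pixels, kept as unrounded
#' reals, plus the weighted intensity.
#'
#' @param image Array from [read_image()] (`rows x cols x 3`, 0-255).
#' @param region A [roi()], or `NULL` for the default centred square
#'   covering 25 % of the shorter image side.
#' @return An object of class `colour_summary`: list with `r_mean`,
#'   `g_mean`, `b_mean`, `intensity`, `n_pixels`.
#' @export
roi_mean <- function(image, region = NULL) {
  d <- dim(image)
  if (is.null(region)) region <- default_roi(image)
  stopifnot(inherits(region, "roi"))
  if (region$x0 + region$width > d[2] || region$y0 + region$height > d[1])
    stop(sprintf(
      "roi [x0=%d, y0=%d, w=%d, h=%d] exceeds image bounds (%d x %d)",
      region$x0, region$y0, region$width, region$height, d[2], d[1]))
  rows <- (region$y0 + 1):(region$y0 + region$height)
  cols <- (region$x0 + 1):(region$x0 + region$width)
  sub <- image[rows, cols, , drop = FALSE]
  m <- apply(sub, 3, mean)
  structure(list(r_mean = m[1], g_mean = m[2], b_mean = m[3],
                 intensity = weighted_intensity(m[1], m[2], m[3]),
                 n_pixels = region$width * region$height),
            class = "colour_summary")
}

#' @export
print.colour_summary <- function(x, ...) {
  cat(sprintf("ROI colour summary (%d px): R %.2f  G %.2f  B %.2f  I %.2f\n",
              x$n_pixels, x$r_mean, x$g_mean, x$b_mean, x$intensity))
  invisible(x)
}

#' Weighted intensity of an RGB triple
#'
#' Luminance-style weighted mean using the Rec. 601 luma weights
#' `0.299 R + 0.587 G + 0.114 B` — ImageJ's "weighted RGB" conversion.
#' For equal channels the intensity equals the channel value.
#'
#' @param r_mean,g_mean,b_mean Channel means in `[0, 255]`; vectorized.
#' @return Weighted intensity on the 0-255 scale.
#' @examples
#' weighted_intensity(100, 100, 100)  # 100
#' @export
weighted_intensity <- function(r_mean, g_mean, b_mean) {
  vals <- c(r_mean, g_mean, b_mean)
  if (any(vals < 0 | vals > 255))
    stop("channel means must lie in [0, 255]")
  0.299 * r_mean + 0.587 * g_mean + 0.114 * b_mean
}

#' Extract ROI colour summaries from image files
#'
#' Applies [read_image()] and [roi_mean()] to each file and stacks the
#' summaries into a table (one row per image), the form consumed by the
#' calibration functions.
#'
#' @param paths Character vector of image paths.
#' @param region A [roi()] applied to every image, or `NULL` for the
#'   per-image default.
#' @return `data.frame` with columns `image`, `r_mean`, `g_mean`, `b_mean`,
#'   `intensity`, `n_pixels`.
#' @export
extract_images <- function(paths, region = NULL) {
  rows <- lapply(paths, function(p) {
    s <- roi_mean(read_image(p), region)
    data.frame(image = p, r_mean = s$r_mean, g_mean = s$g_mean,
               b_mean = s$b_mean, intensity = s$intensity,
               n_pixels = s$n_pixels)
  })
  do.call(rbind, rows)
}
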