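#' Raster images and binary masks
#'
#' A `raster_image` is an 8-bit intensity grid: a numeric `height x width`
#' matrix (single channel) or a `height x width x 3` array (RGB), values in
#' \[0, 255\], stored row-major-compatible as ordinary R matrices/arrays
#' (rows = image rows).  A `binary_image` is a logical matrix of the same
#' layout with `TRUE` marking foreground pixels.
#'
#' @param data numeric matrix (grayscale) or `h x w x 3` array (RGB) with
#'   values in \[0, 255\].
#' @return `raster_image()` returns a validated object of class
#'   `"raster_image"`.
#' @examples
#' img <- raster_image(matrix(0, 16, 16))
#' dim(img)
#' @export
raster_image <- function(data) {
  if (is.logical(data)) data <- data * 255
  if (!is.numeric(data)) stop("image data must be numeric", call. = FALSE)
  d <- dim(data)
  if (is.null(d) || !(length(d) == 2L || (length(d) == 3L && d[3] == 3L)))
    stop("image data must be a matrix or an h x w x 3 array", call. = FALSE)
  if (d[1] < 3L || d[2] < 3L)
    stop("image must be at least 3 x 3 pixels", call. = FALSE)
  if (anyNA(data) || min(data) < 0 || max(data) > 255)
    stop("intensities must lie in [0, 255]", call. = FALSE)
  structure(data, class = "raster_image")
}

#' @rdname raster_image
#' @param mask logical matrix, `TRUE` = foreground.
#' @export
binary_image <- function(mask) {
  if (is.numeric(mask)) {
    dm <- dim(mask)
    mask <- mask > 0
    dim(mask) <- dm
  }
  if (!is.logical(mask) || length(dim(mask)) != 2L)
    stop("mask must be a logical matrix", call. = FALSE)
  if (anyNA(mask)) stop("mask must not contain NA", call. = FALSE)
  structure(mask, class = "binary_image")
}

#' @rdname raster_image
#' @param x object to test or convert.
#' @export
is_raster_image <- function(x) inherits(x, "raster_image")

#' @rdname raster_image
#' @export
is_binary_image <- function(x) inherits(x, "binary_image")

img_channels <- function(img) if (length(dim(img)) == 3L) 3L else 1L

img_dims <- function(img) dim(img)[1:2]

#' Convert an image to single-channel luma
#'
#' RGB images are reduced with the Rec. 601 luma weights
#' (0.299 R + 0.587 G + 0.114 B); grayscale images pass through.
#'
#' @param img a [raster_image()].
#' @return numeric matrix of intensities in \[0, 255\] (bare matrix, not a
#'   `raster_image`).
#' @export
img_gray <- function(img) {
  if (length(dim(img)) == 3L) {
    g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  } else {
    g <- img
  }
  m <- unclass(g)
  dim(m) <- dim(g)[1:2]
  m
}

#' Read and write images
#'
#' PNG, TIFF and JPEG are supported (format inferred from the file
#' extension).  Images are returned as [raster_image()] objects with 8-bit
#' intensities.
#'
#' @param path file path.
#' @return `read_image()` returns a [raster_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path, call. = FALSE)
  x <- EBImage::readImage(path)
  a <- EBImage::imageData(x)
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] >= 3L) {
      arr <- array(0, c(dim(a)[2], dim(a)[1], 3L))
      for (k in 1:3) arr[, , k] <- t(a[, , k])
      a <- arr
    } else {
      a <- t(a[, , 1])
    }
  } else {
    a <- t(a)
  }
  raster_image(round(a * 255))
}

#' @rdname read_image
#' @param img a [raster_image()] or [binary_image()].
#' @export
write_image <- function(img, path) {
  if (is_binary_image(img)) img <- raster_image(unclass(img) * 255)
  a <- unclass(img) / 255
  x <- if (length(dim(a)) == 3L) {
    arr <- array(0, c(dim(a)[2], dim(a)[1], 3L))
    for (k in 1:3) arr[, , k] <- t(a[, , k])
    EBImage::Image(arr, colormode = "Color")
  } else {
    EBImage::Image(t(a))
  }
  EBImage::writeImage(x, path)
  invisible(path)
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<raster_image %d x %d, %d channel%s, range [%g, %g]>\n",
              d[1], d[2], img_channels(x), if (img_channels(x) > 1) "s" else "",
              min(x), max(x)))
  invisible(x)
}

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("<binary_image %d x %d, %d foreground px (%.1f%%)>\n",
              nrow(x), ncol(x), sum(x), 100 * mean(x)))
  invisible(x)
}

# EBImage round-trips: EBImage stores (x, y) = (col, row), so transpose.
as_ebimage_mask <- function(mask) EBImage::Image(t(unclass(mask) * 1))

from_ebimage <- function(x) t(EBImage::imageData(x))
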