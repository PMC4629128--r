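#' Preprocessing: smoothing and denoising
#'
#' Optional smoothing steps applied before segmentation.  All operators use
#' reflect padding at the image border (no dark halos that would seed
#' spurious segmentation boundaries), preserve the image's shape and channel
#' count, and never produce values outside the input's intensity range.
#' A kernel of 1 (or `strength = 0`) is the identity.
#'
#' * `gaussian_blur()`: separable Gaussian; when `sigma` is `NULL` it is
#'   derived from the kernel size as `0.3 * ((kernel - 1) / 2 - 1) + 0.8`,
#'   the convention of the common library default.
#' * `median_blur()`: square-window median.
#' * `bilateral_filter()`: edge-preserving range/domain filter.
#' * `denoise_nlmeans()`: non-local means (patch 7, search window 21);
#'   `strength` is the filtering parameter h in intensity units.
#'
#' @param img a [raster_image()].
#' @param kernel odd window size in pixels (>= 1).
#' @param sigma Gaussian standard deviation in pixels, or `NULL` to derive
#'   from `kernel`.
#' @return a [raster_image()] of the same shape.
#' @examples
#' img <- raster_image(matrix(c(rep(0, 128), rep(200, 128)), 16, 16))
#' blurred <- gaussian_blur(img, 5, 1)
#' range(blurred)
#' @export
gaussian_blur <- function(img, kernel = 5L, sigma = NULL) {
  check_kernel(kernel)
  if (kernel == 1L) return(img)
  if (is.null(sigma)) sigma <- 0.3 * ((kernel - 1) * 0.5 - 1) + 0.8
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  k <- exp(-((seq_len(kernel) - (kernel + 1) / 2)^2) / (2 * sigma^2))
  k <- k / sum(k)
  apply_channels(img, function(m) sepconv_reflect_cpp(m, k))
}

#' @rdname gaussian_blur
#' @export
median_blur <- function(img, kernel = 5L) {
  check_kernel(kernel)
  if (kernel == 1L) return(img)
  apply_channels(img, function(m) median_filter_cpp(m, as.integer(kernel)))
}

#' @rdname gaussian_blur
#' @param diameter window diameter in pixels (odd).
#' @param sigma_color range sigma in intensity units.
#' @param sigma_space domain sigma in pixels.
#' @export
bilateral_filter <- function(img, diameter = 9L, sigma_color = 75,
                             sigma_space = 75) {
  check_kernel(diameter)
  if (sigma_color <= 0 || sigma_space <= 0)
    stop("sigmas must be positive", call. = FALSE)
  if (diameter == 1L) return(img)
  apply_channels(img, function(m)
    bilateral_cpp(m, as.integer(diameter), sigma_color, sigma_space))
}

#' @rdname gaussian_blur
#' @param strength filtering strength h (intensity units); 0 is the identity.
#' @export
denoise_nlmeans <- function(img, strength = 10) {
  if (strength < 0) stop("strength must be >= 0", call. = FALSE)
  if (strength == 0) return(img)
  apply_channels(img, function(m) nlmeans_cpp(m, strength, 7L, 21L))
}

check_kernel <- function(k) {
  if (length(k) != 1L || is.na(k) || k < 1 || k %% 2 == 0)
    stop("kernel size must be an odd integer >= 1", call. = FALSE)
  invisible(k)
}

apply_channels <- function(img, f) {
  lo <- min(img); hi <- max(img)
  clamp <- function(m) pmin(pmax(m, lo), hi)
  if (length(dim(img)) == 3L) {
    out <- unclass(img)
    for (k in 1:3) out[, , k] <- clamp(f(unclass(img)[, , k]))
    raster_image(out)
  } else {
    m <- unclass(img); dim(m) <- dim(img)[1:2]
    raster_image(clamp(f(m)))
  }
}
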