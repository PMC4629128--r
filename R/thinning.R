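#' Guo-Hall thinning
#'
#' Reduces a segmented foreground to a one-pixel-wide skeleton by iterating
#' the two-subiteration Guo-Hall parallel deletion operator until a fixed
#' point.  The operator preserves the 8-connectivity of the foreground and
#' the 4-connectivity of the background, only ever deletes pixels (the
#' skeleton is a subset of the input), and is idempotent.  For straight
#' strokes the skeleton lies on the stroke's geometric centreline, which is
#' what justifies reading stroke widths off the distance transform at
#' skeleton pixels.  The image border is implicitly padded with background.
#'
#' @param segmented a [binary_image()].
#' @return a `skeleton`: a [binary_image()] that also carries its source
#'   segmentation as attribute `"source"`.
#' @examples
#' bar <- matrix(FALSE, 9, 15); bar[4:6, 3:13] <- TRUE
#' sk <- guo_hall_thin(binary_image(bar))
#' sum(sk)  # single-pixel midline
#' @export
guo_hall_thin <- function(segmented) {
  stopifnot(is_binary_image(segmented))
  m <- unclass(segmented)
  thin <- gh_thin_cpp(m)
  structure(thin, class = c("skeleton", "binary_image"),
            source = binary_image(m))
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton %d x %d, %d px>\n", nrow(x), ncol(x), sum(x)))
  invisible(x)
}

skeleton_source <- function(skel) attr(skel, "source")

as_skeleton <- function(mask, source = NULL) {
  structure(unclass(mask), class = c("skeleton", "binary_image"),
            source = source)
}
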