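#' Marker images for guided segmentation
#'
#' A `marker_image` labels every pixel `sure-foreground`, `sure-background`
#' or `unknown`; the marker-guided methods ([seg_watershed()],
#' [seg_grabcut()]) grow a segmentation from the two sure classes.
#' Internally the grid is an integer matrix: 0 = unknown, 1 =
#' sure-background, 2 = sure-foreground.
#'
#' `marker_erosion()` takes a rough binary guess and erodes it (3 x 3
#' square structuring element) to obtain the sure foreground; the sure
#' background is the complement of the guess dilated the same number of
#' times.  `marker_distance_transform()` instead keeps the pixels whose
#' Euclidean distance-transform value reaches `fraction` of the maximum.
#' `marker_adaptive()` applies `marker_erosion()` to an adaptive-threshold
#' guess of the image.
#'
#' @param guess a [binary_image()] with a rough foreground estimate.
#' @param iterations number of 3 x 3 erosion/dilation rounds.
#' @return a `marker_image`.
#' @examples
#' sq <- matrix(FALSE, 20, 20); sq[5:16, 5:16] <- TRUE
#' m <- marker_erosion(binary_image(sq), 1)
#' table(unclass(m))
#' @export
marker_erosion <- function(guess, iterations = 2L) {
  stopifnot(is_binary_image(guess))
  if (!any(guess)) stop("marker guess is empty", call. = FALSE)
  fg <- morph_iter(guess, "erode", iterations)
  if (!any(fg))
    stop(sprintf(
      "degenerate marker: sure-foreground empty after %d erosion(s)",
      iterations), call. = FALSE)
  bg <- !morph_iter(guess, "dilate", iterations)
  new_marker(fg, bg, dim(guess))
}

#' @rdname marker_erosion
#' @param fraction ratio in (0, 1): sure foreground keeps pixels whose
#'   distance-transform value is at least `fraction` times the maximum.
#' @export
marker_distance_transform <- function(guess, fraction = 0.7,
                                      iterations = 2L) {
  stopifnot(is_binary_image(guess))
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie in (0, 1)", call. = FALSE)
  if (!any(guess)) stop("marker guess is empty", call. = FALSE)
  dt <- distance_map(guess)
  fg <- dt >= fraction * max(dt)
  if (!any(fg))
    stop(sprintf(
      "degenerate marker: sure-foreground empty at fraction %.2f", fraction),
      call. = FALSE)
  bg <- !morph_iter(guess, "dilate", iterations)
  new_marker(fg, bg, dim(guess))
}

#' @rdname marker_erosion
#' @param img a [raster_image()].
#' @inheritParams seg_adaptive
#' @export
marker_adaptive <- function(img, block = 51L, offset = 10,
                            iterations = 2L, invert = FALSE) {
  marker_erosion(seg_adaptive(img, block = block, offset = offset,
                              invert = invert), iterations = iterations)
}

new_marker <- function(fg, bg, d) {
  m <- matrix(0L, d[1], d[2])
  m[bg] <- 1L
  m[fg] <- 2L
  structure(m, class = "marker_image")
}

#' @export
print.marker_image <- function(x, ...) {
  cat(sprintf("<marker_image %d x %d: %d sure-fg, %d sure-bg, %d unknown>\n",
              nrow(x), ncol(x), sum(x == 2L), sum(x == 1L), sum(x == 0L)))
  invisible(x)
}

morph_iter <- function(mask, op, iterations) {
  stopifnot(iterations >= 0)
  kern <- EBImage::makeBrush(3L, shape = "box")
  x <- as_ebimage_mask(mask)
  f <- if (op == "erode") EBImage::erode else EBImage::dilate
  for (i in seq_len(iterations)) x <- f(x, kern)
  binary_image(from_ebimage(x) > 0)
}

#' Euclidean distance transform
#'
#' Per-pixel Euclidean distance of each foreground pixel to the nearest
#' background pixel (zero on background), in pixels.
#'
#' @param mask a [binary_image()].
#' @return numeric matrix of distances.
#' @export
distance_map <- function(mask) {
  stopifnot(is_binary_image(mask))
  if (!any(mask)) return(matrix(0, nrow(mask), ncol(mask)))
  from_ebimage(EBImage::distmap(as_ebimage_mask(mask)))
}

#' Segmentation methods
#'
#' Interchangeable algorithms separating the network foreground from the
#' background.  The foreground is the brighter phase by default; set
#' `invert = TRUE` for dark-on-light structures.  All methods are
#' deterministic.
#'
#' * `seg_otsu()`: global threshold maximizing the between-class variance
#'   of the gray histogram; a constant image yields an empty foreground.
#' * `seg_adaptive()`: a pixel is foreground iff its intensity exceeds the
#'   mean of its `block x block` window by more than `offset`, which makes
#'   the result invariant to smooth background gradients.
#' * `seg_watershed()`: marker-controlled watershed flooding the
#'   morphological gradient of the blurred luma from the marker seeds.
#' * `seg_grabcut()`: iterative graph-cut segmentation (Gaussian mixture
#'   appearance models re-estimated each round, minimum cut on the
#'   8-neighbourhood grid); sure marker classes stay pinned.
#'
#' @param img a [raster_image()].
#' @param invert if `TRUE` the darker phase is taken as foreground.
#' @return a [binary_image()] (`TRUE` = structure).
#' @examples
#' m <- matrix(20, 32, 32); m[15:18, 5:28] <- 220
#' seg <- seg_otsu(raster_image(m))
#' sum(seg)
#' @export
seg_otsu <- function(img, invert = FALSE) {
  g <- img_gray(img)
  if (min(g) == max(g)) return(binary_image(matrix(FALSE, nrow(g), ncol(g))))
  thr <- EBImage::otsu(EBImage::Image(t(g / 255)), range = c(0, 1),
                       levels = 256L) * 255
  binary_image(if (invert) g < thr else g > thr)
}

#' @rdname seg_otsu
#' @param block odd local-window size in pixels (>= 3).
#' @param offset intensity margin over the local mean required for
#'   foreground.
#' @export
seg_adaptive <- function(img, block = 11L, offset = 2, invert = FALSE) {
  check_kernel(block)
  if (block < 3L) stop("block must be >= 3", call. = FALSE)
  g <- img_gray(img)
  if (block > min(dim(g)))
    stop("block is larger than the image", call. = FALSE)
  box <- rep(1 / block, block)
  mu <- sepconv_reflect_cpp(g, box)
  binary_image(if (invert) g < mu - offset else g > mu + offset)
}

#' @rdname seg_otsu
#' @param marker a `marker_image` (see [marker_erosion()]).
#' @export
seg_watershed <- function(img, marker) {
  stopifnot(inherits(marker, "marker_image"))
  if (!any(marker == 2L) || !any(marker == 1L))
    stop("degenerate marker: both seed classes are required", call. = FALSE)
  g <- img_gray(gaussian_blur(raster_image(img_gray(img)), 5L))
  kern <- EBImage::makeBrush(3L, shape = "box")
  eb <- EBImage::Image(t(g / 255))
  grad <- from_ebimage(EBImage::dilate(eb, kern) - EBImage::erode(eb, kern))
  lab <- watershed_flood_cpp(grad, unclass(marker))
  binary_image(lab == 2L)
}

#' @rdname seg_otsu
#' @param iterations number of GrabCut refinement rounds (>= 1).
#' @param k number of Gaussian mixture components per side.
#' @param gamma smoothness weight of the pairwise term.
#' @export
seg_grabcut <- function(img, marker, iterations = 5L, k = 5L, gamma = 50) {
  stopifnot(inherits(marker, "marker_image"))
  if (iterations < 1L) stop("iterations must be >= 1", call. = FALSE)
  if (!any(marker == 2L) || !any(marker == 1L))
    stop("degenerate marker: both seed classes are required", call. = FALSE)
  d <- img_dims(img)
  n <- prod(d)
  z <- if (img_channels(img) == 3L) {
    cbind(as.vector(unclass(img)[, , 1]), as.vector(unclass(img)[, , 2]),
          as.vector(unclass(img)[, , 3]))
  } else {
    matrix(as.vector(img_gray(img)), ncol = 1L)
  }
  pin_fg <- as.vector(marker == 2L)
  pin_bg <- as.vector(marker == 1L)
  free <- !(pin_fg | pin_bg)
  alpha <- pin_fg | free                      # initial: unknown counts as fg
  if (!any(free)) {
    out <- matrix(pin_fg, d[1], d[2])
    return(binary_image(out))
  }

  nb <- grid_neighbors(d[1], d[2])
  dz2 <- rowSums((z[nb$a, , drop = FALSE] - z[nb$b, , drop = FALSE])^2)
  beta <- 1 / (2 * max(mean(dz2), 1e-8))
  w_pair <- gamma * exp(-beta * dz2) / nb$dist
  big <- 1e9

  for (it in seq_len(iterations)) {
    u_fg <- gmm_neglog(z, alpha, k)
    u_bg <- gmm_neglog(z, !alpha, k)
    cap_s <- u_bg                              # cut S-i  =>  i is background
    cap_t <- u_fg                              # cut i-T  =>  i is foreground
    cap_s[pin_fg] <- big; cap_t[pin_fg] <- 0
    cap_s[pin_bg] <- 0;   cap_t[pin_bg] <- big
    src <- n + 1L; snk <- n + 2L
    edges <- rbind(cbind(rep(src, n), seq_len(n)),
                   cbind(seq_len(n), rep(snk, n)),
                   cbind(nb$a, nb$b))
    caps <- c(cap_s, cap_t, w_pair)
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    cut <- igraph::min_cut(g, source = src, target = snk, capacity = caps,
                           value.only = FALSE)
    fg_side <- rep(FALSE, n + 2L)
    fg_side[as.integer(cut$partition1)] <- TRUE
    if (!fg_side[src]) fg_side <- !fg_side
    new_alpha <- fg_side[seq_len(n)]
    new_alpha[pin_fg] <- TRUE
    new_alpha[pin_bg] <- FALSE
    if (identical(new_alpha, alpha) && it > 1L) break
    alpha <- new_alpha
  }
  binary_image(matrix(alpha, d[1], d[2]))
}

# 8-neighbourhood pixel pairs of an nr x nc grid (each pair once), linear
# column-major indices; dist is the Euclidean step length.
grid_neighbors <- function(nr, nc) {
  idx <- matrix(seq_len(nr * nc), nr, nc)
  a <- c(); b <- c(); dist <- c()
  add <- function(i, j, d) { a <<- c(a, i); b <<- c(b, j); dist <<- c(dist, rep(d, length(i))) }
  add(as.vector(idx[-nr, ]), as.vector(idx[-1, ]), 1)            # vertical
  add(as.vector(idx[, -nc]), as.vector(idx[, -1]), 1)            # horizontal
  add(as.vector(idx[-nr, -nc]), as.vector(idx[-1, -1]), sqrt(2)) # diag \
  add(as.vector(idx[-1, -nc]), as.vector(idx[-nr, -1]), sqrt(2)) # diag /
  list(a = a, b = b, dist = dist)
}

# Negative log-likelihood of each pixel colour under a Gaussian mixture
# fitted to the pixels of the given side.  Deterministic: k-means is
# initialised from luminance quantiles.
gmm_neglog <- function(z, side, k) {
  zs <- z[side, , drop = FALSE]
  if (nrow(zs) == 0L) return(rep(50, nrow(z)))
  lum <- rowMeans(zs)
  k_eff <- max(1L, min(k, length(unique(round(lum)))))
  if (k_eff == 1L || nrow(zs) <= k_eff) {
    assign <- rep(1L, nrow(zs)); k_eff <- 1L
  } else {
    qs <- stats::quantile(lum, probs = (seq_len(k_eff) - 0.5) / k_eff,
                          names = FALSE, type = 1)
    centers <- zs[vapply(qs, function(q) which.min(abs(lum - q)), 1L), ,
                  drop = FALSE]
    centers <- unique(centers)
    if (nrow(centers) == 1L) {
      assign <- rep(1L, nrow(zs)); k_eff <- 1L
    } else {
      km <- suppressWarnings(stats::kmeans(zs, centers = centers,
                                           iter.max = 20L))
      assign <- km$cluster; k_eff <- nrow(centers)
    }
  }
  dcol <- ncol(z)
  nll <- matrix(Inf, nrow(z), k_eff)
  for (j in seq_len(k_eff)) {
    sel <- assign == j
    if (!any(sel)) next
    pi_j <- mean(sel)
    mu <- colMeans(zs[sel, , drop = FALSE])
    sig <- stats::cov(zs[sel, , drop = FALSE])
    if (any(!is.finite(sig))) sig <- diag(dcol) * 0
    sig <- sig + diag(dcol) * 1e-2            # regularize
    ch <- chol(sig)
    di <- forwardsolve(t(ch), t(z) - mu)
    maha <- colSums(di^2)
    nll[, j] <- -log(pi_j) + 0.5 * maha + sum(log(diag(ch))) +
      0.5 * dcol * log(2 * pi)
  }
  pmin(apply(nll, 1, min), 50)
}
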