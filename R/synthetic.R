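#' Generate a random planar ground-truth graph
#'
#' The benchmark fixture factory: draws a connected planar spatial graph
#' emulating the structure of vein networks in laboratory images --
#' curvilinear spacing, mostly degree-3/4 junctions, a mixture of cycles
#' and dead ends.  Construction: uniform random points with a
#' minimum-separation constraint, Gabriel-graph proximity edges (a
#' subgraph of the Delaunay triangulation, hence planar; a supergraph of
#' the minimum spanning tree, hence connected), random thinning of
#' non-bridge edges, a degree cap of four, and removal of degree-2
#' vertices (the node criterion used at extraction time can only detect
#' endpoints and junctions, and the benchmark's reference graphs share
#' that property).  Each edge gets a stroke width drawn uniformly from the
#' odd integers in `width_range`, a rasterized centreline path and its
#' axial/diagonal chain length.
#'
#' @param n_vertices number of points to place (>= 3); some may be removed
#'   by the degree-2 cleanup.
#' @param width_range range of stroke widths in pixels; odd values are
#'   used.
#' @param seed integer seed; the generator is deterministic given the
#'   seed.
#' @param dim image dimensions `c(height, width)` in pixels.
#' @param margin empty border kept free of vertices, in pixels.
#' @param min_sep minimum pairwise vertex separation in pixels.
#' @param thin_prob probability that a removable (non-bridge) edge is
#'   dropped during thinning.
#' @return a [spatial_graph()] whose edges carry `path`, `diam` and `via`
#'   (polyline control points) columns.
#' @examples
#' g <- generate_truth_graph(12, seed = 1, dim = c(256, 256),
#'                           margin = 20, min_sep = 40)
#' g
#' @export
generate_truth_graph <- function(n_vertices = 40, width_range = c(3, 11),
                                 seed = 1L, dim = c(1024, 1024),
                                 margin = 60, min_sep = 70,
                                 thin_prob = 0.15) {
  stopifnot(n_vertices >= 3)
  with_seed(seed, {
    pts <- sample_separated_points(n_vertices, dim, margin, min_sep)
    adj <- gabriel_edges(pts)
    ed <- tibble::tibble(u = adj[, 1], v = adj[, 2],
                         via = vector("list", nrow(adj)))
    # cap degrees at four: repeatedly drop the longest removable edge at
    # the highest-degree vertex
    repeat {
      deg <- edge_degrees(ed, nrow(pts))
      vmax <- which.max(deg)
      if (deg[vmax] <= 4L) break
      inc <- which(ed$u == vmax | ed$v == vmax)
      lens <- sqrt(rowSums((pts[ed$u[inc], , drop = FALSE] -
                              pts[ed$v[inc], , drop = FALSE])^2))
      drop <- NA_integer_
      for (i in inc[order(-lens)]) {
        if (!is_bridge_edge(ed[-i, ], nrow(pts), ed$u[i], ed$v[i])) {
          drop <- i; break
        }
      }
      if (is.na(drop)) break
      ed <- ed[-drop, ]
    }
    # random thinning of non-bridge edges
    for (i in sample(nrow(ed))) {
      if (i > nrow(ed)) next
      if (runif(1) < thin_prob &&
          !is_bridge_edge(ed[-i, ], nrow(pts), ed$u[i], ed$v[i]))
        ed <- ed[-i, ]
    }
    # degree-2 cleanup: smooth into a polyline edge, or drop an edge when
    # smoothing would create a parallel edge
    repeat {
      deg <- edge_degrees(ed, nrow(pts))
      two <- which(deg == 2L)
      two <- two[!vapply(two, function(v)
        any(ed$u == v & ed$v == v), logical(1))]
      if (!length(two)) break
      v <- two[1]
      inc <- which(ed$u == v | ed$v == v)
      e1 <- ed[inc[1], ]; e2 <- ed[inc[2], ]
      a <- if (e1$u == v) e1$v else e1$u
      b <- if (e2$u == v) e2$v else e2$u
      parallel <- a == b ||
        any((ed$u == a & ed$v == b) | (ed$u == b & ed$v == a))
      if (parallel) {
        ed <- ed[-inc[2], ]
      } else {
        via <- rbind(orient_via(e1$via[[1]], rev = (e1$u == v)),
                     pts[v, , drop = FALSE],
                     orient_via(e2$via[[1]], rev = (e2$u != v)))
        new <- tibble::tibble(u = a, v = b, via = list(via))
        ed <- dplyr::bind_rows(ed[-inc, ], new)
      }
    }
    used <- sort(unique(c(ed$u, ed$v)))
    remap <- match(seq_len(nrow(pts)), used)
    nodes <- tibble::tibble(id = seq_along(used),
                            x = pts[used, 1], y = pts[used, 2])
    widths <- sample(odd_widths(width_range), nrow(ed), replace = TRUE)
    paths <- vector("list", nrow(ed)); diams <- vector("list", nrow(ed))
    lens <- numeric(nrow(ed))
    for (i in seq_len(nrow(ed))) {
      ctrl <- rbind(pts[ed$u[i], ], ed$via[[i]], pts[ed$v[i], ])
      p <- polyline_pixels(ctrl)
      paths[[i]] <- p
      lens[i] <- edge_length(p)
      diams[[i]] <- rep(widths[i], nrow(p))
    }
    edges <- tibble::tibble(
      u = remap[ed$u], v = remap[ed$v], length = lens,
      width_median = as.numeric(widths), width_var = 0,
      path = paths, diam = diams, via = ed$via)
    spatial_graph(nodes, edges, dim = dim)
  })
}

odd_widths <- function(width_range) {
  w <- seq(ceiling(width_range[1]), floor(width_range[2]))
  w <- w[w %% 2 == 1]
  if (!length(w)) stop("width_range contains no odd width", call. = FALSE)
  w
}

sample_separated_points <- function(n, dim, margin, min_sep) {
  lo <- c(margin, margin); hi <- c(dim[2] - margin, dim[1] - margin)
  if (any(hi <= lo))
    stop("margin too large for image dimensions", call. = FALSE)
  pts <- matrix(NA_real_, n, 2)
  got <- 0L; tries <- 0L
  while (got < n) {
    tries <- tries + 1L
    if (tries > 400L * n)
      stop("infeasible separation: cannot place ", n,
           " points at min_sep ", min_sep, call. = FALSE)
    cand <- c(round(runif(1, lo[1], hi[1])), round(runif(1, lo[2], hi[2])))
    if (got == 0L ||
        min(sqrt(rowSums(sweep(pts[seq_len(got), , drop = FALSE], 2,
                               cand)^2))) >= min_sep) {
      got <- got + 1L
      pts[got, ] <- cand
    }
  }
  pts
}

# Gabriel graph: edge (i, j) iff no other point lies strictly inside the
# circle with diameter ij.
gabriel_edges <- function(pts) {
  n <- nrow(pts)
  out <- matrix(0L, 0L, 2L)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    mid <- (pts[i, ] + pts[j, ]) / 2
    r2 <- sum((pts[i, ] - pts[j, ])^2) / 4
    d2 <- rowSums(sweep(pts, 2, mid)^2)
    d2[c(i, j)] <- Inf
    if (all(d2 >= r2 - 1e-9)) out <- rbind(out, c(i, j))
  }
  out
}

edge_degrees <- function(ed, n) {
  d <- rep(0L, n)
  if (nrow(ed)) {
    t1 <- table(factor(c(ed$u, ed$v), levels = seq_len(n)))
    d <- as.integer(t1)
  }
  d
}

# is (u, v) disconnected in the edge table 'ed' (which excludes that edge)?
is_bridge_edge <- function(ed, n, u, v) {
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(ed)) g <- igraph::add_edges(g, rbind(ed$u, ed$v))
  !igraph::are_adjacent(g, u, v) &&
    is.infinite(igraph::distances(g, v = u, to = v)[1, 1])
}

orient_via <- function(via, rev) {
  if (is.null(via)) return(NULL)
  if (rev) via[base::rev(seq_len(nrow(via))), , drop = FALSE] else via
}

# Rasterize a polyline of control points into an 8-connected pixel chain.
polyline_pixels <- function(ctrl) {
  out <- NULL
  for (i in seq_len(nrow(ctrl) - 1L)) {
    seg <- bresenham(ctrl[i, ], ctrl[i + 1L, ])
    out <- if (is.null(out)) seg else rbind(out, seg[-1, , drop = FALSE])
  }
  colnames(out) <- c("x", "y")
  out
}

bresenham <- function(p, q) {
  n <- max(abs(q - p))
  if (n == 0) return(matrix(p, 1L, 2L))
  t <- seq(0, 1, length.out = n + 1L)
  cbind(round(p[1] + t * (q[1] - p[1])), round(p[2] + t * (q[2] - p[2])))
}

#' Distort a ground-truth graph
#'
#' Diversifies reference graphs by applying graph filters and/or random
#' deletion of non-bridge edges (connectivity is preserved).
#'
#' @param g a [spatial_graph()].
#' @param ops list of graph filter names or functions
#'   (see [apply_filters()]).
#' @param edge_delete_prob probability of deleting each edge.
#' @param seed integer seed.
#' @param preserve_connectivity if `TRUE`, deletions that would split a
#'   component are skipped; if `FALSE` (the benchmark's choice), deletions
#'   may disconnect the graph, which diversifies the truth set with
#'   multi-component networks.  Vertices left without edges are dropped.
#' @return a [spatial_graph()].
#' @export
distort_truth <- function(g, ops = list(), edge_delete_prob = 0,
                          seed = 1L, preserve_connectivity = TRUE) {
  g <- apply_filters(g, ops)
  if (edge_delete_prob > 0 && n_edges(g)) {
    g <- with_seed(seed, {
      for (i in sample(n_edges(g))) {
        if (i > n_edges(g)) next
        if (runif(1) < edge_delete_prob) {
          ed <- g$edges[-i, ]
          if (preserve_connectivity) {
            keep <- igraph::make_empty_graph(n = n_vertices(g),
                                             directed = FALSE)
            if (nrow(ed))
              keep <- igraph::add_edges(keep,
                                        rbind(match(ed$u, g$nodes$id),
                                              match(ed$v, g$nodes$id)))
            if (igraph::count_components(keep) !=
                igraph::count_components(as_igraph(g)))
              next
          }
          g$edges <- ed
        }
      }
      g
    })
    iso <- !(g$nodes$id %in% c(g$edges$u, g$edges$v))
    if (any(iso)) g$nodes <- g$nodes[!iso, ]
  }
  g
}

#' Render a spatial graph to an image
#'
#' Draws the graph the way the benchmark protocol requires: Euclidean
#' vertex positions, edge lengths and stroke thicknesses are preserved.
#' Every edge is drawn as a stroke of its `width_median` along its pixel
#' path (edges without a stored path are drawn as straight segments
#' between their endpoints); vertices are drawn as disks of the maximum
#' incident width; no anti-aliasing.
#'
#' @param g a [spatial_graph()] whose edges carry positive widths.
#' @param fg,bg foreground / background intensity (must differ).
#' @return a [raster_image()] carrying `fg` and `bg` as attributes.
#' @export
render_graph <- function(g, fg = 220, bg = 30) {
  if (fg == bg) stop("fg and bg intensities must differ", call. = FALSE)
  d <- g$dim
  if (is.null(d)) stop("graph has no image dimensions", call. = FALSE)
  img <- matrix(bg, d[1], d[2])
  if (n_edges(g) &&
      (any(is.na(g$edges$width_median)) || any(g$edges$width_median <= 0)))
    stop("every edge needs a positive width to be rendered", call. = FALSE)
  for (i in seq_len(n_edges(g)))
    img <- stamp_edge(img, g, i, g$edges$width_median[i], fg)
  img <- stamp_vertices(img, g, fg)
  out <- raster_image(img)
  attr(out, "fg") <- fg
  attr(out, "bg") <- bg
  out
}

edge_ctrl <- function(g, i) {
  u <- match(g$edges$u[i], g$nodes$id); v <- match(g$edges$v[i], g$nodes$id)
  via <- if ("via" %in% names(g$edges)) g$edges$via[[i]] else NULL
  rbind(c(g$nodes$x[u], g$nodes$y[u]), via, c(g$nodes$x[v], g$nodes$y[v]))
}

stamp_edge <- function(img, g, i, w, value) {
  p <- g$edges$path[[i]]
  if (!is.null(p) && nrow(p) > 1L) return(stamp_path(img, p, w, value))
  ctrl <- edge_ctrl(g, i)
  for (s in seq_len(nrow(ctrl) - 1L))
    img <- stamp_segment(img, ctrl[s, ], ctrl[s + 1L, ], w, value)
  img
}

# stroke of width w along a pixel chain: union of disks of radius w/2
# centred at every path pixel (round caps, no anti-aliasing)
stamp_path <- function(img, path, w, value) {
  h <- w / 2
  r <- ceiling(h)
  off <- expand.grid(dx = -r:r, dy = -r:r)
  off <- off[off$dx^2 + off$dy^2 <= h * h, ]
  px <- outer(path[, 1], off$dx, "+")
  py <- outer(path[, 2], off$dy, "+")
  ok <- px >= 0 & px < ncol(img) & py >= 0 & py < nrow(img)
  img[unique(py[ok] + 1L + px[ok] * nrow(img))] <- value
  img
}

stamp_segment <- function(img, p, q, w, value) {
  h <- w / 2
  nr <- nrow(img); nc <- ncol(img)
  x0 <- max(0, floor(min(p[1], q[1]) - h)); x1 <- min(nc - 1, ceiling(max(p[1], q[1]) + h))
  y0 <- max(0, floor(min(p[2], q[2]) - h)); y1 <- min(nr - 1, ceiling(max(p[2], q[2]) + h))
  if (x1 < x0 || y1 < y0) return(img)
  xs <- x0:x1; ys <- y0:y1
  gx <- matrix(rep(xs, each = length(ys)), length(ys))
  gy <- matrix(rep(ys, times = length(xs)), length(ys))
  vx <- q[1] - p[1]; vy <- q[2] - p[2]
  L2 <- vx * vx + vy * vy
  if (L2 == 0) {
    d2 <- (gx - p[1])^2 + (gy - p[2])^2
  } else {
    t <- pmin(pmax(((gx - p[1]) * vx + (gy - p[2]) * vy) / L2, 0), 1)
    d2 <- (gx - (p[1] + t * vx))^2 + (gy - (p[2] + t * vy))^2
  }
  hit <- d2 <= h * h
  sub <- img[ys + 1L, xs + 1L, drop = FALSE]
  sub[hit] <- value
  img[ys + 1L, xs + 1L] <- sub
  img
}

stamp_vertices <- function(img, g, value, per_vertex_value = NULL) {
  if (!n_vertices(g)) return(img)
  deg_w <- vapply(g$nodes$id, function(id) {
    inc <- g$edges$width_median[g$edges$u == id | g$edges$v == id]
    if (length(inc)) max(inc) else 1
  }, numeric(1))
  for (k in seq_len(n_vertices(g))) {
    val <- if (is.null(per_vertex_value)) value else per_vertex_value[k]
    img <- stamp_segment(img, c(g$nodes$x[k], g$nodes$y[k]),
                         c(g$nodes$x[k], g$nodes$y[k]), deg_w[k], val)
  }
  img
}

#' Benchmark distortion conditions
#'
#' Produce the corrupted variants of an ideal render:
#' `condition_brightness()` redraws each edge at a random intensity
#' (uniform in `[lo, hi]`), so local foreground/background contrast varies
#' across the image; `condition_gradient()` replaces the background with a
#' horizontal linear intensity ramp while leaving foreground pixels
#' untouched; `condition_blur()` applies a global Gaussian blur, which
#' makes the depicted edges appear slightly wider.
#'
#' @param img an ideal render from [render_graph()].
#' @param truth the [spatial_graph()] the image depicts.
#' @param lo,hi intensity range of the distortion.
#' @param seed integer seed for the per-edge intensities.
#' @return a [raster_image()].
#' @export
condition_brightness <- function(img, truth, lo = 60, hi = 255, seed = 1L) {
  bg <- attr(img, "bg"); if (is.null(bg)) bg <- mode_intensity(img)
  d <- dim(img)
  with_seed(seed, {
    vals <- round(runif(n_edges(truth), lo, hi))
    out <- matrix(bg, d[1], d[2])
    for (i in seq_len(n_edges(truth)))
      out <- stamp_edge(out, truth, i, truth$edges$width_median[i],
                        vals[i])
    # vertex disks take the intensity of their widest incident edge
    vval <- vapply(truth$nodes$id, function(id) {
      inc <- which(truth$edges$u == id | truth$edges$v == id)
      if (length(inc)) vals[inc[which.max(truth$edges$width_median[inc])]]
      else bg
    }, numeric(1))
    out <- stamp_vertices(out, truth, NA, per_vertex_value = vval)
    res <- raster_image(out)
    attr(res, "bg") <- bg
    res
  })
}

#' @rdname condition_brightness
#' @export
condition_gradient <- function(img, lo = 0, hi = 160) {
  bg <- attr(img, "bg"); if (is.null(bg)) bg <- mode_intensity(img)
  m <- unclass(img)
  ramp <- matrix(rep(seq(lo, hi, length.out = ncol(m)), each = nrow(m)),
                 nrow(m))
  sel <- m == bg
  m[sel] <- round(ramp[sel])
  out <- raster_image(m)
  attr(out, "fg") <- attr(img, "fg")
  out
}

#' @rdname condition_brightness
#' @param sigma Gaussian blur standard deviation in pixels.
#' @export
condition_blur <- function(img, sigma = 2) {
  k <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  out <- gaussian_blur(raster_image(round(unclass(img))), k, sigma)
  attr(out, "fg") <- attr(img, "fg"); attr(out, "bg") <- attr(img, "bg")
  out
}

mode_intensity <- function(img) {
  tab <- table(round(as.vector(unclass(img))))
  as.numeric(names(tab)[which.max(tab)])
}

#' Build a benchmark test set
#'
#' Generates `n_images` independent ground-truth graphs, renders each, and
#' applies the requested distortion condition.  All randomness is derived
#' from the master seed, so the same seed reproduces the identical set.
#'
#' By default the ground truths are *distilled* through the extractor,
#' mirroring the benchmark protocol: a synthetic planar graph is rendered,
#' the rendered image is processed with the reference otsu/thin/detect
#' pipeline, the resulting graph is diversified by random edge deletion
#' (10% by default; deletions may disconnect the network), and the final
#' extraction of the re-rendered graph becomes the ground truth, which is
#' re-rendered once more (positions, pixel paths, lengths and widths
#' preserved) to produce the test image.  This guarantees that the test
#' image depicts exactly the annotated graph, so that discrepancies
#' measured later are attributable to the pipeline under test, not to the
#' fixture.  `distill = 0` keeps the raw geometric graphs as truths.
#'
#' @param n_images number of ground truth / image pairs.
#' @param condition one of `"ideal"`, `"brightness"`, `"gradient"`,
#'   `"blur"`.
#' @param params named list overriding generator/render/distortion
#'   defaults (`n_vertices`, `width_range`, `dim`, `margin`, `min_sep`,
#'   `thin_prob`, `fg`, `bg`, `lo`, `hi`, `sigma`).
#' @param seed master seed.
#' @param distill number of distillation rounds (0 keeps the raw
#'   geometric graphs as truths).  Distillation is iterated because the
#'   extract-and-re-render map needs a few rounds to reach its fixed
#'   point; three rounds suffice for the default conditions.
#' @return list of `truth_pair` objects: `list(truth, image, condition,
#'   seed)`.
#' @examples
#' set <- build_test_set(2, "ideal", params = list(
#'   n_vertices = 10, dim = c(256, 256), margin = 20, min_sep = 40),
#'   seed = 7)
#' length(set)
#' @export
build_test_set <- function(n_images, condition = c("ideal", "brightness",
                                                   "gradient", "blur"),
                           params = list(), seed = 1L, distill = 3L) {
  condition <- match.arg(condition)
  p <- modifyList(list(n_vertices = 40, width_range = c(3, 11),
                       dim = c(1024, 1024), margin = 60, min_sep = 70,
                       thin_prob = 0.15, fg = 220, bg = 30,
                       delete_prob = 0.1, lo = NULL, hi = NULL,
                       sigma = 2), params)
  sub <- with_seed(seed, sample.int(2^31 - 1L, 2L * n_images))
  ref <- method_pipeline("otsu")
  lapply(seq_len(n_images), function(i) {
    truth <- generate_truth_graph(p$n_vertices, p$width_range,
                                  seed = sub[2L * i - 1L], dim = p$dim,
                                  margin = p$margin, min_sep = p$min_sep,
                                  thin_prob = p$thin_prob)
    img <- render_graph(truth, fg = p$fg, bg = p$bg)
    for (round in seq_len(distill)) {
      truth <- run_pipeline(img, ref)$final_graph
      if (round == max(1L, distill - 2L) && p$delete_prob > 0) {
        truth <- distort_truth(truth, edge_delete_prob = p$delete_prob,
                               seed = sub[2L * i],
                               preserve_connectivity = FALSE)
        truth <- smooth_degree_two(truth)
      }
      img <- render_graph(truth, fg = p$fg, bg = p$bg)
    }
    img <- switch(condition,
      ideal = img,
      brightness = condition_brightness(
        img, truth, lo = p$lo %||% 60, hi = p$hi %||% 255,
        seed = sub[2L * i]),
      gradient = condition_gradient(img, lo = p$lo %||% 0,
                                    hi = p$hi %||% 160),
      blur = condition_blur(img, sigma = p$sigma))
    structure(list(truth = truth, image = img, condition = condition,
                   seed = sub[2L * i - 1L]), class = "truth_pair")
  })
}

# evaluate code with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}
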