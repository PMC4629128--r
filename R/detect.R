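#' Node detection on a skeleton
#'
#' A white skeleton pixel becomes a node when deleting it leaves exactly one
#' or at least three 4-connected white components among its eight
#' neighbours: one component marks the end of a path, three or more mark a
#' junction.  Because the eight neighbours form a cycle under 4-adjacency,
#' the component count equals the number of circular runs of white
#' neighbours.  A consequence of single-pixel node locations is that
#' detected vertices have degree at most four; higher-degree junctions in
#' the depicted structure appear as several nearby nodes, which
#' [merge_close_nodes()] can collapse.
#'
#' @param skel a skeleton ([guo_hall_thin()]) or [binary_image()].
#' @return tibble of node pixels with columns `x`, `y` (0-based pixel
#'   coordinates) in row-major scan order.
#' @examples
#' line <- matrix(FALSE, 5, 7); line[3, 2:6] <- TRUE
#' detect_nodes(binary_image(line))  # the two end pixels
#' @export
detect_nodes <- function(skel) {
  nc4 <- neighbor_components(skel)
  node <- unclass(skel) & (nc4 == 1L | nc4 >= 3L)
  idx <- which(node, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])   # row-major scan order
  tibble::tibble(x = as.integer(idx[ord, 2] - 1L),
                 y = as.integer(idx[ord, 1] - 1L))
}

# Number of 4-connected white components among the 8 neighbours of every
# pixel (background off-grid).  Equals the circular run count of the
# neighbour ring N, NE, E, SE, S, SW, W, NW.
neighbor_components <- function(mask) {
  m <- unclass(mask) * 1L
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  sh <- function(dr, dc) pad[(2L + dr):(nr + 1L + dr),
                             (2L + dc):(nc + 1L + dc)]
  ring <- list(sh(-1L, 0L), sh(-1L, 1L), sh(0L, 1L), sh(1L, 1L),
               sh(1L, 0L), sh(1L, -1L), sh(0L, -1L), sh(-1L, -1L))
  runs <- matrix(0L, nr, nc)
  for (i in 1:8) {
    j <- if (i == 8L) 1L else i + 1L
    runs <- runs + (ring[[i]] == 1L & ring[[j]] == 0L)
  }
  allwhite <- Reduce(`&`, lapply(ring, function(r) r == 1L))
  runs[allwhite] <- 1L
  runs
}

#' Trace edges between nodes by simultaneous breadth-first search
#'
#' Every white pixel 8-adjacent to a node seeds a uniquely numbered queue
#' (labels assigned in row-major scan order); queues are serviced
#' round-robin in ascending label order, one pixel per pass.  An unmarked
#' dequeued pixel takes the queue's label and enqueues its white
#' neighbours; a pixel already carrying a different label means two
#' searches met, i.e. an edge between the two owning nodes has been found.
#' Node-free cycle components (perfect rings, on which the node criterion
#' fires nowhere) receive an anchor node at their row-major-smallest pixel
#' so the cycle is representable; the resulting self-loop is kept.
#' Self-loops shorter than `min_loop` path units are discarded as thinning
#' artifacts.
#'
#' @param skel a skeleton.
#' @param nodes tibble with `x`, `y` node pixel coordinates
#'   (see [detect_nodes()]); defaults to running the node criterion.
#' @param min_loop minimum self-loop length kept, in path units.
#' @return tibble with columns `u`, `v` (1-based indices into the node
#'   table, anchors appended) and list-column `path` of (x, y) pixel
#'   matrices oriented from `u` to `v`, plus the node table as attribute
#'   `"nodes"`.
#' @export
trace_edges <- function(skel, nodes = detect_nodes(skel), min_loop = 3) {
  m <- unclass(skel)
  mode(m) <- "logical"
  nr <- nrow(m)
  nodes <- tibble::as_tibble(nodes)
  if (nrow(nodes) && any(!m[cbind(nodes$y + 1L, nodes$x + 1L)]))
    stop("nodes must be skeleton foreground pixels", call. = FALSE)
  anchors <- ring_anchors(m, nodes)
  if (nrow(anchors)) nodes <- dplyr::bind_rows(nodes, anchors)
  nodeid <- matrix(0L, nrow(m), ncol(m))
  if (nrow(nodes))
    nodeid[cbind(nodes$y + 1L, nodes$x + 1L)] <- seq_len(nrow(nodes))
  node_px <- (nodes$y) + (nodes$x) * nr        # 0-based linear index
  tr <- trace_edges_cpp(m, nodeid, as.integer(node_px))
  paths <- lapply(tr$paths, function(p)
    cbind(x = p[, 2], y = p[, 1]))             # (row,col) -> (x,y)
  ed <- tibble::tibble(u = tr$u, v = tr$v, path = paths)
  if (nrow(ed)) {
    # orient each path so that path[1] is u's node pixel
    for (i in seq_len(nrow(ed))) {
      p <- ed$path[[i]]
      upx <- c(nodes$x[ed$u[i]], nodes$y[ed$u[i]])
      if (!all(p[1, ] == upx) && all(p[nrow(p), ] == upx))
        ed$path[[i]] <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    }
    keep <- vapply(seq_len(nrow(ed)), function(i) {
      if (ed$u[i] != ed$v[i]) return(TRUE)
      edge_length(ed$path[[i]]) >= min_loop
    }, logical(1))
    ed <- ed[keep, ]
  }
  attr(ed, "nodes") <- nodes
  ed
}

# Anchor nodes for 8-connected skeleton components containing no node:
# the row-major smallest pixel of each such component.
ring_anchors <- function(m, nodes) {
  comp <- label_components8(m)
  if (is.null(comp))
    return(tibble::tibble(x = integer(), y = integer()))
  node_comps <- if (nrow(nodes))
    unique(comp$labels[match((nodes$x) * nrow(m) + nodes$y + 1L,
                             comp$pixels)]) else integer()
  orphan <- setdiff(unique(comp$labels), node_comps)
  if (!length(orphan))
    return(tibble::tibble(x = integer(), y = integer()))
  nr <- nrow(m)
  px <- comp$pixels[comp$labels %in% orphan]   # 1-based linear col-major
  lb <- comp$labels[comp$labels %in% orphan]
  r <- (px - 1L) %% nr
  c <- (px - 1L) %/% nr
  rank <- r * ncol(m) + c                      # row-major order
  best <- tapply(seq_along(px), lb, function(ii) ii[which.min(rank[ii])])
  best <- unlist(best, use.names = FALSE)
  ord <- order(rank[best])
  tibble::tibble(x = as.integer(c[best][ord]), y = as.integer(r[best][ord]))
}

# 8-connected component labels of a logical matrix, via igraph.
# Returns list(pixels = 1-based linear indices, labels) or NULL if empty.
label_components8 <- function(m) {
  idx <- which(m)
  if (!length(idx)) return(NULL)
  nr <- nrow(m); nc <- ncol(m)
  id <- matrix(0L, nr, nc)
  id[idx] <- seq_along(idx)
  pairs <- list()
  shift_pairs <- function(dr, dc) {
    r1 <- max(1L, 1L + dr):min(nr, nr + dr)
    c1 <- max(1L, 1L + dc):min(nc, nc + dc)
    a <- id[r1 - dr, c1 - dc, drop = FALSE]
    b <- id[r1, c1, drop = FALSE]
    ok <- a > 0L & b > 0L
    cbind(a[ok], b[ok])
  }
  pr <- rbind(shift_pairs(1L, 0L), shift_pairs(0L, 1L),
              shift_pairs(1L, 1L), shift_pairs(1L, -1L))
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(pr)) g <- igraph::add_edges(g, t(pr))
  memb <- igraph::components(g)$membership
  list(pixels = idx, labels = as.integer(memb))
}

#' Path length in axial/diagonal units
#'
#' Sums step weights along an 8-connected pixel chain: horizontal and
#' vertical steps count one unit, diagonal steps count sqrt(2) units.
#'
#' @param path m x 2 matrix of pixel coordinates with consecutive rows
#'   8-adjacent.
#' @return numeric length; 0 for a single-pixel path.
#' @examples
#' edge_length(cbind(0:4, rep(0, 5)))   # 4
#' edge_length(cbind(0:2, 0:2))         # 2 * sqrt(2)
#' @export
edge_length <- function(path) {
  if (is.null(dim(path)) || nrow(path) < 2L) return(0)
  d <- abs(diff(path))
  if (any(d > 1L) || any(rowSums(d) == 0))
    stop("path integrity error: consecutive pixels must be 8-adjacent",
         call. = FALSE)
  sum(ifelse(d[, 1] & d[, 2], sqrt(2), 1))
}

#' Stroke widths along an edge path
#'
#' Reads the Euclidean distance transform of the segmented image at every
#' path pixel; assuming the skeleton runs along the middle of the stroke,
#' the local stroke diameter is `2 * d - 1` pixels, where `d` is the
#' distance to the nearest background pixel (a stroke of odd width w has
#' centreline distance (w + 1) / 2, so this recovers w exactly).  Returns
#' the median and the population variance of the per-pixel diameters.
#'
#' @param path m x 2 matrix of (x, y) pixel coordinates.
#' @param dist distance map of the segmentation (see [distance_map()]).
#' @return list with `width_median`, `width_var` and the per-pixel `diam`
#'   vector.
#' @export
edge_widths <- function(path, dist) {
  d <- dist[cbind(path[, 2] + 1L, path[, 1] + 1L)]
  if (any(d <= 0))
    stop("width lookup error: path pixel lies on background ",
         "(skeleton/segmentation mismatch)", call. = FALSE)
  diam <- 2 * d - 1
  list(width_median = stats::median(diam),
       width_var = mean((diam - mean(diam))^2),
       diam = diam)
}

#' Assemble a spatial graph from traced components
#'
#' @param nodes tibble with `x`, `y` (0-based pixel coordinates); vertex
#'   ids are assigned 1..n in row order.
#' @param edges tibble with `u`, `v` (indices into `nodes`) and list-column
#'   `path`.
#' @param dist optional distance map used to attach width attributes.
#' @param dim image dimensions `c(height, width)`.
#' @return a [spatial_graph()].
#' @export
build_graph <- function(nodes, edges, dist = NULL, dim = NULL) {
  nodes <- tibble::as_tibble(nodes)
  nd <- tibble::tibble(id = seq_len(nrow(nodes)), x = as.numeric(nodes$x),
                       y = as.numeric(nodes$y))
  if (is.null(edges) || nrow(edges) == 0L)
    return(spatial_graph(nd, NULL, dim = dim))
  if (any(!c(edges$u, edges$v) %in% nd$id))
    stop("dangling edge endpoint", call. = FALSE)
  lens <- vapply(edges$path, edge_length, numeric(1))
  if (is.null(dist)) {
    wm <- rep(NA_real_, nrow(edges)); wv <- rep(NA_real_, nrow(edges))
    dm <- rep(list(NULL), nrow(edges))
  } else {
    ws <- lapply(edges$path, edge_widths, dist = dist)
    wm <- vapply(ws, `[[`, numeric(1), "width_median")
    wv <- vapply(ws, `[[`, numeric(1), "width_var")
    dm <- lapply(ws, `[[`, "diam")
  }
  ed <- tibble::tibble(u = edges$u, v = edges$v, length = lens,
                       width_median = wm, width_var = wv,
                       path = edges$path, diam = dm)
  spatial_graph(nd, ed, dim = dim)
}

#' Merge nearby nodes
#'
#' Collapses clusters of nodes (single-linkage over pairwise distance
#' `<= radius`) to their centroid pixel, re-attaching incident edges.
#' Self-edges created by a collapse are dropped when their length is at
#' most `radius`.  `radius = 0` is the identity.  Useful because junctions
#' of degree above four necessarily appear as several single-pixel nodes
#' close together.
#'
#' @param g a [spatial_graph()].
#' @param radius merge radius in pixels (>= 0).
#' @return a [spatial_graph()].
#' @export
merge_close_nodes <- function(g, radius = 0) {
  stopifnot(radius >= 0)
  if (radius == 0 || n_vertices(g) < 2L) return(g)
  xy <- cbind(g$nodes$x, g$nodes$y)
  dmat <- as.matrix(stats::dist(xy))
  adj <- dmat <= radius
  cl <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                        diag = FALSE))$membership
  nd <- g$nodes |>
    dplyr::mutate(cluster = cl) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(x = round(mean(.data$x)), y = round(mean(.data$y)),
                     .groups = "drop") |>
    dplyr::mutate(id = dplyr::row_number()) |>
    dplyr::select("id", "x", "y")
  map <- stats::setNames(match(cl, sort(unique(cl))), g$nodes$id)
  ed <- g$edges
  if (nrow(ed)) {
    old_u <- ed$u; old_v <- ed$v
    ed$u <- unname(map[as.character(old_u)])
    ed$v <- unname(map[as.character(old_v)])
    # self-loops at or below the merge radius are below the structural
    # resolution being enforced (whether created by the collapse or not)
    ed <- ed[!(ed$u == ed$v & ed$length <= radius), ]
    # extend pixel paths to the moved (centroid) node pixels so that path
    # endpoints still coincide with their vertices
    for (i in seq_len(nrow(ed))) {
      p <- ed$path[[i]]
      if (is.null(p)) next
      dm <- ed$diam[[i]]
      up <- c(nd$x[ed$u[i]], nd$y[ed$u[i]])
      vp <- c(nd$x[ed$v[i]], nd$y[ed$v[i]])
      if (!all(p[1, ] == up)) {
        ext <- bresenham(up, p[1, ])
        if (nrow(ext) > 1L) {
          p <- rbind(ext[-nrow(ext), , drop = FALSE], p)
          if (!is.null(dm)) dm <- c(rep(dm[1], nrow(ext) - 1L), dm)
        }
      }
      if (!all(p[nrow(p), ] == vp)) {
        ext <- bresenham(p[nrow(p), ], vp)
        if (nrow(ext) > 1L) {
          p <- rbind(p, ext[-1, , drop = FALSE])
          if (!is.null(dm)) dm <- c(dm, rep(dm[length(dm)], nrow(ext) - 1L))
        }
      }
      colnames(p) <- c("x", "y")
      ed$path[i] <- list(p)
      ed$diam[i] <- list(dm)
      ed$length[i] <- edge_length(p)
      if (!is.null(dm)) {
        ed$width_median[i] <- stats::median(dm)
        ed$width_var[i] <- mean((dm - mean(dm))^2)
      }
    }
  }
  spatial_graph(nd, ed, dim = g$dim)
}

#' Full graph detection from a segmentation
#'
#' Thins the segmentation (unless a skeleton is supplied), detects nodes,
#' traces edges, attaches lengths and distance-transform widths, optionally
#' merges nearby nodes.
#'
#' @param segmented a [binary_image()].
#' @param skeleton optional precomputed skeleton of `segmented`.
#' @param merge_radius radius for [merge_close_nodes()]; 0 disables
#'   merging.
#' @param min_loop minimum self-loop length kept (path units).
#' @return a [spatial_graph()].
#' @export
detect_graph <- function(segmented, skeleton = NULL, merge_radius = 0,
                         min_loop = 3) {
  stopifnot(is_binary_image(segmented))
  if (is.null(skeleton)) skeleton <- guo_hall_thin(segmented)
  if (!any(skeleton))
    return(spatial_graph(NULL, NULL, dim = dim(segmented)))
  dist <- distance_map(segmented)
  ed <- trace_edges(skeleton, min_loop = min_loop)
  nodes <- attr(ed, "nodes")
  g <- build_graph(nodes, ed, dist = dist, dim = dim(segmented))
  if (merge_radius > 0) g <- merge_close_nodes(g, merge_radius)
  g
}
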