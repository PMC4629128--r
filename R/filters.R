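#' Graph filters
#'
#' Post-detection cleanup that operates purely on the extracted graph,
#' never on the segmented image or the skeleton: artifacts are carried into
#' the graph and removed there, where their structure (tiny components,
#' stray spurs, dead ends) makes them easy to identify.
#'
#' * `keep_largest_component()` drops everything outside the connected
#'   component with the most vertices (ties broken by edge count, then by
#'   the component containing the lexicographically smallest vertex
#'   coordinate).
#' * `smooth_degree_two()` replaces every degree-2 vertex by a single edge
#'   joining its neighbours -- except where that would introduce a parallel
#'   edge or a self-loop -- iterated to a fixed point.  The new edge's
#'   length is the exact sum of the two lengths; its width statistics are
#'   recomputed from the concatenated per-pixel diameter samples (medians
#'   do not compose, so they are not averaged).
#' * `keep_cycles()` removes every edge that lies on no cycle (i.e. every
#'   bridge; parallel pairs and self-loops count as cycles) and every
#'   vertex left without an edge, pruning dead ends.
#'
#' All filters are idempotent and return subgraphs (for smoothing, a
#' topological minor) with surviving vertex coordinates unchanged.
#'
#' @param g a [spatial_graph()].
#' @return a filtered [spatial_graph()].
#' @examples
#' tri <- spatial_graph(
#'   nodes = data.frame(id = 1:4, x = c(0, 10, 0, 30), y = c(0, 0, 10, 30)),
#'   edges = data.frame(u = c(1, 2, 3, 2), v = c(2, 3, 1, 4),
#'                      length = c(10, 15, 10, 30),
#'                      width_median = 3, width_var = 0))
#' keep_cycles(tri)     # pendant 2-4 edge removed
#' @export
keep_largest_component <- function(g) {
  if (n_vertices(g) == 0L) return(g)
  memb <- igraph::components(as_igraph(g))$membership
  names(memb) <- as.character(g$nodes$id)
  sizes <- table(memb)
  nedge <- tapply(seq_len(n_edges(g)),
                  factor(memb[as.character(g$edges$u)],
                         levels = names(sizes)),
                  length)
  nedge[is.na(nedge)] <- 0L
  # lexicographically smallest (x, y) per component, for the final tie-break
  ord <- order(g$nodes$x, g$nodes$y)
  first_comp <- memb[as.character(g$nodes$id[ord])]
  lex_rank <- match(names(sizes), as.character(first_comp))
  score <- order(-as.integer(sizes), -as.integer(nedge), lex_rank)
  best <- names(sizes)[score[1]]
  keep_ids <- g$nodes$id[memb[as.character(g$nodes$id)] == best]
  subgraph_by_ids(g, keep_ids)
}

#' @rdname keep_largest_component
#' @export
smooth_degree_two <- function(g) {
  repeat {
    deg <- graph_degrees(g)
    loops <- unique(g$edges$u[g$edges$u == g$edges$v])
    cand <- g$nodes$id[deg[as.character(g$nodes$id)] == 2L &
                         !(g$nodes$id %in% loops)]
    if (!length(cand)) break
    done_any <- FALSE
    for (v in sort(cand)) {
      ei <- which(g$edges$u == v | g$edges$v == v)
      if (length(ei) != 2L) next        # degree changed by earlier merge
      e1 <- g$edges[ei[1], ]; e2 <- g$edges[ei[2], ]
      a <- if (e1$u == v) e1$v else e1$u
      b <- if (e2$u == v) e2$v else e2$u
      if (a == b) next                  # would create a self-loop
      exists_ab <- any((g$edges$u == a & g$edges$v == b) |
                         (g$edges$u == b & g$edges$v == a))
      if (exists_ab) next               # would create a parallel edge
      p1 <- orient_path(e1$path[[1]], from_last = (e1$u == v))
      p2 <- orient_path(e2$path[[1]], from_last = (e2$u != v))
      d1 <- orient_vec(e1$diam[[1]], rev = (e1$u == v))
      d2 <- orient_vec(e2$diam[[1]], rev = (e2$u != v))
      # p1 runs a..v, p2 runs v..b
      newpath <- if (!is.null(p1) && !is.null(p2))
        rbind(p1, p2[-1, , drop = FALSE]) else NULL
      newdiam <- if (!is.null(d1) && !is.null(d2)) c(d1, d2[-1]) else NULL
      if (!is.null(newdiam)) {
        wm <- stats::median(newdiam)
        wv <- mean((newdiam - mean(newdiam))^2)
      } else {
        # no per-pixel samples: length-weighted pooled approximation
        wtot <- e1$length + e2$length
        wm <- (e1$width_median * e1$length + e2$width_median * e2$length) /
          wtot
        wv <- (e1$width_var * e1$length + e2$width_var * e2$length) / wtot
      }
      newedge <- tibble::tibble(
        u = a, v = b, length = e1$length + e2$length,
        width_median = wm, width_var = wv,
        path = list(newpath), diam = list(newdiam))
      g$edges <- dplyr::bind_rows(g$edges[-ei, ], newedge)
      g$nodes <- g$nodes[g$nodes$id != v, ]
      done_any <- TRUE
      break                             # re-derive candidates
    }
    if (!done_any) break
  }
  g
}

#' @rdname keep_largest_component
#' @export
keep_cycles <- function(g) {
  if (n_edges(g) == 0L)
    return(spatial_graph(NULL, NULL, dim = g$dim))
  ig <- as_igraph(g)
  br <- as.integer(igraph::bridges(ig))
  ed <- if (length(br)) g$edges[-br, ] else g$edges
  keep_ids <- g$nodes$id[g$nodes$id %in% c(ed$u, ed$v)]
  g$edges <- ed
  subgraph_by_ids(g, keep_ids)
}

#' @rdname keep_largest_component
#' @param filters ordered list of filter names (`"largest_component"`,
#'   `"smooth"`, `"cycles"`) or functions, applied left to right.
#' @export
apply_filters <- function(g, filters = list()) {
  for (f in filters) {
    fn <- if (is.function(f)) f else switch(
      as.character(f),
      largest_component = keep_largest_component,
      smooth = smooth_degree_two,
      cycles = keep_cycles,
      stop("unknown graph filter: ", f, call. = FALSE))
    g <- fn(g)
  }
  g
}

subgraph_by_ids <- function(g, ids) {
  nd <- g$nodes[g$nodes$id %in% ids, ]
  ed <- g$edges[g$edges$u %in% ids & g$edges$v %in% ids, ]
  spatial_graph(nd, ed, dim = g$dim)
}

orient_path <- function(p, from_last) {
  if (is.null(p)) return(NULL)
  if (from_last) p[rev(seq_len(nrow(p))), , drop = FALSE] else p
}

orient_vec <- function(d, rev) {
  if (is.null(d)) return(NULL)
  if (rev) base::rev(d) else d
}
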