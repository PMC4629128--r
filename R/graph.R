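#' Spatial graphs
#'
#' A `spatial_graph` is an undirected multigraph whose vertices carry pixel
#' coordinates and whose edges carry geometric attributes.  Vertices live in
#' a `tibble` with columns `id`, `x` (pixel column, 0-based) and `y` (pixel
#' row, 0-based).  Edges live in a `tibble` with columns `u`, `v` (vertex
#' ids), `length` (path units: 1 per axial step, sqrt(2) per diagonal step),
#' `width_median`, `width_var` (pixels, pixels^2) and list-columns `path`
#' (the traced pixel chain as an m x 2 matrix of (x, y), oriented from `u`
#' to `v`) and `diam` (per-pixel diameter samples along the path).
#' Self-loops and parallel edges are allowed.
#'
#' @param nodes tibble or data.frame with columns `id`, `x`, `y`.
#' @param edges tibble or data.frame with columns `u`, `v`, `length`,
#'   `width_median`, `width_var` and optionally list-columns `path`, `diam`,
#'   `via`.
#' @param dim image dimensions `c(height, width)` the coordinates refer to.
#' @return an object of class `"spatial_graph"`.
#' @examples
#' g <- spatial_graph(
#'   nodes = data.frame(id = 1:2, x = c(0, 10), y = c(0, 0)),
#'   edges = data.frame(u = 1, v = 2, length = 10,
#'                      width_median = 3, width_var = 0),
#'   dim = c(32, 32))
#' g
#' @export
spatial_graph <- function(nodes = NULL, edges = NULL, dim = NULL) {
  nodes <- if (is.null(nodes) || nrow(nodes) == 0L) {
    tibble::tibble(id = integer(), x = double(), y = double())
  } else {
    tibble::as_tibble(nodes)[, c("id", "x", "y")]
  }
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- tibble::tibble(u = integer(), v = integer(), length = double(),
                            width_median = double(), width_var = double(),
                            path = list(), diam = list())
  } else {
    edges <- tibble::as_tibble(edges)
    need <- c("u", "v", "length", "width_median", "width_var")
    miss <- setdiff(need, names(edges))
    if (length(miss))
      stop("edges lack columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
    if (!"path" %in% names(edges))
      edges$path <- rep(list(NULL), nrow(edges))
    if (!"diam" %in% names(edges))
      edges$diam <- rep(list(NULL), nrow(edges))
  }
  if (nrow(edges) && !all(c(edges$u, edges$v) %in% nodes$id))
    stop("dangling edge endpoint: edge refers to an unknown vertex id",
         call. = FALSE)
  if (nrow(edges) && any(edges$length < 0))
    stop("edge lengths must be positive", call. = FALSE)
  if (anyDuplicated(nodes$id))
    stop("duplicate vertex ids", call. = FALSE)
  if (!is.null(dim)) {
    if (nrow(nodes) &&
        (any(nodes$x < 0 | nodes$x >= dim[2]) ||
         any(nodes$y < 0 | nodes$y >= dim[1])))
      stop("vertex coordinates outside image bounds", call. = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, dim = dim),
            class = "spatial_graph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname spatial_graph
#' @param g,x a `spatial_graph`.
#' @export
graph_vertices <- function(g) g$nodes

#' @rdname spatial_graph
#' @export
graph_edges <- function(g) g$edges

n_vertices <- function(g) nrow(g$nodes)
n_edges <- function(g) nrow(g$edges)

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("<spatial_graph: %d vertices, %d edges%s>\n",
              n_vertices(x), n_edges(x),
              if (!is.null(x$dim))
                sprintf(", image %d x %d", x$dim[1], x$dim[2]) else ""))
  if (n_edges(x)) {
    cat(sprintf("  total length %.1f, width_median range [%.1f, %.1f]\n",
                sum(x$edges$length),
                min(x$edges$width_median), max(x$edges$width_median)))
  }
  invisible(x)
}

#' Vertex degrees of a spatial graph
#'
#' Self-loops count twice, as usual for undirected graphs.
#'
#' @param g a [spatial_graph()].
#' @return named integer vector indexed by vertex id.
#' @export
graph_degrees <- function(g) {
  d <- setNames(rep(0L, n_vertices(g)), as.character(g$nodes$id))
  if (n_edges(g)) {
    t1 <- table(c(g$edges$u, g$edges$v))
    d[names(t1)] <- as.integer(t1)
  }
  d
}

#' Convert a spatial graph to an igraph object
#'
#' Vertex attributes `x`, `y`; edge attributes `length`, `width_median`,
#' `width_var`.  Pixel paths are not carried over.
#'
#' @param g a [spatial_graph()].
#' @return an [igraph::graph] object.
#' @export
as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = n_vertices(g), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "name", value = as.character(g$nodes$id))
  ig <- igraph::set_vertex_attr(ig, "x", value = g$nodes$x)
  ig <- igraph::set_vertex_attr(ig, "y", value = g$nodes$y)
  if (n_edges(g)) {
    idx <- match(c(rbind(g$edges$u, g$edges$v)), g$nodes$id)
    ig <- igraph::add_edges(ig, idx,
                            length = g$edges$length,
                            width_median = g$edges$width_median,
                            width_var = g$edges$width_var)
  }
  ig
}

#' Read and write spatial graphs
#'
#' Supported formats: GraphML and GML (via igraph) and a plain-text
#' edge-list format with a `# nodes` section (`id x y`) and a `# edges`
#' section (`u v length width_median width_var`).  Pixel paths are not
#' serialized; a graph read back carries coordinates and edge weights only.
#'
#' @param g a [spatial_graph()].
#' @param path output file.
#' @param format `"graphml"`, `"gml"` or `"edgelist"`; default inferred
#'   from the file extension.
#' @return `read_graph_file()` returns a [spatial_graph()].
#' @export
write_graph_file <- function(g, path,
                             format = c("auto", "graphml", "gml",
                                        "edgelist")) {
  format <- pick_format(match.arg(format), path)
  if (format == "edgelist") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# nodes: id x y", con)
    if (n_vertices(g))
      writeLines(sprintf("%d %g %g", g$nodes$id, g$nodes$x, g$nodes$y), con)
    writeLines("# edges: u v length width_median width_var", con)
    if (n_edges(g))
      writeLines(sprintf("%d %d %.10g %.10g %.10g", g$edges$u, g$edges$v,
                         g$edges$length, g$edges$width_median,
                         g$edges$width_var), con)
  } else {
    ig <- as_igraph(g)
    if (format == "gml" && igraph::ecount(ig)) {
      # GML keys must be alphanumeric: camel-case the attribute names
      igraph::E(ig)$widthMedian <- igraph::E(ig)$width_median
      igraph::E(ig)$widthVar <- igraph::E(ig)$width_var
      ig <- igraph::delete_edge_attr(ig, "width_median")
      ig <- igraph::delete_edge_attr(ig, "width_var")
    }
    igraph::write_graph(ig, path, format = format)
  }
  invisible(path)
}

#' @rdname write_graph_file
#' @export
read_graph_file <- function(path,
                            format = c("auto", "graphml", "gml",
                                       "edgelist")) {
  format <- pick_format(match.arg(format), path)
  if (format == "edgelist") {
    ln <- readLines(path)
    sec2 <- grep("^# edges", ln)
    if (!length(sec2) || !grepl("^# nodes", ln[1]))
      stop("malformed edge-list file: missing section headers",
           call. = FALSE)
    nd <- ln[setdiff(seq_len(sec2 - 1L), 1L)]
    ed <- ln[-seq_len(sec2)]
    nd <- nd[nzchar(nd)]; ed <- ed[nzchar(ed)]
    nodes <- if (length(nd)) {
      m <- do.call(rbind, lapply(strsplit(nd, "\\s+"), as.numeric))
      tibble::tibble(id = as.integer(m[, 1]), x = m[, 2], y = m[, 3])
    } else NULL
    edges <- if (length(ed)) {
      m <- do.call(rbind, lapply(strsplit(ed, "\\s+"), as.numeric))
      tibble::tibble(u = as.integer(m[, 1]), v = as.integer(m[, 2]),
                     length = m[, 3], width_median = m[, 4],
                     width_var = m[, 5])
    } else NULL
    return(spatial_graph(nodes, edges))
  }
  ig <- igraph::read_graph(path, format = format)
  va <- igraph::vertex_attr(ig)
  ids <- if (!is.null(va$name)) as.integer(va$name) else
    seq_len(igraph::vcount(ig))
  nodes <- tibble::tibble(id = ids, x = as.numeric(va$x),
                          y = as.numeric(va$y))
  edges <- NULL
  if (igraph::ecount(ig)) {
    el <- igraph::as_edgelist(ig, names = FALSE)
    ea <- igraph::edge_attr(ig)
    wm <- ea$width_median %||% ea$widthMedian
    wv <- ea$width_var %||% ea$widthVar
    edges <- tibble::tibble(u = ids[el[, 1]], v = ids[el[, 2]],
                            length = as.numeric(ea$length),
                            width_median = as.numeric(wm),
                            width_var = as.numeric(wv))
  }
  spatial_graph(nodes, edges)
}

pick_format <- function(format, path) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         graphml = "graphml",
         gml = "gml",
         txt = "edgelist",
         tsv = "edgelist",
         edgelist = "edgelist",
         stop("cannot infer graph format from extension: ", ext,
              call. = FALSE))
}

#' Tidy views of netextract objects
#'
#' `tidy()` returns a one-row-per-edge tibble (with endpoint coordinates
#' joined in); `glance()` returns a one-row summary.
#'
#' @param x an object.
#' @param ... unused.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname tidy
#' @export
tidy.spatial_graph <- function(x, ...) {
  e <- x$edges[, c("u", "v", "length", "width_median", "width_var")]
  nd <- x$nodes
  e |>
    dplyr::left_join(dplyr::rename(nd, u = "id", x0 = "x", y0 = "y"),
                     by = "u") |>
    dplyr::left_join(dplyr::rename(nd, v = "id", x1 = "x", y1 = "y"),
                     by = "v")
}

#' @rdname tidy
#' @export
glance.spatial_graph <- function(x, ...) {
  tibble::tibble(
    n_vertices = n_vertices(x),
    n_edges = n_edges(x),
    total_length = sum(x$edges$length),
    mean_width = if (n_edges(x)) mean(x$edges$width_median) else NA_real_,
    n_components = if (n_vertices(x))
      as.integer(igraph::count_components(as_igraph(x))) else 0L)
}
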