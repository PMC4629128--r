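triangle_with_tail <- function() {
  graph_from_tables(
    nodes = data.frame(id = 1:4, x = c(10, 40, 10, 80), y = c(10, 10, 40, 80)),
    edges = data.frame(u = c(1, 2, 3, 2), v = c(2, 3, 1, 4),
                       length = c(30, 42, 30, 56),
                       width_median = c(3, 5, 3, 7), width_var = 0))
}

test_that("keep_largest_component keeps the triangle, not the stray path", {
  g <- graph_from_tables(
    nodes = data.frame(id = 1:5, x = c(10, 40, 10, 90, 100),
                       y = c(10, 10, 40, 90, 100)),
    edges = data.frame(u = c(1, 2, 3, 4), v = c(2, 3, 1, 5),
                       length = c(30, 42, 30, 14),
                       width_median = 3, width_var = 0))
  out <- keep_largest_component(g)
  expect_setequal(out$nodes$id, 1:3)
  expect_identical(n_edges(out), 3L)
  # identity on connected input
  tri <- triangle_with_tail()
  expect_identical(n_vertices(keep_largest_component(tri)), 4L)
})

test_that("component ties break on edges then lexicographic coordinate", {
  # two 2-vertex components: same order; right one has 2 parallel edges
  g <- graph_from_tables(
    nodes = data.frame(id = 1:4, x = c(50, 60, 5, 6), y = c(5, 5, 50, 50)),
    edges = data.frame(u = c(1, 3, 3), v = c(2, 4, 4),
                       length = c(10, 1.5, 2.5),
                       width_median = 3, width_var = 0))
  out <- keep_largest_component(g)
  expect_setequal(out$nodes$id, 3:4)              # more edges wins
  # equal vertices and edges: smallest lexicographic (x, y) coordinate
  g2 <- graph_from_tables(
    nodes = data.frame(id = 1:4, x = c(50, 60, 5, 6), y = c(5, 5, 50, 50)),
    edges = data.frame(u = c(1, 3), v = c(2, 4), length = c(10, 1.5),
                       width_median = 3, width_var = 0))
  out2 <- keep_largest_component(g2)
  expect_setequal(out2$nodes$id, 3:4)             # contains x = 5
})

test_that("smooth_degree_two contracts chains and conserves length", {
  g <- graph_from_tables(
    nodes = data.frame(id = 1:3, x = c(10, 20, 30), y = c(10, 10, 10)),
    edges = data.frame(u = c(1, 2), v = c(2, 3), length = c(10, 10),
                       width_median = c(3, 5), width_var = 0))
  out <- smooth_degree_two(g)
  expect_identical(n_vertices(out), 2L)
  expect_identical(n_edges(out), 1L)
  expect_equal(out$edges$length, 20)
  # degree-3 vertices are untouched
  tri <- triangle_with_tail()
  expect_identical(n_vertices(smooth_degree_two(tri)), 4L)
})

test_that("smoothing never introduces parallel edges (triangle clause)", {
  tri <- graph_from_tables(
    nodes = data.frame(id = 1:3, x = c(10, 40, 10), y = c(10, 10, 40)),
    edges = data.frame(u = c(1, 2, 3), v = c(2, 3, 1),
                       length = c(30, 42, 30),
                       width_median = 3, width_var = 0))
  out <- smooth_degree_two(tri)
  keys <- paste(pmin(out$edges$u, out$edges$v),
                pmax(out$edges$u, out$edges$v))
  expect_identical(anyDuplicated(keys), 0L)
  expect_equal(sum(out$edges$length), 102)
})

test_that("smoothing recomputes widths from concatenated diameters", {
  p1 <- bres_path(c(0, 0), c(10, 0)); p2 <- bres_path(c(10, 0), c(20, 0))
  g <- spatial_graph(
    nodes = data.frame(id = 1:3, x = c(0, 10, 20), y = 0),
    edges = tibble::tibble(u = c(1L, 2L), v = c(2L, 3L),
                           length = c(10, 10),
                           width_median = c(3, 9), width_var = c(0, 0),
                           path = list(p1, p2),
                           diam = list(rep(3, 11), rep(9, 11))),
    dim = c(64, 64))
  out <- smooth_degree_two(g)
  expect_identical(n_edges(out), 1L)
  expect_equal(out$edges$width_median, median(c(rep(3, 11), rep(9, 10))))
  expect_gt(out$edges$width_var, 0)
  expect_identical(nrow(out$edges$path[[1]]), 21L)
})

test_that("keep_cycles removes exactly the bridges and dead ends", {
  tri <- triangle_with_tail()
  out <- keep_cycles(tri)
  expect_setequal(out$nodes$id, 1:3)
  expect_identical(n_edges(out), 3L)
  # trees vanish entirely
  tree <- graph_from_tables(
    nodes = data.frame(id = 1:4, x = c(0, 10, 20, 30), y = 0),
    edges = data.frame(u = 1:3, v = 2:4, length = 10,
                       width_median = 3, width_var = 0))
  expect_identical(n_vertices(keep_cycles(tree)), 0L)
  # two triangles joined by a bridge: both survive, bridge goes
  g2 <- graph_from_tables(
    nodes = data.frame(id = 1:6, x = c(0, 10, 5, 50, 60, 55),
                       y = c(0, 0, 10, 0, 0, 10)),
    edges = data.frame(u = c(1, 2, 3, 4, 5, 6, 2), v = c(2, 3, 1, 5, 6, 4, 4),
                       length = c(10, 12, 12, 10, 12, 12, 40),
                       width_median = 3, width_var = 0))
  expect_identical(sum(oracle_bridges(g2)), 1L)
  out2 <- keep_cycles(g2)
  expect_identical(n_edges(out2), 6L)
  expect_identical(n_vertices(out2), 6L)
  expect_false(any(oracle_bridges(out2)))
})

test_that("self-loops and parallel pairs count as cycles", {
  g <- graph_from_tables(
    nodes = data.frame(id = 1:3, x = c(0, 20, 60), y = 0),
    edges = data.frame(u = c(1, 1, 2, 2), v = c(1, 2, 1, 3),
                       length = c(8, 20, 22, 40),
                       width_median = 3, width_var = 0))
  out <- keep_cycles(g)
  expect_setequal(out$nodes$id, 1:2)
  expect_identical(n_edges(out), 3L)              # loop + parallel pair
})

test_that("filters are idempotent and subgraph-producing on random graphs", {
  for (seed in 1:25) {
    g <- random_spatial_graph(n = 8, m = 12, seed = seed)
    for (f in list(keep_largest_component, keep_cycles)) {
      h <- f(g)
      expect_true(all(h$nodes$id %in% g$nodes$id))
      # surviving coordinates unchanged
      expect_identical(h$nodes,
                       g$nodes[match(h$nodes$id, g$nodes$id), ])
      expect_identical(f(h), h)
    }
    h <- smooth_degree_two(g)
    expect_equal(sum(h$edges$length), sum(g$edges$length),
                 tolerance = 1e-9)
    h2 <- smooth_degree_two(h)
    expect_identical(n_vertices(h2), n_vertices(h))
    expect_identical(n_edges(h2), n_edges(h))
    out <- keep_cycles(g)
    if (n_edges(out)) {
      expect_false(any(oracle_bridges(out)))
      deg <- graph_degrees(out)
      expect_true(all(deg >= 2))
    }
  }
})

test_that("apply_filters composes left to right and order can matter", {
  g <- random_spatial_graph(n = 9, m = 12, seed = 3)
  expect_identical(apply_filters(g, list()), g)
  both <- apply_filters(g, list("largest_component", "cycles"))
  onlyc <- keep_cycles(g)
  # [largest, cycles] output is a subgraph of [cycles] alone
  expect_true(all(both$nodes$id %in% onlyc$nodes$id))
  # a distinguishing fixture: small cycle component + large tree component
  g2 <- graph_from_tables(
    nodes = data.frame(id = 1:8, x = c(0, 10, 5, 40, 50, 60, 70, 80),
                       y = c(0, 0, 8, 0, 0, 0, 0, 0)),
    edges = data.frame(u = c(1, 2, 3, 4, 5, 6, 7), v = c(2, 3, 1, 5, 6, 7, 8),
                       length = c(10, 10, 10, 10, 10, 10, 10),
                       width_median = 3, width_var = 0))
  a <- apply_filters(g2, list("cycles", "largest_component"))
  b <- apply_filters(g2, list("largest_component", "cycles"))
  expect_identical(n_vertices(a), 3L)             # triangle survives
  expect_identical(n_vertices(b), 0L)             # tree chosen, then emptied
  expect_error(apply_filters(g2, list("nope")), "unknown graph filter")
})
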