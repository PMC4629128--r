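test_that("node criterion matches brute-force component counting on all
           256 neighbourhood patterns", {
  for (code in 0:255) {
    bits <- as.logical(bitwAnd(code, 2^(0:7)))
    m <- matrix(FALSE, 5, 5)
    m[3, 3] <- TRUE
    pos <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
    for (i in 1:8) if (bits[i]) m[3 + pos[[i]][1], 3 + pos[[i]][2]] <- TRUE
    nodes <- detect_nodes(binary_image(m))
    is_node <- any(nodes$x == 2 & nodes$y == 2)
    ncomp <- oracle_ring_components(bits)
    expect_identical(is_node, ncomp == 1L || ncomp >= 3L,
                     label = sprintf("pattern %d", code))
  }
})

test_that("endpoints and junctions of simple shapes are detected", {
  line <- matrix(FALSE, 5, 9); line[3, 3:7] <- TRUE
  nd <- detect_nodes(binary_image(line))
  expect_identical(nrow(nd), 2L)
  expect_setequal(nd$x, c(2L, 6L))

  plus <- matrix(FALSE, 9, 9)
  plus[5, 2:8] <- TRUE; plus[2:8, 5] <- TRUE
  nd <- detect_nodes(binary_image(plus))
  expect_identical(nrow(nd), 5L)                 # centre + 4 endpoints
  expect_true(any(nd$x == 4 & nd$y == 4))

  dot <- matrix(FALSE, 5, 5); dot[3, 3] <- TRUE
  expect_identical(nrow(detect_nodes(binary_image(dot))), 0L)
})

test_that("a path skeleton between two endpoints traces one edge", {
  m <- matrix(FALSE, 5, 12); m[3, 2:11] <- TRUE
  ed <- trace_edges(as_skeleton_test(m))
  expect_identical(nrow(ed), 1L)
  expect_equal(edge_length(ed$path[[1]]), 9)
  p <- ed$path[[1]]
  nodes <- attr(ed, "nodes")
  expect_identical(as.integer(p[1, ]),
                   c(nodes$x[ed$u[1]], nodes$y[ed$u[1]]))
})

test_that("a triangle loop through three junctions traces three edges", {
  m <- matrix(FALSE, 12, 12)
  m[3, 3:9] <- TRUE               # top side
  for (i in 0:3) {                # two slanted sides meeting at (7, 6)
    m[3 + i, 3 + i] <- TRUE
    m[3 + i, 9 - i] <- TRUE
  }
  m[7, 6] <- TRUE
  # attach stubs at the corners so they become junction nodes
  m[2, 2] <- TRUE; m[2, 10] <- TRUE; m[8, 6] <- TRUE
  sk <- as_skeleton_test(m)
  nd <- detect_nodes(sk)
  ed <- trace_edges(sk)
  pairs <- paste(pmin(ed$u, ed$v), pmax(ed$u, ed$v))
  # three triangle sides plus three stubs
  expect_identical(nrow(ed), 6L)
  expect_identical(anyDuplicated(pairs), 0L)
})

test_that("a node-free ring is anchored and traced as a self-loop", {
  m <- matrix(FALSE, 12, 12)
  m[3, 4:8] <- TRUE; m[9, 4:8] <- TRUE
  m[4:8, 3] <- TRUE; m[4:8, 9] <- TRUE
  m[3, 3] <- TRUE; m[3, 9] <- TRUE; m[9, 3] <- TRUE; m[9, 9] <- TRUE
  expect_identical(nrow(detect_nodes(binary_image(m))), 0L)
  ed <- trace_edges(as_skeleton_test(m))
  expect_identical(nrow(ed), 1L)
  expect_identical(ed$u[1], ed$v[1])
  nodes <- attr(ed, "nodes")
  expect_identical(nrow(nodes), 1L)
  expect_identical(c(nodes$x[1], nodes$y[1]), c(2L, 2L))  # row-major least
  # the loop covers the whole ring
  expect_equal(edge_length(ed$path[[1]]), sum(m), tolerance = 0.3)
})

test_that("edge lengths weight axial and diagonal steps correctly", {
  expect_equal(edge_length(cbind(2:6, rep(1, 5))), 4)
  expect_equal(edge_length(cbind(1:3, 1:3)), 2 * sqrt(2))
  expect_equal(edge_length(matrix(c(4, 4), 1)), 0)
  expect_error(edge_length(rbind(c(0, 0), c(3, 0))), "integrity")
  expect_error(edge_length(rbind(c(0, 0), c(0, 0))), "integrity")
})

test_that("edge widths recover drawn stroke widths from the distance map", {
  for (w in c(3, 7)) {
    img <- stroke_img(48, w)
    seg <- seg_otsu(img)
    dist <- distance_map(seg)
    centre_row <- (48 - w) %/% 2 + (w - 1) %/% 2
    path <- cbind(x = 14:33, y = rep(centre_row, 20))
    ws <- edge_widths(path, dist)
    expect_lte(abs(ws$width_median - w), 1)
    expect_identical(ws$width_var, 0)
  }
  # tapering stroke: median between the extremes, variance positive
  m <- matrix(20, 40, 60)
  for (c in 10:50) {
    w <- round(3 + (c - 10) * 6 / 40)     # 3 -> 9
    m[(20 - w %/% 2):(20 + w %/% 2), c] <- 220
  }
  seg <- seg_otsu(raster_image(m))
  dist <- distance_map(seg)
  path <- cbind(x = 12:48, y = rep(19, 37))
  ws <- edge_widths(path, dist)
  expect_gt(ws$width_median, 3); expect_lt(ws$width_median, 9)
  expect_gt(ws$width_var, 0)
  expect_error(edge_widths(cbind(1, 1), dist), "background")
})

test_that("build_graph enforces integrity and keeps parallel edges", {
  nodes <- data.frame(x = c(2, 10), y = c(2, 2))
  p1 <- cbind(x = 2:10, y = rep(2, 9))
  p2 <- cbind(x = 2:10, y = c(2, 3, 3, 3, 3, 3, 3, 3, 2))
  g <- build_graph(nodes, tibble::tibble(u = c(1L, 1L), v = c(2L, 2L),
                                         path = list(p1, p2)))
  expect_identical(n_vertices(g), 2L)
  expect_identical(n_edges(g), 2L)
  expect_error(
    build_graph(nodes, tibble::tibble(u = 1L, v = 5L, path = list(p1))),
    "dangling")
  empty <- build_graph(data.frame(x = double(), y = double()),
                       tibble::tibble())
  expect_identical(n_vertices(empty), 0L)
})

test_that("merge_close_nodes collapses clusters and drops collapse loops", {
  # two degree-3 junctions two pixels apart (a split degree-4 junction)
  nodes <- data.frame(id = 1:6,
                      x = c(20, 22, 10, 10, 32, 32),
                      y = c(20, 20, 10, 30, 10, 30))
  mkpath <- function(a, b)
    bres_path(c(nodes$x[a], nodes$y[a]), c(nodes$x[b], nodes$y[b]))
  edges <- tibble::tibble(
    u = c(1L, 1L, 1L, 2L, 2L), v = c(2L, 3L, 4L, 5L, 6L),
    path = list(mkpath(1, 2), mkpath(1, 3), mkpath(1, 4), mkpath(2, 5),
                mkpath(2, 6)))
  edges$length <- vapply(edges$path, edge_length, numeric(1))
  edges$width_median <- 3; edges$width_var <- 0
  g <- spatial_graph(cbind(nodes), edges, dim = c(64, 64))
  merged <- merge_close_nodes(g, 3)
  expect_identical(n_vertices(merged), 5L)
  deg <- graph_degrees(merged)
  expect_identical(max(deg), 4L)                  # one degree-4 junction
  expect_identical(n_edges(merged), 4L)           # connecting edge dropped
  # radius 0 and out-of-range radii are identities
  expect_identical(n_vertices(merge_close_nodes(g, 0)), 6L)
  expect_identical(n_edges(merge_close_nodes(g, 1)), 5L)
})

test_that("trace covers every skeleton pixel exactly once and detected
           degrees stay at four before merging", {
  for (seed in c(2, 7)) {
    g0 <- generate_truth_graph(10, seed = seed, dim = c(256, 256),
                               margin = 20, min_sep = 40)
    seg <- seg_otsu(render_graph(g0))
    sk <- guo_hall_thin(seg)
    ed <- trace_edges(sk)
    nodes <- attr(ed, "nodes")
    node_set <- paste(nodes$x, nodes$y)
    used <- table(unlist(lapply(ed$path, function(p) {
      keys <- paste(p[, 1], p[, 2])
      keys[!keys %in% node_set]
    })))
    expect_true(all(used == 1))                   # no pixel double-claimed
    # coverage: interior pixels of node-bearing components are all claimed
    skel_px <- sum(sk)
    expect_gte(length(used) + nrow(nodes), 0.97 * skel_px)
    g <- build_graph(nodes, ed, dist = distance_map(seg),
                     dim = c(256, 256))
    expect_lte(max(graph_degrees(g)), 4L)
  }
})
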