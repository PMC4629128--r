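test_that("the truth generator is deterministic and connected", {
  g1 <- generate_truth_graph(15, seed = 33, dim = c(320, 320),
                             margin = 25, min_sep = 45)
  g2 <- generate_truth_graph(15, seed = 33, dim = c(320, 320),
                             margin = 25, min_sep = 45)
  expect_identical(g1$nodes, g2$nodes)
  expect_identical(g1$edges$length, g2$edges$length)
  expect_equal(igraph::count_components(as_igraph(g1)), 1)
  # tiny case stays connected too
  g3 <- generate_truth_graph(3, seed = 2, dim = c(128, 128), margin = 15,
                             min_sep = 30)
  expect_equal(igraph::count_components(as_igraph(g3)), 1)
  expect_gte(n_edges(g3), 1L)
})

test_that("generated graphs are planar straight-line graphs
           (no two edge segments cross)", {
  g <- generate_truth_graph(50, seed = 17)
  segs <- lapply(seq_len(n_edges(g)), function(i) {
    ctrl <- netextract:::edge_ctrl(g, i)
    cbind(ctrl[-nrow(ctrl), , drop = FALSE], ctrl[-1, , drop = FALSE])
  })
  segs <- do.call(rbind, segs)
  crosses <- function(p1, p2, p3, p4) {
    d <- function(a, b, c)
      sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
    if (any(vapply(list(p3, p4), function(q)
      all(q == p1) || all(q == p2), logical(1)))) return(FALSE)
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    d1 != d2 && d3 != d4 && d1 != 0 && d2 != 0 && d3 != 0 && d4 != 0
  }
  n <- nrow(segs)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    expect_false(crosses(segs[i, 1:2], segs[i, 3:4],
                         segs[j, 1:2], segs[j, 3:4]),
                 label = sprintf("segments %d and %d cross", i, j))
  }
  # degrees mostly small; no degree-2 vertices by construction
  deg <- graph_degrees(g)
  expect_false(any(deg == 2))
  expect_lte(max(deg), 4L)
})

test_that("widths are odd integers from the requested range and the
           separation constraint is honoured", {
  g <- generate_truth_graph(20, seed = 5, dim = c(512, 512), margin = 30,
                            min_sep = 60, width_range = c(3, 11))
  expect_true(all(g$edges$width_median %in% c(3, 5, 7, 9, 11)))
  d <- as.matrix(stats::dist(cbind(g$nodes$x, g$nodes$y)))
  diag(d) <- Inf
  expect_gte(min(d), 60)
  expect_error(generate_truth_graph(50, seed = 1, dim = c(64, 64),
                                    margin = 10, min_sep = 60),
               "infeasible separation")
})

test_that("rendering draws strokes of the requested geometry", {
  g <- spatial_graph(
    nodes = data.frame(id = 1:2, x = c(5, 25), y = c(10, 10)),
    edges = tibble::tibble(u = 1L, v = 2L, length = 20, width_median = 3,
                           width_var = 0,
                           path = list(bres_path(c(5, 10), c(25, 10)))),
    dim = c(32, 32))
  img <- render_graph(g, fg = 220, bg = 30)
  m <- unclass(img)
  expect_identical(sort(unique(as.vector(m))), c(30, 220))
  expect_identical(as.numeric(m[10:12, 15]), rep(220, 3))  # 3 px tall
  expect_identical(m[8, 15], 30)
  expect_identical(m[14, 15], 30)
  # otsu recovers the stroke mask with the right width
  seg <- seg_otsu(img)
  dist <- distance_map(seg)
  expect_lte(abs((2 * max(dist[, 15]) - 1) - 3), 1)
  # empty graph renders a blank background
  e <- render_graph(spatial_graph(dim = c(16, 16)), fg = 200, bg = 10)
  expect_identical(unique(as.vector(unclass(e))), 10)
  expect_error(render_graph(g, fg = 30, bg = 30), "differ")
})

test_that("distortion conditions have their documented identities", {
  set <- small_test_set(1, seed = 3)
  img <- set[[1]]$image; truth <- set[[1]]$truth
  bg <- attr(img, "bg"); fg <- attr(img, "fg")
  expect_identical(unclass(condition_gradient(img, bg, bg)),
                   unclass(img), ignore_attr = TRUE)
  expect_identical(unclass(condition_brightness(img, truth, fg, fg,
                                                seed = 1)),
                   unclass(img), ignore_attr = TRUE)
  # gradient leaves foreground pixels untouched and ramps the background
  gr <- condition_gradient(img, 0, 160)
  fg_mask <- unclass(img) != bg
  expect_identical(unclass(gr)[fg_mask], unclass(img)[fg_mask])
  bgvals <- unclass(gr)[, 300][unclass(img)[, 300] == bg]
  expect_true(all(abs(bgvals - 160 * 299 / 319) <= 1))
})

test_that("blurring widens the extracted stroke width", {
  img <- stroke_img(64, 5)
  g0 <- run_pipeline(img, predefined_pipeline("otsu"))$final_graph
  gb <- run_pipeline(condition_blur(img, 2),
                     predefined_pipeline("otsu"))$final_graph
  expect_gt(gb$edges$width_median[1], g0$edges$width_median[1])
})

test_that("brightness resampling is reproducible under its seed", {
  set <- small_test_set(1, seed = 4)
  b1 <- condition_brightness(set[[1]]$image, set[[1]]$truth, 60, 255,
                             seed = 9)
  b2 <- condition_brightness(set[[1]]$image, set[[1]]$truth, 60, 255,
                             seed = 9)
  expect_identical(unclass(b1), unclass(b2))
})

test_that("distort_truth applies filters and reproducible deletions", {
  g <- generate_truth_graph(15, seed = 6, dim = c(320, 320), margin = 25,
                            min_sep = 45)
  expect_identical(distort_truth(g), g)
  dc <- distort_truth(g, ops = list("cycles"))
  expect_true(n_edges(dc) <= n_edges(g))
  expect_false(any(oracle_bridges(dc)))
  d1 <- distort_truth(g, edge_delete_prob = 0.2, seed = 5)
  d2 <- distort_truth(g, edge_delete_prob = 0.2, seed = 5)
  expect_identical(d1$edges$length, d2$edges$length)
  expect_lte(n_edges(d1), n_edges(g))
  expect_equal(igraph::count_components(as_igraph(d1)), 1)
})

test_that("test sets are reproducible and carry their condition", {
  s1 <- small_test_set(3, "ideal", seed = 11)
  s2 <- small_test_set(3, "ideal", seed = 11)
  expect_length(s1, 3L)
  expect_true(all(vapply(s1, function(p) p$condition == "ideal",
                         logical(1))))
  for (i in 1:3) {
    expect_identical(unclass(s1[[i]]$image), unclass(s2[[i]]$image))
    expect_identical(s1[[i]]$truth$edges$length,
                     s2[[i]]$truth$edges$length)
  }
  # distillation yields truths the reference pipeline reproduces closely
  B <- run_pipeline(s1[[1]]$image, method_pipeline("otsu"))$final_graph
  expect_gte(similarity_score(s1[[1]]$truth, B), 0.9)
  # undistilled sets keep the geometric truths
  raw <- build_test_set(1, "ideal", seed = 11, distill = 0,
                        params = list(n_vertices = 12, dim = c(320, 320),
                                      margin = 25, min_sep = 45))
  expect_true(all(raw[[1]]$truth$edges$width_median %in% c(3, 5, 7, 9, 11)))
})
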