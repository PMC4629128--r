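test_that("otsu separates a bimodal image and matches brute-force search", {
  m <- matrix(20, 30, 30); m[10:14, 5:25] <- 220
  seg <- seg_otsu(raster_image(m))
  expect_identical(unclass(seg), m == 220, ignore_attr = TRUE)

  # brute-force between-class variance maximization on the histogram
  vals <- as.vector(m)
  best_t <- which.max(vapply(0:254, function(t) {
    w0 <- mean(vals <= t); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) return(-Inf)
    mu0 <- mean(vals[vals <= t]); mu1 <- mean(vals[vals > t])
    w0 * w1 * (mu0 - mu1)^2
  }, numeric(1))) - 1
  expect_gte(best_t, 20); expect_lt(best_t, 220)
  # the mask implied by the brute-force threshold agrees
  expect_identical(unclass(seg), m > best_t, ignore_attr = TRUE)
})

test_that("otsu on a constant image yields empty foreground", {
  seg <- seg_otsu(blank_img(12, 99))
  expect_identical(sum(seg), 0L)
})

test_that("otsu invert flag targets dark structures", {
  m <- matrix(220, 30, 30); m[10:12, 5:25] <- 20
  seg <- seg_otsu(raster_image(m), invert = TRUE)
  expect_identical(unclass(seg), m == 20, ignore_attr = TRUE)
})

test_that("adaptive threshold cancels a linear background gradient", {
  g <- generate_truth_graph(8, seed = 3, dim = c(256, 256), margin = 20,
                            min_sep = 40)
  ideal <- render_graph(g)
  withramp <- condition_gradient(ideal, 0, 120)
  a1 <- seg_adaptive(ideal, 51, 10)
  a2 <- seg_adaptive(withramp, 51, 10)
  # identical masks away from a border strip
  inner <- 30:226
  expect_identical(unclass(a1)[inner, inner], unclass(a2)[inner, inner])
})

test_that("adaptive threshold edge cases", {
  expect_identical(sum(seg_adaptive(blank_img(16, 50), 5, 2)), 0L)
  expect_error(seg_adaptive(blank_img(8), 11, 2), "larger than the image")
  expect_error(seg_adaptive(blank_img(8), 4, 2), "odd")
  # a single bright line is recovered as by otsu
  img <- stroke_img(48, 3)
  expect_identical(unclass(seg_adaptive(img, 15, 5)),
                   unclass(seg_otsu(img)))
})

test_that("erosion marker of a solid square has the expected core", {
  sq <- matrix(FALSE, 20, 20); sq[5:16, 5:16] <- TRUE
  mk <- marker_erosion(binary_image(sq), 1)
  expect_identical(sum(mk == 2L), 100L)           # 10 x 10 core
  core <- matrix(FALSE, 20, 20); core[6:15, 6:15] <- TRUE
  expect_identical(unclass(mk) == 2L, core, ignore_attr = TRUE)
  # sure background is the complement of the dilated square
  expect_identical(sum(mk == 1L), 400L - 14L * 14L)
})

test_that("distance-transform marker of a disk is a concentric disk", {
  n <- 41
  yy <- matrix(seq_len(n), n, n); xx <- t(yy)
  disk <- (yy - 21)^2 + (xx - 21)^2 <= 10^2
  mk <- marker_distance_transform(binary_image(disk), 0.5)
  core <- unclass(mk) == 2L
  # every sure-fg pixel lies within ~radius 6 of the centre and the core
  # contains the radius-4 disk (exact EDT of a disk: d = 10 - r + O(1))
  dc <- sqrt((yy - 21)^2 + (xx - 21)^2)
  expect_true(all(dc[core] <= 6.5))
  expect_true(all(core[dc <= 4]))
})

test_that("degenerate markers are rejected with a parameter message", {
  single <- matrix(FALSE, 9, 9); single[5, 5] <- TRUE
  expect_error(marker_erosion(binary_image(single), 1), "degenerate marker")
  expect_error(marker_erosion(binary_image(matrix(FALSE, 5, 5))), "empty")
  expect_error(marker_distance_transform(binary_image(single), 1.2),
               "fraction")
})

test_that("watershed recovers an ideal render from an eroded otsu marker", {
  g <- generate_truth_graph(6, seed = 8, dim = c(200, 200), margin = 20,
                            min_sep = 40, width_range = c(7, 11))
  img <- render_graph(g)
  guess <- seg_otsu(img)
  ws <- seg_watershed(img, marker_erosion(guess, 2))
  # masks agree within a 1-px boundary band: every disagreeing pixel is
  # adjacent to the other mask (Hausdorff <= 1)
  d_guess <- distance_map(guess)
  d_ws <- distance_map(ws)
  only_ws <- unclass(ws) & !unclass(guess)
  only_g <- unclass(guess) & !unclass(ws)
  bgd_g <- distance_map(binary_image(!unclass(guess)))
  bgd_w <- distance_map(binary_image(!unclass(ws)))
  if (any(only_ws)) expect_lte(max(bgd_g[only_ws] - 0), 1.5)
  if (any(only_g)) expect_lte(max(bgd_w[only_g] - 0), 1.5)
})

test_that("watershed with an all-foreground seed floods everything", {
  m <- matrix(0L, 12, 12); m[] <- 2L; m[1, 1] <- 1L
  marker <- structure(m, class = "marker_image")
  out <- seg_watershed(blank_img(12, 100), marker)
  expect_gte(mean(out), 0.99)
})

test_that("watershed recovers two separated blobs from per-blob seeds", {
  m <- matrix(20, 40, 40)
  m[5:15, 5:15] <- 220; m[25:35, 25:35] <- 220
  img <- raster_image(m)
  mk <- marker_erosion(seg_otsu(img), 1)
  ws <- seg_watershed(img, mk)
  expect_identical(oracle_n_components(ws, conn = 8), 2L)
})

test_that("watershed requires both seed classes", {
  m <- matrix(0L, 8, 8); m[4, 4] <- 2L
  expect_error(seg_watershed(blank_img(8), structure(m, class = "marker_image")),
               "degenerate marker")
})

test_that("grabcut matches otsu on an ideal high-contrast render", {
  g <- generate_truth_graph(5, seed = 21, dim = c(96, 96), margin = 12,
                            min_sep = 25, width_range = c(5, 9))
  img <- render_graph(g)
  ot <- seg_otsu(img)
  gc <- seg_grabcut(img, marker_erosion(ot, 1), iterations = 2)
  disagree <- sum(unclass(gc) != unclass(ot))
  expect_lte(disagree / sum(ot), 0.05)
  # and never at distance > 1 px from the otsu boundary
  bgd <- distance_map(ot); fgd <- distance_map(binary_image(!unclass(ot)))
  band <- bgd <= 1.5 & fgd <= 1.5 | bgd > 0 & bgd <= 1.5 | fgd > 0 & fgd <= 1.5
  expect_true(all(band[unclass(gc) != unclass(ot)]))
})

test_that("grabcut returns the marker when every pixel is pinned", {
  m <- matrix(1L, 16, 16); m[5:9, 5:9] <- 2L
  marker <- structure(m, class = "marker_image")
  out <- seg_grabcut(blank_img(16, 60), marker, iterations = 1)
  expect_identical(unclass(out), m == 2L, ignore_attr = TRUE)
})

test_that("segmentation is deterministic", {
  g <- generate_truth_graph(5, seed = 4, dim = c(96, 96), margin = 12,
                            min_sep = 25)
  img <- condition_blur(render_graph(g), 1)
  for (f in list(seg_otsu,
                 function(x) seg_adaptive(x, 31, 6),
                 function(x) seg_watershed(x, marker_erosion(seg_otsu(x), 1)),
                 function(x) seg_grabcut(x, marker_erosion(seg_otsu(x), 1),
                                         iterations = 2))) {
    expect_identical(unclass(f(img)), unclass(f(img)))
  }
})
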