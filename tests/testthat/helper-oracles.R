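# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive results by brute force or from published
# definitions, independent of the package's own code paths.

# ---- fixture builders -----------------------------------------------------

blank_img <- function(n = 32, value = 0) raster_image(matrix(value, n, n))

# horizontal stroke of odd width w centred in an n x n image
stroke_img <- function(n = 64, w = 3, fg = 220, bg = 20, margin = 8) {
  m <- matrix(bg, n, n)
  r0 <- (n - w) %/% 2 + 1
  m[r0:(r0 + w - 1), margin:(n - margin)] <- fg
  raster_image(m)
}

# random blob mask: union of random axis-aligned rectangles and disks
random_blob_mask <- function(n = 128, k = 6, seed = 1) {
  set.seed(seed)
  m <- matrix(FALSE, n, n)
  for (i in seq_len(k)) {
    if (runif(1) < 0.5) {
      r <- sort(sample.int(n, 2)); c <- sort(sample.int(n, 2))
      m[r[1]:r[2], c[1]:c[2]] <- TRUE
    } else {
      cy <- runif(1, 1, n); cx <- runif(1, 1, n); rad <- runif(1, 2, n / 5)
      yy <- matrix(seq_len(n), n, n); xx <- t(yy)
      m <- m | ((yy - cy)^2 + (xx - cx)^2 <= rad^2)
    }
  }
  binary_image(m)
}

# random spatial multigraph (no pixel paths); may contain parallel edges
# and self-loops
random_spatial_graph <- function(n = 10, m = 14, seed = 1, dim = c(256, 256)) {
  set.seed(seed)
  nodes <- data.frame(id = seq_len(n),
                      x = sample.int(dim[2] - 1, n, replace = TRUE),
                      y = sample.int(dim[1] - 1, n, replace = TRUE))
  u <- sample.int(n, m, replace = TRUE)
  v <- sample.int(n, m, replace = TRUE)
  len <- sqrt((nodes$x[u] - nodes$x[v])^2 + (nodes$y[u] - nodes$y[v])^2) +
    runif(m, 1, 5)
  edges <- data.frame(u = u, v = v, length = len,
                      width_median = sample(3:9, m, replace = TRUE),
                      width_var = runif(m, 0, 1))
  spatial_graph(nodes, edges, dim = dim)
}

# tiny graphs from explicit tables
graph_from_tables <- function(nodes, edges, dim = c(128, 128)) {
  spatial_graph(nodes, edges, dim = dim)
}

# ---- connected-component oracles -----------------------------------------

# component count of a logical mask under 4- or 8-connectivity, via igraph
# built directly from pixel adjacencies (independent of package internals)
oracle_n_components <- function(mask, conn = 8) {
  m <- unclass(mask)
  idx <- which(m)
  if (!length(idx)) return(0L)
  nr <- nrow(m)
  id <- matrix(0L, nr, ncol(m)); id[idx] <- seq_along(idx)
  offs <- if (conn == 8) list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
          else list(c(1, 0), c(0, 1))
  pairs <- NULL
  for (o in offs) {
    dr <- o[1]; dc <- o[2]
    nrm <- nrow(m); ncm <- ncol(m)
    r1 <- max(1, 1 + dr):min(nrm, nrm + dr)
    c1 <- max(1, 1 + dc):min(ncm, ncm + dc)
    a <- id[r1 - dr, c1 - dc, drop = FALSE]; b <- id[r1, c1, drop = FALSE]
    ok <- a > 0 & b > 0
    pairs <- rbind(pairs, cbind(a[ok], b[ok]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(pairs) && nrow(pairs)) g <- igraph::add_edges(g, t(pairs))
  as.integer(igraph::count_components(g))
}

# ---- Guo-Hall reference (plain R, straight from the published operator) --

gh_reference <- function(mask) {
  m <- unclass(mask) * 1L
  nr <- nrow(m); nc <- ncol(m)
  px <- function(r, c) if (r < 1 || c < 1 || r > nr || c > nc) 0L else m[r, c]
  repeat {
    changed <- FALSE
    for (iter in 0:1) {
      del <- NULL
      for (c in seq_len(nc)) for (r in seq_len(nr)) {
        if (!m[r, c]) next
        p2 <- px(r - 1, c);     p3 <- px(r - 1, c + 1)
        p4 <- px(r,     c + 1); p5 <- px(r + 1, c + 1)
        p6 <- px(r + 1, c);     p7 <- px(r + 1, c - 1)
        p8 <- px(r,     c - 1); p9 <- px(r - 1, c - 1)
        C <- ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
             ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2))
        N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
        N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
        N <- min(N1, N2)
        mm <- if (iter == 0) (p6 | p7 | (!p9)) & p8 else
          (p2 | p3 | (!p5)) & p4
        if (C == 1 && N >= 2 && N <= 3 && mm == 0)
          del <- rbind(del, c(r, c))
      }
      if (!is.null(del)) {
        changed <- TRUE
        m[del] <- 0L
      }
    }
    if (!changed) break
  }
  binary_image(m > 0)
}

# ---- node criterion oracle ------------------------------------------------

# number of 4-connected white components among the 8 neighbours of the
# centre of a 3x3 pattern, by explicit BFS over the neighbour pixels
oracle_ring_components <- function(bits) {
  # bits: logical length-8 in order N, NE, E, SE, S, SW, W, NW
  pos <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
              c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  on <- which(bits)
  if (!length(on)) return(0L)
  adj <- function(i, j) {
    d <- abs(pos[[i]] - pos[[j]])
    sum(d) == 1L          # 4-adjacent pixels
  }
  seen <- rep(FALSE, length(on)); ncomp <- 0L
  for (s in seq_along(on)) {
    if (seen[s]) next
    ncomp <- ncomp + 1L
    stack <- s
    while (length(stack)) {
      i <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[i]) next
      seen[i] <- TRUE
      for (j in seq_along(on))
        if (!seen[j] && adj(on[i], on[j])) stack <- c(stack, j)
    }
  }
  ncomp
}

# ---- bridge oracle --------------------------------------------------------

# an edge is a bridge iff removing it increases the number of components
oracle_bridges <- function(g) {
  ig <- as_igraph(g)
  base <- igraph::count_components(ig)
  vapply(seq_len(igraph::ecount(ig)), function(i)
    igraph::count_components(igraph::delete_edges(ig, i)) > base,
    logical(1))
}

# ---- brute-force assignment oracle ---------------------------------------

# minimum total distance over all injective assignments of A vertices to
# B vertices (pairs beyond the radius forbidden), maximizing cardinality
oracle_assignment <- function(ax, ay, bx, by, radius) {
  nA <- length(ax); nB <- length(bx)
  dmat <- sqrt(outer(ax, bx, "-")^2 + outer(ay, by, "-")^2)
  best <- list(card = -1L, cost = Inf)
  # enumerate assignments of each A vertex to a B vertex or none
  rec <- function(i, used, cost, card) {
    if (i > nA) {
      if (card > best$card ||
          (card == best$card && cost < best$cost - 1e-12))
        best <<- list(card = card, cost = cost)
      return(invisible())
    }
    rec(i + 1L, used, cost, card)          # A_i unmatched
    for (j in seq_len(nB)) {
      if (!used[j] && dmat[i, j] <= radius) {
        used[j] <- TRUE
        rec(i + 1L, used, cost + dmat[i, j], card + 1L)
        used[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, nB), 0, 0L)
  best
}

# small helper: similarity-protocol test set at reduced scale (kept small
# so the suite stays fast; the acceptance script runs the full protocol)
small_test_set <- function(n, condition = "ideal", seed = 1, ...) {
  build_test_set(n, condition,
                 params = list(n_vertices = 12, dim = c(320, 320),
                               margin = 25, min_sep = 45, ...),
                 seed = seed)
}

as_skeleton_test <- function(m) {
  netextract:::as_skeleton(binary_image(m))
}

bres_path <- function(p, q) {
  out <- netextract:::bresenham(p, q)
  colnames(out) <- c("x", "y")
  out
}

# background 4-component count honouring the implicit background padding
# outside the frame (regions touching the border connect through it)
oracle_bg_components <- function(mask) {
  m <- unclass(mask)
  p <- matrix(FALSE, nrow(m) + 2L, ncol(m) + 2L)
  p[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  oracle_n_components(binary_image(!p), 4)
}
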