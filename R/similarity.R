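#' Vertex and edge correspondence between two spatial graphs
#'
#' Computes an injective matching between the vertex sets of a ground
#' truth `A` and an extracted graph `B`: among all pairs within `radius`
#' pixels of each other, the matching of maximum cardinality with minimum
#' total distance is chosen (optimal assignment via maximum-weight
#' bipartite matching, not greedy nearest neighbour, so the result is
#' deterministic).  Two edges correspond when both endpoint pairs
#' correspond; parallel edges between the same matched vertex pair are
#' paired off in order of increasing length.
#'
#' @param A,B [spatial_graph()] objects (A: reference, B: candidate).
#' @param radius matching radius in pixels.  Default: 10 px at a 1024-px
#'   image scale, scaled proportionally with the reference image size.
#' @return a `correspondence`: list with tibbles `vertex_matches`
#'   (`a`, `b`, `dist`), `edge_matches` (`ea`, `eb` edge row indices) and
#'   the unmatched counts on both sides.
#' @export
match_vertices <- function(A, B, radius = NULL) {
  radius <- radius %||% default_radius(A)
  stopifnot(radius > 0)
  nA <- n_vertices(A); nB <- n_vertices(B)
  vm <- tibble::tibble(a = integer(), b = integer(), dist = double())
  if (nA > 0L && nB > 0L) {
    ax <- A$nodes$x; ay <- A$nodes$y
    bx <- B$nodes$x; by <- B$nodes$y
    dmat <- sqrt(outer(ax, bx, "-")^2 + outer(ay, by, "-")^2)
    cand <- which(dmat <= radius, arr.ind = TRUE)
    if (nrow(cand)) {
      d <- dmat[cand]
      big <- radius * (min(nA, nB) + 1)     # cardinality dominates distance
      g <- igraph::make_empty_graph(n = nA + nB, directed = FALSE)
      g <- igraph::set_vertex_attr(g, "type",
                                   value = c(rep(FALSE, nA), rep(TRUE, nB)))
      g <- igraph::add_edges(g, rbind(cand[, 1], nA + cand[, 2]))
      mm <- igraph::max_bipartite_match(g, weights = big - d)
      mt <- mm$matching[seq_len(nA)]
      ok <- !is.na(mt)
      if (any(ok)) {
        a <- which(ok); b <- as.integer(mt[ok]) - nA
        vm <- tibble::tibble(a = a, b = b,
                             dist = dmat[cbind(a, b)])
      }
    }
  }
  em <- match_edges(A, B, vm)
  structure(list(vertex_matches = vm, edge_matches = em,
                 unmatched_a = nA - nrow(vm), unmatched_b = nB - nrow(vm),
                 unmatched_ea = n_edges(A) - nrow(em),
                 unmatched_eb = n_edges(B) - nrow(em),
                 radius = radius),
            class = "correspondence")
}

match_edges <- function(A, B, vm) {
  em <- tibble::tibble(ea = integer(), eb = integer())
  if (!nrow(vm) || !n_edges(A) || !n_edges(B)) return(em)
  map <- stats::setNames(B$nodes$id[vm$b], as.character(A$nodes$id[vm$a]))
  akey <- edge_keys(A$edges$u, A$edges$v, map)
  bkey <- paste(pmin(B$edges$u, B$edges$v), pmax(B$edges$u, B$edges$v))
  for (key in unique(akey[!is.na(akey)])) {
    ia <- which(!is.na(akey) & akey == key)
    ib <- which(bkey == key)
    if (!length(ib)) next
    ia <- ia[order(A$edges$length[ia])]
    ib <- ib[order(B$edges$length[ib])]
    k <- min(length(ia), length(ib))
    em <- dplyr::bind_rows(em, tibble::tibble(ea = ia[seq_len(k)],
                                              eb = ib[seq_len(k)]))
  }
  dplyr::arrange(em, .data$ea)
}

edge_keys <- function(u, v, map) {
  mu <- unname(map[as.character(u)]); mv <- unname(map[as.character(v)])
  ifelse(is.na(mu) | is.na(mv), NA_character_,
         paste(pmin(mu, mv), pmax(mu, mv)))
}

default_radius <- function(A) {
  if (!is.null(A$dim)) 10 * max(A$dim) / 1024 else 10
}

#' Graph similarity score
#'
#' Scores an extracted graph against a reference on a 0-1 scale:
#' \deqn{s = \tfrac12 S_V + \tfrac12 S_E}
#' where the vertex term averages positional agreement of matched vertices
#' over the larger vertex set,
#' \eqn{S_V = \sum_{(a,b)} (1 - d(a,b)/r) / \max(|V_A|, |V_B|)},
#' and the edge term averages length and width agreement of matched edges
#' over the larger edge set,
#' \eqn{S_E = \sum \tfrac12 [c(\ell_A, \ell_B) + c(w_A, w_B)] /
#' \max(|E_A|, |E_B|)} with \eqn{c(x, y) = 1 - |x - y| / \max(x, y)} and
#' \eqn{c(0, 0) = 1}.  The score is 1 when a graph is compared with
#' itself, 0 when no correspondence exists, symmetric in its arguments,
#' and decreases monotonically as positions, lengths or widths drift
#' apart or features disappear.  Two empty graphs score 1 by convention.
#' This is measure version "netextract-s1"; scores are comparable only
#' within a version.
#'
#' @inheritParams match_vertices
#' @param corr optional precomputed [match_vertices()] correspondence.
#' @return similarity in \[0, 1\].
#' @export
similarity_score <- function(A, B, corr = NULL, radius = NULL) {
  radius <- radius %||% default_radius(A)
  corr <- corr %||% match_vertices(A, B, radius)
  nA <- n_vertices(A); nB <- n_vertices(B)
  eA <- n_edges(A); eB <- n_edges(B)
  if (nA == 0L && nB == 0L) return(1)
  vm <- corr$vertex_matches
  s_v <- if (nrow(vm)) sum(1 - vm$dist / radius) / max(nA, nB) else 0
  if (eA == 0L && eB == 0L) {
    s_e <- 1
  } else if (nrow(corr$edge_matches)) {
    em <- corr$edge_matches
    cl <- cmp_ratio(A$edges$length[em$ea], B$edges$length[em$eb])
    cw <- cmp_ratio(A$edges$width_median[em$ea],
                    B$edges$width_median[em$eb])
    s_e <- sum(0.5 * (cl + cw)) / max(eA, eB)
  } else {
    s_e <- 0
  }
  0.5 * s_v + 0.5 * s_e
}

cmp_ratio <- function(x, y) {
  out <- 1 - abs(x - y) / pmax(abs(x), abs(y))
  out[x == 0 & y == 0] <- 1
  out[is.na(x) | is.na(y)] <- 1     # missing widths do not penalize
  out
}

#' Pooled confusion counts
#'
#' Pools vertices and edges: `tp` counts matched vertices plus matched
#' edges; `fn` counts reference features without a correspondence; `fp`
#' counts extracted features without a correspondence.  (True negatives
#' are not defined for this task.)
#'
#' @inheritParams similarity_score
#' @return list with `tp`, `fp`, `fn`.
#' @export
count_confusion <- function(A, B, corr = NULL, radius = NULL) {
  corr <- corr %||% match_vertices(A, B, radius %||% default_radius(A))
  list(tp = nrow(corr$vertex_matches) + nrow(corr$edge_matches),
       fp = corr$unmatched_b + corr$unmatched_eb,
       fn = corr$unmatched_a + corr$unmatched_ea)
}

#' Score one extraction against its ground truth
#'
#' Convenience wrapper: computes the correspondence once and returns the
#' similarity score together with pooled sensitivity `tp / (tp + fn)` and
#' precision `tp / (tp + fp)` (reported as `NA` when undefined).
#'
#' @inheritParams similarity_score
#' @return a `similarity_report` list with `s`, `tp`, `fp`, `fn`,
#'   `sensitivity`, `precision`.
#' @export
similarity_report <- function(A, B, radius = NULL) {
  radius <- radius %||% default_radius(A)
  corr <- match_vertices(A, B, radius)
  cc <- count_confusion(A, B, corr)
  structure(list(
    s = similarity_score(A, B, corr, radius),
    tp = cc$tp, fp = cc$fp, fn = cc$fn,
    sensitivity = if (cc$tp + cc$fn > 0) cc$tp / (cc$tp + cc$fn)
      else NA_real_,
    precision = if (cc$tp + cc$fp > 0) cc$tp / (cc$tp + cc$fp)
      else NA_real_,
    measure_version = "netextract-s1"),
    class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf(
    "<similarity_report: s = %.3f, sensitivity = %.3f, precision = %.3f",
    x$s, x$sensitivity, x$precision))
  cat(sprintf(" (tp %d, fp %d, fn %d)>\n", x$tp, x$fp, x$fn))
  invisible(x)
}

#' @rdname tidy
#' @export
glance.similarity_report <- function(x, ...) {
  tibble::tibble(s = x$s, tp = x$tp, fp = x$fp, fn = x$fn,
                 sensitivity = x$sensitivity, precision = x$precision)
}

#' Evaluate extraction pipelines on a benchmark test set
#'
#' Runs every pipeline on every image of the test set, scores each
#' extracted graph against its ground truth, and summarises the
#' similarity score, pooled sensitivity and pooled precision per pipeline
#' as mean and sample standard deviation -- the format of the benchmark
#' tables.
#'
#' @param pipelines named list of [pipeline_config()] objects.
#' @param test_set list of pairs from [build_test_set()].
#' @param radius matching radius (default scales with the image).
#' @return an `eval_report` tibble with one row per pipeline and columns
#'   `method`, `n`, `s_mean`, `s_sd`, `sensitivity_mean`,
#'   `sensitivity_sd`, `precision_mean`, `precision_sd`.
#' @export
evaluate_pipelines <- function(pipelines, test_set, radius = NULL) {
  stopifnot(length(names(pipelines)) == length(pipelines))
  rows <- lapply(names(pipelines), function(nm) {
    per <- lapply(test_set, function(pair) {
      B <- run_pipeline(pair$image, pipelines[[nm]])$final_graph
      glance(similarity_report(pair$truth, B, radius))
    })
    per <- dplyr::bind_rows(per)
    tibble::tibble(
      method = nm, n = nrow(per),
      s_mean = mean(per$s), s_sd = stats::sd(per$s),
      sensitivity_mean = mean(per$sensitivity),
      sensitivity_sd = stats::sd(per$sensitivity),
      precision_mean = mean(per$precision),
      precision_sd = stats::sd(per$precision))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("eval_report", class(out))
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d test image(s):\n", max(x$n)))
  cat(sprintf("%-24s %-15s %-15s %-15s\n", "Method", "Similarity s",
              "Sensitivity", "Precision"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-24s %.3f +/- %.3f %.3f +/- %.3f %.3f +/- %.3f\n",
                x$method[i], x$s_mean[i], x$s_sd[i],
                x$sensitivity_mean[i], x$sensitivity_sd[i],
                x$precision_mean[i], x$precision_sd[i]))
  }
  invisible(x)
}
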