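#' Summary statistics over a numeric vector
#'
#' The common summary reported for per-vertex and per-pair statistics:
#' maximum, minimum, mean and the population (divide-by-count) standard
#' deviation, together with the number of values summarized.  An empty input
#' yields an all-`NA` summary with `count = 0` rather than an error, so that
#' profiles of degenerate graphs stay tabulable.
#'
#' @param x numeric vector (NAs removed before summarizing).
#' @return a list of class `summary_stats` with fields `maximum`, `minimum`,
#'   `mean`, `sd`, `count`.
#' @export
summary_stats <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) {
    out <- list(maximum = NA_real_, minimum = NA_real_, mean = NA_real_,
                sd = NA_real_, count = 0L)
  } else {
    m <- mean(x)
    out <- list(maximum = max(x), minimum = min(x), mean = m,
                sd = sqrt(mean((x - m)^2)), count = n)
  }
  structure(out, class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("summary_stats: n=%d max=%s min=%s mean=%s sd=%s\n", x$count,
    format(x$maximum), format(x$minimum), format(x$mean), format(x$sd)))
  invisible(x)
}

#' Edge density of a graph
#'
#' Number of edges divided by the number of vertex pairs, `|E| / C(|V|, 2)`.
#'
#' @param g interaction network with at least two vertices.
#' @return density in \[0, 1\].
#' @export
edge_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) stop("edge density is undefined for graphs with fewer than 2 vertices",
                  call. = FALSE)
  igraph::ecount(g) / choose(n, 2)
}

#' Vertex and edge k-connectivity
#'
#' The largest `k` such that the graph is k-vertex-connected (k disjoint paths
#' between every vertex pair; equivalently no set of fewer than k vertices
#' disconnects it).  A disconnected graph, or one with at most one vertex, has
#' connectivity 0; the complete graph on n vertices has vertex connectivity
#' n - 1.  `edge_connectivity()` is the edge-disjoint analogue.
#'
#' @param g interaction network.
#' @return nonnegative integer.
#' @export
vertex_connectivity <- function(g) {
  n <- igraph::vcount(g)
  if (n <= 1) return(0L)
  as.integer(igraph::vertex_connectivity(g))
}

#' @rdname vertex_connectivity
#' @export
edge_connectivity <- function(g) {
  n <- igraph::vcount(g)
  if (n <= 1) return(0L)
  as.integer(igraph::edge_connectivity(g))
}

#' Degree statistics
#'
#' Summary of per-vertex degrees.  When `normalize = TRUE` each degree is
#' divided by the number of vertices in the graph (not `|V| - 1`), so the
#' normalized maximum degree is always strictly below 1; this makes graphs of
#' different sizes comparable.
#'
#' @param g interaction network with at least one vertex.
#' @param normalize divide degrees by `|V|`?
#' @return a [summary_stats()] object.
#' @export
degree_statistics <- function(g, normalize = FALSE) {
  n <- igraph::vcount(g)
  if (n == 0L) stop("degree statistics are undefined on an empty graph", call. = FALSE)
  d <- igraph::degree(g)
  if (normalize) d <- d / n
  summary_stats(d)
}

#' Global clustering coefficient
#'
#' Three times the number of triangles divided by the number of length-2
#' paths.  When the graph has no length-2 path the ratio is undefined; by
#' convention 0 is returned, flagged with attribute `defined = FALSE`, so
#' profiles of tiny graphs remain tabulable.
#'
#' @param g interaction network.
#' @return clustering coefficient in \[0, 1\] with logical attribute `defined`.
#' @export
clustering_coefficient <- function(g) {
  d <- igraph::degree(g)
  p2 <- sum(choose(d, 2))
  if (p2 == 0) return(structure(0, defined = FALSE))
  structure(3 * triangle_count(g) / p2, defined = TRUE)
}

#' Mutual clustering coefficient of a vertex pair
#'
#' The number of neighbors shared by two vertices divided by the smaller of
#' their degrees (the best-performing of the ratio definitions for assessing
#' interaction confidence).  The shared-neighbor set excludes the two
#' endpoints themselves.  Undefined (error) when either endpoint has degree 0.
#'
#' @param g interaction network.
#' @param u,v distinct vertex names.
#' @return MCC in \[0, 1\].
#' @export
mutual_clustering_coefficient <- function(g, u, v) {
  if (identical(u, v)) stop("MCC requires two distinct vertices", call. = FALSE)
  nu <- igraph::V(g)$name[igraph::neighbors(g, u)]
  nv <- igraph::V(g)$name[igraph::neighbors(g, v)]
  if (length(nu) == 0L || length(nv) == 0L) {
    stop("MCC is undefined when an endpoint has degree 0", call. = FALSE)
  }
  shared <- setdiff(intersect(nu, nv), c(u, v))
  length(shared) / min(length(nu), length(nv))
}

#' MCC summary over all vertex pairs
#'
#' Summarizes the mutual clustering coefficient over all unordered vertex
#' pairs for which it is defined; pairs where either endpoint has degree 0
#' are excluded from the summary rather than scored 0.
#'
#' @param g interaction network.
#' @return a [summary_stats()] object (`count` = number of defined pairs).
#' @export
mcc_statistics <- function(g) {
  d <- igraph::degree(g)
  keep <- names(d)[d > 0]
  if (length(keep) < 2) return(summary_stats(numeric()))
  adj <- igraph::as_adjacency_matrix(g, sparse = TRUE)[keep, keep]
  co <- as.matrix(adj %*% adj)        # shared-neighbor counts (within keep)
  # degree-0 vertices share nothing, so restricting to `keep` loses no shared
  # neighbor; endpoints u,v never count themselves (no self loops) but u can
  # appear as a "shared neighbor" via a u-v edge: co[u,v] counts paths u-x-v
  # with x != u,v automatically in a simple graph.
  dm <- outer(d[keep], d[keep], pmin)
  vals <- (co / dm)[upper.tri(co)]
  summary_stats(vals)
}

#' Count triangles and 4-cycles
#'
#' `triangle_count()` is the number of distinct 3-cliques.
#' `four_cycle_count()` is the number of distinct simple 4-cycles (not
#' necessarily induced), each counted once, via the pair-counting identity
#' `sum over unordered vertex pairs of C(#common neighbors, 2) / 2`: each
#' quadrilateral is counted once per diagonal pair.
#'
#' @param g interaction network.
#' @return nonnegative integer count.
#' @export
triangle_count <- function(g) {
  as.integer(sum(igraph::count_triangles(g)) / 3)
}

#' @rdname triangle_count
#' @export
four_cycle_count <- function(g) {
  if (igraph::vcount(g) < 4) return(0L)
  adj <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  co <- adj %*% adj
  codeg <- co[upper.tri(as.matrix(co))]
  as.integer(sum(choose(codeg, 2)) / 2)
}

#' Betweenness centrality statistics
#'
#' Per-vertex shortest-path betweenness under the standard fractional
#' convention (each s-t pair contributes to v the fraction of shortest s-t
#' paths through v; endpoints excluded), optionally divided by `|V|` to
#' compare graphs of different sizes.  Betweenness is only reported for
#' connected graphs with at least 3 vertices: in a disconnected graph not
#' all pairs have paths between them.
#'
#' @param g interaction network.
#' @param normalize divide each vertex's betweenness by `|V|`?
#' @return a [summary_stats()] object.
#' @export
betweenness_statistics <- function(g, normalize = FALSE) {
  n <- igraph::vcount(g)
  if (n < 3 || !igraph::is_connected(g)) {
    stop("betweenness is undefined for unconnected graphs or graphs with fewer than 3 vertices",
         call. = FALSE)
  }
  b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  if (normalize) b <- b / n
  summary_stats(b)
}
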