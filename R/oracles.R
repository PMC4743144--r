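#' Brute-force connectivity oracle
#'
#' Computes vertex or edge connectivity by exhaustive removal: all subsets of
#' vertices (edges) are deleted in increasing subset size until the remaining
#' graph is disconnected (or, in vertex mode, reduced below 2 vertices).
#' Exponential and therefore restricted to graphs with at most 10 vertices;
#' used as the independent reference in tests of the production connectivity
#' path.
#'
#' @param g interaction network with at most 10 vertices.
#' @param mode `"vertex"` or `"edge"`.
#' @return connectivity as a nonnegative integer.
#' @export
brute_force_connectivity_oracle <- function(g, mode = c("vertex", "edge")) {
  mode <- match.arg(mode)
  n <- igraph::vcount(g)
  if (n > 10) stop("oracle restricted to graphs with at most 10 vertices", call. = FALSE)
  if (n <= 1) return(0L)
  if (!igraph::is_connected(g)) return(0L)
  if (mode == "vertex") {
    verts <- seq_len(n)
    for (k in 0:(n - 2)) {
      for (rem in .subsets(verts, k)) {
        h <- igraph::delete_vertices(g, rem)
        if (igraph::vcount(h) >= 2 && !igraph::is_connected(h)) return(k)
      }
    }
    return(n - 1L)  # complete graph: no removal of <= n-2 vertices disconnects
  }
  m <- igraph::ecount(g)
  for (k in 0:m) {
    for (rem in .subsets(seq_len(m), k)) {
      h <- igraph::delete_edges(g, rem)
      if (!igraph::is_connected(h)) return(k)
    }
  }
  m
}

# all k-subsets of x as a list (k = 0 gives one empty set)
.subsets <- function(x, k) {
  if (k == 0L) return(list(integer()))
  if (k > length(x)) return(list())
  cmb <- utils::combn(x, k)
  lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
}
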