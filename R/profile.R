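#' Full topological profile of a graph
#'
#' Computes every per-graph statistic reported by the survey: size, component
#' structure, edge density, vertex and edge connectivity, normalized degree
#' summary, global clustering coefficient, mutual clustering coefficient
#' summary, triangle and 4-cycle counts, and normalized betweenness summary.
#' Statistics whose preconditions fail (density on < 2 vertices, betweenness
#' on disconnected graphs, MCC with no defined pair) are `NA`-marked, never
#' fabricated.
#'
#' @param g interaction network.
#' @return a list of class `topology_profile`.
#' @export
topology_profile <- function(g) {
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  comp <- if (n > 0) igraph::count_components(g) else 0L
  cc <- if (n > 0) clustering_coefficient(g) else structure(0, defined = FALSE)
  prof <- list(
    n_vertices = n,
    n_edges = m,
    n_components = as.integer(comp),
    is_connected = n > 0 && comp == 1L,
    edge_density = if (n >= 2) edge_density(g) else NA_real_,
    vertex_connectivity = vertex_connectivity(g),
    edge_connectivity = edge_connectivity(g),
    degree_stats = if (n >= 1) degree_statistics(g, normalize = TRUE)
                   else summary_stats(numeric()),
    clustering_coefficient = as.numeric(cc),
    cc_defined = attr(cc, "defined"),
    mcc_stats = mcc_statistics(g),
    triangle_count = triangle_count(g),
    four_cycle_count = four_cycle_count(g),
    betweenness_stats = if (n >= 3 && comp == 1L) {
      betweenness_statistics(g, normalize = TRUE)
    } else {
      summary_stats(numeric())
    }
  )
  structure(prof, class = "topology_profile")
}

#' @export
print.topology_profile <- function(x, ...) {
  cat(sprintf(
    "topology_profile: %d vertices, %d edges, %d component(s)\n  density=%s k=%d lambda=%d CC=%s%s triangles=%d 4-cycles=%d\n",
    x$n_vertices, x$n_edges, x$n_components,
    format(x$edge_density, digits = 4), x$vertex_connectivity,
    x$edge_connectivity, format(x$clustering_coefficient, digits = 4),
    if (isFALSE(x$cc_defined)) " (undefined)" else "",
    x$triangle_count, x$four_cycle_count))
  invisible(x)
}

# fixed column order of the flat serialization; shared by all result tables
.profile_cols <- c(
  "n_vertices", "n_edges", "n_components", "is_connected", "edge_density",
  "vertex_connectivity", "edge_connectivity",
  "degree_max", "degree_min", "degree_mean", "degree_sd",
  "clustering_coefficient", "cc_defined",
  "mcc_max", "mcc_min", "mcc_mean", "mcc_sd", "mcc_pairs",
  "triangle_count", "four_cycle_count",
  "betweenness_max", "betweenness_min", "betweenness_mean", "betweenness_sd")

#' Flatten a profile to a one-row data frame
#'
#' Column order is fixed (see the returned names) so result tables from
#' different runs line up.
#'
#' @param p a [topology_profile()].
#' @return one-row data frame.
#' @export
profile_row <- function(p) {
  stopifnot(inherits(p, "topology_profile"))
  data.frame(
    n_vertices = p$n_vertices, n_edges = p$n_edges,
    n_components = p$n_components, is_connected = p$is_connected,
    edge_density = p$edge_density,
    vertex_connectivity = p$vertex_connectivity,
    edge_connectivity = p$edge_connectivity,
    degree_max = p$degree_stats$maximum, degree_min = p$degree_stats$minimum,
    degree_mean = p$degree_stats$mean, degree_sd = p$degree_stats$sd,
    clustering_coefficient = p$clustering_coefficient,
    cc_defined = isTRUE(p$cc_defined),
    mcc_max = p$mcc_stats$maximum, mcc_min = p$mcc_stats$minimum,
    mcc_mean = p$mcc_stats$mean, mcc_sd = p$mcc_stats$sd,
    mcc_pairs = p$mcc_stats$count,
    triangle_count = p$triangle_count, four_cycle_count = p$four_cycle_count,
    betweenness_max = p$betweenness_stats$maximum,
    betweenness_min = p$betweenness_stats$minimum,
    betweenness_mean = p$betweenness_stats$mean,
    betweenness_sd = p$betweenness_stats$sd,
    stringsAsFactors = FALSE)
}
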