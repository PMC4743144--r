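#' Configuration for degree-preserving switching
#'
#' Switching randomizes a network while preserving its exact degree sequence
#' by repeatedly picking two edges (A,B) and (C,D) with four distinct
#' endpoints and replacing them with (A,D) and (C,B).  For a network with n
#' vertices the process performs `repeats_per_vertex * n` successful swaps to
#' ensure proper mixing (default 100n), and the whole randomization is
#' repeated `n_replicates` times (default 10) to form a comparison ensemble.
#'
#' @param repeats_per_vertex successful swaps per vertex (default 100).
#' @param n_replicates ensemble size (default 10).
#' @param seed integer seed from which each replicate's stream is derived.
#' @export
switch_config <- function(repeats_per_vertex = 100L, n_replicates = 10L,
                          seed = 1L) {
  stopifnot(repeats_per_vertex >= 1, n_replicates >= 1)
  structure(list(repeats_per_vertex = as.integer(repeats_per_vertex),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "switch_config")
}

#' Degree-preserving switching randomization
#'
#' Performs `cfg$repeats_per_vertex * |V|` successful edge swaps on a copy of
#' the network.  A proposed swap is rejected (and not counted) when the four
#' endpoints are not distinct or when either replacement edge already exists,
#' so the result is always simple with the input's exact degree sequence.  A
#' proposal cap of 1000 times the swap target guarantees termination on
#' graphs where few or no valid swaps exist (a clique is returned unchanged).
#'
#' @param network interaction network with at least 2 edges.
#' @param cfg a [switch_config()].
#' @param seed optional integer; when given, seeds the RNG for this call.
#' @return randomized network on the same vertex set.
#' @export
switch_randomize <- function(network, cfg = switch_config(), seed = NULL) {
  m <- igraph::ecount(network)
  if (m < 2) stop("switching needs at least 2 edges", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  el <- igraph::as_edgelist(network, names = FALSE)
  n <- igraph::vcount(network)
  target <- cfg$repeats_per_vertex * n
  cap <- 1000 * target
  adj <- new.env(hash = TRUE, size = 4L * m, parent = emptyenv())
  ekey <- function(a, b) if (a < b) paste0(a, "_", b) else paste0(b, "_", a)
  for (i in seq_len(m)) assign(ekey(el[i, 1], el[i, 2]), TRUE, envir = adj)
  done <- 0L; proposals <- 0L
  while (done < target && proposals < cap) {
    proposals <- proposals + 1L
    ij <- sample.int(m, 2L)
    a <- el[ij[1], 1]; b <- el[ij[1], 2]
    c <- el[ij[2], 1]; d <- el[ij[2], 2]
    # swap orientation at random so both pairings (A,D)/(C,B) and (A,C)/(B,D)
    # are reachable; without this, edge orientations bias the walk
    if (stats::runif(1) < 0.5) { tmp <- c; c <- d; d <- tmp }
    if (a == c || a == d || b == c || b == d) next
    k1 <- ekey(a, d); k2 <- ekey(c, b)
    if (exists(k1, envir = adj, inherits = FALSE) ||
        exists(k2, envir = adj, inherits = FALSE)) next
    rm(list = c(ekey(a, b), ekey(c, d)), envir = adj)
    assign(k1, TRUE, envir = adj)
    assign(k2, TRUE, envir = adj)
    el[ij[1], ] <- c(a, d)
    el[ij[2], ] <- c(c, b)
    done <- done + 1L
  }
  out <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(out)$name <- igraph::V(network)$name
  igraph::add_edges(out, t(el))
}

#' Ensemble of switching-randomized networks
#'
#' Generates `cfg$n_replicates` independent randomizations; replicate i is
#' seeded deterministically from `cfg$seed` and i, so identical
#' configurations reproduce identical ensembles.
#'
#' @inheritParams switch_randomize
#' @return list of randomized networks.
#' @export
random_ensemble <- function(network, cfg = switch_config()) {
  lapply(seq_len(cfg$n_replicates), function(i) {
    switch_randomize(network, cfg, seed = cfg$seed + 7919L * i)
  })
}

#' Motif enrichment against a randomized ensemble
#'
#' Compares the observed count of a motif (triangles or 4-cycles) in the
#' network with its mean and standard deviation over an ensemble of
#' degree-matched randomized networks.
#'
#' @param network interaction network.
#' @param ensemble nonempty list of networks (e.g. from [random_ensemble()]).
#' @param motif `"triangle"` or `"four_cycle"`.
#' @return list of class `motif_enrichment` with fields `motif`, `observed`,
#'   `random_mean`, `random_sd` (population sd), `ratio`
#'   (`observed / random_mean`, `NA` when the mean is 0).
#' @export
motif_enrichment <- function(network, ensemble, motif = c("triangle", "four_cycle")) {
  motif <- match.arg(motif)
  if (length(ensemble) == 0L) stop("ensemble must be nonempty", call. = FALSE)
  counter <- if (motif == "triangle") triangle_count else four_cycle_count
  observed <- counter(network)
  counts <- vapply(ensemble, counter, integer(1))
  mu <- mean(counts)
  structure(list(
    motif = motif, observed = observed, random_mean = mu,
    random_sd = sqrt(mean((counts - mu)^2)),
    ratio = if (mu > 0) observed / mu else NA_real_
  ), class = "motif_enrichment")
}

#' Configuration for pseudocomplex sampling
#'
#' Pseudocomplexes are random connected "complex-like" subgraphs grown from a
#' triangle edge, used as size-matched nulls for real complexes.  Only
#' complexes with at least `min_complex_size` members present in the network
#' are matched (default 4: smaller connected graphs force several measures
#' unreasonably high and would skew comparisons).
#'
#' @param replicates_per_complex pseudocomplexes drawn per complex
#'   (default 100).
#' @param min_complex_size minimum members present (default 4).
#' @param max_restarts growth restarts allowed per sample (default 50).
#' @param seed integer seed.
#' @export
pseudocomplex_config <- function(replicates_per_complex = 100L,
                                 min_complex_size = 4L,
                                 max_restarts = 50L, seed = 1L) {
  stopifnot(replicates_per_complex >= 1, min_complex_size >= 1,
            max_restarts >= 1)
  structure(list(replicates_per_complex = as.integer(replicates_per_complex),
                 min_complex_size = as.integer(min_complex_size),
                 max_restarts = as.integer(max_restarts),
                 seed = as.integer(seed)),
            class = "pseudocomplex_config")
}

# all distinct triangles of a network as a 3-column matrix of vertex ids
.triangle_table <- function(network) {
  tri <- igraph::triangles(network)
  if (length(tri) == 0L) return(matrix(integer(), ncol = 3))
  matrix(as.integer(tri), ncol = 3, byrow = TRUE)
}

#' Grow one pseudocomplex
#'
#' Seeds with a uniformly random edge of a uniformly random triangle, then
#' repeatedly picks a uniformly random network edge with exactly one endpoint
#' in the current vertex set and adds the outside endpoint together with all
#' of its edges into the set, until `n` vertices are reached.  Sampling edges
#' (not neighbors) makes vertices with several edges into the current set
#' proportionally more likely to join, biasing samples toward complex-like
#' wiring.  If growth stalls inside an exhausted component the sample
#' restarts from a fresh triangle, up to `max_restarts` times.
#'
#' @param network interaction network containing at least one triangle.
#' @param n requested vertex count (>= 4, and at least 2).
#' @param max_restarts restart budget.
#' @param seed optional integer seed for this draw.
#' @param triangles optional precomputed [.triangle_table()]-style matrix
#'   (internal use; avoids re-enumerating triangles per draw).
#' @return induced subgraph on the grown vertex set, with graph attribute
#'   `seed_edge` (character vector of the two seed endpoints).
#' @export
sample_pseudocomplex <- function(network, n, max_restarts = 50L, seed = NULL,
                                 triangles = NULL) {
  if (n < 4) stop("pseudocomplexes are only grown for n >= 4", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  if (is.null(triangles)) triangles <- .triangle_table(network)
  if (nrow(triangles) == 0L) stop("network contains no triangle", call. = FALSE)
  adj <- igraph::as_adj_list(network)
  adj <- lapply(adj, as.integer)
  for (attempt in seq_len(max_restarts)) {
    tri <- triangles[sample.int(nrow(triangles), 1L), ]
    seed_edge <- tri[-sample.int(3L, 1L)]     # drop one corner, keep an edge
    members <- as.integer(seed_edge)
    in_set <- logical(igraph::vcount(network))
    in_set[members] <- TRUE
    while (length(members) < n) {
      # boundary half-edges: for each member, neighbors outside the set;
      # sampling uniformly over these = uniform over boundary edges
      outside <- unlist(lapply(members, function(v) adj[[v]][!in_set[adj[[v]]]]),
                        use.names = FALSE)
      if (length(outside) == 0L) break
      new_v <- outside[sample.int(length(outside), 1L)]
      members <- c(members, new_v)
      in_set[new_v] <- TRUE
    }
    if (length(members) == n) {
      g <- igraph::induced_subgraph(network, members)
      g$seed_edge <- igraph::V(network)$name[as.integer(seed_edge)]
      return(g)
    }
  }
  stop(sprintf("could not grow a pseudocomplex of %d vertices in %d restarts",
               n, max_restarts), call. = FALSE)
}

#' Matched pseudocomplexes for a set of complexes
#'
#' For every eligible complex (at least `cfg$min_complex_size` members
#' present in the network and at least one induced edge), draws
#' `cfg$replicates_per_complex` pseudocomplexes with the same vertex count as
#' the complex's induced graph and profiles each through the same variant
#' pipeline as real complexes.
#'
#' @param network interaction network.
#' @param complexes list of [complex_definition()]s.
#' @param cfg a [pseudocomplex_config()].
#' @return named list (by complex id) of lists of `variant_profiles`;
#'   ineligible complexes are omitted.
#' @export
matched_pseudocomplexes <- function(network, complexes,
                                    cfg = pseudocomplex_config()) {
  triangles <- .triangle_table(network)
  out <- list()
  for (ci in seq_along(complexes)) {
    cx <- complexes[[ci]]
    g <- complex_graph(network, cx$members)
    n_present <- igraph::vcount(g)
    if (n_present < cfg$min_complex_size || igraph::ecount(g) == 0L) next
    profs <- lapply(seq_len(cfg$replicates_per_complex), function(r) {
      p <- sample_pseudocomplex(network, n_present,
        max_restarts = cfg$max_restarts,
        seed = cfg$seed + 104729L * ci + r, triangles = triangles)
      .variant_profiles_graph(p, paste0(cx$complex_id, ":pseudo", r))
    })
    out[[cx$complex_id]] <- profs
  }
  out
}
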