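#' Complex definitions
#'
#' A protein complex is a named set of member proteins, optionally carrying
#' reference edges (internal interactions determined by a reliable method
#' such as X-ray crystallography).  Membership-only definitions model
#' MIPS-style catalog entries; definitions with reference edges model
#' crystallography-derived complexes.
#'
#' @param complex_id identifier string.
#' @param members character vector of member proteins (duplicates collapsed).
#' @param reference_edges optional two-column matrix/data frame of member
#'   pairs; every endpoint must be a member.
#' @return a list of class `complex_definition`.
#' @export
complex_definition <- function(complex_id, members, reference_edges = NULL) {
  members <- sort(unique(as.character(members)))
  if (length(members) < 1) stop("a complex needs at least one member", call. = FALSE)
  if (!is.null(reference_edges)) {
    reference_edges <- as.matrix(reference_edges)
    if (nrow(reference_edges) > 0) {
      reference_edges <- cbind(as.character(reference_edges[, 1]),
                               as.character(reference_edges[, 2]))
      if (!all(reference_edges %in% members)) {
        stop("every reference edge must join two members", call. = FALSE)
      }
      swap <- reference_edges[, 1] > reference_edges[, 2]
      reference_edges[swap, ] <- reference_edges[swap, c(2, 1), drop = FALSE]
      reference_edges <- unique(reference_edges)
      reference_edges <-
        reference_edges[order(reference_edges[, 1], reference_edges[, 2]), ,
                        drop = FALSE]
    }
  }
  structure(list(complex_id = as.character(complex_id), members = members,
                 reference_edges = reference_edges),
            class = "complex_definition")
}

#' Induced complex graph
#'
#' The graph a complex induces in the interaction network: members present in
#' the network plus all network edges among them.  Members absent from the
#' network are dropped (the network defines the observable universe); the
#' attribute `coverage` on the result records the fraction of members that
#' were present.
#'
#' @param network interaction network.
#' @param members character vector of member proteins.
#' @return induced subgraph with graph attribute `coverage`.
#' @export
complex_graph <- function(network, members) {
  members <- unique(as.character(members))
  present <- intersect(members, igraph::V(network)$name)
  g <- igraph::induced_subgraph(network, present)
  g$coverage <- if (length(members)) length(present) / length(members) else 0
  g
}

#' Haircut: recursive removal of degree <= 1 vertices
#'
#' Repeatedly deletes every vertex of current degree 1 or less (including
#' isolated vertices) until none remains; the result is either empty or has
#' minimum degree at least 2.  The operation is idempotent and can never
#' remove a triangle: all three vertices of a triangle keep degree >= 2 for
#' as long as the triangle is intact.
#'
#' @param g interaction network.
#' @return the peeled subgraph (possibly empty).
#' @export
haircut <- function(g) {
  repeat {
    d <- igraph::degree(g)
    drop <- which(d <= 1)
    if (length(drop) == 0L) return(g)
    g <- igraph::delete_vertices(g, drop)
  }
}

#' Most highly connected subgraph (MHCS)
#'
#' Finds an induced subgraph with at least 3 vertices attaining the maximum
#' vertex connectivity over all such subgraphs, by recursive minimum-cut
#' splitting: record the connectivity of each connected candidate, find one
#' minimum vertex cut C, and recurse into every component of G - C augmented
#' with C.  Any subgraph more highly connected than the candidate cannot
#' straddle C (its intersection with C would be a smaller cut of it), so the
#' optimum survives into some branch and the search is exact.  Ties are
#' broken deterministically: more vertices first, then the lexicographically
#' smallest sorted vertex-name list.
#'
#' @param g interaction network.
#' @return list with `graph` (induced subgraph; empty when no component has
#'   3 or more vertices) and `k` (its vertex connectivity; 0 when empty).
#' @export
mhcs <- function(g) {
  best <- list(k = -1L, names = character())
  seen <- new.env(hash = TRUE, parent = emptyenv())

  consider <- function(k, nms) {
    nms <- sort(nms)
    if (k > best$k ||
        (k == best$k && (length(nms) > length(best$names) ||
          (length(nms) == length(best$names) &&
           paste(nms, collapse = "\r") < paste(best$names, collapse = "\r"))))) {
      best <<- list(k = k, names = nms)
    }
  }

  explore <- function(h) {
    key <- paste(sort(igraph::V(h)$name), collapse = "\r")
    if (exists(key, envir = seen, inherits = FALSE)) return(invisible())
    assign(key, TRUE, envir = seen)
    for (comp in components_list(h)) {
      nc <- igraph::vcount(comp)
      if (nc < 3) next
      k <- vertex_connectivity(comp)
      consider(k, igraph::V(comp)$name)
      if (k == nc - 1L) next  # complete graph: nothing left to split
      # only a strictly higher connectivity can improve on what is already
      # recorded (equal-k candidates deeper in the recursion have fewer
      # vertices and lose the tie), and a k-connected subgraph has minimum
      # internal degree >= k, so it lives inside the k-core: restrict the
      # branch to the (best+1)-core before splitting
      target <- best$k + 1L
      core <- igraph::coreness(comp)
      keep <- igraph::V(comp)$name[core >= target]
      if (length(keep) < max(3L, target + 1L)) next
      if (length(keep) < nc) {
        explore(igraph::induced_subgraph(comp, keep))
        next
      }
      cuts <- igraph::min_separators(comp)
      cut <- .smallest_name_set(lapply(cuts, function(s) igraph::V(comp)$name[s]))
      rest <- igraph::delete_vertices(comp, cut)
      for (piece in components_list(rest)) {
        sub_names <- union(igraph::V(piece)$name, cut)
        if (length(sub_names) >= 3 && length(sub_names) < nc) {
          explore(igraph::induced_subgraph(comp, sub_names))
        }
      }
    }
    invisible()
  }

  explore(g)
  if (best$k < 0L) {
    return(list(graph = interaction_network(matrix(character(), ncol = 2)), k = 0L))
  }
  list(graph = igraph::induced_subgraph(g, best$names), k = as.integer(best$k))
}

# deterministic choice among vertex-name sets: smallest sorted name vector
.smallest_name_set <- function(sets) {
  keys <- vapply(sets, function(s) paste(sort(s), collapse = "\r"), character(1))
  sets[[order(keys)[1]]]
}

#' Connected components as separate graphs
#'
#' @param g interaction network.
#' @return list of induced subgraphs, one per component, ordered by
#'   decreasing size then by smallest vertex name (deterministic).
#' @export
components_list <- function(g) {
  if (igraph::vcount(g) == 0L) return(list())
  memb <- igraph::components(g)$membership
  groups <- split(names(memb), memb)
  first <- vapply(groups, function(v) min(v), character(1))
  groups <- groups[order(-lengths(groups), first)]
  lapply(groups, function(v) igraph::induced_subgraph(g, v))
}

#' Profile a complex across its subgraph variants
#'
#' Builds the complex graph (induced from the network, or from the complex's
#' reference edges), then profiles the full graph, its haircut, its most
#' highly connected subgraph, and every connected component.
#'
#' @param network interaction network.
#' @param cx a [complex_definition()].
#' @param source `"induced"` (edges from the network) or `"reference"`
#'   (edges from crystallography-style reference data; members absent from
#'   the reference edge set appear as isolated vertices).
#' @return a list of class `variant_profiles` with fields `complex_id`,
#'   `coverage`, `full`, `haircut` (NULL when the haircut is empty), `mhcs`
#'   (NULL when empty), `mhcs_k`, `components` (list of profiles).
#' @export
variant_profiles <- function(network, cx, source = c("induced", "reference")) {
  source <- match.arg(source)
  stopifnot(inherits(cx, "complex_definition"))
  if (source == "induced") {
    g <- complex_graph(network, cx$members)
    coverage <- g$coverage
  } else {
    if (is.null(cx$reference_edges)) {
      stop("complex has no reference edges", call. = FALSE)
    }
    g <- interaction_network(cx$reference_edges, vertices = cx$members)
    coverage <- 1
  }
  .variant_profiles_graph(g, cx$complex_id, coverage)
}

# profile an already-built complex graph (shared by real and pseudo complexes)
.variant_profiles_graph <- function(g, complex_id, coverage = 1) {
  hc <- haircut(g)
  mh <- mhcs(g)
  structure(list(
    complex_id = complex_id,
    coverage = coverage,
    full = topology_profile(g),
    haircut = if (igraph::vcount(hc) > 0) topology_profile(hc) else NULL,
    mhcs = if (igraph::vcount(mh$graph) > 0) topology_profile(mh$graph) else NULL,
    mhcs_k = mh$k,
    components = lapply(components_list(g), topology_profile)
  ), class = "variant_profiles")
}

#' Overlap between a reference complex and the network
#'
#' Compares a complex's crystallography-style reference edges with the edges
#' the same proteins induce in the interaction network: how many members are
#' present at all, how many reference edges were also observed, and how many
#' induced edges have no reference counterpart.
#'
#' @param cx a [complex_definition()] with reference edges.
#' @param network interaction network.
#' @return list of class `overlap_report` with fields `members_present`,
#'   `members_total`, `shared_edges`, `reference_edges`, `network_only_edges`.
#' @export
reference_overlap <- function(cx, network) {
  stopifnot(inherits(cx, "complex_definition"))
  if (is.null(cx$reference_edges)) stop("complex has no reference edges", call. = FALSE)
  g <- complex_graph(network, cx$members)
  ind <- igraph::as_edgelist(g)
  ind_keys <- .edge_keys(ind)
  ref_keys <- .edge_keys(cx$reference_edges)
  structure(list(
    members_present = igraph::vcount(g),
    members_total = length(cx$members),
    shared_edges = length(intersect(ref_keys, ind_keys)),
    reference_edges = length(ref_keys),
    network_only_edges = length(setdiff(ind_keys, ref_keys))
  ), class = "overlap_report")
}

.edge_keys <- function(el) {
  if (is.null(el) || nrow(el) == 0L) return(character())
  a <- pmin(el[, 1], el[, 2]); b <- pmax(el[, 1], el[, 2])
  unique(paste(a, b, sep = "\r"))
}
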