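#' Build an interaction network from an edge table
#'
#' Constructs a simple undirected graph over protein identifiers.  Duplicate
#' reported interactions (in either orientation) collapse to a single edge and
#' self-interactions are dropped, since all downstream statistics assume a
#' simple graph.  Vertices without any surviving edge are kept, so the vertex
#' set may contain degree-0 proteins.
#'
#' @param edges two-column character matrix or data frame of interactor pairs;
#'   may have zero rows.
#' @param vertices optional character vector of additional vertex identifiers
#'   (e.g. proteins assayed but never observed to interact).
#' @return an [igraph::graph] with a `name` vertex attribute; attributes
#'   `n_self_dropped` and `n_dup_dropped` record how many input rows were
#'   discarded on ingest.
#' @export
interaction_network <- function(edges, vertices = character()) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 0 && ncol(edges) != 2) {
    stop("`edges` must have exactly two columns", call. = FALSE)
  }
  if (nrow(edges) == 0L) {
    ep <- matrix(character(), ncol = 2)
  } else {
    ep <- cbind(as.character(edges[, 1]), as.character(edges[, 2]))
  }
  self <- ep[, 1] == ep[, 2]
  n_self <- sum(self)
  ep <- ep[!self, , drop = FALSE]
  # canonical orientation so "A B" and "B A" are the same edge
  swap <- ep[, 1] > ep[, 2]
  ep[swap, ] <- ep[swap, c(2, 1), drop = FALSE]
  dup <- duplicated(paste(ep[, 1], ep[, 2], sep = "\r"))
  n_dup <- sum(dup)
  ep <- ep[!dup, , drop = FALSE]
  verts <- sort(unique(c(as.character(vertices), ep)))
  g <- igraph::graph_from_edgelist(ep, directed = FALSE)
  g <- igraph::add_vertices(g, length(setdiff(verts, igraph::V(g)$name)),
    name = setdiff(verts, igraph::V(g)$name))
  g <- igraph::permute(g, match(igraph::V(g)$name, sort(igraph::V(g)$name)))
  g$n_self_dropped <- n_self
  g$n_dup_dropped <- n_dup
  g
}

#' Read an interaction network from disk
#'
#' Two formats are supported.  `"edgelist"` is a headerless two-column
#' tab-separated file, one interaction per line.  `"biogrid_tab"` is a
#' BioGRID-style tab-separated export with a header line: the first two
#' columns whose names contain "interactor" (case-insensitive; falling back
#' to the first two columns) are taken as the interactor pair, and when a
#' column whose name contains "experimental" and "system" is present, only
#' rows whose value matches "two-hybrid" (case-insensitive) are kept.
#'
#' @param path file path.
#' @param fmt `"edgelist"` or `"biogrid_tab"`.
#' @param quiet suppress the ingest log message.
#' @return an interaction network; see [interaction_network()].
#' @export
read_network <- function(path, fmt = c("edgelist", "biogrid_tab"),
                         quiet = FALSE) {
  fmt <- match.arg(fmt)
  if (fmt == "edgelist") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) {
      return(interaction_network(matrix(character(), ncol = 2)))
    }
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 2L)
    if (length(bad)) {
      stop(sprintf("malformed edge on line %d of %s (need 2 tab-separated fields)",
        bad[1], path), call. = FALSE)
    }
    ep <- t(vapply(parts, function(p) trimws(p[1:2]), character(2)))
  } else {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
      stringsAsFactors = FALSE, check.names = FALSE)
    nm <- tolower(names(tab))
    ia <- which(grepl("interactor", nm))
    if (length(ia) >= 2) {
      acol <- ia[1]; bcol <- ia[2]
    } else {
      acol <- 1L; bcol <- 2L
    }
    sys_col <- which(grepl("experimental", nm) & grepl("system", nm))
    if (length(sys_col)) {
      keep <- grepl("two.?hybrid", tab[[sys_col[1]]], ignore.case = TRUE)
      tab <- tab[keep, , drop = FALSE]
    }
    ep <- cbind(as.character(tab[[acol]]), as.character(tab[[bcol]]))
  }
  g <- interaction_network(ep)
  if (!quiet) {
    message(sprintf("read %d vertices, %d edges (%d self edges and %d duplicates dropped)",
      igraph::vcount(g), igraph::ecount(g), g$n_self_dropped, g$n_dup_dropped))
  }
  g
}

#' Write a network as a two-column edge list
#'
#' @param g interaction network.
#' @param path output file; tab-separated, one edge per line, endpoints in
#'   sorted order and lines sorted, so identical graphs serialize identically.
#' @export
write_network <- function(g, path) {
  el <- igraph::as_edgelist(g)
  if (nrow(el)) {
    swap <- el[, 1] > el[, 2]
    el[swap, ] <- el[swap, c(2, 1), drop = FALSE]
    el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  }
  writeLines(paste(el[, 1], el[, 2], sep = "\t"), path)
  invisible(path)
}

# small internal helper used across the package
.graph_from_pairs <- function(...) {
  pairs <- matrix(c(...), ncol = 2, byrow = TRUE)
  interaction_network(pairs)
}
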