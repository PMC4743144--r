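# graph builders and independent oracles shared across the suite

gfp <- function(...) {
  interaction_network(matrix(c(...), ncol = 2, byrow = TRUE))
}

path_graph <- function(labels) {
  n <- length(labels)
  interaction_network(cbind(labels[-n], labels[-1]))
}

cycle_graph <- function(labels) {
  n <- length(labels)
  interaction_network(cbind(labels, labels[c(2:n, 1)]))
}

clique_graph <- function(labels) {
  pairs <- t(utils::combn(labels, 2))
  interaction_network(pairs)
}

star_graph <- function(center, leaves) {
  interaction_network(cbind(center, leaves))
}

# G(n, p) with stable letter/number names
random_named_gnp <- function(n, p) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}

# independent oracle: 4-cycles by exhaustive enumeration of 4-vertex subsets,
# counting the (at most 3) spanning quadrilaterals of each subset
exhaustive_four_cycles <- function(g) {
  n <- igraph::vcount(g)
  if (n < 4) return(0L)
  adj <- as.matrix(igraph::as_adjacency_matrix(g)) > 0
  total <- 0L
  for (sub in asplit(utils::combn(n, 4), 2)) {
    a <- sub[1]; b <- sub[2]; c <- sub[3]; d <- sub[4]
    # three distinct cyclic orderings of 4 labelled vertices
    cycles <- list(c(a, b, c, d), c(a, b, d, c), c(a, c, b, d))
    for (cy in cycles) {
      if (adj[cy[1], cy[2]] && adj[cy[2], cy[3]] &&
          adj[cy[3], cy[4]] && adj[cy[4], cy[1]]) total <- total + 1L
    }
  }
  total
}

# independent oracle: triangles by exhaustive 3-subset enumeration
exhaustive_triangles <- function(g) {
  n <- igraph::vcount(g)
  if (n < 3) return(0L)
  adj <- as.matrix(igraph::as_adjacency_matrix(g)) > 0
  total <- 0L
  for (sub in asplit(utils::combn(n, 3), 2)) {
    if (adj[sub[1], sub[2]] && adj[sub[2], sub[3]] && adj[sub[1], sub[3]]) {
      total <- total + 1L
    }
  }
  total
}

# independent oracle: maximum vertex connectivity over all induced subgraphs
# with >= 3 vertices, by exhaustive subset enumeration
exhaustive_mhcs_k <- function(g) {
  n <- igraph::vcount(g)
  if (n < 3) return(0L)
  best <- 0L
  for (size in 3:n) {
    for (sub in asplit(utils::combn(n, size), 2)) {
      k <- vertex_connectivity(igraph::induced_subgraph(g, sub))
      if (k > best) best <- k
    }
  }
  best
}

expect_same_graph <- function(a, b) {
  expect_setequal(igraph::V(a)$name, igraph::V(b)$name)
  key <- function(g) {
    el <- igraph::as_edgelist(g)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  expect_identical(key(a), key(b))
}
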