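test_that("network ingest yields a simple graph and keeps isolated vertices", {
  g <- interaction_network(rbind(c("A", "B"), c("B", "A"), c("C", "C"), c("B", "C")),
                           vertices = "Z")
  expect_equal(igraph::ecount(g), 2)
  expect_setequal(igraph::V(g)$name, c("A", "B", "C", "Z"))
  expect_equal(g$n_self_dropped, 1)
  expect_equal(g$n_dup_dropped, 1)
  expect_equal(unname(igraph::degree(g)["Z"]), 0)
})

test_that("edge density is edges over vertex pairs", {
  expect_equal(edge_density(clique_graph(LETTERS[1:4])), 1.0)
  expect_equal(edge_density(cycle_graph(LETTERS[1:4])), 4 / 6)
  expect_equal(edge_density(clique_graph(LETTERS[1:3])), 1.0)
  expect_error(edge_density(interaction_network(matrix(character(), ncol = 2),
                                                vertices = "A")),
               "fewer than 2")
})

test_that("vertex connectivity matches known families", {
  expect_equal(vertex_connectivity(cycle_graph(LETTERS[1:5])), 2L)
  expect_equal(vertex_connectivity(clique_graph(LETTERS[1:4])), 3L)
  bowtie <- gfp("A", "X", "B", "X", "A", "B", "C", "X", "D", "X", "C", "D")
  expect_equal(vertex_connectivity(bowtie), 1L)  # X is an articulation point
  expect_equal(vertex_connectivity(interaction_network(matrix(character(), ncol = 2),
                                                       vertices = c("A", "B"))), 0L)
})

test_that("edge connectivity matches known families", {
  expect_equal(edge_connectivity(path_graph(LETTERS[1:3])), 1L)
  expect_equal(edge_connectivity(cycle_graph(LETTERS[1:4])), 2L)
  expect_equal(edge_connectivity(clique_graph(LETTERS[1:5])), 4L)
})

test_that("degree statistics normalize by the vertex count", {
  st <- degree_statistics(star_graph("H", c("a", "b", "c")), normalize = TRUE)
  expect_equal(st$maximum, 3 / 4)
  expect_equal(st$minimum, 1 / 4)
  k4 <- degree_statistics(clique_graph(LETTERS[1:4]), normalize = TRUE)
  expect_equal(k4$maximum, k4$minimum)
  expect_equal(k4$maximum, 3 / 4)
  iso <- degree_statistics(interaction_network(matrix(character(), ncol = 2),
                                               vertices = c("A", "B")))
  expect_equal(iso$maximum, 0)
  expect_error(degree_statistics(interaction_network(matrix(character(), ncol = 2))),
               "empty")
})

test_that("clustering coefficient is 3 triangles over length-2 paths", {
  expect_equal(as.numeric(clustering_coefficient(clique_graph(LETTERS[1:3]))), 1.0)
  expect_equal(as.numeric(clustering_coefficient(star_graph("H", c("a", "b", "c")))), 0.0)
  # K4 minus one edge: 2 triangles, 8 length-2 paths
  k4m <- gfp("A", "B", "A", "C", "A", "D", "B", "C", "B", "D")
  expect_equal(as.numeric(clustering_coefficient(k4m)), 0.75)
  single <- gfp("A", "B")
  cc <- clustering_coefficient(single)
  expect_equal(as.numeric(cc), 0)
  expect_false(attr(cc, "defined"))
})

test_that("mutual clustering coefficient divides shared neighbors by min degree", {
  tri <- clique_graph(c("A", "B", "C"))
  expect_equal(mutual_clustering_coefficient(tri, "A", "B"), 0.5)
  c4 <- cycle_graph(c("A", "B", "C", "D"))
  expect_equal(mutual_clustering_coefficient(c4, "A", "C"), 1.0)  # opposite
  expect_equal(mutual_clustering_coefficient(c4, "A", "B"), 0.0)  # adjacent
  g0 <- interaction_network(rbind(c("A", "B")), vertices = "Z")
  expect_error(mutual_clustering_coefficient(g0, "A", "Z"), "degree 0")
  expect_error(mutual_clustering_coefficient(tri, "A", "A"), "distinct")
})

test_that("MCC summaries enumerate all defined unordered pairs", {
  tri <- clique_graph(c("A", "B", "C"))
  st <- mcc_statistics(tri)
  expect_equal(st$mean, 0.5)
  expect_equal(st$sd, 0)
  expect_equal(st$count, 3)
  c4 <- mcc_statistics(cycle_graph(c("A", "B", "C", "D")))
  expect_equal(c4$mean, (2 * 1.0 + 4 * 0.0) / 6)
  k4 <- mcc_statistics(clique_graph(LETTERS[1:4]))
  expect_equal(k4$mean, 2 / 3)
  # degree-0 vertices are excluded from pairs, not scored 0
  with_iso <- interaction_network(rbind(c("A", "B"), c("B", "C"), c("A", "C")),
                                  vertices = "Z")
  expect_equal(mcc_statistics(with_iso)$count, 3)
  expect_equal(mcc_statistics(interaction_network(matrix(character(), ncol = 2),
                                                  vertices = c("A", "B")))$count, 0)
})

test_that("triangle and 4-cycle counts match hand counts", {
  expect_equal(triangle_count(clique_graph(LETTERS[1:4])), 4L)
  expect_equal(triangle_count(cycle_graph(LETTERS[1:4])), 0L)
  two_tri <- gfp("A", "B", "A", "C", "B", "C", "A", "D", "B", "D")
  expect_equal(triangle_count(two_tri), 2L)
  expect_equal(four_cycle_count(cycle_graph(LETTERS[1:4])), 1L)
  expect_equal(four_cycle_count(clique_graph(LETTERS[1:4])), 3L)
  expect_equal(four_cycle_count(star_graph("H", letters[1:5])), 0L)
  expect_equal(four_cycle_count(path_graph(LETTERS[1:6])), 0L)
})

test_that("betweenness uses the fractional convention, normalized by |V|", {
  p3 <- betweenness_statistics(path_graph(c("A", "B", "C")), normalize = TRUE)
  expect_equal(p3$maximum, 1 / 3)  # middle vertex carries the single A-C pair
  st <- betweenness_statistics(star_graph("H", c("a", "b", "c")), normalize = TRUE)
  expect_equal(st$maximum, 3 / 4)  # center carries all 3 leaf pairs
  k5 <- betweenness_statistics(clique_graph(LETTERS[1:5]), normalize = TRUE)
  expect_equal(k5$maximum, 0)
  expect_equal(k5$minimum, 0)
  expect_error(betweenness_statistics(gfp("A", "B")), "fewer than 3|unconnected")
  disc <- interaction_network(rbind(c("A", "B"), c("C", "D")))
  expect_error(betweenness_statistics(disc), "unconnected|fewer")
})

test_that("topology profiles compose the individual statistics", {
  p <- topology_profile(clique_graph(LETTERS[1:4]))
  expect_equal(p$edge_density, 1.0)
  expect_equal(p$vertex_connectivity, 3L)
  expect_equal(p$clustering_coefficient, 1.0)
  expect_equal(p$triangle_count, 4L)
  expect_equal(p$betweenness_stats$maximum, 0)

  e <- topology_profile(interaction_network(matrix(character(), ncol = 2),
                                            vertices = c("A", "B", "C")))
  expect_equal(e$edge_density, 0)
  expect_equal(e$vertex_connectivity, 0L)
  expect_false(e$cc_defined)
  expect_true(is.na(e$betweenness_stats$maximum))

  c4 <- topology_profile(cycle_graph(LETTERS[1:4]))
  expect_equal(c4$vertex_connectivity, 2L)
  expect_equal(c4$clustering_coefficient, 0)
  expect_equal(c4$four_cycle_count, 1L)

  row <- profile_row(p)
  expect_equal(nrow(row), 1)
  expect_true(all(c("edge_density", "mcc_mean", "betweenness_max") %in% names(row)))
})

test_that("summary stats use the population standard deviation", {
  st <- summary_stats(c(1, 2, 3, 4))
  expect_equal(st$sd, sqrt(mean((c(1, 2, 3, 4) - 2.5)^2)))
  expect_true(st$minimum <= st$mean && st$mean <= st$maximum)
  empty <- summary_stats(numeric())
  expect_equal(empty$count, 0)
  expect_true(is.na(empty$mean))
})

test_that("brute-force connectivity oracle agrees on known graphs and rejects big inputs", {
  expect_equal(brute_force_connectivity_oracle(cycle_graph(LETTERS[1:4]), "vertex"), 2L)
  expect_equal(brute_force_connectivity_oracle(clique_graph(LETTERS[1:4]), "edge"), 3L)
  expect_equal(brute_force_connectivity_oracle(gfp("A", "B"), "vertex"), 1L)
  expect_error(brute_force_connectivity_oracle(clique_graph(sprintf("v%d", 1:11))),
               "at most 10")
})

test_that("metric invariants hold on random graphs", {
  set.seed(101)
  for (i in 1:60) {
    g <- random_named_gnp(sample(3:8, 1), runif(1, 0.2, 0.8))
    kv <- vertex_connectivity(g)
    ke <- edge_connectivity(g)
    dmin <- min(igraph::degree(g))
    expect_lte(kv, ke)            # Whitney
    expect_lte(ke, dmin)
    cc <- as.numeric(clustering_coefficient(g))
    expect_gte(cc, 0); expect_lte(cc, 1)
    if (triangle_count(g) == 0) expect_equal(cc, 0)
  }
  # cliques have CC exactly 1
  for (n in 3:6) {
    expect_equal(as.numeric(clustering_coefficient(clique_graph(sprintf("q%d", 1:n)))), 1)
  }
})

test_that("adding a degree-0 vertex changes only size-dependent statistics", {
  set.seed(7)
  g <- random_named_gnp(6, 0.6)
  g2 <- igraph::add_vertices(g, 1, name = "iso")
  expect_equal(triangle_count(g2), triangle_count(g))
  expect_equal(four_cycle_count(g2), four_cycle_count(g))
  expect_equal(edge_connectivity(g2), 0L)   # isolated vertex disconnects
  expect_equal(vertex_connectivity(g2), 0L)
  expect_equal(mcc_statistics(g2)$mean, mcc_statistics(g)$mean)
  expect_equal(degree_statistics(g2, normalize = FALSE)$maximum,
               degree_statistics(g, normalize = FALSE)$maximum)
})
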