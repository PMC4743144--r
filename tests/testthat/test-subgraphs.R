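test_that("complex graphs are induced on members present in the network", {
  net <- clique_graph(LETTERS[1:5])
  net <- igraph::add_vertices(net, 1, name = "P")
  net <- igraph::add_edges(net, c("E", "P"))

  g <- complex_graph(net, LETTERS[1:5])
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 10)   # the 5-clique without the pendant
  expect_equal(g$coverage, 1)

  none <- complex_graph(net, c("X1", "X2"))
  expect_equal(igraph::vcount(none), 0)
  expect_equal(none$coverage, 0)

  all_of_it <- complex_graph(net, igraph::V(net)$name)
  expect_same_graph(all_of_it, net)

  half <- complex_graph(net, c("A", "B", "X1", "X2"))
  expect_equal(half$coverage, 0.5)
})

test_that("haircut peels to minimum degree 2 and is idempotent", {
  expect_equal(igraph::vcount(haircut(path_graph(LETTERS[1:6]))), 0)
  tree <- gfp("A", "B", "A", "C", "C", "D", "C", "E")
  expect_equal(igraph::vcount(haircut(tree)), 0)
  tri_pendant <- gfp("A", "B", "B", "C", "A", "C", "C", "P")
  expect_setequal(igraph::V(haircut(tri_pendant))$name, c("A", "B", "C"))
  c4 <- cycle_graph(LETTERS[1:4])
  expect_same_graph(haircut(c4), c4)
})

test_that("haircut contract holds on random graphs: idempotence, degree, triangles", {
  set.seed(202)
  for (i in 1:80) {
    g <- random_named_gnp(sample(4:12, 1), runif(1, 0.1, 0.5))
    h <- haircut(g)
    if (igraph::vcount(h) > 0) expect_gte(min(igraph::degree(h)), 2)
    expect_same_graph(haircut(h), h)
    expect_equal(triangle_count(h), triangle_count(g))
  }
})

test_that("MHCS finds the most highly connected subgraph", {
  # K5 with a pendant path dangling off it
  g <- clique_graph(LETTERS[1:5])
  g <- igraph::add_vertices(g, 2, name = c("P", "Q"))
  g <- igraph::add_edges(g, c("E", "P", "P", "Q"))
  m <- mhcs(g)
  expect_equal(m$k, 4L)
  expect_setequal(igraph::V(m$graph)$name, LETTERS[1:5])

  bowtie <- gfp("A", "X", "B", "X", "A", "B", "C", "X", "D", "X", "C", "D")
  m2 <- mhcs(bowtie)
  expect_equal(m2$k, 2L)
  expect_setequal(igraph::V(m2$graph)$name, c("A", "B", "X"))  # lexicographic tie

  star <- star_graph("H", letters[1:5])
  m3 <- mhcs(star)
  expect_equal(m3$k, 1L)
  expect_equal(igraph::vcount(m3$graph), 6)  # no 2-connected subgraph exists

  edge_only <- gfp("A", "B")
  m4 <- mhcs(edge_only)
  expect_equal(m4$k, 0L)
  expect_equal(igraph::vcount(m4$graph), 0)
})

test_that("MHCS k dominates whole-graph connectivity and is exact on small graphs", {
  set.seed(303)
  for (i in 1:50) {
    g <- random_named_gnp(sample(4:8, 1), runif(1, 0.2, 0.7))
    m <- mhcs(g)
    expect_gte(m$k, vertex_connectivity(g))
    expect_equal(m$k, exhaustive_mhcs_k(g))
    if (igraph::vcount(m$graph) > 0) {
      expect_equal(vertex_connectivity(m$graph), m$k)
      expect_true(igraph::is_connected(m$graph))
    }
  }
  for (n in 3:6) {
    m <- mhcs(clique_graph(sprintf("k%d", 1:n)))
    expect_equal(m$k, n - 1L)
    expect_equal(igraph::vcount(m$graph), n)
  }
})

test_that("MHCS is deterministic", {
  set.seed(404)
  g <- random_named_gnp(12, 0.3)
  m1 <- mhcs(g); m2 <- mhcs(g)
  expect_identical(sort(igraph::V(m1$graph)$name), sort(igraph::V(m2$graph)$name))
  expect_identical(m1$k, m2$k)
})

test_that("connected components come back as ordered graphs", {
  g <- gfp("A", "B", "B", "C", "A", "C", "D", "E")
  g <- igraph::add_vertices(g, 1, name = "Z")
  comps <- components_list(g)
  expect_length(comps, 3)
  expect_equal(unname(vapply(comps, igraph::vcount, numeric(1))), c(3, 2, 1))
  expect_length(components_list(interaction_network(matrix(character(), ncol = 2))), 0)
  solo <- components_list(cycle_graph(LETTERS[1:4]))
  expect_length(solo, 1)
  expect_same_graph(solo[[1]], cycle_graph(LETTERS[1:4]))
})

test_that("variant profiles cover full, haircut, MHCS and components", {
  net <- clique_graph(c("A", "B", "C"))
  cx <- complex_definition("tri", c("A", "B", "C"))
  vp <- variant_profiles(net, cx)
  expect_s3_class(vp, "variant_profiles")
  expect_equal(vp$full$n_vertices, 3)
  expect_equal(vp$haircut$n_vertices, 3)   # haircut leaves the clique alone
  expect_equal(vp$mhcs_k, 2L)
  expect_gte(vp$mhcs_k, vp$full$vertex_connectivity)
  expect_length(vp$components, 1)

  pathy <- complex_definition("path", LETTERS[1:5])
  vp2 <- variant_profiles(path_graph(LETTERS[1:5]), pathy)
  expect_null(vp2$haircut)
  expect_lte(vp2$mhcs_k, 1L)

  refcx <- complex_definition("ref", c("A", "B", "C", "D"),
    reference_edges = rbind(c("A", "B"), c("B", "C"), c("A", "C")))
  vr <- variant_profiles(interaction_network(matrix(character(), ncol = 2),
                                             vertices = "A"),
                         refcx, source = "reference")
  expect_equal(vr$full$n_vertices, 4)      # D isolated in the reference graph
  expect_equal(vr$full$triangle_count, 1L)
  expect_error(variant_profiles(net, cx, source = "reference"), "reference")
})

test_that("reference overlap counts shared and network-only edges", {
  ref_edges <- rbind(c("A", "B"), c("B", "C"), c("C", "D"), c("A", "D"))
  cx <- complex_definition("cx", LETTERS[1:4], reference_edges = ref_edges)

  net_same <- interaction_network(ref_edges)
  ov <- reference_overlap(cx, net_same)
  expect_equal(ov$shared_edges, ov$reference_edges)
  expect_equal(ov$network_only_edges, 0)

  net_partial <- interaction_network(rbind(c("A", "B"), c("A", "C")))
  ov2 <- reference_overlap(cx, net_partial)
  expect_equal(ov2$members_present, 3)
  expect_equal(ov2$members_total, 4)
  expect_equal(ov2$shared_edges, 1)        # A-B is shared, A-C is network-only
  expect_equal(ov2$network_only_edges, 1)

  net_none <- interaction_network(rbind(c("X", "Y")))
  ov3 <- reference_overlap(cx, net_none)
  expect_equal(ov3$members_present, 0)
  expect_equal(ov3$shared_edges, 0)
  expect_error(reference_overlap(complex_definition("m", "A"), net_none),
               "reference")
})

test_that("a sparse observation of a dense reference keeps few shared edges", {
  # 32-edge reference complex observed through heavy dropout: the induced
  # graph retains exactly the 8 surviving reference edges
  members <- sprintf("p%02d", 1:12)
  ref <- t(utils::combn(members, 2))[1:32, ]
  cx <- complex_definition("big", members, reference_edges = ref)
  observed <- interaction_network(ref[seq(1, 32, by = 4), ])
  ov <- reference_overlap(cx, observed)
  expect_equal(ov$reference_edges, 32)
  expect_equal(ov$shared_edges, 8)
})
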