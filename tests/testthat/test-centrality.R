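test_that("as_weighted_graph validates simplicity and substitutes Inf weights", {
  expect_error(as_weighted_graph(edge_tbl("a", "a")), "self-loops")
  expect_error(as_weighted_graph(edge_tbl(c("a", "b"), c("b", "a"))), "duplicate")
  expect_error(as_weighted_graph(edge_tbl("a", "b", -1)), "positive")

  g <- as_weighted_graph(edge_tbl(c("a", "b"), c("b", "c"), c(Inf, 4)))
  expect_equal(sort(igraph::E(g)$weight), c(4, 4))
  g2 <- as_weighted_graph(edge_tbl(c("a", "b"), c("b", "c"), c(Inf, 4)),
                          inf_weight = 9)
  expect_equal(sort(igraph::E(g2)$weight), c(4, 9))
})

test_that("centrality hand values hold on the star and the triangle", {
  cs <- centrality_suite(as_weighted_graph(star_edges(4)))
  center <- cs[cs$node == "center", ]
  leaves <- cs[cs$node != "center", ]
  expect_equal(center$degree, 4)
  expect_equal(center$betweenness, 6)           # C(4,2) leaf pairs
  expect_equal(leaves$degree, rep(1, 4))
  expect_equal(leaves$betweenness, rep(0, 4))   # leaves route nothing
  expect_equal(max(cs$closeness), center$closeness)

  tri <- centrality_suite(as_weighted_graph(edge_tbl(c("a", "a", "b"),
                                                     c("b", "c", "c"))))
  expect_equal(tri$network, rep(2, 3))          # two incident edges, ECC 1
  expect_equal(tri$lac, rep(1, 3))
})

test_that("vertex-transitive graphs score uniformly on every measure", {
  for (edges in list(cycle_edges(6), complete_edges(5))) {
    cs <- centrality_suite(as_weighted_graph(edges))
    for (m in setdiff(names(cs), "node")) {
      expect_lt(max(cs[[m]]) - min(cs[[m]]), 1e-9)
    }
  }
})

test_that("weight scaling doubles degree and preserves eigenvector ranking", {
  set.seed(51)
  fix <- generate_fixtures(fixture_spec(n_mirnas = 40, clique_sizes = c(5, 4), seed = 5))
  db <- suppressMessages(build_db(merge_on_key(fix$mirna_gene, fix$gene_disease)))
  net <- suppressMessages(build_network(db))
  g1 <- as_weighted_graph(net)
  net2 <- net
  net2$weight <- net2$weight * 2
  g2 <- as_weighted_graph(net2)
  c1 <- centrality_suite(g1)
  c2 <- centrality_suite(g2)
  expect_equal(c2$degree, 2 * c1$degree)
  expect_equal(c2$eigenvector, c1$eigenvector, tolerance = 1e-6)
})

test_that("disconnected graphs are handled per component", {
  # two components: a triangle and a single edge
  edges <- edge_tbl(c("a", "a", "b", "x"), c("b", "c", "c", "y"))
  cs <- centrality_suite(as_weighted_graph(edges))
  expect_equal(cs$betweenness, rep(0, 5))
  expect_true(all(cs$closeness[cs$node %in% c("x", "y")] > 0))
  # eigenvector mass concentrates on the dominant component
  expect_lt(max(cs$eigenvector[cs$node %in% c("x", "y")]),
            min(cs$eigenvector[cs$node %in% c("a", "b", "c")]))
})

test_that("centrality scores are stable across repeated runs", {
  fix <- generate_fixtures(fixture_spec(n_mirnas = 50, clique_sizes = c(6, 5, 4), seed = 9))
  db <- suppressMessages(build_db(merge_on_key(fix$mirna_gene, fix$gene_disease)))
  net <- suppressMessages(build_network(db))
  g <- as_weighted_graph(net)
  c1 <- centrality_suite(g)
  c2 <- centrality_suite(g)
  for (m in setdiff(names(c1), "node")) {
    expect_equal(c1[[m]], c2[[m]], tolerance = 1e-9)
  }
})

test_that("edge-percolation centrality is symmetric, seeded and topology-aware", {
  g1 <- as_weighted_graph(edge_tbl("a", "b"))
  s1 <- epc(g1, reps = 100, seed = 3)
  expect_equal(s1$epc, c(1, 1))   # single edge retained with probability 1

  # automorphism invariance on two disjoint triangles
  g2 <- as_weighted_graph(edge_tbl(c("a", "a", "b", "x", "x", "y"),
                                   c("b", "c", "c", "y", "z", "z")))
  s2 <- epc(g2, reps = 4000, seed = 5)
  expect_equal(max(s2$epc) - min(s2$epc), 0, tolerance = 0.05)

  # star center beats every path node at the same size
  s_star <- epc(as_weighted_graph(star_edges(4)), reps = 2000, seed = 7)
  s_path <- epc(as_weighted_graph(edge_tbl(sprintf("p%d", 1:4), sprintf("p%d", 2:5))),
                reps = 2000, seed = 7)
  expect_gt(s_star$epc[s_star$node == "center"], max(s_path$epc))

  # deterministic for a fixed seed
  expect_equal(epc(g2, reps = 50, seed = 11), epc(g2, reps = 50, seed = 11))
})

test_that("consensus counts top-list agreements with the >= threshold", {
  # construct scores where hub5 makes exactly 5 top lists and hub4 exactly 4
  nodes <- c("hub5", "hub4", sprintf("f%03d", 1:150))
  scores <- tibble::tibble(node = nodes)
  for (j in 1:7) {
    s <- c(
      if (j <= 5) 1000 else -1000,
      if (j <= 4) 999 else -999,
      seq_along(nodes[-(1:2)])
    )
    scores[[paste0("meas", j)]] <- s
  }
  rep <- consensus(scores, top_t = 100, min_agreement = 5)
  ag <- rep$agreement
  expect_equal(ag$agreement[ag$node == "hub5"], 5)
  expect_equal(ag$agreement[ag$node == "hub4"], 4)
  expect_true("hub5" %in% rep$consensus$node)
  expect_false("hub4" %in% rep$consensus$node)

  # lowering the threshold only adds nodes
  rep4 <- consensus(scores, top_t = 100, min_agreement = 4)
  expect_true(all(rep$consensus$node %in% rep4$consensus$node))

  # measure order is irrelevant
  shuf <- scores[c("node", sample(paste0("meas", 1:7)))]
  rep_s <- consensus(shuf, top_t = 100, min_agreement = 5)
  expect_equal(rep_s$agreement, rep$agreement)

  expect_error(consensus(scores, top_t = 0), "top_t")
  expect_error(consensus(scores, min_agreement = 8), "measures")
})

test_that("a node topping every measure reaches full agreement", {
  # wheel: hub + 6-cycle rim; the hub dominates all seven measures
  rim <- sprintf("leaf%d", 1:6)
  edges <- dplyr::bind_rows(star_edges(6), edge_tbl(rim, c(rim[-1], rim[1])))
  rep <- consensus_hubs(edges, top_t = 1, min_agreement = 7)
  expect_equal(rep$consensus$node, "center")
  expect_equal(rep$consensus$agreement, 7)
  expect_equal(glance(rep)$n_measures, 7)
  expect_equal(nrow(tidy(rep)), 7)  # one row per node of the wheel
})
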