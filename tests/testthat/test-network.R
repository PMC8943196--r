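test_that("build_network turns reactions into CAR-weighted edges", {
  u <- quick_compounds(c(eth = "CCO", ald = "CC=O", o2 = "O=O",
                         h2o2 = "OO"))
  rx <- unify_reactions(data.frame(
    id = "k1",
    equation = "eth + o2 <=> ald + h2o2",
    ec = NA, source_db = "t"), u)$reactions
  g <- build_network(rx, u, cofactors = cofactors_cached())
  expect_setequal(igraph::V(g)$name, c("eth", "ald", "o2", "h2o2"))
  # candidate edges: eth-ald (MCS 3), eth-h2o2 (O), o2-ald (O),
  # o2-h2o2 (cofactor pair)
  e_ethald <- igraph::E(g)[igraph::V(g)["eth"] %--% igraph::V(g)["ald"]]
  expect_equal(e_ethald$car, 1)
  expect_equal(e_ethald$distance, 1)
  e_redox <- igraph::E(g)[igraph::V(g)["o2"] %--% igraph::V(g)["h2o2"]]
  expect_identical(e_redox$car_source, "cofactor_table")
  expect_equal(e_redox$car, 1)
})

test_that("an A + B <=> C + D reaction yields the four candidate edges minus zero-CAR pairs", {
  u <- quick_compounds(c(A = "CCN", B = "OCCO", C = "CCO", D = "OCCN"))
  rx <- unify_reactions(data.frame(
    id = "r", equation = "A + B <=> C + D", ec = NA, source_db = "t"),
    u)$reactions
  g <- build_network(rx, u, cofactors = NULL)
  # every pair shares atoms here: 4 edges (A-C, A-D, B-C, B-D)
  expect_equal(igraph::ecount(g), 4)
  # with a carbon-free partner, pairs sharing no element are dropped
  u2 <- quick_compounds(c(A = "CC", B = "O", C = "CCO"))
  rx2 <- unify_reactions(data.frame(
    id = "r", equation = "A + B <=> C", ec = NA, source_db = "t"),
    u2)$reactions
  g2 <- build_network(rx2, u2, cofactors = NULL)
  edges <- apply(igraph::as_edgelist(g2), 1, paste, collapse = "-")
  expect_false("A-B" %in% edges || "B-A" %in% edges)
})

test_that("parallel reactions on one pair aggregate ids and keep the best CAR", {
  u <- quick_compounds(c(eth = "CCO", ald = "CC=O", o2 = "O=O",
                         h2o2 = "OO", nadp = "O=P(O)(O)O"))
  rx <- unify_reactions(data.frame(
    id = c("k1", "k2"),
    equation = c("eth + o2 <=> ald + h2o2", "eth <=> ald"),
    ec = NA, source_db = "t"), u)$reactions
  g <- build_network(rx, u, cofactors = cofactors_cached())
  e <- igraph::E(g)[igraph::V(g)["eth"] %--% igraph::V(g)["ald"]]
  ids <- strsplit(e$reaction_ids, ";")[[1]]
  expect_length(ids, 2)
  expect_equal(e$car, 1)
})

test_that("rule atom maps override the fallback cascade in the network", {
  u <- quick_compounds(c(eth = "CCO", o2 = "O=O", h2o2 = "OO", h2o = "O"))
  ex <- expand(u, toy_rules_cached()["r1_alcohol_oxidase"],
               both_directions = FALSE)
  g <- build_network(ex$reactions, ex$compounds,
                     cofactors = cofactors_cached())
  # pairs covered by the rule atom map carry stage-1 provenance; pairs the
  # rewrite does not connect (e.g. substrate vs leaving peroxide) fall back
  el <- igraph::as_edgelist(g)
  src <- igraph::E(g)$car_source
  ald_id <- ex$novel_compounds$id[ex$novel_compounds$formula == "C2H4O"]
  e1 <- igraph::get_edge_ids(g, c("eth", ald_id))
  expect_identical(src[e1], "rule_atom_map")
  e2 <- igraph::get_edge_ids(g, c("o2", "h2o2"))
  expect_identical(src[e2], "rule_atom_map")
  # stage-1 counts are never below what the MCS stage would give
  for (i in which(src == "rule_atom_map")) {
    mols <- attr(ex$compounds, "mols")
    nc_map <- igraph::E(g)$n_c[i]
    nc_mcs <- mcs_heavy_atoms(mols[[el[i, 1]]], mols[[el[i, 2]]])
    expect_gte(nc_map, nc_mcs)
  }
})

test_that("the CAR cutoff removes strictly below and keeps nodes", {
  edges <- data.frame(s = c("a", "b", "c", "d"),
                      t = c("b", "c", "d", "e"),
                      car = c(0.3399, 0.34, 1, 0.1))
  g <- manual_car_graph(edges)
  cut <- apply_cutoff(g, 0.34)
  expect_equal(igraph::vcount(cut), 5)            # nodes invariant
  expect_equal(igraph::ecount(cut), 2)            # 0.3399 and 0.1 removed
  kept <- apply(igraph::as_edgelist(cut), 1, paste, collapse = "-")
  expect_setequal(kept, c("b-c", "c-d"))
  expect_false("weight" %in% igraph::edge_attr_names(cut))
  # threshold 0 removes nothing; all-CAR-1 graphs are unchanged
  expect_equal(igraph::ecount(apply_cutoff(g, 0)), 4)
  g1 <- manual_car_graph(data.frame(s = c("a", "b"), t = c("b", "c"),
                                    car = 1))
  expect_equal(igraph::ecount(apply_cutoff(g1, 0.34)), 2)
})

test_that("network statistics match hand-computable graphs", {
  p9 <- igraph::make_ring(9, circular = FALSE)
  igraph::V(p9)$name <- letters[1:9]
  st <- network_stats(p9)
  expect_equal(length(st$components), 1)
  expect_equal(st$diameter, 8)
  tri2 <- igraph::disjoint_union(igraph::make_ring(3), igraph::make_ring(3))
  igraph::V(tri2)$name <- letters[1:6]
  st2 <- network_stats(tri2)
  expect_equal(st2$components, c(3L, 3L))
  expect_equal(st2$main_component_fraction, 0.5)
  expect_equal(st2$diameter, 1)
  empty <- igraph::make_empty_graph(0, directed = FALSE)
  expect_equal(network_stats(empty)$n_nodes, 0)
})

test_that("network statistics equal the all-pairs BFS oracle on random graphs", {
  for (seed in 1:8) {
    n <- c(15, 30, 50, 80, 120, 160, 50, 200)[seed]
    g <- random_weighted_graph(n, 2.2 / n, seed, weighted = FALSE)
    st <- network_stats(g)
    d <- all_pairs_bfs(g)
    finite_class <- apply(is.finite(d), 1, paste, collapse = "")
    comp_sizes <- sort(as.integer(table(finite_class)), decreasing = TRUE)
    expect_identical(st$components, comp_sizes)
    main <- names(which.max(table(finite_class)))
    idx <- which(finite_class == main)
    dm <- d[idx, idx, drop = FALSE]
    if (length(idx) >= 2) {
      expect_equal(st$diameter, max(dm))
      expect_equal(st$average_path_length,
                   mean(dm[upper.tri(dm)]))
    }
    # invariants
    expect_equal(sum(st$components), igraph::vcount(g))
    if (length(idx) >= 2) {
      expect_gte(st$diameter, ceiling(st$average_path_length) - 1)
    }
  }
})

test_that("edge lists round-trip through TSV", {
  edges <- data.frame(s = c("a", "b"), t = c("b", "c"), car = c(0.5, 0.8))
  g <- manual_car_graph(edges)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(g, path)
  g2 <- read_edge_list(path)
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  expect_equal(sort(igraph::E(g2)$car), sort(igraph::E(g)$car))
  expect_equal(sort(igraph::E(g2)$weight), sort(1 / edges$car))
})
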