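test_that("k_shortest handles trivial and degenerate graphs", {
  g <- manual_car_graph(data.frame(s = "a", t = "b", car = 0.5))
  paths <- k_shortest(g, "a", "b", k = 5)
  expect_length(paths, 1)
  expect_identical(paths[[1]]$nodes, c("a", "b"))
  expect_equal(paths[[1]]$total_distance, 2)
  expect_equal(paths[[1]]$car_product, 0.5)
  # isolated source
  g2 <- igraph::add_vertices(g, 1)
  igraph::V(g2)$name[3] <- "z"
  expect_length(k_shortest(g2, "z", "b", k = 5), 0)
  expect_error(k_shortest(g, "a", "a"), "source != target")
})

test_that("k_shortest equals exhaustive enumeration on random graphs", {
  n_checked <- 0
  for (seed in 1:25) {
    n <- sample(4:10, 1)
    g <- random_weighted_graph(n, 0.4, seed)
    vn <- igraph::V(g)$name
    st <- sample(vn, 2)
    want <- enumerate_simple_paths(g, st[1], st[2])
    got <- k_shortest(g, st[1], st[2], k = 20)
    expect_length(got, min(20, length(want)))
    for (i in seq_along(got)) {
      expect_identical(got[[i]]$nodes, want[[i]]$nodes,
                       info = sprintf("seed %d rank %d", seed, i))
      expect_equal(got[[i]]$total_distance, want[[i]]$distance)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 50)
})

test_that("pathway invariants hold on search output", {
  g <- random_weighted_graph(9, 0.45, 99)
  # reinterpret weights as CAR-derived distances for the invariant checks
  igraph::E(g)$car <- pmin(1, 1 / igraph::E(g)$weight)
  igraph::E(g)$weight <- 1 / igraph::E(g)$car
  igraph::E(g)$distance <- igraph::E(g)$weight
  vn <- igraph::V(g)$name
  paths <- k_shortest(g, vn[1], vn[5], k = 15)
  for (p in paths) {
    expect_false(any(duplicated(p$nodes)))                 # loopless
    expect_equal(p$total_distance, sum(1 / p$step_cars))   # distance = sum 1/CAR
    expect_true(p$car_product > 0 && p$car_product <= 1)
  }
  expect_true(!is.unsorted(vapply(paths, `[[`, 0, "total_distance")))
})

test_that("rank_native finds a better 2-step alternative ahead of a 3-step native path", {
  # native: P1-P2-P3-P4 (3 steps, CAR 0.9); alternative: P1-X-P4 (2 steps,
  # CAR 0.8): alternative distance 2.5 < native 3.33
  g <- manual_car_graph(data.frame(
    s = c("P1", "P2", "P3", "P1", "X"),
    t = c("P2", "P3", "P4", "X", "P4"),
    car = c(0.9, 0.9, 0.9, 0.8, 0.8)))
  rec <- rank_native(g, c("P1", "P2", "P3", "P4"), k_max = 10)
  expect_true(rec$native_found_in_network)
  expect_identical(rec$native_rank, 2L)
  # the native path as unique connection ranks first
  g1 <- manual_car_graph(data.frame(s = c("P1", "P2"), t = c("P2", "P3"),
                                    car = c(0.5, 0.5)))
  expect_identical(rank_native(g1, c("P1", "P2", "P3"))$native_rank, 1L)
})

test_that("rank_native reports unfound references and monotone ranks", {
  g <- manual_car_graph(data.frame(
    s = c("P1", "P2", "P1", "X"), t = c("P2", "P3", "X", "P3"),
    car = c(0.4, 0.4, 0.9, 0.9)))
  # an edge of the reference removed by the cutoff
  cut <- apply_cutoff(g, 0.5, drop_weights = FALSE)
  rec <- rank_native(cut, c("P1", "P2", "P3"))
  expect_false(rec$native_found_in_network)
  expect_true(is.na(rec$native_rank))
  # found-at-k stays found at larger k
  r2 <- rank_native(g, c("P1", "P2", "P3"), k_max = 2)
  r10 <- rank_native(g, c("P1", "P2", "P3"), k_max = 10)
  expect_identical(r2$native_rank, r10$native_rank)
})

test_that("linearize_reference recovers chains and longest branches", {
  u <- quick_compounds(c(A = "CCO", B = "CC=O", C = "CC(=O)O", D = "CN",
                         E = "CCN", F = "CCC"))
  chain <- data.frame(
    id = c("r1", "r2", "r3"),
    equation = c("A <=> B", "B <=> C", "C <=> D"),
    ec = NA, source_db = "t")
  lin <- linearize_reference(unify_reactions(chain, u)$reactions, u,
                             exclude = character(0))
  expect_identical(lin$nodes, c("A", "B", "C", "D"))
  expect_identical(lin$precursor, "A")
  expect_identical(lin$target, "D")
  # branched pathway: trunk of 4 steps beats a 2-step branch
  branched <- data.frame(
    id = paste0("r", 1:6),
    equation = c("A <=> B", "B <=> C", "C <=> D", "D <=> E",
                 "B <=> F", "F <=> F"),
    ec = NA, source_db = "t")
  br <- unify_reactions(branched, u)$reactions
  lin2 <- linearize_reference(br, u, exclude = character(0))
  expect_identical(lin2$nodes, c("A", "B", "C", "D", "E"))
  expect_equal(lin2$length, 4)
  expect_error(
    linearize_reference(unify_reactions(chain[1, ], u)$reactions, u),
    class = "carnet_benchmark_error")
})

test_that("cofactor exclusion prevents linearization shortcuts", {
  u <- quick_compounds(c(A = "CCO", B = "CC=O", C = "CC(=O)O", D = "CCN",
                         nad = paste0("NC(=O)c1ccc[n+](c1)C1OC(COP(=O)(O)",
                                      "OP(=O)(O)OCC2OC(n3cnc4c(N)ncnc43)",
                                      "C(O)C2O)C(O)C1O")))
  rx <- unify_reactions(data.frame(
    id = c("r1", "r2", "r3"),
    equation = c("A + nad <=> B + nad", "B + nad <=> C + nad",
                 "C + nad <=> D + nad"),
    ec = NA, source_db = "t"), u)$reactions
  # without exclusion the shared cofactor shortcuts every pair to <= 2 steps
  lin_raw <- linearize_reference(rx, u, exclude = character(0))
  expect_equal(lin_raw$length, 2)
  # with the bundled exclusion list the full chain A-B-C-D is recovered
  lin <- linearize_reference(rx, u)
  expect_identical(lin$nodes, c("A", "B", "C", "D"))
  expect_equal(lin$length, 3)
})

test_that("benchmark filters apply the eight curation criteria", {
  u <- quick_compounds(c(A = "CCO", B = "CC=O", C = "CC(=O)O",
                         S = "OS(=O)(=O)O"))
  mk <- function(eqs, ids = paste0("x", seq_along(eqs)), ec = NA, ...) {
    list(pathway_id = "p", reactions = data.frame(
      id = ids, equation = eqs, ec = ec, stringsAsFactors = FALSE), ...)
  }
  # single reaction fails (i)
  f <- filter_benchmark(list(mk("A <=> B")))
  expect_false(f$pass)
  expect_match(f$reasons, "\\bi\\b")
  # transport reaction fails (ii)
  f2 <- filter_benchmark(list(mk(c("A <=> A", "A <=> B"))))
  expect_match(f2$reasons, "ii")
  # electron-transfer EC class fails (ii)
  f2b <- filter_benchmark(list(mk(c("A <=> B", "B <=> C"),
                                  ec = c("1.97.1.1", NA))))
  expect_match(f2b$reasons, "ii")
  # unresolvable reaction id fails (iii)
  tab <- data.frame(id = "x1")
  f3 <- filter_benchmark(list(mk(c("A <=> B", "B <=> C"))),
                         reaction_table = tab)
  expect_match(f3$reasons, "iii")
  # non-carbon compound fails (iv)
  f4 <- filter_benchmark(list(mk(c("A <=> S", "S <=> B"))), compounds = u)
  expect_match(f4$reasons, "iv")
  # circular pathway fails (v)
  f5 <- filter_benchmark(list(mk(c("A <=> B", "B <=> A"),
                                 nodes = c("A", "B", "A"))))
  expect_match(f5$reasons, "v")
  # flag-based criteria (vi)-(viii)
  f6 <- filter_benchmark(list(
    mk(c("A <=> B", "B <=> C"),
       flags = list(polymerization = TRUE, light_dependent = TRUE,
                    superpathway = TRUE))))
  expect_match(f6$reasons, "vi")
  expect_match(f6$reasons, "vii")
  expect_match(f6$reasons, "viii")
  # a clean three-step linear pathway passes
  f7 <- filter_benchmark(list(mk(c("A <=> B", "B <=> C", "C <=> A2"))),
                         compounds = NULL)
  expect_true(f7$pass)
  expect_identical(f7$reasons, "")
})

test_that("reaction reconstruction classifies exact, alternative-cofactor and multi-step cases", {
  u <- quick_compounds(c(A = "CCCO", B = "CCC=O", X = "CCCN"))
  rx <- unify_reactions(data.frame(
    id = "known1", equation = "A <=> B", ec = NA, source_db = "t"),
    u)$reactions
  # exact: the reaction itself is in the network's reaction set
  g_direct <- manual_car_graph(data.frame(s = "A", t = "B", car = 1))
  rec <- reconstruct_reaction(rx[1, ], g_direct, u,
                              network_reactions = rx)
  expect_identical(rec$class, "exact")
  # alternative route, one step: same main pair, other backing reaction
  rec2 <- reconstruct_reaction(rx[1, ], g_direct, u)
  expect_identical(rec2$class, "alternative_cofactor")
  # two steps with CARs 0.8 and 0.6: product 0.48 >= 0.34
  g2 <- manual_car_graph(data.frame(s = c("A", "X"), t = c("X", "B"),
                                    car = c(0.8, 0.6)))
  rec3 <- reconstruct_reaction(rx[1, ], g2, u)
  expect_identical(rec3$class, "multi_step")
  expect_identical(rec3$steps, 2L)
  expect_equal(rec3$pairs$car_product, 0.48)
  # CAR product 0.8 x 0.4 = 0.32 < 0.34: rejected
  g3 <- manual_car_graph(data.frame(s = c("A", "X"), t = c("X", "B"),
                                    car = c(0.8, 0.4)))
  rec4 <- reconstruct_reaction(rx[1, ], g3, u)
  expect_identical(rec4$class, "not_reconstructed")
  expect_equal(rec4$pairs$car_product, 0.32)
  # beyond max_steps: rejected even with good conservation
  g5 <- manual_car_graph(data.frame(
    s = c("A", "m1", "m2", "m3", "m4"),
    t = c("m1", "m2", "m3", "m4", "B"),
    car = rep(0.99, 5)))
  rec5 <- reconstruct_reaction(rx[1, ], g5, u, max_steps = 4)
  expect_identical(rec5$class, "not_reconstructed")
})
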