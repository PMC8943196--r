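test_that("expand generates the exhaustive application set, deduplicated", {
  u <- quick_compounds(c(eth = "CCO", ald = "CC=O", o2 = "O=O",
                         h2o2 = "OO", h2o = "O"))
  rules <- toy_rules_cached()[c("r1_alcohol_oxidase", "r8_dehydratase")]
  ex <- expand(u, rules)
  # brute-force oracle over every (rule, direction, compound, site)
  sig_set <- character(0)
  for (r in rules) {
    for (dir in list(r, reverse_rule(r))) {
      for (id in u$id) {
        mol <- attr(u, "mols")[[id]]
        for (st in match_reactive_sites(dir, mol)) {
          ap <- apply_rule(dir, mol, st)
          if (ap$status != "ok") next
          lhs <- paste(sort(rep(ap$reactants$key, ap$reactants$coef)),
                       collapse = "+")
          rhs <- paste(sort(rep(ap$products$key, ap$products$coef)),
                       collapse = "+")
          if (lhs == rhs) next
          sig_set <- union(sig_set,
                           paste(sort(c(lhs, rhs)), collapse = "||"))
        }
      }
    }
  }
  expect_equal(nrow(ex$reactions), length(sig_set))
})

test_that("reactions found by two rules are stored once with both rule ids", {
  rules <- toy_rules_cached()["r1_alcohol_oxidase"]
  clone <- rules[[1]]
  clone$rule_id <- "r1_clone"
  rules$r1_clone <- clone
  u <- quick_compounds(c(eth = "CCO", o2 = "O=O", h2o2 = "OO"))
  ex <- expand(u, rules, both_directions = FALSE)
  ox <- ex$reactions[grepl("eth", ex$reactions$equation), ]
  expect_equal(nrow(ox), 1)
  expect_identical(ox$rule_ids, "r1_alcohol_oxidase;r1_clone")
})

test_that("re-running expand on its own output adds no duplicate reactions", {
  u <- quick_compounds(c(eth = "CCO", o2 = "O=O", h2o2 = "OO", h2o = "O"))
  rules <- toy_rules_cached()["r1_alcohol_oxidase"]
  ex1 <- expand(u, rules)
  expect_gt(nrow(ex1$reactions), 0)
  # feed the augmented universe and the generated set back in
  ex2 <- expand(ex1$compounds, rules, known = ex1$reactions)
  expect_equal(nrow(ex2$reactions), 0)
  expect_true(all(ex1$reactions$id %in% names(ex2$known_matched)))
})

test_that("expand output is invariant to seed-compound input order", {
  smis <- c(eth = "CCO", ac = "CC(=O)O", o2 = "O=O", h2o2 = "OO",
            h2o = "O", meoh = "CO")
  rules <- toy_rules_cached()[c("r1_alcohol_oxidase",
                                "r3_o_methyltransferase")]
  ex1 <- expand(quick_compounds(smis), rules)
  ex2 <- expand(quick_compounds(rev(smis)), rules)
  expect_identical(as.data.frame(ex1$reactions), as.data.frame(ex2$reactions))
  expect_identical(attr(ex1$reactions, "pairs"), attr(ex2$reactions, "pairs"))
})

test_that("scope classification separates bio- and chem-scope predictions", {
  # fully biological mini-universe: ethanol oxidation products all known
  smis <- c(eth = "CCO", ald = "CC=O", o2 = "O=O", h2o2 = "OO")
  u <- quick_compounds(smis, scope = "biological")
  ex <- expand(u, toy_rules_cached()["r1_alcohol_oxidase"],
               both_directions = FALSE)
  expect_true(all(ex$reactions$scope == "bio" |
                    ex$reactions$scope == "chem"))
  ox <- ex$reactions[grepl("^ald \\+", ex$reactions$equation) |
                       grepl("eth", ex$reactions$equation), ]
  expect_true(any(ox$scope == "bio"))
  # same universe but with the aldehyde unknown: product becomes a novel
  # chemical compound and the reaction lands in the chem scope
  u2 <- quick_compounds(smis[c("eth", "o2", "h2o2")])
  ex2 <- expand(u2, toy_rules_cached()["r1_alcohol_oxidase"],
                both_directions = FALSE)
  expect_true(all(ex2$reactions$scope == "chem"))
  expect_gte(nrow(ex2$novel_compounds), 1)
  expect_true(all(ex2$novel_compounds$scope == "chemical"))
  # scopes partition the generated set
  expect_equal(sum(ex2$reactions$scope == "bio") +
                 sum(ex2$reactions$scope == "chem"), nrow(ex2$reactions))
})

test_that("all expand-generated reactions are balanced by construction", {
  ex <- toy_expansion_cached()
  expect_gt(nrow(ex$reactions), 0)
  for (i in seq_len(nrow(ex$reactions))) {
    expect_identical(check_balance(ex$reactions$equation[i], ex$compounds),
                     "balanced", info = ex$reactions$equation[i])
  }
})

test_that("orphan integration counts compounds per scope", {
  u <- bio_universe_cached()
  known <- unify_reactions(data.frame(
    id = c("k1", "k2"),
    equation = c("ethanol + dioxygen <=> acetaldehyde + hydrogen_peroxide",
                 "pyruvate <=> acetaldehyde + carbon_dioxide"),
    ec = NA, source_db = "toy"), u)$reactions
  rep0 <- orphan_integration_report(u, known)
  tot <- rep0[rep0$scope == "total", ]
  expect_equal(tot$n_in_known, 6)
  expect_equal(tot$n_orphans, nrow(u) - 6)
  ex <- expand(u, toy_rules_cached()["r6_amidase"], known,
               both_directions = FALSE)
  rep1 <- orphan_integration_report(ex$compounds, known, ex$reactions)
  tot1 <- rep1[rep1$scope == "total", ]
  # amide hydrolysis integrates the orphan acetamide (and ammonia, acetate)
  expect_gte(tot1$n_orphans_integrated, 3)
  expect_equal(tot1$fraction_orphans_integrated,
               tot1$n_orphans_integrated / tot1$n_orphans)
})
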