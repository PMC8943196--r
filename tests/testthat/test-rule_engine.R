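test_that("toy rule library loads, validates and reverses", {
  rules <- toy_rules_cached()
  expect_length(rules, 8)
  expect_setequal(vapply(rules, `[[`, "", "ec3"),
                  c("1.1.3", "1.2.3", "2.1.1", "2.6.1", "3.1.1", "3.5.1",
                    "4.1.1", "4.2.1"))
  for (r in rules) {
    expect_silent(validate_rule(r))
    expect_true(isSymmetric(unname(r$delta)))
    expect_true(all(r$delta[row(r$delta) != col(r$delta)] +
                      r$site[row(r$site) != col(r$site)] >= 0))
    rr <- reverse_rule(r)
    expect_silent(validate_rule(rr))
    # reversing twice recovers the original matrices
    rrr <- reverse_rule(rr)
    expect_identical(rrr$site, r$site)
    expect_identical(rrr$delta, r$delta)
    expect_identical(rrr$hdelta, r$hdelta)
  }
  bad <- rules[[1]]
  bad$delta[1, 2] <- -5
  bad$delta[2, 1] <- -5
  expect_error(validate_rule(bad), class = "carnet_rule_error")
})

test_that("kekule enumeration covers aromatic alternations", {
  expect_length(enumerate_kekule(admit_compound("CCO")), 1)
  expect_length(enumerate_kekule(admit_compound("c1ccccc1")), 2)
  expect_length(enumerate_kekule(admit_compound("c1ccc2ccccc2c1")), 3)
  # non-aromatic rings stay unique
  expect_length(enumerate_kekule(admit_compound("C1CCCCC1")), 1)
  # every enumerated structure preserves per-atom bond-order sums
  mol <- admit_compound("c1ccc2ccccc2c1")$mol
  base <- rowSums(mol$bond)
  for (kb in enumerate_kekule(mol)) {
    expect_identical(rowSums(kb), base)
  }
})

test_that("site matching agrees with the exhaustive oracle on fixture molecules", {
  rules <- toy_rules_cached()
  pool <- fixture_pool()
  mols <- pool$smiles[vapply(pool$smiles, function(s) {
    admit_compound(s)$heavy_atom_count <= 12
  }, TRUE)]
  n_checked <- 0
  for (r in rules) {
    for (dir in list(r, reverse_rule(r))) {
      for (smi in mols) {
        cp <- admit_compound(smi)
        got <- match_reactive_sites(dir, cp)
        want <- exhaustive_site_match(dir, cp)
        expect_identical(length(got), length(want),
                         info = sprintf("%s on %s", dir$rule_id, smi))
        got_atoms <- sort(vapply(got, function(s) {
          paste(sort(s$map), collapse = ",")
        }, ""))
        want_atoms <- sort(vapply(want, function(m) {
          paste(sort(m), collapse = ",")
        }, ""))
        expect_identical(got_atoms, want_atoms)
        n_checked <- n_checked + 1
      }
    }
  }
  expect_gt(n_checked, 100)
})

test_that("site counts match hand-derived expectations", {
  rules <- toy_rules_cached()
  ox <- rules$r1_alcohol_oxidase
  expect_length(match_reactive_sites(ox, admit_compound("CCO")), 1)
  expect_length(match_reactive_sites(ox, admit_compound("CC")), 0)
  # two distinct hydroxyl carbons: two sites, not merged by symmetry
  expect_length(match_reactive_sites(ox, admit_compound("OCCCO")), 2)
  expect_length(exhaustive_site_match(ox, admit_compound("OCCCO")), 2)
  # ethanol under {oxidation, ester hydrolysis}: oxidation only
  scr <- screen_reactivity(quick_compounds(c(eth = "CCO")),
                           rules[c("r1_alcohol_oxidase",
                                   "r5_methylester_hydrolase")])
  expect_identical(scr$by_compound$eth, "r1_alcohol_oxidase")
})

test_that("a rule written against a localized C=C matches aromatic bonds", {
  rules <- toy_rules_cached()
  hydratase <- reverse_rule(rules$r8_dehydratase) # site contains C=C
  benzene <- admit_compound("c1ccccc1")
  sites <- match_reactive_sites(hydratase, benzene)
  # every ring bond is a double bond in one kekule form: 6 edges x 2 roles
  expect_gt(length(sites), 0)
  atom_pairs <- unique(vapply(sites, function(s) {
    paste(sort(s$map[1:2]), collapse = "-")
  }, ""))
  expect_length(atom_pairs, 6)
})

test_that("rule application rewrites ethanol to acetaldehyde with its redox pair", {
  rules <- toy_rules_cached()
  eth <- admit_compound("CCO")
  site <- match_reactive_sites(rules$r1_alcohol_oxidase, eth)[[1]]
  ap <- apply_rule(rules$r1_alcohol_oxidase, eth, site)
  expect_identical(ap$status, "ok")
  expect_setequal(ap$product_keys, c(canonicalize("CC=O"),
                                     canonicalize("OO")))
  expect_setequal(ap$reactants$key, c(canonicalize("CCO"),
                                      canonicalize("O=O")))
  # atom map: all 3 substrate heavy atoms conserved into the aldehyde
  pr <- ap$pairs[ap$pairs$sub_key == canonicalize("CCO"), ]
  expect_identical(pr$n_c[pr$prod_key == canonicalize("CC=O")], 3L)
})

test_that("forward-then-reverse application recovers the substrate", {
  rules <- toy_rules_cached()
  probes <- c("CCO", "CC=O", "CC(=O)O", "CC(=O)C", "COC(=O)C", "CC(N)=O",
              "CC(O)C(=O)O", "OCCCO", "OCC(O)CO", "O=Cc1ccccc1")
  n_pairs <- 0
  for (rn in names(rules)) {
    for (r in list(rules[[rn]], reverse_rule(rules[[rn]]))) {
      rr <- reverse_rule(r)
      for (smi in probes) {
        cp <- admit_compound(smi)
        for (st in match_reactive_sites(r, cp)) {
          ap <- apply_rule(r, cp, st)
          if (ap$status != "ok") next
          n_pairs <- n_pairs + 1
          recovered <- FALSE
          for (pk in unique(ap$product_keys)) {
            pc <- admit_compound(pk)
            if (!inherits(pc, "compound")) next
            for (st2 in match_reactive_sites(rr, pc)) {
              ap2 <- apply_rule(rr, pc, st2)
              if (ap2$status == "ok" &&
                  cp$canonical_key %in% ap2$product_keys) {
                recovered <- TRUE
              }
            }
          }
          expect_true(recovered,
                      info = sprintf("%s on %s", r$rule_id, smi))
        }
      }
    }
  }
  expect_gt(n_pairs, 40)
})

test_that("every successful application yields an elementally balanced reaction", {
  rules <- toy_rules_cached()
  probes <- c("CCO", "CC(=O)O", "CC(=O)C", "COC(=O)C", "CC(N)=O", "OCCCO")
  for (r in rules) {
    for (smi in probes) {
      cp <- admit_compound(smi)
      for (st in match_reactive_sites(r, cp)) {
        ap <- apply_rule(r, cp, st)
        if (ap$status != "ok") next
        all_keys <- unique(c(ap$reactants$key, ap$products$key))
        cps <- quick_compounds(setNames(all_keys, all_keys))
        eq <- list(
          reactants = data.frame(
            id = carnet:::resolve_compound_ids(cps, ap$reactants$key),
            coef = ap$reactants$coef),
          products = data.frame(
            id = carnet:::resolve_compound_ids(cps, ap$products$key),
            coef = ap$products$coef))
        expect_identical(check_balance(eq, cps), "balanced",
                         info = sprintf("%s on %s", r$rule_id, smi))
      }
    }
  }
})

test_that("screen_reactivity reports the designed reactive fraction", {
  # forward direction: 9 of these 10 compounds carry a recognized group,
  # the plain alkane carries none
  smis <- c(eth = "CCO", ald = "CC=O", ac = "CC(=O)O", act = "CC(=O)C",
            est = "COC(=O)C", amd = "CC(N)=O", lac = "CC(O)C(=O)O",
            gly = "OCC(O)CO", mal = "OC(=O)CC(O)C(=O)O", alk = "CCCCCC")
  scr <- screen_reactivity(quick_compounds(smis), toy_rules_cached(),
                           both_directions = FALSE)
  expect_identical(scr$by_compound$alk, character(0))
  expect_equal(scr$summary$fraction_reactive, 0.9)
  # bidirectional screening can only add rules per compound
  scr2 <- screen_reactivity(quick_compounds(smis), toy_rules_cached())
  for (id in names(scr$by_compound)) {
    expect_true(all(scr$by_compound[[id]] %in% scr2$by_compound[[id]]))
  }
})
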