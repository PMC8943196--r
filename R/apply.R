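# Rule application: rewrite the molecule's bond-electron matrix with the
# rule's difference matrix at a matched site, attach co-substrate templates,
# split the result into product fragments, and emit a balanced reaction with
# a full substrate -> product atom map.

# Parse and embed the co-substrate templates of a rule. Returns a list per
# fragment label: mol, map (pattern atom index -> template atom index).
rule_templates <- function(rule) {
  labs <- setdiff(unique(rule$src_frag), "S")
  out <- list()
  for (f in labs) {
    smi <- rule$cosub[[f]]
    if (is.null(smi)) {
      stop_carnet(sprintf("rule %s: no template for fragment %s",
                          rule$rule_id, f), "carnet_rule_error")
    }
    tmol <- neutralize_mol(mol_from_smiles(smi))
    idx <- which(rule$src_frag == f)
    req <- rule$site[idx, idx, drop = FALSE]
    diag(req) <- 0
    eff_minh <- pmax(rule$min_h[idx], -rule$hdelta[idx])
    keks <- enumerate_kekule(tmol)
    emb <- NULL
    for (ki in seq_along(keks)) {
      maps <- match_fragment(rule$elem[idx], rule$chg[idx], eff_minh, req,
                             tmol, keks[[ki]], max_maps = 1)
      if (length(maps) > 0) { emb <- maps[[1]]; break }
    }
    if (is.null(emb)) {
      stop_carnet(sprintf(
        "rule %s: pattern atoms %s do not match template %s",
        rule$rule_id, paste(idx, collapse = ","), smi), "carnet_rule_error")
    }
    out[[f]] <- list(mol = tmol, map = emb, pattern_idx = idx, smiles = smi)
  }
  out
}

#' Apply a reaction rule at a matched site
#'
#' Updates the molecule's bond matrix with the rule's difference matrix at
#' the mapped atoms, adjusts hydrogen counts, appends the rule's
#' co-substrates, and splits the rewritten structure into product fragments.
#' The generated reaction is elementally balanced by construction because the
#' rewrite conserves every atom.
#'
#' @param rule a `reaction_rule`.
#' @param compound a `compound` or internal molecule (the substrate).
#' @param site one element of the list returned by
#'   [match_reactive_sites()] for this rule and compound.
#' @return a `rule_application`: list with `status` (`"ok"` or
#'   `"valence_violation"`), `products` (canonical keys), `reactants`/
#'   `products` multisets (`key`, `coef`), `pairs` (data.frame of reactant
#'   key, product key and conserved heavy atoms `n_c` from the atom map) and
#'   `atom_map` (combined-system atom index -> product fragment).
#' @export
apply_rule <- function(rule, compound, site) {
  mol <- if (inherits(compound, "compound")) compound$mol else compound
  keks <- enumerate_kekule(mol)
  kb <- keks[[site$kek]]
  work <- mol
  work$bond <- kb
  tmpl <- rule_templates(rule)
  # combined system: substrate then each co-substrate template
  frag_of <- rep("S", mol$n)
  pat2comb <- integer(length(rule$elem))
  idx_s <- which(rule$src_frag == "S")
  pat2comb[idx_s] <- site$map
  src_frags <- list(S = list(key = NULL, atoms = seq_len(mol$n)))
  for (f in names(tmpl)) {
    off <- work$n
    work <- mol_union(work, tmpl[[f]]$mol)
    frag_of <- c(frag_of, rep(f, tmpl[[f]]$mol$n))
    pat2comb[tmpl[[f]]$pattern_idx] <- off + tmpl[[f]]$map
    src_frags[[f]] <- list(key = NULL, atoms = off + seq_len(tmpl[[f]]$mol$n))
  }
  # rewrite bonds and hydrogens
  k <- length(rule$elem)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i < j && rule$delta[i, j] != 0) {
        a <- pat2comb[i]; b <- pat2comb[j]
        nb <- work$bond[a, b] + rule$delta[i, j]
        if (nb < 0) {
          return(structure(list(status = "valence_violation",
                                rule_id = rule$rule_id),
                           class = "rule_application"))
        }
        work$bond[a, b] <- nb
        work$bond[b, a] <- nb
      }
    }
    work$hyd[pat2comb[i]] <- work$hyd[pat2comb[i]] + rule$hdelta[i]
  }
  if (any(work$hyd < 0) || !mol_valence_ok(work)) {
    return(structure(list(status = "valence_violation",
                          rule_id = rule$rule_id),
                     class = "rule_application"))
  }
  # split into product fragments and canonicalize
  comps <- mol_components(work)
  prod_keys <- character(length(comps))
  prod_atoms <- vector("list", length(comps))
  for (ci in seq_along(comps)) {
    frag <- mol_subset(work, comps[[ci]])
    prod_keys[ci] <- mol_to_smiles(neutralize_mol(frag))
    prod_atoms[[ci]] <- comps[[ci]]
  }
  sub_key <- mol_to_smiles(neutralize_mol(mol))
  reac_keys <- c(S = sub_key,
                 vapply(tmpl, function(t) mol_to_smiles(t$mol), ""))
  names(reac_keys)[1] <- "S"
  # conserved heavy atoms per (reactant fragment, product fragment)
  pairs <- list()
  for (f in names(src_frags)) {
    for (ci in seq_along(comps)) {
      nc <- length(intersect(src_frags[[f]]$atoms, prod_atoms[[ci]]))
      if (nc > 0) {
        pairs[[length(pairs) + 1]] <- data.frame(
          sub_key = reac_keys[[f]], prod_key = prod_keys[ci],
          n_c = nc, n_r = length(src_frags[[f]]$atoms),
          n_p = length(prod_atoms[[ci]]), stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- do.call(rbind, pairs)
  multiset <- function(keys) {
    agg <- tapply(rep(1L, length(keys)), keys, sum)
    data.frame(key = names(agg), coef = as.integer(agg),
               stringsAsFactors = FALSE)
  }
  structure(list(
    status = "ok",
    rule_id = rule$rule_id,
    substrate_key = sub_key,
    reactants = multiset(unname(reac_keys)),
    products = multiset(prod_keys),
    product_keys = prod_keys,
    pairs = pairs,
    atom_map = setNames(rep(seq_along(comps), lengths(prod_atoms))[
      order(unlist(prod_atoms))], NULL),
    frag_of = frag_of
  ), class = "rule_application")
}

#' @export
print.rule_application <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("<rule_application %s: %s>\n", x$rule_id, x$status))
  } else {
    cat(sprintf("<rule_application %s: %s => %s>\n", x$rule_id,
                paste(x$reactants$key, collapse = " + "),
                paste(x$products$key, collapse = " + ")))
  }
  invisible(x)
}

#' Screen a compound set for reactivity under a rule library
#'
#' Each compound is assigned the sorted list of rule identifiers that
#' recognize at least one reactive site on it, screening both the forward
#' and the reverse orientation of every (bidirectional) rule.
#'
#' @param compounds a `compound_set`.
#' @param rules named list of `reaction_rule`s.
#' @param both_directions also screen reversed rules (default `TRUE`).
#' @return list with `by_compound` (named list of character vectors of rule
#'   ids) and `summary` (data.frame with the fraction of compounds having at
#'   least one rule).
#' @export
screen_reactivity <- function(compounds, rules, both_directions = TRUE) {
  mols <- attr(compounds, "mols")
  all_rules <- rules
  if (both_directions) {
    all_rules <- c(rules, lapply(rules, reverse_rule))
  }
  by_compound <- lapply(compounds$id, function(id) {
    hits <- character(0)
    for (r in all_rules) {
      if (length(match_reactive_sites(r, mols[[id]])) > 0) {
        hits <- c(hits, r$rule_id)
      }
    }
    lex_sort(unique(sub("_rev$", "", hits)))
  })
  names(by_compound) <- compounds$id
  frac <- if (nrow(compounds) > 0) {
    mean(lengths(by_compound) > 0)
  } else {
    NA_real_
  }
  list(by_compound = by_compound,
       summary = data.frame(n_compounds = nrow(compounds),
                            n_reactive = sum(lengths(by_compound) > 0),
                            fraction_reactive = frac))
}
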