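# Network expansion: apply a rule library to a compound universe,
# deduplicate the generated reactions against the known set, and classify
# them into the bio-scope (all participants biological/bioactive) or the
# chem-scope (at least one chemical or previously unseen participant).

#' Expand a compound universe with a rule library
#'
#' Attempts every (rule, compound, site) application once, in both rule
#' directions. Generated reactions are deduplicated by the
#' direction-insensitive reaction identity against both the known reaction
#' set and previously generated reactions; on a collision only the rule
#' identifier is appended. Product structures never seen before are admitted
#' as new chemical-scope compounds with deterministic hash-derived ids.
#'
#' @param compounds seed `compound_set` (unified).
#' @param rules named list of `reaction_rule`s.
#' @param known optional known `reaction_set` over `compounds`.
#' @param both_directions apply the reverse of every rule too
#'   (default `TRUE`).
#' @return list with `reactions` (generated `reaction_set`, one row per
#'   unique new reaction, with a `scope` column `bio`/`chem` and the
#'   aggregated `rule_ids`; substrate-product conserved-atom counts from the
#'   rule atom maps attached as attribute `"pairs"`), `compounds` (seed set
#'   augmented with novel products), `novel_compounds`, `known_matched`
#'   (signature -> rule ids for generated reactions already present in the
#'   known set), `failures`, and `summary`.
#' @export
expand <- function(compounds, rules, known = NULL, both_directions = TRUE) {
  mols <- attr(compounds, "mols")
  id_of <- setNames(compounds$id, compounds$smiles)
  scope_of <- setNames(compounds$scope, compounds$id)

  known_sigs <- character(0)
  if (!is.null(known) && nrow(known) > 0) {
    known_sigs <- vapply(known$equation, function(eq) {
      s <- reaction_signature(parse_equation(eq), compounds)
      if (s$resolved) s$signature else NA_character_
    }, "")
    names(known_sigs) <- known$id
  }

  all_rules <- rules
  if (both_directions) all_rules <- c(all_rules, lapply(rules, reverse_rule))

  apps <- list()
  failures <- list()
  tally <- setNames(integer(length(all_rules)),
                    vapply(all_rules, `[[`, "", "rule_id"))
  for (cid in lex_sort(compounds$id)) {
    mol <- mols[[cid]]
    for (r in all_rules) {
      sites <- match_reactive_sites(r, mol)
      for (st in sites) {
        ap <- tryCatch(apply_rule(r, mol, st), error = function(e) e)
        if (inherits(ap, "condition")) {
          failures[[length(failures) + 1]] <-
            list(rule = r$rule_id, compound = cid,
                 reason = conditionMessage(ap))
          next
        }
        if (ap$status != "ok") {
          failures[[length(failures) + 1]] <-
            list(rule = r$rule_id, compound = cid, reason = ap$status)
          next
        }
        tally[r$rule_id] <- tally[r$rule_id] + 1L
        apps[[length(apps) + 1]] <- ap
      }
    }
  }

  # admit novel product structures as chemical-scope compounds
  seen_keys <- names(id_of)
  novel_keys <- lex_sort(unique(unlist(lapply(apps, function(a) {
    setdiff(c(a$reactants$key, a$products$key), seen_keys)
  }))))
  novel_rows <- list()
  used_ids <- compounds$id
  for (k in novel_keys) {
    nid <- paste0("N", fnv1a32(k))
    while (nid %in% used_ids) nid <- paste0("N", fnv1a32(paste0(nid, k)))
    used_ids <- c(used_ids, nid)
    cp <- admit_compound(k, scope = "chemical", id = nid)
    if (inherits(cp, "compound_rejection")) next
    novel_rows[[nid]] <- cp
  }
  novel <- if (length(novel_rows) > 0) {
    df <- do.call(rbind, lapply(novel_rows, function(cp) {
      data.frame(id = cp$id, smiles = cp$canonical_key, scope = cp$scope,
                 formula = mol_formula(cp$mol),
                 heavy_atoms = cp$heavy_atom_count,
                 mw = cp$molecular_weight, xrefs = "",
                 stringsAsFactors = FALSE)
    }))
    rownames(df) <- NULL
    structure(df, mols = lapply(novel_rows, `[[`, "mol"),
              class = c("compound_set", "data.frame"))
  } else {
    empty_compound_set()
  }
  aug <- rbind(as.data.frame(compounds), as.data.frame(novel))
  attr(aug, "mols") <- c(attr(compounds, "mols"), attr(novel, "mols"))
  class(aug) <- c("compound_set", "data.frame")
  id_of <- setNames(aug$id, aug$smiles)
  scope_of <- setNames(aug$scope, aug$id)

  # deduplicate generated reactions by identity signature
  gen <- list()        # signature -> record
  known_matched <- list()
  for (ap in apps) {
    to_side <- function(ms) {
      data.frame(id = unname(id_of[ms$key]), coef = ms$coef,
                 stringsAsFactors = FALSE)
    }
    sides <- list(reactants = to_side(ap$reactants),
                  products = to_side(ap$products))
    if (anyNA(sides$reactants$id) || anyNA(sides$products$id)) next
    s <- reaction_signature(sides, aug)
    if (!s$resolved || s$degenerate) next
    rid_rule <- sub("_rev$", "", ap$rule_id)
    if (s$signature %in% known_sigs) {
      kid <- names(known_sigs)[match(s$signature, known_sigs)]
      known_matched[[kid]] <- lex_sort(unique(c(known_matched[[kid]],
                                                rid_rule)))
      next
    }
    eq <- if (s$flip) {
      format_equation(list(reactants = sides$products,
                           products = sides$reactants))
    } else {
      format_equation(sides)
    }
    pr <- ap$pairs
    pr$sub_id <- unname(id_of[pr$sub_key])
    pr$prod_id <- unname(id_of[pr$prod_key])
    if (is.null(gen[[s$signature]])) {
      gen[[s$signature]] <- list(equation = eq, rule_ids = rid_rule,
                                 pairs = pr)
    } else {
      gen[[s$signature]]$rule_ids <-
        lex_sort(unique(c(gen[[s$signature]]$rule_ids, rid_rule)))
      # keep the pair table with the best (maximal) conservation per pair
      old <- gen[[s$signature]]$pairs
      comb <- rbind(old, pr)
      keysp <- paste(comb$sub_id, comb$prod_id)
      best <- tapply(seq_len(nrow(comb)), keysp,
                     function(ix) ix[which.max(comb$n_c[ix])])
      gen[[s$signature]]$pairs <- comb[unlist(best), , drop = FALSE]
    }
  }

  sigs <- names(gen)
  rows <- lapply(sigs, function(s) {
    g <- gen[[s]]
    part <- c(parse_equation(g$equation)$reactants$id,
              parse_equation(g$equation)$products$id)
    scope <- if (all(scope_of[part] %in% c("biological", "bioactive"))) {
      "bio"
    } else {
      "chem"
    }
    data.frame(id = paste0("P", fnv1a32(s)), equation = g$equation,
               ec = NA_character_, sources = "",
               rule_ids = paste(g$rule_ids, collapse = ";"),
               provenance = "predicted", balance = "balanced",
               scope = scope, stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0) {
    df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    df[order(df$id, method = "radix"), , drop = FALSE]
  } else {
    cbind(empty_reaction_set(), data.frame(scope = character()))
  }
  rownames(out) <- NULL
  pair_tab <- do.call(rbind, lapply(sigs, function(s) {
    cbind(reaction_id = paste0("P", fnv1a32(s)), gen[[s]]$pairs)
  }))
  if (!is.null(pair_tab)) {
    pair_tab <- pair_tab[order(pair_tab$reaction_id, pair_tab$sub_id,
                               pair_tab$prod_id, method = "radix"), ,
                         drop = FALSE]
    rownames(pair_tab) <- NULL
  }
  attr(out, "pairs") <- pair_tab
  class(out) <- c("reaction_set", "data.frame")
  list(reactions = out,
       compounds = aug,
       novel_compounds = novel,
       known_matched = known_matched,
       failures = failures,
       summary = list(
         n_applications = length(apps),
         n_failures = length(failures),
         n_generated = nrow(out),
         n_bio_scope = sum(out$scope == "bio"),
         n_chem_scope = sum(out$scope == "chem"),
         n_novel_compounds = nrow(novel),
         n_matched_known = length(known_matched),
         per_rule = as.list(tally)))
}

reaction_participants <- function(reactions) {
  lapply(reactions$equation, function(eq) {
    s <- parse_equation(eq)
    unique(c(s$reactants$id, s$products$id))
  })
}

#' Orphan-compound integration report
#'
#' An orphan compound participates in no known reaction. The report counts,
#' per scope, how many compounds participate in at least one reaction of
#' each supplied reaction set, and how many orphans the predicted reactions
#' integrate.
#'
#' @param compounds a `compound_set`.
#' @param known known `reaction_set` (may be empty).
#' @param predicted predicted `reaction_set` (may be `NULL`).
#' @return data.frame with one row per scope plus a `total` row.
#' @export
orphan_integration_report <- function(compounds, known, predicted = NULL) {
  in_known <- unique(unlist(reaction_participants(known)))
  in_pred <- if (!is.null(predicted)) {
    unique(unlist(reaction_participants(predicted)))
  } else {
    character(0)
  }
  one <- function(ids) {
    orphan <- setdiff(ids, in_known)
    integrated <- intersect(orphan, in_pred)
    data.frame(n_compounds = length(ids),
               n_in_known = sum(ids %in% in_known),
               n_orphans = length(orphan),
               n_orphans_integrated = length(integrated),
               fraction_orphans_integrated =
                 if (length(orphan) > 0) {
                   length(integrated) / length(orphan)
                 } else {
                   NA_real_
                 })
  }
  scopes <- split(compounds$id, compounds$scope)
  out <- do.call(rbind, lapply(scopes, one))
  out <- rbind(out, total = one(compounds$id))
  cbind(scope = rownames(out), out, row.names = NULL)
}
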