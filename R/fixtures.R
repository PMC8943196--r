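# Deterministic toy fixtures: a hand-curated pool of small metabolite-like
# and xenobiotic-like structures, the bundled rule library, and a seeded
# toy compound universe with known reactions and a ground-truth manifest.

#' The curated fixture molecule pool
#'
#' About forty named structures of at most 14 heavy atoms, split into a
#' biological/metabolite-like pool, a chemical/xenobiotic-like pool, and the
#' co-substrate core used by the toy rule library (water, dioxygen,
#' hydrogen peroxide, ammonia, methanol, 2-aminopropanoate, pyruvate,
#' carbon dioxide).
#'
#' @return data.frame with columns `name`, `smiles`, `pool`
#'   (`core`/`bio`/`chem`).
#' @export
fixture_pool <- function() {
  core <- c(
    water = "O", dioxygen = "O=O", hydrogen_peroxide = "OO",
    ammonia = "N", methanol = "CO", alanine = "CC(N)C(=O)O",
    pyruvate = "CC(=O)C(=O)O", carbon_dioxide = "O=C=O")
  bio <- c(
    ethanol = "CCO", acetaldehyde = "CC=O", acetate = "CC(=O)O",
    lactate = "CC(O)C(=O)O", glycerol = "OCC(O)CO",
    glyceraldehyde = "OCC(O)C=O", dihydroxyacetone = "OCC(=O)CO",
    glycine = "NCC(=O)O", serine = "OCC(N)C(=O)O",
    succinate = "OC(=O)CCC(=O)O", fumarate = "OC(=O)C=CC(=O)O",
    malate = "OC(=O)CC(O)C(=O)O", oxaloacetate = "OC(=O)CC(=O)C(=O)O",
    citrate = "OC(=O)CC(O)(CC(=O)O)C(=O)O",
    oxoglutarate = "O=C(CCC(=O)O)C(=O)O",
    glutamate = "NC(CCC(=O)O)C(=O)O", aspartate = "NC(CC(=O)O)C(=O)O",
    propanol = "CCCO", propanal = "CCC=O", propanoate = "CCC(=O)O",
    propanediol = "OCCCO", ethylene_glycol = "OCCO",
    glycolaldehyde = "OCC=O", glycolate = "OCC(=O)O",
    glyoxylate = "O=CC(=O)O", acetone = "CC(=O)C", isopropanol = "CC(O)C",
    acetamide = "CC(N)=O", methyl_acetate = "COC(=O)C",
    benzoate = "OC(=O)c1ccccc1", benzaldehyde = "O=Cc1ccccc1",
    benzyl_alcohol = "OCc1ccccc1", phenylalanine = "NC(Cc1ccccc1)C(=O)O",
    ethanolamine = "NCCO", urea = "NC(N)=O", formaldehyde = "C=O")
  chem <- c(
    ethane = "CC", hexane = "CCCCCC", cyclohexane = "C1CCCCC1",
    cyclohexanol = "OC1CCCCC1", cyclohexanone = "O=C1CCCCC1",
    toluene = "Cc1ccccc1", phenol = "Oc1ccccc1", styrene = "C=Cc1ccccc1",
    anisole = "COc1ccccc1", naphthalene = "c1ccc2ccccc2c1",
    chlorobenzene = "Clc1ccccc1", aniline = "Nc1ccccc1",
    benzamide = "NC(=O)c1ccccc1", methyl_benzoate = "COC(=O)c1ccccc1",
    catechol = "Oc1ccccc1O", propene = "CC=C")
  data.frame(
    name = c(names(core), names(bio), names(chem)),
    smiles = c(unname(core), unname(bio), unname(chem)),
    pool = rep(c("core", "bio", "chem"),
               c(length(core), length(bio), length(chem))),
    stringsAsFactors = FALSE)
}

#' Load the bundled toy rule library
#'
#' Eight hand-verified bidirectional rules spanning EC classes 1-4
#' (alcohol and aldehyde oxidation, O-methylation, transamination, methyl
#' ester and amide hydrolysis, decarboxylation, dehydration).
#'
#' @return named list of `reaction_rule`s.
#' @export
make_toy_rules <- function() {
  read_rules(system.file("extdata", "toy_rules.txt", package = "carnet"))
}

# known-reaction templates over fixture names; included in a universe when
# every participant is present
toy_known_templates <- function() {
  list(
    list(id = "K_adh", ec = "1.1.3.13",
         eq = c("ethanol", "dioxygen"), pr = c("acetaldehyde",
                                               "hydrogen_peroxide")),
    list(id = "K_aldox", ec = "1.2.3.1",
         eq = c("acetaldehyde", "hydrogen_peroxide"),
         pr = c("acetate", "water")),
    list(id = "K_fumarase", ec = "4.2.1.2",
         eq = c("malate"), pr = c("fumarate", "water")),
    list(id = "K_pdc", ec = "4.1.1.1",
         eq = c("pyruvate"), pr = c("acetaldehyde", "carbon_dioxide")),
    list(id = "K_transam", ec = "2.6.1.44",
         eq = c("glyoxylate", "alanine"), pr = c("glycine", "pyruvate")),
    list(id = "K_esterase", ec = "3.1.1.1",
         eq = c("methyl_acetate", "water"), pr = c("acetate", "methanol")),
    list(id = "K_amidase", ec = "3.5.1.4",
         eq = c("acetamide", "water"), pr = c("acetate", "ammonia")),
    list(id = "K_benzdh", ec = "1.1.3.7",
         eq = c("benzyl_alcohol", "dioxygen"),
         pr = c("benzaldehyde", "hydrogen_peroxide")))
}

#' Build a deterministic toy compound universe
#'
#' Selects a seeded pseudo-random universe from the curated fixture pool.
#' The biological selection always starts with the co-substrate core (the
#' currency metabolites every metabolic database carries), topped up from
#' the metabolite pool; the chemical selection is drawn from the
#' xenobiotic pool. Known reactions are the curated templates whose
#' participants are all selected. The manifest records the universe
#' composition and, when requested, ground-truth counts (reactive-compound
#' fraction, expansion and scope counts, component structure after the
#' 0.34 cutoff).
#'
#' @param n_bio number of biological compounds (>= 1; values above the
#'   core size add sampled metabolites).
#' @param n_chem number of chemical compounds (>= 1).
#' @param seed RNG seed (default 7); identical seeds give identical
#'   universes.
#' @param with_manifest also run screening/expansion/network analysis to
#'   record ground-truth counts (default `TRUE`).
#' @return list with `compounds` (a `compound_set`), `known`
#'   (`reaction_set`), `records` (the raw compound records), and
#'   `manifest`.
#' @export
make_toy_universe <- function(n_bio = 10, n_chem = 5, seed = 7,
                              with_manifest = TRUE) {
  stopifnot(n_bio >= 1, n_chem >= 1)
  pool <- fixture_pool()
  core <- pool[pool$pool == "core", ]
  bio <- pool[pool$pool == "bio", ]
  chem <- pool[pool$pool == "chem", ]
  set.seed(seed)
  sel_bio <- core[seq_len(min(n_bio, nrow(core))), ]
  extra <- min(n_bio - nrow(sel_bio), nrow(bio))
  if (extra > 0) {
    sel_bio <- rbind(sel_bio, bio[sample(nrow(bio), extra), ])
  }
  sel_chem <- chem[sample(nrow(chem), min(n_chem, nrow(chem))), ]
  records <- data.frame(
    source_db = "toy",
    source_id = c(sel_bio$name, sel_chem$name),
    id = c(sel_bio$name, sel_chem$name),
    structure = c(sel_bio$smiles, sel_chem$smiles),
    scope = rep(c("biological", "chemical"),
                c(nrow(sel_bio), nrow(sel_chem))),
    stringsAsFactors = FALSE)
  uni <- unify_compounds(records)
  compounds <- uni$compounds
  have <- compounds$id
  templ <- toy_known_templates()
  krows <- list()
  for (tp in templ) {
    if (all(c(tp$eq, tp$pr) %in% have)) {
      krows[[tp$id]] <- data.frame(
        id = tp$id,
        equation = paste(paste(tp$eq, collapse = " + "), "<=>",
                         paste(tp$pr, collapse = " + ")),
        ec = tp$ec, source_db = "toy", stringsAsFactors = FALSE)
    }
  }
  known <- if (length(krows) > 0) {
    unify_reactions(do.call(rbind, krows), compounds)$reactions
  } else {
    empty_reaction_set()
  }
  manifest <- list(seed = seed, n_bio = n_bio, n_chem = n_chem,
                   compounds = setNames(compounds$smiles, compounds$id),
                   n_known_reactions = nrow(known))
  if (with_manifest) {
    rules <- make_toy_rules()
    scr <- screen_reactivity(compounds, rules)
    ex <- expand(compounds, rules, known)
    net <- build_network(ex$reactions, ex$compounds,
                         cofactors = load_cofactor_pairs())
    cut <- apply_cutoff(net, 0.34)
    st <- network_stats(cut)
    manifest$fraction_reactive <- scr$summary$fraction_reactive
    manifest$rules_by_compound <- scr$by_compound
    manifest$expansion <- ex$summary
    manifest$components_after_cutoff <- st$components
    manifest$diameter_after_cutoff <- st$diameter
  }
  list(compounds = compounds, known = known, records = records,
       manifest = manifest)
}

#' Write a universe manifest as JSON
#'
#' @param universe result of [make_toy_universe()].
#' @param path output JSON file.
#' @export
write_manifest <- function(universe, path) {
  jsonlite::write_json(universe$manifest, path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
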