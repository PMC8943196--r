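# Shared fixtures, lazily computed and cached for the whole test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

toy_rules_cached <- function() cached("rules", make_toy_rules())

cofactors_cached <- function() cached("cofactors", load_cofactor_pairs())

# default toy universe (manifest off: tests compute their own ground truth)
toy_universe_cached <- function() {
  cached("universe", make_toy_universe(10, 5, seed = 7,
                                       with_manifest = FALSE))
}

toy_expansion_cached <- function() {
  cached("expansion", {
    u <- toy_universe_cached()
    expand(u$compounds, toy_rules_cached(), u$known)
  })
}

# a compact, fully biological universe in which the rule library is active
bio_universe_cached <- function() {
  cached("bio_universe", {
    nm <- c("water", "dioxygen", "hydrogen_peroxide", "ammonia", "methanol",
            "alanine", "pyruvate", "carbon_dioxide", "ethanol",
            "acetaldehyde", "acetate", "glycine", "glyoxylate",
            "methyl_acetate", "acetamide", "propanediol")
    pool <- fixture_pool()
    sel <- pool[match(nm, pool$name), ]
    recs <- data.frame(source_db = "toy", source_id = sel$name,
                       id = sel$name, structure = sel$smiles,
                       scope = "biological", stringsAsFactors = FALSE)
    unify_compounds(recs)$compounds
  })
}

# unify a named character vector of SMILES into a compound_set
quick_compounds <- function(smiles, scope = "biological") {
  recs <- data.frame(source_db = "t", source_id = names(smiles),
                     id = names(smiles), structure = unname(smiles),
                     scope = scope, stringsAsFactors = FALSE)
  unify_compounds(recs)$compounds
}

# build a weighted CAR graph directly from an edge table (s, t, car)
manual_car_graph <- function(edges) {
  nodes <- sort(unique(c(edges$s, edges$t)))
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  igraph::V(g)$name <- nodes
  g <- igraph::add_edges(g, rbind(match(edges$s, nodes),
                                  match(edges$t, nodes)))
  igraph::E(g)$car <- edges$car
  igraph::E(g)$distance <- 1 / edges$car
  igraph::E(g)$weight <- 1 / edges$car
  igraph::E(g)$car_source <- "fixture"
  igraph::E(g)$reaction_ids <- edges$rid %||% paste0("RX", seq_len(nrow(edges)))
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random connected-ish weighted graph for search/stats tests
random_weighted_graph <- function(n, p, seed, weighted = TRUE) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  if (weighted && igraph::ecount(g) > 0) {
    igraph::E(g)$weight <- round(stats::runif(igraph::ecount(g), 0.5, 3), 3)
  }
  g
}

# independent composition oracle: element counts parsed from the OpenBabel
# InChI formula layer (not from the package's own composition code)
inchi_composition <- function(smiles) {
  out <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", "INCHI", paste0(smiles, "\n")))
  line <- grep("^InChI=", strsplit(out, "\n")[[1]], value = TRUE)[1]
  formula <- strsplit(line, "/", fixed = TRUE)[[1]][2]
  parts <- regmatches(formula,
                      gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  counts <- list()
  for (p in parts) {
    el <- gsub("[0-9]", "", p)
    nn <- gsub("[^0-9]", "", p)
    counts[[el]] <- (counts[[el]] %||% 0L) + if (nzchar(nn)) {
      as.integer(nn)
    } else {
      1L
    }
  }
  counts
}

# non-canonical SMILES written after a random atom permutation of the
# molecule; feeding it back through canonicalize() must recover one key
permuted_smiles <- function(smiles, seed) {
  m <- carnet:::mol_from_smiles(smiles)
  set.seed(seed)
  perm <- sample(m$n)
  out <- suppressWarnings(ChemmineOB::convertFormat(
    "SDF", "SMI", carnet:::write_molblock(carnet:::mol_subset(m, perm))))
  trimws(sub("\t.*$", "", strsplit(out, "\n")[[1]][1]))
}
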