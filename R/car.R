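# Conserved atom ratio (CAR) between substrate-product pairs.
#
# For a pair with n_c conserved heavy atoms, n_r reactant heavy atoms and
# n_p product heavy atoms:
#
#   CAR_r = n_c / n_r,  CAR_p = n_c / n_p,  CAR = (CAR_r + CAR_p) / 2
#   distance = 1 / CAR
#
# Hydrogen atoms are always excluded. When no reaction-mechanism atom map is
# available, n_c is estimated through a fallback cascade: a configurable
# cofactor-pair table (standard cofactor pairs conserve all atoms of the
# smaller partner), a maximum-common-substructure search, the element-wise
# minimum of the two molecular formulas, and finally zero.

#' Load a cofactor-pair table
#'
#' The table is a TSV with columns `name_a`, `smiles_a`, `name_b`,
#' `smiles_b`; each row declares a substrate-product pair whose atom
#' conservation is taken as complete (all heavy atoms of the smaller
#' partner). The bundled default covers the classic redox and phosphate
#' carriers (NAD(P)+/NAD(P)H, ATP/ADP/AMP, CoA pairs, ...).
#'
#' @param path TSV path; default is the bundled table.
#' @return data.frame with canonical keys and the pair's conserved-atom
#'   count, keyed for lookup by [conserved_atoms()].
#' @export
load_cofactor_pairs <- function(path = system.file("extdata",
                                                   "cofactor_pairs.tsv",
                                                   package = "carnet")) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    ma <- neutralize_mol(mol_from_smiles(df$smiles_a[i]))
    mb <- neutralize_mol(mol_from_smiles(df$smiles_b[i]))
    ka <- mol_to_smiles(ma); kb <- mol_to_smiles(mb)
    data.frame(name_a = df$name_a[i], name_b = df$name_b[i],
               key_a = ka, key_b = kb,
               n_a = ma$n, n_b = mb$n, n_c = min(ma$n, mb$n),
               pair_key = paste(lex_sort(c(ka, kb)), collapse = "||"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Maximum common substructure size (heavy atoms)
#'
#' Size of the largest common induced subgraph of two heavy-atom molecular
#' graphs with matching elements (bond orders are not compared, so e.g. an
#' oxidized and a reduced form of the same skeleton share all atoms).
#' Computed as a maximum clique of the modular product graph, with fast
#' paths for isomorphic molecules and full-subgraph containment.
#'
#' @param a,b internal molecule objects or `compound`s.
#' @param max_product_vertices safety cap on the modular product graph;
#'   `NA` is returned when exceeded (callers fall back to a formula bound).
#' @return integer count of common heavy atoms, or `NA`.
#' @export
mcs_heavy_atoms <- function(a, b, max_product_vertices = 2000) {
  if (inherits(a, "compound")) a <- a$mol
  if (inherits(b, "compound")) b <- b$mol
  gi <- function(m) {
    g <- igraph::graph_from_adjacency_matrix(m$bond > 0, mode = "undirected")
    igraph::V(g)$color <- match(m$elem, unique(c(a$elem, b$elem)))
    g
  }
  ga <- gi(a); gb <- gi(b)
  if (a$n == b$n &&
      identical(sort(a$elem), sort(b$elem)) &&
      igraph::isomorphic(ga, gb, method = "vf2",
                         vertex.color1 = igraph::V(ga)$color,
                         vertex.color2 = igraph::V(gb)$color)) {
    return(a$n)
  }
  small <- if (a$n <= b$n) a else b
  large <- if (a$n <= b$n) b else a
  gs <- gi(small); gl <- gi(large)
  if (igraph::subgraph_isomorphic(gs, gl, method = "vf2",
                                  vertex.color1 = igraph::V(gl)$color,
                                  vertex.color2 = igraph::V(gs)$color)) {
    return(small$n)
  }
  # modular product: vertices are element-compatible atom pairs, edges join
  # pairs that agree on adjacency; a maximum clique is a maximum common
  # induced subgraph
  pairs <- which(outer(small$elem, large$elem, "=="), arr.ind = TRUE)
  np <- nrow(pairs)
  if (np == 0) return(0L)
  if (np > max_product_vertices) return(NA_integer_)
  adj <- matrix(FALSE, np, np)
  for (u in seq_len(np - 1)) {
    i <- pairs[u, 1]; j <- pairs[u, 2]
    for (v in (u + 1):np) {
      k <- pairs[v, 1]; l <- pairs[v, 2]
      if (i != k && j != l &&
          (small$bond[i, k] > 0) == (large$bond[j, l] > 0)) {
        adj[u, v] <- TRUE
      }
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj | t(adj), mode = "undirected")
  as.integer(igraph::clique_num(g))
}

#' Conserved heavy atoms between a substrate and a product
#'
#' Resolves n_c through the fallback cascade: (1) a reaction-mechanism atom
#' map when supplied, (2) the cofactor-pair table, (3) maximum common
#' substructure (molecules up to `mcs_max_atoms` heavy atoms), (4) the
#' element-wise minimum of the two compositions, (5) zero when the molecules
#' share no element.
#'
#' @param a,b internal molecules or `compound`s.
#' @param atom_map_nc conserved-atom count from a rule atom map, if known.
#' @param cofactors cofactor table from [load_cofactor_pairs()], or `NULL`
#'   to skip stage 2.
#' @param mcs_max_atoms per-molecule size ceiling for the MCS stage.
#' @return list with `n_c` and `car_source` (one of `rule_atom_map`,
#'   `cofactor_table`, `mcs`, `formula_bound`, `zero`).
#' @export
conserved_atoms <- function(a, b, atom_map_nc = NULL, cofactors = NULL,
                            mcs_max_atoms = 60) {
  if (inherits(a, "compound")) a <- a$mol
  if (inherits(b, "compound")) b <- b$mol
  if (!is.null(atom_map_nc) && !is.na(atom_map_nc)) {
    return(list(n_c = as.integer(atom_map_nc), car_source = "rule_atom_map"))
  }
  if (!is.null(cofactors) && nrow(cofactors) > 0) {
    ka <- mol_to_smiles(a); kb <- mol_to_smiles(b)
    pk <- paste(lex_sort(c(ka, kb)), collapse = "||")
    hit <- match(pk, cofactors$pair_key)
    if (!is.na(hit) && ka != kb) {
      return(list(n_c = cofactors$n_c[hit], car_source = "cofactor_table"))
    }
  }
  if (a$n <= mcs_max_atoms && b$n <= mcs_max_atoms) {
    nc <- mcs_heavy_atoms(a, b)
    if (!is.na(nc)) {
      return(list(n_c = nc,
                  car_source = if (nc > 0) "mcs" else "zero"))
    }
  }
  ca <- mol_composition(a); cb <- mol_composition(b)
  els <- setdiff(intersect(names(ca), names(cb)), "H")
  nc <- sum(vapply(els, function(e) min(ca[[e]], cb[[e]]), 0L))
  list(n_c = as.integer(nc),
       car_source = if (nc > 0) "formula_bound" else "zero")
}

#' Conserved atom ratio of a reactant pair
#'
#' @param n_c conserved heavy atoms.
#' @param n_r,n_p heavy-atom counts of reactant and product.
#' @param car_source provenance tag from [conserved_atoms()].
#' @param correction optional correction-factor hook
#'   `function(car_r, car_p, n_c, n_r, n_p)` multiplying the mean ratio;
#'   the default multiplier is 1.
#' @return a `reactant_pair` list: `n_c`, `n_r`, `n_p`, `car_r`, `car_p`,
#'   `car`, `distance` (`1/car`, `Inf` when `car` is 0), `car_source`.
#' @export
compute_car <- function(n_c, n_r, n_p, car_source = NA_character_,
                        correction = NULL) {
  stopifnot(n_r >= 1, n_p >= 1, n_c >= 0, n_c <= min(n_r, n_p))
  car_r <- n_c / n_r
  car_p <- n_c / n_p
  car <- (car_r + car_p) / 2
  if (!is.null(correction)) {
    car <- car * correction(car_r, car_p, n_c, n_r, n_p)
  }
  car <- min(max(car, 0), 1)
  structure(list(n_c = n_c, n_r = n_r, n_p = n_p,
                 car_r = car_r, car_p = car_p, car = car,
                 distance = if (car > 0) 1 / car else Inf,
                 car_source = car_source),
            class = "reactant_pair")
}

#' @export
print.reactant_pair <- function(x, ...) {
  cat(sprintf(
    "<reactant_pair: n_c %d / (%d, %d), CAR %.3f, distance %.3f [%s]>\n",
    x$n_c, x$n_r, x$n_p, x$car, x$distance, x$car_source))
  invisible(x)
}
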