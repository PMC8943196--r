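# Pathway search in the CAR-weighted network: Yen's k-shortest loopless
# path algorithm with fully deterministic tie-breaking (equal-length paths
# are ordered by their lexicographic node sequence), plus the benchmarking
# harness (reference-pathway linearization, native-rank search, pathway
# filters) and multi-step reconstruction of known reactions.

edge_weights <- function(graph) {
  if ("weight" %in% igraph::edge_attr_names(graph)) {
    igraph::E(graph)$weight
  } else if ("distance" %in% igraph::edge_attr_names(graph)) {
    igraph::E(graph)$distance
  } else {
    rep(1, igraph::ecount(graph))
  }
}

# Lexicographically smallest shortest path source -> target, by walking the
# distance-to-target field and always picking the smallest admissible
# neighbour name. Returns NULL when disconnected.
lex_shortest_path <- function(graph, source, target, tol = 1e-9) {
  w <- edge_weights(graph)
  dt <- igraph::distances(graph, v = target, weights = w)[1, ]
  names(dt) <- igraph::V(graph)$name
  if (!is.finite(dt[source])) return(NULL)
  path <- source
  total <- 0
  cur <- source
  while (cur != target) {
    nb <- igraph::neighbors(graph, cur)
    nbn <- nb$name
    eids <- igraph::get_edge_ids(graph, rbind(rep(cur, length(nbn)), nbn))
    ok <- which(abs(w[eids] + dt[nbn] - dt[cur]) <= tol)
    if (length(ok) == 0) return(NULL)
    pick <- ok[order(nbn[ok], method = "radix")[1]]
    total <- total + w[eids[pick]]
    cur <- nbn[pick]
    path <- c(path, cur)
  }
  list(nodes = path, distance = unname(dt[source]))
}

path_edge_data <- function(graph, nodes) {
  eids <- igraph::get_edge_ids(graph,
                               rbind(nodes[-length(nodes)], nodes[-1]))
  cars <- if ("car" %in% igraph::edge_attr_names(graph)) {
    igraph::E(graph)$car[eids]
  } else {
    rep(NA_real_, length(eids))
  }
  w <- edge_weights(graph)[eids]
  list(cars = cars, distances = w)
}

new_pathway <- function(graph, nodes, rank = NA_integer_) {
  ed <- path_edge_data(graph, nodes)
  structure(list(nodes = nodes,
                 step_cars = ed$cars,
                 step_distances = ed$distances,
                 total_distance = sum(ed$distances),
                 car_product = prod(ed$cars),
                 rank = rank),
            class = "pathway")
}

#' @export
print.pathway <- function(x, ...) {
  cat(sprintf("<pathway rank %s: %s (distance %.4f, CAR product %.4f)>\n",
              format(x$rank), paste(x$nodes, collapse = " -> "),
              x$total_distance, x$car_product))
  invisible(x)
}

#' Yen's k-shortest loopless path search
#'
#' Retrieves up to `k` loopless pathways between two compounds, ordered by
#' ascending total distance (= sum of 1/CAR over the steps, i.e. pathways
#' with the highest atom conservation come first). Ties are broken by the
#' lexicographic order of the node sequences, making the output fully
#' deterministic. A disconnected source/target yields an empty list.
#'
#' @param graph weighted network (edge attribute `weight` or `distance`;
#'   unweighted graphs count steps).
#' @param source,target compound ids (vertex names); must differ.
#' @param k maximum number of pathways.
#' @return list of `pathway` objects with `rank` set (possibly fewer
#'   than `k`).
#' @export
k_shortest <- function(graph, source, target, k = 10) {
  stopifnot(source != target)
  vn <- igraph::V(graph)$name
  if (!(source %in% vn) || !(target %in% vn)) {
    stop_carnet("source or target not in graph", "carnet_lookup_error")
  }
  first <- lex_shortest_path(graph, source, target)
  if (is.null(first)) return(list())
  A <- list(first)
  B <- list()
  bkeys <- character(0)
  while (length(A) < k) {
    prev <- A[[length(A)]]$nodes
    for (i in seq_len(length(prev) - 1)) {
      spur <- prev[i]
      root <- prev[seq_len(i)]
      g2 <- graph
      # remove edges that would replay a previously accepted path
      for (p in A) {
        pn <- p$nodes
        if (length(pn) > i && identical(pn[seq_len(i)], root)) {
          eid <- igraph::get_edge_ids(g2, c(pn[i], pn[i + 1]))
          eid <- eid[eid > 0]
          if (length(eid) > 0) g2 <- igraph::delete_edges(g2, eid)
        }
      }
      if (i > 1) {
        g2 <- igraph::delete_vertices(g2, root[seq_len(i - 1)])
      }
      sp <- lex_shortest_path(g2, spur, target)
      if (is.null(sp)) next
      cand_nodes <- c(root[-length(root)], sp$nodes)
      key <- paste(cand_nodes, collapse = "\r")
      if (key %in% bkeys) next
      if (any(vapply(A, function(p) identical(p$nodes, cand_nodes), TRUE))) {
        next
      }
      ed <- path_edge_data(graph, cand_nodes)
      B[[length(B) + 1]] <- list(nodes = cand_nodes,
                                 distance = sum(ed$distances))
      bkeys <- c(bkeys, key)
    }
    if (length(B) == 0) break
    dists <- vapply(B, `[[`, 0, "distance")
    best <- which(dists <= min(dists) + 1e-12)
    if (length(best) > 1) {
      ord <- best[1]
      for (b in best[-1]) {
        if (seq_lt(B[[b]]$nodes, B[[ord]]$nodes)) ord <- b
      }
      best <- ord
    }
    A[[length(A) + 1]] <- B[[best]]
    bkeys <- setdiff(bkeys, paste(B[[best]]$nodes, collapse = "\r"))
    B <- B[-best]
  }
  lapply(seq_along(A), function(r) new_pathway(graph, A[[r]]$nodes, r))
}

#' Rank a reference pathway among network alternatives
#'
#' First checks that every edge of the reference node sequence exists in
#' the network; if so, iterates the k-shortest search until the reference
#' sequence is produced (in either direction of traversal) or `k_max`
#' alternatives have been examined.
#'
#' @param graph weighted network.
#' @param reference character vector of compound ids (the linearized
#'   reference pathway, precursor first).
#' @param k_max search depth (default 100).
#' @return a `benchmark_record` list: `precursor`, `target`,
#'   `native_found_in_network`, `native_rank` (`NA` when not found),
#'   `n_alternatives_searched`.
#' @export
rank_native <- function(graph, reference, k_max = 100) {
  stopifnot(length(reference) >= 2)
  vn <- igraph::V(graph)$name
  edges_ok <- all(reference %in% vn)
  if (edges_ok) {
    eids <- igraph::get_edge_ids(graph, rbind(reference[-length(reference)],
                                              reference[-1]))
    edges_ok <- all(eids > 0)
  }
  rec <- list(precursor = reference[1],
              target = reference[length(reference)],
              native_found_in_network = edges_ok,
              native_rank = NA_integer_,
              n_alternatives_searched = 0L)
  if (!edges_ok) return(structure(rec, class = "benchmark_record"))
  paths <- k_shortest(graph, reference[1], reference[length(reference)],
                      k = k_max)
  rec$n_alternatives_searched <- length(paths)
  for (p in paths) {
    if (identical(p$nodes, reference) ||
        identical(p$nodes, rev(reference))) {
      rec$native_rank <- p$rank
      break
    }
  }
  structure(rec, class = "benchmark_record")
}

#' @export
print.benchmark_record <- function(x, ...) {
  cat(sprintf(
    "<benchmark_record %s -> %s: in network %s, native rank %s (%d searched)>\n",
    x$precursor, x$target, x$native_found_in_network,
    format(x$native_rank), x$n_alternatives_searched))
  invisible(x)
}

#' Load the cofactor exclusion list for pathway linearization
#'
#' @param path text file, one SMILES per line (optional name after a tab).
#' @return character vector of canonical keys.
#' @export
load_cofactor_exclusions <- function(path = system.file(
  "extdata", "cofactor_exclude.txt", package = "carnet")) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  smi <- vapply(strsplit(lines, "\t"), `[[`, "", 1)
  vapply(smi, canonicalize, "", USE.NAMES = FALSE)
}

#' Linearize a reference pathway
#'
#' Turns a set of reactions (a curated pathway) into a linear compound
#' sequence: every substrate-product pair of every reaction becomes a
#' unit-distance edge (no atom-conservation information is assumed for
#' reference data), common cofactors are excluded to prevent shortcuts, and
#' the longest of all-pairs shortest paths is returned as the reference
#' pathway - for a branched pathway, its longest branch. Ties are broken by
#' the lexicographic order of the endpoint pair.
#'
#' @param reactions `reaction_set` (or data.frame with `equation`) of at
#'   least 2 reactions.
#' @param compounds `compound_set` used to resolve exclusions by structure;
#'   optional when `exclude` already contains compound ids.
#' @param exclude canonical keys (or compound ids) of cofactors to drop
#'   from the pathway graph; default is the bundled exclusion list when
#'   `compounds` is given.
#' @return list with `nodes` (ordered compound ids), `precursor`, `target`,
#'   `length` (steps).
#' @export
linearize_reference <- function(reactions, compounds = NULL,
                                exclude = NULL) {
  if (nrow(reactions) < 2) {
    stop_carnet("a reference pathway needs at least 2 reactions",
                "carnet_benchmark_error")
  }
  if (is.null(exclude) && !is.null(compounds)) {
    exclude <- load_cofactor_exclusions()
  }
  drop_ids <- character(0)
  if (!is.null(exclude)) {
    drop_ids <- exclude
    if (!is.null(compounds)) {
      drop_ids <- union(drop_ids,
                        compounds$id[compounds$smiles %in% exclude])
    }
  }
  edges <- list()
  nodes <- character(0)
  for (eq in reactions$equation) {
    sides <- parse_equation(eq)
    rs <- setdiff(sides$reactants$id, drop_ids)
    ps <- setdiff(sides$products$id, drop_ids)
    nodes <- union(nodes, c(rs, ps))
    for (s in rs) for (p in ps) {
      if (s != p) edges[[length(edges) + 1]] <- c(s, p)
    }
  }
  nodes <- lex_sort(nodes)
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  igraph::V(g)$name <- nodes
  if (length(edges) > 0) {
    em <- unique(t(vapply(edges, lex_sort, character(2))))
    g <- igraph::add_edges(g, rbind(match(em[, 1], nodes),
                                    match(em[, 2], nodes)))
  }
  d <- igraph::distances(g, weights = NA)
  d[!is.finite(d)] <- -1
  dmax <- max(d)
  if (dmax < 2) {
    stop_carnet("degenerate pathway: no linear path of length >= 2",
                "carnet_benchmark_error")
  }
  hits <- which(d == dmax, arr.ind = TRUE)
  ends <- t(apply(hits, 1, function(ij) lex_sort(nodes[ij])))
  ends <- unique(ends)
  ends <- ends[order(ends[, 1], ends[, 2], method = "radix"), ,
               drop = FALSE]
  a <- unname(ends[1, 1]); b <- unname(ends[1, 2])
  sp <- lex_shortest_path(igraph::set_edge_attr(g, "weight",
                                                value = 1), a, b)
  list(nodes = unname(sp$nodes), precursor = a, target = b,
       length = length(sp$nodes) - 1)
}

EC_ELECTRON_TRANSFER <- c("^1\\.97\\.", "^1\\.9\\.", "^1\\.96\\.",
                          "^1\\.18\\.", "^1\\.19\\.", "^1\\.20\\.99")

#' Filter candidate benchmark pathways
#'
#' Applies the eight curation criteria for reference pathways: (i) at least
#' two reactions; (ii) no transport or electron-transfer reactions; (iii)
#' all reactions resolvable; (iv) no undefined, non-carbon, protein/peptide,
#' RNA or unknown compounds; (v) not circular; (vi) not a polymerization
#' pathway; (vii) not light-dependent; (viii) not a superpathway. Criteria
#' vi-viii (and protein/RNA/unknown classes for iv) rely on annotation flags
#' supplied with the record, as they cannot be derived from structures.
#'
#' @param records list of pathway records; each a list with `pathway_id`,
#'   `reactions` (data.frame with `id`, `equation`, optional `ec`),
#'   optional `nodes` (compound sequence, for circularity), optional
#'   `compound_flags` (data.frame `id`, `class` with levels ok/undefined/
#'   non_carbon/protein/rna/unknown) and optional logical `flags`
#'   (`polymerization`, `light_dependent`, `superpathway`,
#'   `electron_transfer`).
#' @param reaction_table optional `reaction_set` of resolvable reactions
#'   (criterion iii); `NULL` skips the lookup.
#' @param compounds optional `compound_set` used to detect non-carbon
#'   compounds from structures.
#' @return data.frame: `pathway_id`, `pass`, `reasons` (comma-joined
#'   criterion tags, empty when passing).
#' @export
filter_benchmark <- function(records, reaction_table = NULL,
                             compounds = NULL) {
  one <- function(rec) {
    reasons <- character(0)
    rx <- rec$reactions
    if (is.null(rx) || nrow(rx) < 2) reasons <- c(reasons, "i")
    flags <- rec$flags %||% list()
    if (!is.null(rx) && nrow(rx) > 0) {
      transport <- vapply(rx$equation, function(eq) {
        s <- parse_equation(eq)
        identical(format_side(s$reactants), format_side(s$products))
      }, TRUE)
      etrans <- FALSE
      if (!is.null(rx$ec)) {
        etrans <- any(vapply(rx$ec[!is.na(rx$ec)], function(ec) {
          any(vapply(EC_ELECTRON_TRANSFER, grepl, TRUE, x = ec))
        }, TRUE))
      }
      if (any(transport) || etrans || isTRUE(flags$electron_transfer)) {
        reasons <- c(reasons, "ii")
      }
      if (!is.null(reaction_table) &&
          !all(rx$id %in% reaction_table$id)) {
        reasons <- c(reasons, "iii")
      }
    }
    bad_class <- FALSE
    if (!is.null(rec$compound_flags)) {
      bad_class <- any(rec$compound_flags$class != "ok")
    }
    if (!is.null(compounds) && !is.null(rx)) {
      ids <- unique(unlist(lapply(rx$equation, function(eq) {
        s <- parse_equation(eq); c(s$reactants$id, s$products$id)
      })))
      mols <- attr(compounds, "mols")[ids]
      known <- !vapply(mols, is.null, TRUE)
      if (!all(known)) bad_class <- TRUE
      carbon <- vapply(mols[known], function(m) any(m$elem == "C"), TRUE)
      if (any(!carbon)) bad_class <- TRUE
    }
    if (bad_class) reasons <- c(reasons, "iv")
    if (!is.null(rec$nodes) && length(rec$nodes) >= 2 &&
        rec$nodes[1] == rec$nodes[length(rec$nodes)]) {
      reasons <- c(reasons, "v")
    }
    if (isTRUE(flags$polymerization)) reasons <- c(reasons, "vi")
    if (isTRUE(flags$light_dependent)) reasons <- c(reasons, "vii")
    if (isTRUE(flags$superpathway)) reasons <- c(reasons, "viii")
    data.frame(pathway_id = rec$pathway_id %||% NA_character_,
               pass = length(reasons) == 0,
               reasons = paste(reasons, collapse = ","),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(records, one))
  rownames(out) <- NULL
  out
}

#' Reconstruct a known reaction within a predicted network
#'
#' Classifies how a reaction is recovered by the rule-derived network:
#' `exact` when the reaction itself (same reactant and product multisets)
#' backs a network edge set; `alternative_cofactor` when every main
#' reactant pair (CAR >= `threshold`) is directly connected by an edge
#' backed by other reactions (same main biotransformation, different
#' co-substrates); `multi_step` when every main pair connects by a shortest
#' path of 2..`max_steps` steps whose CAR product stays at or above the
#' threshold (the reaction class is the worst pair, i.e. the maximum step
#' count); otherwise `not_reconstructed`.
#'
#' @param reaction one-row `reaction_set` slice (or list with `id`,
#'   `equation`).
#' @param graph weighted network built from the reaction set under
#'   consideration (typically rule-annotated reactions only, after cutoff
#'   with weights kept).
#' @param compounds `compound_set`.
#' @param network_reactions the `reaction_set` the network was built from
#'   (for the exact-match test).
#' @param cofactors cofactor table for the CAR cascade on the assessed
#'   reaction's own pairs.
#' @param max_steps maximum reconstruction depth (default 4).
#' @param threshold main-pair CAR threshold and path CAR-product floor
#'   (default 0.34).
#' @return list with `class`, `steps`, and `pairs` (per main pair:
#'   endpoints, connection steps, path CAR product).
#' @export
reconstruct_reaction <- function(reaction, graph, compounds,
                                 network_reactions = NULL,
                                 cofactors = NULL, max_steps = 4,
                                 threshold = 0.34) {
  eq <- if (is.data.frame(reaction)) reaction$equation[1] else
    reaction$equation
  sides <- parse_equation(eq)
  sig <- reaction_signature(sides, compounds)
  if (!is.null(network_reactions) && sig$resolved) {
    net_sigs <- vapply(network_reactions$equation, function(e) {
      s <- reaction_signature(parse_equation(e), compounds)
      if (s$resolved) s$signature else NA_character_
    }, "")
    if (sig$signature %in% net_sigs) {
      return(list(class = "exact", steps = 0L, pairs = NULL))
    }
  }
  mols <- attr(compounds, "mols")
  main <- list()
  for (s in sides$reactants$id) {
    for (p in sides$products$id) {
      if (s == p) next
      ms <- mols[[s]]; mp <- mols[[p]]
      if (is.null(ms) || is.null(mp)) next
      res <- conserved_atoms(ms, mp, cofactors = cofactors)
      pr <- compute_car(res$n_c, ms$n, mp$n, res$car_source)
      if (pr$car >= threshold) {
        main[[length(main) + 1]] <- list(s = s, p = p, car = pr$car)
      }
    }
  }
  if (length(main) == 0) {
    return(list(class = "not_reconstructed", steps = NA_integer_,
                pairs = NULL))
  }
  vn <- igraph::V(graph)$name
  per_pair <- lapply(main, function(mp) {
    out <- data.frame(substrate = mp$s, product = mp$p,
                      steps = NA_integer_, car_product = NA_real_,
                      stringsAsFactors = FALSE)
    if (!(mp$s %in% vn) || !(mp$p %in% vn)) return(out)
    sp <- lex_shortest_path(graph, mp$s, mp$p)
    if (is.null(sp)) return(out)
    ed <- path_edge_data(graph, sp$nodes)
    out$steps <- length(sp$nodes) - 1L
    out$car_product <- prod(ed$cars)
    out
  })
  pairs <- do.call(rbind, per_pair)
  ok <- !is.na(pairs$steps) & pairs$steps <= max_steps &
    pairs$car_product >= threshold
  if (!all(ok)) {
    return(list(class = "not_reconstructed", steps = NA_integer_,
                pairs = pairs))
  }
  kmax <- max(pairs$steps)
  cls <- if (kmax <= 1) "alternative_cofactor" else "multi_step"
  list(class = cls, steps = as.integer(kmax), pairs = pairs)
}
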