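# The biotransformation network: an undirected graph whose nodes are
# compounds and whose edges are substrate-product reactant pairs weighted by
# distance = 1/CAR. An edge aggregates every reaction that performs the same
# biotransformation; the aggregated CAR is the best (maximum) conservation
# over those reactions.

#' Build the CAR-weighted biotransformation graph
#'
#' Enumerates every reactant-product compound pair of every reaction,
#' resolves its conserved-atom count (using rule atom maps when the reaction
#' set carries them, otherwise the fallback cascade of
#' [conserved_atoms()]), and emits one undirected edge per unordered pair
#' with positive CAR. Parallel biotransformations collapse onto a single
#' edge carrying all backing reaction ids and the maximum CAR.
#'
#' @param reactions a `reaction_set` (known, predicted or a union).
#' @param compounds `compound_set` resolving every participant.
#' @param cofactors cofactor table from [load_cofactor_pairs()], `NULL` to
#'   disable stage 2 of the cascade.
#' @param mcs_max_atoms MCS stage size ceiling (heavy atoms per molecule).
#' @param correction optional CAR correction-factor hook, see
#'   [compute_car()].
#' @return an igraph with vertex attribute `name` (compound id) and edge
#'   attributes `car`, `distance`, `weight` (= distance), `car_source`,
#'   `reaction_ids` (semicolon-joined).
#' @export
build_network <- function(reactions, compounds, cofactors = NULL,
                          mcs_max_atoms = 60, correction = NULL) {
  mols <- attr(compounds, "mols")
  pair_tab <- attr(reactions, "pairs")
  edges <- new.env(parent = emptyenv())
  nodes <- character(0)
  for (i in seq_len(nrow(reactions))) {
    sides <- parse_equation(reactions$equation[i])
    rid <- reactions$id[i]
    part <- unique(c(sides$reactants$id, sides$products$id))
    nodes <- union(nodes, part)
    for (s in sides$reactants$id) {
      for (p in sides$products$id) {
        if (s == p) next
        ms <- mols[[s]]; mp <- mols[[p]]
        if (is.null(ms) || is.null(mp)) next
        nc_known <- NULL
        if (!is.null(pair_tab)) {
          hit <- which(pair_tab$reaction_id == rid &
                         ((pair_tab$sub_id == s & pair_tab$prod_id == p) |
                            (pair_tab$sub_id == p & pair_tab$prod_id == s)))
          if (length(hit) > 0) nc_known <- max(pair_tab$n_c[hit])
        }
        res <- conserved_atoms(ms, mp, atom_map_nc = nc_known,
                               cofactors = cofactors,
                               mcs_max_atoms = mcs_max_atoms)
        if (res$n_c == 0) next
        pr <- compute_car(res$n_c, ms$n, mp$n, res$car_source,
                          correction = correction)
        if (pr$car <= 0) next
        key <- paste(lex_sort(c(s, p)), collapse = "\r")
        cur <- edges[[key]]
        if (is.null(cur) || pr$car > cur$car) {
          pr$reaction_ids <- unique(c(cur$reaction_ids, rid))
          edges[[key]] <- pr
        } else {
          cur$reaction_ids <- unique(c(cur$reaction_ids, rid))
          edges[[key]] <- cur
        }
      }
    }
  }
  keys <- lex_sort(ls(edges))
  ep <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  nodes <- lex_sort(nodes)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (length(keys) > 0) {
    idx <- rbind(match(ep[, 1], nodes), match(ep[, 2], nodes))
    g <- igraph::add_edges(g, as.vector(idx))
    recs <- lapply(keys, function(k) edges[[k]])
    igraph::E(g)$car <- vapply(recs, `[[`, 0, "car")
    igraph::E(g)$distance <- vapply(recs, `[[`, 0, "distance")
    igraph::E(g)$weight <- igraph::E(g)$distance
    igraph::E(g)$car_source <- vapply(recs, `[[`, "", "car_source")
    igraph::E(g)$n_c <- vapply(recs, `[[`, 0, "n_c")
    igraph::E(g)$reaction_ids <- vapply(recs, function(r) {
      paste(lex_sort(r$reaction_ids), collapse = ";")
    }, "")
  }
  g
}

#' Apply the CAR cutoff to a weighted network
#'
#' Removes edges whose CAR is strictly below the threshold (an edge at
#' exactly the threshold is kept) and, by default, drops the weights from
#' the surviving edges, yielding the unweighted graph used for
#' component/diameter analysis. The node set is unchanged: compounds whose
#' edges are all removed remain as isolated nodes.
#'
#' @param graph network from [build_network()].
#' @param threshold CAR cutoff (default 0.34).
#' @param drop_weights drop `weight`/`distance` attributes (default `TRUE`);
#'   keep them when the result feeds the pathway search.
#' @return the filtered igraph.
#' @export
apply_cutoff <- function(graph, threshold = 0.34, drop_weights = TRUE) {
  drop <- which(igraph::E(graph)$car < threshold)
  g <- igraph::delete_edges(graph, drop)
  if (drop_weights) {
    for (at in c("weight", "distance")) {
      if (at %in% igraph::edge_attr_names(g)) {
        g <- igraph::delete_edge_attr(g, at)
      }
    }
  }
  g
}

#' Graph statistics of a biotransformation network
#'
#' Connected components, size of the main component, and the diameter
#' (longest shortest path) and average path length of the main component,
#' all in unweighted steps. Graphs whose main component exceeds
#' `exact_ceiling` nodes are estimated from breadth-first searches rooted at
#' an evenly spaced deterministic sample of nodes.
#'
#' @param graph an igraph (typically after [apply_cutoff()]).
#' @param exact_ceiling main-component size up to which the computation is
#'   exact (default 2000).
#' @param n_samples BFS roots used above the ceiling (default 200).
#' @return a `network_stats` list: `n_nodes`, `n_edges`, `components`
#'   (sizes, descending), `main_component_fraction`, `diameter`,
#'   `average_path_length`, `exact`.
#' @export
network_stats <- function(graph, exact_ceiling = 2000, n_samples = 200) {
  n <- igraph::vcount(graph)
  if (n == 0) {
    return(structure(list(n_nodes = 0L, n_edges = 0L, components = integer(),
                          main_component_fraction = NA_real_,
                          diameter = NA_real_,
                          average_path_length = NA_real_, exact = TRUE),
                     class = "network_stats"))
  }
  comp <- igraph::components(graph)
  sizes <- sort(as.integer(comp$csize), decreasing = TRUE)
  main_id <- which.max(comp$csize)
  main <- igraph::induced_subgraph(graph,
                                   which(comp$membership == main_id))
  nm <- igraph::vcount(main)
  if (nm < 2) {
    diam <- 0; apl <- NA_real_; exact <- TRUE
  } else if (nm <= exact_ceiling) {
    diam <- igraph::diameter(main, weights = NA)
    apl <- igraph::mean_distance(main, weights = NA)
    exact <- TRUE
  } else {
    roots <- igraph::V(main)[unique(round(seq(1, nm,
                                              length.out = n_samples)))]
    d <- igraph::distances(main, v = roots, weights = NA)
    d <- d[is.finite(d) & d > 0]
    diam <- max(d); apl <- mean(d); exact <- FALSE
  }
  structure(list(n_nodes = n, n_edges = igraph::ecount(graph),
                 components = sizes,
                 main_component_fraction = sizes[1] / n,
                 diameter = diam, average_path_length = apl,
                 exact = exact),
            class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "<network_stats: %d nodes, %d edges, %d components ",
    "(main %.0f%%), diameter %s, avg path length %s%s>\n"),
    x$n_nodes, x$n_edges, length(x$components),
    100 * (x$main_component_fraction %||% NA),
    format(x$diameter), format(round(x$average_path_length %||% NA, 3)),
    if (isTRUE(x$exact)) "" else " [sampled]"))
  invisible(x)
}

#' Write the network edge list as TSV
#'
#' Columns: substrate_id, product_id, car, distance, car_source,
#' reaction_ids (semicolon-joined).
#'
#' @param graph network igraph.
#' @param path output file.
#' @export
write_edge_list <- function(graph, path) {
  if (igraph::ecount(graph) == 0) {
    write.table(data.frame(substrate_id = character(),
                           product_id = character(), car = numeric(),
                           distance = numeric(), car_source = character(),
                           reaction_ids = character()),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  el <- igraph::as_edgelist(graph)
  df <- data.frame(substrate_id = el[, 1], product_id = el[, 2],
                   car = igraph::E(graph)$car,
                   distance = if ("distance" %in%
                                    igraph::edge_attr_names(graph)) {
                     igraph::E(graph)$distance
                   } else {
                     NA_real_
                   },
                   car_source = igraph::E(graph)$car_source,
                   reaction_ids = igraph::E(graph)$reaction_ids,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a network edge list written by [write_edge_list()]
#'
#' @param path TSV path.
#' @return a weighted igraph.
#' @export
read_edge_list <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  nodes <- lex_sort(unique(c(df$substrate_id, df$product_id)))
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  igraph::V(g)$name <- nodes
  g <- igraph::add_edges(g, rbind(match(df$substrate_id, nodes),
                                  match(df$product_id, nodes)))
  igraph::E(g)$car <- df$car
  igraph::E(g)$distance <- df$distance
  igraph::E(g)$weight <- df$distance
  igraph::E(g)$car_source <- df$car_source
  igraph::E(g)$reaction_ids <- df$reaction_ids
  g
}
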