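# Brute-force reference implementations used as ground truth in the test
# suite. They are deliberately independent of the production code paths
# (pure-R breadth-first search, exhaustive permutation enumeration) and
# refuse instances large enough to blow up combinatorially.

#' Exhaustively enumerate simple paths
#'
#' Depth-first enumeration of every loopless path between two vertices,
#' with total distances; the reference oracle for [k_shortest()].
#'
#' @param graph an igraph (weights from `weight`/`distance`, else unit).
#' @param source,target vertex names.
#' @param max_nodes refuse graphs above this size (default 12).
#' @return list of `list(nodes, distance)` sorted by (distance, node
#'   sequence).
#' @export
enumerate_simple_paths <- function(graph, source, target, max_nodes = 12) {
  if (igraph::vcount(graph) > max_nodes) {
    stop_carnet(sprintf("graph too large for exhaustive enumeration (> %d)",
                        max_nodes), "carnet_oracle_error")
  }
  vn <- igraph::V(graph)$name
  w <- edge_weights(graph)
  adj <- lapply(seq_along(vn), function(i) {
    nb <- igraph::neighbors(graph, i)
    as.integer(nb)
  })
  s <- match(source, vn); t <- match(target, vn)
  out <- list()
  visited <- logical(length(vn))
  walk <- function(u, path, dist) {
    if (u == t) {
      out[[length(out) + 1]] <<- list(nodes = vn[path], distance = dist)
      return()
    }
    for (v in adj[[u]]) {
      if (visited[v]) next
      eid <- igraph::get_edge_ids(graph, c(u, v))
      visited[v] <<- TRUE
      walk(v, c(path, v), dist + w[eid])
      visited[v] <<- FALSE
    }
  }
  visited[s] <- TRUE
  walk(s, s, 0)
  if (length(out) == 0) return(out)
  ord <- order(vapply(out, `[[`, 0, "distance"))
  out <- out[ord]
  # stable tie-break by node sequence
  i <- 1
  while (i < length(out)) {
    j <- i
    while (j < length(out) &&
           abs(out[[j + 1]]$distance - out[[i]]$distance) <= 1e-12) {
      j <- j + 1
    }
    if (j > i) {
      blk <- out[i:j]
      for (a in seq_along(blk)) for (b in seq_along(blk)) {
        if (b > a && seq_lt(blk[[b]]$nodes, blk[[a]]$nodes)) {
          tmp <- blk[[a]]; blk[[a]] <- blk[[b]]; blk[[b]] <- tmp
        }
      }
      out[i:j] <- blk
    }
    i <- j + 1
  }
  out
}

#' All-pairs BFS distances (pure R)
#'
#' Hand-rolled breadth-first search over an adjacency structure, independent
#' of igraph; the reference oracle for [network_stats()].
#'
#' @param graph an igraph (treated as unweighted) with at most `max_nodes`
#'   vertices.
#' @param max_nodes refusal ceiling (default 250).
#' @return symmetric integer matrix of step counts (`Inf` when
#'   disconnected), dimnames = vertex names.
#' @export
all_pairs_bfs <- function(graph, max_nodes = 250) {
  n <- igraph::vcount(graph)
  if (n > max_nodes) {
    stop_carnet("graph too large for the BFS oracle", "carnet_oracle_error")
  }
  vn <- igraph::V(graph)$name %||% as.character(seq_len(n))
  el <- igraph::as_edgelist(graph, names = FALSE)
  adj <- vector("list", n)
  for (r in seq_len(nrow(el))) {
    a <- el[r, 1]; b <- el[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  d <- matrix(Inf, n, n, dimnames = list(vn, vn))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    queue <- s
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) {
        if (is.infinite(dist[v])) {
          dist[v] <- dist[u] + 1
          queue <- c(queue, v)
        }
      }
    }
    d[s, ] <- dist
  }
  d
}

#' Exhaustive reactive-site matching
#'
#' Enumerates every injective assignment of the rule's substrate pattern
#' atoms to molecule atoms by brute force over atom permutations (no
#' backtracking pruning), across all kekule structures, and reduces the
#' assignments to pattern-symmetry orbits. Reference oracle for
#' [match_reactive_sites()].
#'
#' @param rule a `reaction_rule`.
#' @param compound a `compound` or internal molecule with at most
#'   `max_atoms` heavy atoms.
#' @param max_atoms refusal ceiling (default 14).
#' @return list of orbit representatives (integer maps), comparable to the
#'   `map` entries of [match_reactive_sites()].
#' @export
exhaustive_site_match <- function(rule, compound, max_atoms = 14) {
  mol <- if (inherits(compound, "compound")) compound$mol else compound
  if (mol$n > max_atoms) {
    stop_carnet("molecule too large for the exhaustive matcher",
                "carnet_oracle_error")
  }
  idx_s <- which(rule$src_frag == "S")
  k <- length(idx_s)
  if (k == 0 || k > mol$n) return(list())
  elem <- rule$elem[idx_s]; chg <- rule$chg[idx_s]
  minh <- pmax(rule$min_h[idx_s], -rule$hdelta[idx_s])
  req <- rule$site[idx_s, idx_s, drop = FALSE]
  diag(req) <- 0
  keks <- enumerate_kekule(mol)
  autos <- pattern_automorphisms(rule, idx_s)
  combos <- utils::combn(mol$n, k, simplify = FALSE)
  reps <- character(0)
  maps <- list()
  for (kb in keks) {
    for (cmb in combos) {
      for (perm in all_perms(seq_len(k))) {
        asg <- integer(k)
        asg[perm] <- cmb
        ok <- TRUE
        for (i in seq_len(k)) {
          a <- asg[i]
          if (!(elem[i] == "*" || mol$elem[a] == elem[i]) ||
              mol$chg[a] != chg[i] || mol$hyd[a] < minh[i]) {
            ok <- FALSE; break
          }
        }
        if (ok) {
          for (i in seq_len(k)) {
            for (j in seq_len(k)) {
              if (i < j && kb[asg[i], asg[j]] != req[i, j]) {
                ok <- FALSE; break
              }
            }
            if (!ok) break
          }
        }
        if (!ok) next
        canon <- lex_sort(vapply(autos, function(pm) {
          paste(asg[pm], collapse = ",")
        }, ""))[1]
        if (!(canon %in% reps)) {
          reps <- c(reps, canon)
          maps[[length(maps) + 1]] <-
            as.integer(strsplit(canon, ",")[[1]])
        }
      }
    }
  }
  maps
}
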