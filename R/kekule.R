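#' Enumerate kekule structures of a molecule
#'
#' Aromatic systems admit several alternating single/double bond
#' assignments; a reactive-site pattern written against localized bonds can
#' match in one assignment and not another, so site screening runs over the
#' union of all assignments. The enumeration keeps every atom's total
#' bond-order sum fixed and reassigns orders only on ring bonds of order 1
#' or 2; molecules without such systems yield exactly their input structure.
#'
#' @param mol a compound (as returned by [admit_compound()]) or an internal
#'   molecule object.
#' @param max_structures safety ceiling on the number of structures
#'   enumerated (default 1000).
#' @return list of bond-order matrices; the first entry is the input
#'   assignment.
#' @export
enumerate_kekule <- function(mol, max_structures = 1000) {
  if (inherits(mol, "compound")) mol <- mol$mol
  stopifnot(inherits(mol, "cmol"))
  n <- mol$n
  if (n < 3) return(list(mol$bond))
  g <- igraph::graph_from_adjacency_matrix(mol$bond > 0, mode = "undirected")
  br <- igraph::bridges(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  ring <- setdiff(seq_len(nrow(el)), as.integer(br))
  # variable edges: ring bonds of order 1 or 2
  var <- ring[vapply(ring, function(e) {
    mol$bond[el[e, 1], el[e, 2]] %in% c(1L, 2L)
  }, TRUE)]
  if (length(var) == 0) return(list(mol$bond))
  va <- el[var, 1]; vb <- el[var, 2]
  orig <- vapply(seq_along(var), function(k) mol$bond[va[k], vb[k]], 0L)
  # per-atom target: sum of orders over its variable edges
  target <- integer(n)
  nedge <- integer(n)
  for (k in seq_along(var)) {
    target[va[k]] <- target[va[k]] + orig[k]
    target[vb[k]] <- target[vb[k]] + orig[k]
    nedge[va[k]] <- nedge[va[k]] + 1L
    nedge[vb[k]] <- nedge[vb[k]] + 1L
  }
  results <- list()
  assign_order <- order(pmin(va, vb) * (n + 1) + pmax(va, vb))
  va <- va[assign_order]; vb <- vb[assign_order]
  rem_t <- target; rem_e <- nedge
  cur <- integer(length(var))
  recurse <- function(k) {
    if (length(results) >= max_structures) return()
    if (k > length(var)) {
      b <- mol$bond
      for (j in seq_along(var)) {
        b[va[j], vb[j]] <- cur[j]
        b[vb[j], va[j]] <- cur[j]
      }
      results[[length(results) + 1]] <<- b
      return()
    }
    for (o in c(1L, 2L)) {
      a1 <- va[k]; a2 <- vb[k]
      ok <- TRUE
      for (a in c(a1, a2)) {
        nt <- rem_t[a] - o; ne <- rem_e[a] - 1L
        if (nt < ne || nt > 2L * ne) { ok <- FALSE; break }
      }
      if (!ok) next
      cur[k] <<- o
      rem_t[a1] <<- rem_t[a1] - o; rem_e[a1] <<- rem_e[a1] - 1L
      rem_t[a2] <<- rem_t[a2] - o; rem_e[a2] <<- rem_e[a2] - 1L
      recurse(k + 1)
      rem_t[a1] <<- rem_t[a1] + o; rem_e[a1] <<- rem_e[a1] + 1L
      rem_t[a2] <<- rem_t[a2] + o; rem_e[a2] <<- rem_e[a2] + 1L
    }
  }
  recurse(1)
  # put the input assignment first for deterministic downstream use
  is_orig <- vapply(results, function(b) identical(b, mol$bond), TRUE)
  c(results[is_orig], results[!is_orig])
}
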