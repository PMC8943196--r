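# Reactive-site matching: injective mapping of a rule's pattern atoms onto
# molecule atoms, preserving element, formal charge, minimum hydrogen count
# and every pattern bond order (entry 0 = atoms must not be bonded), taken
# over the union of kekule structures.

# Generic backtracking matcher for one pattern fragment against one kekule
# bond matrix. `req` is the exact bond-order requirement between pattern
# atoms. Returns a list of integer vectors (pattern index -> atom index).
match_fragment <- function(elem, chg, minh, req, mol, kek_bond,
                           max_maps = 10000) {
  k <- length(elem)
  n <- mol$n
  cand <- lapply(seq_len(k), function(i) {
    which((elem[i] == "*" | mol$elem == elem[i]) &
            mol$chg == chg[i] & mol$hyd >= minh[i])
  })
  if (any(lengths(cand) == 0)) return(list())
  # order pattern atoms: start at the most constrained, grow by connectivity
  ord <- integer(0)
  remaining <- seq_len(k)
  ord[1] <- remaining[which.min(lengths(cand)[remaining])]
  remaining <- setdiff(remaining, ord[1])
  while (length(remaining) > 0) {
    conn <- remaining[vapply(remaining, function(i) {
      any(req[i, ord] > 0)
    }, TRUE)]
    pick <- if (length(conn) > 0) conn else remaining
    nxt <- pick[which.min(lengths(cand)[pick])]
    ord <- c(ord, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  maps <- list()
  assign <- integer(k)
  used <- logical(n)
  recurse <- function(step) {
    if (length(maps) >= max_maps) return()
    if (step > k) {
      maps[[length(maps) + 1]] <<- assign
      return()
    }
    i <- ord[step]
    for (a in cand[[i]]) {
      if (used[a]) next
      ok <- TRUE
      for (sj in seq_len(step - 1)) {
        j <- ord[sj]
        if (kek_bond[a, assign[j]] != req[i, j]) { ok <- FALSE; break }
      }
      if (!ok) next
      assign[i] <<- a
      used[a] <<- TRUE
      recurse(step + 1)
      used[a] <<- FALSE
    }
  }
  recurse(1)
  maps
}

# Permutations of the substrate pattern atoms that leave the rule invariant
# (element, charge, min_h, hdelta, and both matrices). Used to deduplicate
# symmetric site maps.
pattern_automorphisms <- function(rule, idx_s) {
  key <- paste(rule$elem[idx_s], rule$chg[idx_s], rule$min_h[idx_s],
               rule$hdelta[idx_s], rule$src_frag[idx_s], rule$dst_frag[idx_s])
  groups <- split(seq_along(idx_s), key)
  perm_sets <- lapply(groups, function(g) {
    if (length(g) == 1) return(list(g))
    all_perms(g)
  })
  combos <- Reduce(function(acc, ps) {
    out <- list()
    for (a in acc) for (p in ps) out[[length(out) + 1]] <- c(a, p)
    out
  }, perm_sets, accumulate = FALSE, right = FALSE)
  # reconstruct full permutation in original local ordering
  pos <- unlist(groups)
  full <- lapply(combos, function(cb) {
    perm <- integer(length(idx_s))
    perm[pos] <- cb
    perm
  })
  n <- length(rule$elem)
  keep <- vapply(full, function(perm) {
    ext <- seq_len(n)
    ext[idx_s] <- idx_s[perm]
    identical(rule$delta[ext, ext], rule$delta) &&
      identical(rule$site[ext, ext][row(rule$site) != col(rule$site)],
                rule$site[row(rule$site) != col(rule$site)])
  }, TRUE)
  full[keep]
}

all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

#' Find reactive sites of a rule on a molecule
#'
#' Screens every kekule structure of the molecule for injective embeddings of
#' the rule's substrate site pattern. Embeddings that coincide up to a
#' symmetry of the pattern itself are reported once; distinct atom sets (for
#' example the two hydroxyl carbons of 1,3-propanediol under an alcohol
#' oxidation rule) remain distinct sites.
#'
#' @param rule a `reaction_rule`.
#' @param compound a `compound` or internal molecule object.
#' @return list of sites, each a list with `map` (pattern atom -> molecule
#'   atom indices, substrate fragment only), `kek` (index of the kekule
#'   structure it matched in) and `atoms` (sorted mapped atom indices).
#'   Empty list when the molecule is unreactive under the rule.
#' @export
match_reactive_sites <- function(rule, compound) {
  mol <- if (inherits(compound, "compound")) compound$mol else compound
  stopifnot(inherits(mol, "cmol"))
  idx_s <- which(rule$src_frag == "S")
  if (length(idx_s) == 0) return(list())
  eff_minh <- pmax(rule$min_h[idx_s], -rule$hdelta[idx_s])
  req <- rule$site[idx_s, idx_s, drop = FALSE]
  diag(req) <- 0  # diagonal is unconstrained in this dialect
  keks <- enumerate_kekule(mol)
  autos <- pattern_automorphisms(rule, idx_s)
  seen <- character(0)
  sites <- list()
  for (ki in seq_along(keks)) {
    maps <- match_fragment(rule$elem[idx_s], rule$chg[idx_s], eff_minh,
                           req, mol, keks[[ki]])
    for (m in maps) {
      reps <- vapply(autos, function(perm) {
        paste(m[perm], collapse = ",")
      }, "")
      canon <- lex_sort(reps)[1]
      if (canon %in% seen) next
      seen <- c(seen, canon)
      mm <- as.integer(strsplit(canon, ",")[[1]])
      sites[[length(sites) + 1]] <- list(map = mm, kek = ki,
                                         atoms = sort(mm))
    }
  }
  sites
}
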