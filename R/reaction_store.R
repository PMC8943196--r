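# Reactions are stoichiometric multisets over compound ids. The TSV equation
# dialect is "2 C00001 + C00007 <=> 2 C00027": integer coefficients (1 may be
# omitted), ' + ' between participants, ' <=> ' between sides.

#' Parse a reaction equation string
#'
#' @param equation equation string, e.g. `"2 A + B <=> C"`.
#' @return list with data.frames `reactants` and `products`
#'   (columns `id`, `coef`).
#' @export
parse_equation <- function(equation) {
  sides <- strsplit(equation, "<=>", fixed = TRUE)[[1]]
  if (length(sides) != 2) {
    stop_carnet(sprintf("equation lacks ' <=> ': '%s'", equation),
                "carnet_parse_error")
  }
  parse_side <- function(s) {
    terms <- strsplit(s, " + ", fixed = TRUE)[[1]]
    terms <- trimws(terms)
    terms <- terms[nzchar(terms)]
    if (length(terms) == 0) {
      stop_carnet(sprintf("empty reaction side in '%s'", equation),
                  "carnet_parse_error")
    }
    coef <- rep(1L, length(terms))
    id <- terms
    has_coef <- grepl("^[0-9]+ ", terms)
    coef[has_coef] <- as.integer(sub(" .*$", "", terms[has_coef]))
    id[has_coef] <- sub("^[0-9]+ ", "", terms[has_coef])
    agg <- tapply(coef, id, sum)
    data.frame(id = names(agg), coef = as.integer(agg),
               stringsAsFactors = FALSE)
  }
  list(reactants = parse_side(sides[1]), products = parse_side(sides[2]))
}

format_side <- function(side) {
  side <- side[order(side$id, method = "radix"), , drop = FALSE]
  paste(ifelse(side$coef == 1, side$id, paste(side$coef, side$id)),
        collapse = " + ")
}

format_equation <- function(sides) {
  paste(format_side(sides$reactants), "<=>", format_side(sides$products))
}

# Cancel species appearing on both sides with net-zero change and translate
# compound ids to canonical keys. Returns the direction-insensitive identity
# signature plus the canonically oriented equation (lexicographically smaller
# side first) and a degeneracy flag (sides identical after canonicalization:
# transport or stereo-only reactions).
reaction_signature <- function(sides, compounds) {
  key_of <- setNames(compounds$smiles, compounds$id)
  translate <- function(side) {
    k <- key_of[resolve_compound_ids(compounds, side$id)]
    if (anyNA(k)) return(NULL)
    agg <- tapply(side$coef, k, sum)
    data.frame(key = names(agg), coef = as.integer(agg),
               stringsAsFactors = FALSE)
  }
  r <- translate(sides$reactants)
  p <- translate(sides$products)
  if (is.null(r) || is.null(p)) {
    return(list(resolved = FALSE))
  }
  # cancel net-zero participants
  common <- intersect(r$key, p$key)
  for (k in common) {
    d <- min(r$coef[r$key == k], p$coef[p$key == k])
    r$coef[r$key == k] <- r$coef[r$key == k] - d
    p$coef[p$key == k] <- p$coef[p$key == k] - d
  }
  r <- r[r$coef > 0, , drop = FALSE]
  p <- p[p$coef > 0, , drop = FALSE]
  side_str <- function(s) {
    s <- s[order(s$key, method = "radix"), , drop = FALSE]
    paste(s$coef, s$key, collapse = " + ")
  }
  rs <- side_str(r); ps <- side_str(p)
  degenerate <- nrow(r) == 0 || nrow(p) == 0 || identical(rs, ps)
  flip <- !degenerate && seq_lt(ps, rs)
  list(resolved = TRUE, degenerate = degenerate, flip = flip,
       signature = if (flip) paste(ps, "||", rs) else paste(rs, "||", ps))
}

#' Check the elemental balance of a reaction
#'
#' Sums element counts (hydrogen included) over both sides given the
#' stoichiometric coefficients. Implicit protons are never added: an equation
#' that is short of hydrogens is reported as unbalanced, matching the use of
#' balance as a quality-control category rather than something to repair.
#'
#' @param sides parsed equation (see [parse_equation()]), or an equation
#'   string.
#' @param compounds a `compound_set` resolving every participant.
#' @return `"balanced"`, `"unbalanced"`, or `"unprocessable"` when a
#'   participant is unknown or has no defined structure.
#' @export
check_balance <- function(sides, compounds) {
  if (is.character(sides)) sides <- parse_equation(sides)
  mols <- attr(compounds, "mols")
  tally <- function(side) {
    ids <- resolve_compound_ids(compounds, side$id)
    if (anyNA(ids)) return(NULL)
    tot <- list()
    for (i in seq_len(nrow(side))) {
      m <- mols[[ids[i]]]
      if (is.null(m)) return(NULL)
      comp <- mol_composition(m)
      for (e in names(comp)) {
        tot[[e]] <- (tot[[e]] %||% 0L) + comp[[e]] * side$coef[i]
      }
    }
    tot
  }
  lhs <- tally(sides$reactants)
  rhs <- tally(sides$products)
  if (is.null(lhs) || is.null(rhs)) return("unprocessable")
  els <- union(names(lhs), names(rhs))
  for (e in els) {
    if ((lhs[[e]] %||% 0L) != (rhs[[e]] %||% 0L)) return("unbalanced")
  }
  "balanced"
}

empty_reaction_set <- function() {
  structure(data.frame(id = character(), equation = character(),
                       ec = character(), sources = character(),
                       rule_ids = character(), provenance = character(),
                       balance = character(), stringsAsFactors = FALSE),
            class = c("reaction_set", "data.frame"))
}

#' Unify reaction records into a deduplicated reaction set
#'
#' Reaction identity is the pair of canonicalized reactant and product
#' multisets, direction-insensitive: A => B and B => A merge into one record
#' stored in a canonical orientation (lexicographically smaller side as
#' reactants). Transport reactions (same compound multiset on both sides) and
#' stereo-only reactions (sides identical once stereochemistry is stripped)
#' are filtered out, keeping only reactions that change atom connectivity.
#'
#' @param records data.frame with columns `id`, `equation`, `ec`,
#'   `source_db`.
#' @param compounds unified `compound_set`; equations must reference its ids.
#' @return list with `reactions` (a `reaction_set` data.frame: id, equation
#'   in canonical orientation, ec, sources, rule_ids, provenance, balance)
#'   and `report` (per-source counts).
#' @export
unify_reactions <- function(records, compounds) {
  stopifnot(all(c("id", "equation", "source_db") %in% names(records)))
  if (is.null(records$ec)) records$ec <- NA_character_
  n <- nrow(records)
  sig <- character(n); status <- character(n)
  oriented <- character(n)
  for (i in seq_len(n)) {
    sides <- tryCatch(parse_equation(records$equation[i]),
                      carnet_error = function(e) NULL)
    if (is.null(sides)) { status[i] <- "unparsable"; next }
    # rewrite aliased participant ids to the unified compound ids
    ra <- resolve_compound_ids(compounds, sides$reactants$id)
    pa <- resolve_compound_ids(compounds, sides$products$id)
    if (!anyNA(ra) && !anyNA(pa)) {
      agg <- function(ids, coef) {
        a <- tapply(coef, ids, sum)
        data.frame(id = names(a), coef = as.integer(a),
                   stringsAsFactors = FALSE)
      }
      sides$reactants <- agg(ra, sides$reactants$coef)
      sides$products <- agg(pa, sides$products$coef)
    }
    s <- reaction_signature(sides, compounds)
    if (!s$resolved) { status[i] <- "unresolved"; sig[i] <- NA; next }
    if (s$degenerate) { status[i] <- "filtered"; next }
    status[i] <- "ok"
    sig[i] <- s$signature
    oriented[i] <- if (s$flip) {
      format_equation(list(reactants = sides$products,
                           products = sides$reactants))
    } else {
      format_equation(sides)
    }
  }
  ok <- which(status == "ok")
  usig <- unique(sig[ok])
  # deterministic order: by oriented equation
  first <- vapply(usig, function(s) ok[sig[ok] == s][1], 0L)
  ord <- order(oriented[first], method = "radix")
  usig <- usig[ord]; first <- first[ord]
  rows <- lapply(seq_along(usig), function(j) {
    idx <- ok[sig[ok] == usig[j]]
    ecs <- unique(records$ec[idx]); ecs <- ecs[!is.na(ecs) & nzchar(ecs)]
    eq <- oriented[first[j]]
    data.frame(
      id = paste0("R", fnv1a32(usig[j])),
      equation = eq,
      ec = if (length(ecs) > 0) lex_sort(ecs)[1] else NA_character_,
      sources = paste(lex_sort(unique(paste0(records$source_db[idx], ":",
                                             records$id[idx]))),
                      collapse = ";"),
      rule_ids = "",
      provenance = "known",
      balance = check_balance(parse_equation(eq), compounds),
      stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    empty_reaction_set()
  }
  class(out) <- c("reaction_set", "data.frame")
  report <- do.call(rbind, lapply(split(seq_len(n), records$source_db),
    function(idx) {
      okx <- idx[status[idx] == "ok"]
      data.frame(source_db = records$source_db[idx[1]],
                 n_records = length(idx),
                 n_unique = length(unique(sig[okx])),
                 n_duplicates = length(okx) - length(unique(sig[okx])),
                 n_filtered = sum(status[idx] == "filtered"),
                 n_unresolved = sum(status[idx] %in%
                                      c("unresolved", "unparsable")),
                 stringsAsFactors = FALSE)
    }))
  rownames(report) <- NULL
  list(reactions = out, report = report)
}

#' @export
print.reaction_set <- function(x, ...) {
  cat(sprintf("<reaction_set: %d reactions (%d balanced)>\n", nrow(x),
              sum(x$balance == "balanced")))
  if (nrow(x) > 0) print.data.frame(head(as.data.frame(x), 10))
  invisible(x)
}

#' Read / write reaction tables
#'
#' Reaction TSV files have header columns `id`, `equation`, `ec`,
#' `source_db`.
#'
#' @param path file path.
#' @rdname reaction_tsv
#' @export
read_reaction_records <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  # unified-set exports carry a 'sources' column instead of per-record ones
  if (is.null(df$source_db)) df$source_db <- rep("input", nrow(df))
  df
}

#' @param reactions a `reaction_set`.
#' @rdname reaction_tsv
#' @export
write_reaction_set <- function(reactions, path) {
  write.table(as.data.frame(reactions), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
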