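#' Canonicalize a structure string
#'
#' Computes the canonical key used throughout the package to decide whether
#' two structure strings describe the same 2D molecule. The policy follows
#' the unification rules of large biochemical databases: stereochemical
#' descriptors are stripped (the package does not distinguish stereoisomers),
#' aromatic systems are perceived so that resonance/kekule forms collapse,
#' and simple charged acid/base groups (carboxylates, protonated amines, ...)
#' are neutralized so that dissociated states of one compound merge. The key
#' is the OpenBabel canonical SMILES of the normalized structure.
#'
#' @param structure a SMILES string.
#' @param neutralize neutralize simple +1/-1 acid/base centers before
#'   canonicalization (default `TRUE`).
#' @return the canonical key (character scalar).
#' @examples
#' \dontrun{
#' canonicalize("OCC") == canonicalize("CCO")      # TRUE
#' canonicalize("C/C=C/O") == canonicalize("C/C=C\\O")  # TRUE, 2D policy
#' }
#' @export
canonicalize <- function(structure, neutralize = TRUE) {
  mol <- mol_from_smiles(structure)
  if (neutralize) mol <- neutralize_mol(mol)
  mol_to_smiles(mol)
}

SCOPES <- c("biological", "bioactive", "chemical")

strongest_scope <- function(scopes) {
  scopes <- scopes[!is.na(scopes)]
  SCOPES[min(match(scopes, SCOPES))]
}

count_wildcards <- function(structure) {
  # wildcard / dummy atoms written as * (optionally bracketed)
  lengths(regmatches(structure, gregexpr("\\*", structure)))[1]
}

#' Admit a structure as a Compound
#'
#' Applies the compound filters used when unifying heterogeneous sources:
#' only defined, single-fragment molecular structures become compounds
#' (no salts or other multi-fragment records, no wildcard/undefined atoms,
#' no repeat-unit polymer notations).
#'
#' @param structure SMILES string.
#' @param scope one of `"biological"`, `"bioactive"`, `"chemical"`.
#' @param xrefs optional data.frame with columns `source_db`, `source_id`.
#' @param id optional identifier; derived from the canonical key when absent.
#' @return an object of class `compound` on success, or a
#'   `compound_rejection` carrying a machine-readable `reason` code among
#'   `multi_fragment`, `undefined_atom`, `polymer`, `parse_error`.
#' @export
admit_compound <- function(structure, scope = "biological", xrefs = NULL,
                           id = NULL) {
  scope <- match.arg(scope, SCOPES)
  reject <- function(reason) {
    structure(list(structure = structure, reason = reason, scope = scope),
              class = "compound_rejection")
  }
  nwild <- tryCatch(count_wildcards(structure), error = function(e) 0L)
  if (nwild >= 2) return(reject("polymer"))
  if (nwild == 1) return(reject("undefined_atom"))
  mol <- tryCatch(mol_from_smiles(structure), carnet_error = function(e) e)
  if (inherits(mol, "condition")) return(reject("parse_error"))
  if (length(mol_components(mol)) > 1) return(reject("multi_fragment"))
  if (any(mol$elem %in% c("*", "R", "R#", "Du", "A", "Q"))) {
    return(reject("undefined_atom"))
  }
  mol <- neutralize_mol(mol)
  key <- mol_to_smiles(mol)
  structure(list(
    id = id %||% paste0("X", fnv1a32(key)),
    canonical_key = key,
    mol = mol,
    composition = mol_composition(mol),
    heavy_atom_count = mol$n,
    molecular_weight = mol_weight(mol),
    scope = scope,
    xrefs = xrefs %||% data.frame(source_db = character(),
                                  source_id = character())
  ), class = "compound")
}

#' @export
print.compound <- function(x, ...) {
  cat(sprintf("<compound %s: %s, %s, %.2f Da, scope %s>\n",
              x$id, x$canonical_key, mol_formula(x$mol),
              x$molecular_weight, x$scope))
  invisible(x)
}

#' @export
print.compound_rejection <- function(x, ...) {
  cat(sprintf("<rejected structure '%s': %s>\n", x$structure, x$reason))
  invisible(x)
}

empty_compound_set <- function() {
  structure(
    data.frame(id = character(), smiles = character(), scope = character(),
               formula = character(), heavy_atoms = integer(),
               mw = numeric(), xrefs = character(),
               stringsAsFactors = FALSE),
    mols = list(), class = c("compound_set", "data.frame"))
}

#' Unify compound records into a deduplicated compound set
#'
#' Merges raw records (one row per source entry) into one compound per
#' canonical key. Stereoisomers, resonance forms and simple dissociated or
#' charged states of the same structure collapse onto a single entry whose
#' cross-references are the union of the merged records. When sources
#' disagree on the scope label, the strongest one wins
#' (biological > bioactive > chemical).
#'
#' @param records data.frame with columns `source_db`, `source_id`,
#'   `structure` (SMILES) and `scope`; an optional `id` column proposes
#'   identifiers.
#' @return a list with elements `compounds` (a `compound_set`: data.frame of
#'   id, smiles (canonical key), scope, formula, heavy_atoms, mw, xrefs, with
#'   parsed molecules attached as an attribute), `report` (per-source record
#'   / unique / duplicate / rejection counts) and `rejections`.
#' @export
unify_compounds <- function(records) {
  stopifnot(all(c("source_db", "source_id", "structure", "scope") %in%
                  names(records)))
  if (is.null(records$id)) records$id <- NA_character_
  n <- nrow(records)
  keys <- character(n)
  reasons <- character(n)
  comps <- vector("list", n)
  for (i in seq_len(n)) {
    cp <- admit_compound(records$structure[i], records$scope[i])
    if (inherits(cp, "compound_rejection")) {
      reasons[i] <- cp$reason
      keys[i] <- NA_character_
    } else {
      comps[[i]] <- cp
      keys[i] <- cp$canonical_key
      reasons[i] <- ""
    }
  }
  ok <- which(!is.na(keys))
  ukeys <- lex_sort(unique(keys[ok]))
  rows <- vector("list", length(ukeys))
  mols <- vector("list", length(ukeys))
  ids <- character(length(ukeys))
  for (j in seq_along(ukeys)) {
    idx <- ok[keys[ok] == ukeys[j]]
    prop <- records$id[idx]
    prop <- prop[!is.na(prop) & nzchar(prop)]
    ids[j] <- if (length(prop) > 0) lex_sort(prop)[1] else
      paste0("X", fnv1a32(ukeys[j]))
    cp <- comps[[idx[1]]]
    # re-parse from the canonical key so the stored molecule (atom order,
    # kekule assignment) is independent of which record came first
    cp$mol <- mol_from_smiles(ukeys[j])
    xr <- unique(data.frame(source_db = records$source_db[idx],
                            source_id = records$source_id[idx],
                            stringsAsFactors = FALSE))
    xr <- xr[order(xr$source_db, xr$source_id, method = "radix"), ,
             drop = FALSE]
    rows[[j]] <- data.frame(
      id = ids[j], smiles = ukeys[j],
      scope = strongest_scope(records$scope[idx]),
      formula = mol_formula(cp$mol),
      heavy_atoms = cp$heavy_atom_count,
      mw = cp$molecular_weight,
      xrefs = paste(paste0(xr$source_db, ":", xr$source_id), collapse = ";"),
      stringsAsFactors = FALSE)
    mols[[j]] <- cp$mol
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE))) %||%
    empty_compound_set()
  out <- out[order(out$id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mols") <- setNames(mols, ids)[out$id]
  # alias map: every proposed record id resolves to the merged compound id
  alias_src <- character(0); alias_dst <- character(0)
  for (j in seq_along(ukeys)) {
    idx <- ok[keys[ok] == ukeys[j]]
    prop <- unique(records$id[idx])
    prop <- prop[!is.na(prop) & nzchar(prop)]
    alias_src <- c(alias_src, prop)
    alias_dst <- c(alias_dst, rep(ids[j], length(prop)))
  }
  attr(out, "aliases") <- setNames(alias_dst, alias_src)
  class(out) <- c("compound_set", "data.frame")

  reason_levels <- c("multi_fragment", "undefined_atom", "polymer",
                     "parse_error")
  report <- do.call(rbind, lapply(split(seq_len(n), records$source_db),
    function(idx) {
      k <- keys[idx]
      admitted <- sum(!is.na(k))
      rej <- table(factor(reasons[idx][reasons[idx] != ""],
                          levels = reason_levels))
      cbind(data.frame(source_db = records$source_db[idx[1]],
                       n_records = length(idx),
                       n_unique = length(unique(k[!is.na(k)])),
                       n_duplicates = admitted - length(unique(k[!is.na(k)])),
                       n_rejected = sum(!is.na(match(reasons[idx],
                                                     reason_levels))),
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(rej)))
    }))
  rownames(report) <- NULL
  rejections <- data.frame(structure = records$structure[reasons != ""],
                           source_db = records$source_db[reasons != ""],
                           reason = reasons[reasons != ""],
                           stringsAsFactors = FALSE)
  list(compounds = out, report = report, rejections = rejections)
}

#' @export
print.compound_set <- function(x, ...) {
  cat(sprintf("<compound_set: %d compounds (%s)>\n", nrow(x),
              paste(sprintf("%s %d", names(table(x$scope)), table(x$scope)),
                    collapse = ", ")))
  if (nrow(x) > 0) print.data.frame(head(as.data.frame(x), 10))
  invisible(x)
}

compound_mols <- function(compounds) attr(compounds, "mols")

#' Read / write compound tables
#'
#' Compound TSV files have header columns `id`, `smiles`, `scope`,
#' `source_db`, `source_id` (UTF-8, tab-separated).
#'
#' @param path file path.
#' @rdname compound_tsv
#' @export
read_compound_records <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "smiles"] <- "structure"
  # unified-set exports omit per-record source columns; derive them
  if (is.null(df$source_db)) df$source_db <- rep("input", nrow(df))
  if (is.null(df$source_id)) df$source_id <- df$id
  if (is.null(df$scope)) df$scope <- rep("biological", nrow(df))
  df
}

#' @param compounds a `compound_set`.
#' @rdname compound_tsv
#' @export
write_compound_set <- function(compounds, path) {
  write.table(as.data.frame(compounds), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @param report a merge report from [unify_compounds()].
#' @rdname compound_tsv
#' @export
write_merge_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# resolve possibly-aliased compound ids (ids of records that merged into
# another entry during unification) to the ids of the unified set; unknown
# ids become NA
resolve_compound_ids <- function(compounds, ids) {
  out <- ifelse(ids %in% compounds$id, ids, NA_character_)
  al <- attr(compounds, "aliases")
  miss <- which(is.na(out))
  if (length(miss) > 0 && !is.null(al)) {
    out[miss] <- unname(al[ids[miss]])
  }
  out
}

# look up parsed molecule for a compound id
get_mol <- function(compounds, id) {
  m <- attr(compounds, "mols")[[id]]
  if (is.null(m)) stop_carnet(sprintf("unknown compound id '%s'", id),
                              "carnet_lookup_error")
  m
}
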