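# Internal molecular-graph representation.
#
# A `cmol` is a heavy-atom graph: element symbols, formal charges, implicit
# hydrogen counts and an integer bond-order matrix. All chemistry perception
# (SMILES parsing, aromaticity, canonical SMILES) is delegated to OpenBabel
# through ChemmineOB; this file only moves structures between that toolkit
# and the matrix form the rule engine works on. The V2000 molblock text is
# written/read directly because the rule engine needs formal charges
# ("M  CHG" lines) and tolerates zero-bond records.

OB_ERR_PATTERNS <- "Open Babel Error"

ob_convert <- function(from, to, text, add_h = FALSE) {
  tryCatch(suppressWarnings({
    if (add_h) {
      ChemmineOB::convertFormat(from, to, text,
                                options = data.frame(names = "h", args = ""))
    } else {
      ChemmineOB::convertFormat(from, to, text)
    }
  }), error = function(e) "")
}

strip_stereo <- function(smiles) {
  # 2D-only policy: drop cis/trans slashes (plain single bonds) and
  # tetrahedral @/@@ marks before canonicalization.
  gsub("@", "", gsub("[/\\\\]", "", smiles))
}

# Standard atomic weights for the elements the engine supports.
ATOMIC_MASS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.086, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, Fe = 55.845, Se = 78.971,
  Br = 79.904, I = 126.904
)

# Allowed total valence (bond-order sum + hydrogens) per element and charge.
allowed_valences <- function(elem, chg) {
  base <- switch(elem,
    H = 1, C = 4, B = 3, Si = 4,
    N = 3, P = c(3, 5),
    O = 2, S = c(2, 4, 6), Se = c(2, 4, 6),
    F = 1, Cl = c(1, 3, 5, 7), Br = c(1, 3, 5, 7), I = c(1, 3, 5, 7),
    Na = 1, K = 1, Mg = 2, Ca = 2, Fe = c(2, 3),
    NULL)
  if (is.null(base)) return(NULL)
  # cations of the N/O groups gain a bond, anions lose one (N+ 4, N- 2,
  # O- 1, O+ 3, S- 1, ...)
  if (elem %in% c("N", "P", "O", "S", "Se")) base <- base + chg
  if (elem %in% c("F", "Cl", "Br", "I") && chg == -1) base <- 0
  if (elem %in% c("Na", "K") && chg == 1) base <- 0
  base[base >= 0]
}

new_cmol <- function(elem, chg, hyd, bond) {
  stopifnot(length(elem) == length(chg), length(elem) == length(hyd),
            nrow(bond) == length(elem), ncol(bond) == length(elem))
  structure(list(elem = elem, chg = as.integer(chg), hyd = as.integer(hyd),
                 bond = bond, n = length(elem)),
            class = "cmol")
}

#' @export
print.cmol <- function(x, ...) {
  cat(sprintf("<cmol: %d heavy atoms, formula %s>\n", x$n, mol_formula(x)))
  invisible(x)
}

# ---- V2000 molblock text <-> cmol ------------------------------------------

# Parse one V2000 record (character vector of lines, hydrogens explicit)
# into a cmol with hydrogens folded into per-atom counts.
parse_molblock <- function(lines) {
  counts <- lines[4]
  natoms <- as.integer(substr(counts, 1, 3))
  nbonds <- as.integer(substr(counts, 4, 6))
  if (is.na(natoms) || natoms < 1) {
    stop_carnet("molblock with no atoms", "carnet_parse_error")
  }
  at <- lines[5:(4 + natoms)]
  elem <- trimws(substr(at, 32, 34))
  chg <- integer(natoms)
  bond_full <- matrix(0L, natoms, natoms)
  if (nbonds > 0) {
    bl <- lines[(5 + natoms):(4 + natoms + nbonds)]
    i <- as.integer(substr(bl, 1, 3))
    j <- as.integer(substr(bl, 4, 6))
    o <- as.integer(substr(bl, 7, 9))
    for (k in seq_len(nbonds)) {
      bond_full[i[k], j[k]] <- o[k]
      bond_full[j[k], i[k]] <- o[k]
    }
  }
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    toks <- as.integer(strsplit(trimws(substring(ln, 7)), "\\s+")[[1]])
    nn <- toks[1]
    for (k in seq_len(nn)) {
      chg[toks[2 * k]] <- toks[2 * k + 1]
    }
  }
  heavy <- which(elem != "H")
  if (length(heavy) == 0) {
    stop_carnet("molecule has no heavy atoms", "carnet_parse_error")
  }
  hyd <- vapply(heavy, function(a) sum(elem[bond_full[a, ] > 0] == "H"), 0L)
  new_cmol(elem[heavy], chg[heavy], hyd, bond_full[heavy, heavy, drop = FALSE])
}

split_sdf_records <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  ends <- grep("^\\$\\$\\$\\$", lines)
  starts <- c(1, head(ends, -1) + 1)
  Map(function(s, e) lines[s:(e - 1)], starts, ends)
}

# Serialize a cmol to V2000 with explicit hydrogens and M CHG lines.
write_molblock <- function(mol) {
  n <- mol$n
  nh <- sum(mol$hyd)
  natoms <- n + nh
  atom_lines <- character(natoms)
  fmt_atom <- function(el) {
    sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0", el)
  }
  for (a in seq_len(n)) atom_lines[a] <- fmt_atom(mol$elem[a])
  bond_lines <- character(0)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (b > a && mol$bond[a, b] > 0) {
        bond_lines <- c(bond_lines, sprintf("%3d%3d%3d  0  0  0  0", a, b, mol$bond[a, b]))
      }
    }
  }
  hidx <- n
  for (a in seq_len(n)) {
    if (mol$hyd[a] > 0) {
      for (k in seq_len(mol$hyd[a])) {
        hidx <- hidx + 1
        atom_lines[hidx] <- fmt_atom("H")
        bond_lines <- c(bond_lines, sprintf("%3d%3d  1  0  0  0  0", a, hidx))
      }
    }
  }
  chg_lines <- character(0)
  charged <- which(mol$chg != 0)
  if (length(charged) > 0) {
    for (grp in split(charged, ceiling(seq_along(charged) / 8))) {
      chg_lines <- c(chg_lines,
        paste0("M  CHG", sprintf("%3d", length(grp)),
               paste0(sprintf("%4d%4d", grp, mol$chg[grp]), collapse = "")))
    }
  }
  paste(c("", " carnet", "",
          sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", natoms, length(bond_lines)),
          atom_lines, bond_lines, chg_lines, "M  END", "$$$$", ""),
        collapse = "\n")
}

# ---- SMILES <-> cmol --------------------------------------------------------

mol_from_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    stop_carnet("empty or missing structure string", "carnet_parse_error")
  }
  smi <- strip_stereo(trimws(smiles))
  sdf <- ob_convert("SMI", "SDF", paste0(smi, "\n"), add_h = TRUE)
  if (!nzchar(sdf) || !grepl("V2000", sdf, fixed = TRUE)) {
    stop_carnet(sprintf("cannot parse structure: '%s'", smiles),
                "carnet_parse_error", structure_string = smiles)
  }
  parse_molblock(split_sdf_records(sdf)[[1]])
}

# canonical SMILES of a cmol (OpenBabel canonical dialect, title stripped)
mol_to_smiles <- function(mol) {
  out <- ob_convert("SDF", "CAN", write_molblock(mol))
  out <- trimws(strsplit(out, "\n", fixed = TRUE)[[1]][1])
  out <- sub("\t.*$", "", out)
  if (!nzchar(out)) {
    stop_carnet("OpenBabel could not serialize molecule", "carnet_parse_error")
  }
  out
}

# Neutralize simple acid/base groups in place: -1 centers that can accept a
# proton (O, S, N) gain one H; +1 centers that carry a proton (N, O, S with
# >= 1 H) lose one. Quaternary cations and metal ions are left untouched.
neutralize_mol <- function(mol) {
  for (a in seq_len(mol$n)) {
    if (mol$chg[a] == -1 && mol$elem[a] %in% c("O", "S", "N")) {
      mol$hyd[a] <- mol$hyd[a] + 1L
      mol$chg[a] <- 0L
    } else if (mol$chg[a] == 1 && mol$elem[a] %in% c("N", "O", "S") &&
               mol$hyd[a] >= 1) {
      mol$hyd[a] <- mol$hyd[a] - 1L
      mol$chg[a] <- 0L
    }
  }
  mol
}

mol_components <- function(mol) {
  g <- igraph::graph_from_adjacency_matrix(mol$bond > 0, mode = "undirected")
  split(seq_len(mol$n), igraph::components(g)$membership)
}

mol_subset <- function(mol, idx) {
  new_cmol(mol$elem[idx], mol$chg[idx], mol$hyd[idx],
           mol$bond[idx, idx, drop = FALSE])
}

# Disjoint union of two cmols; returns combined mol and index offset of `b`.
mol_union <- function(a, b) {
  n <- a$n + b$n
  bond <- matrix(0L, n, n)
  bond[seq_len(a$n), seq_len(a$n)] <- a$bond
  bond[a$n + seq_len(b$n), a$n + seq_len(b$n)] <- b$bond
  new_cmol(c(a$elem, b$elem), c(a$chg, b$chg), c(a$hyd, b$hyd), bond)
}

mol_formula <- function(mol) {
  comp <- mol_composition(mol)
  els <- names(comp)
  ord <- c(intersect(c("C", "H"), els), lex_sort(setdiff(els, c("C", "H"))))
  paste0(vapply(ord, function(e) {
    if (comp[[e]] == 1) e else paste0(e, comp[[e]])
  }, ""), collapse = "")
}

# element -> count map including hydrogen
mol_composition <- function(mol) {
  comp <- tapply(rep(1L, mol$n), mol$elem, sum)
  comp <- as.list(comp)
  h <- sum(mol$hyd)
  if (h > 0) comp$H <- (comp$H %||% 0L) + h
  comp[order(names(comp), method = "radix")]
}

mol_weight <- function(mol) {
  comp <- mol_composition(mol)
  unknown <- setdiff(names(comp), names(ATOMIC_MASS))
  if (length(unknown) > 0) {
    stop_carnet(sprintf("no atomic mass for element(s): %s",
                        paste(unknown, collapse = ", ")),
                "carnet_parse_error")
  }
  sum(unlist(comp) * ATOMIC_MASS[names(comp)])
}

# total valence (bond orders + hydrogens) of each heavy atom
mol_valences <- function(mol) {
  rowSums(mol$bond) + mol$hyd
}

mol_valence_ok <- function(mol) {
  for (a in seq_len(mol$n)) {
    allowed <- allowed_valences(mol$elem[a], mol$chg[a])
    if (is.null(allowed)) next  # unknown element: no constraint enforced
    if (!(mol_valences(mol)[a] %in% allowed)) return(FALSE)
  }
  TRUE
}
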