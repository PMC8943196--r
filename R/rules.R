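# Generalized enzymatic reaction rules as bond-electron matrices (BEM).
#
# A rule describes a reactive-site pattern (elements, charges, minimum
# hydrogen counts, required bond orders between pattern atoms) together with
# a difference matrix stating how bond orders change, a per-atom hydrogen
# delta, and fixed co-substrate / co-product molecule templates. Rules are
# bidirectional: the reverse rule is (site + delta, -delta).
#
# Rule file format (plain text, '#' comments allowed):
#
#   RULE <rule_id>
#   EC <three-level EC class, e.g. 1.1.3>
#   NAME <free text>
#   ATOM <i> <element> <charge> <min_h> <src_frag> <dst_frag>
#   ...                  # src_frag: S (substrate) or C1, C2 ... cosubstrate
#                        # dst_frag: P (main product) or Q1, Q2 ... coproduct
#   SITE                 # symmetric matrix, one row per line; the diagonal
#   . 1 0 ...            # holds non-bonding electron counts and is
#   ...                  # unconstrained ('.') in this rule dialect
#   DELTA                # symmetric integer matrix, zero diagonal
#   0 1 0 ...
#   ...
#   HDELTA <d1> <d2> ... # hydrogen count change per pattern atom
#   COSUB <frag> <smiles>
#   COPROD <frag> <smiles>
#   END

new_rule <- function(rule_id, ec3, name, elem, chg, min_h, src_frag,
                     dst_frag, site, delta, hdelta, cosub, coprod,
                     direction = "forward") {
  r <- structure(list(
    rule_id = rule_id, ec3 = ec3, name = name,
    elem = elem, chg = as.integer(chg), min_h = as.integer(min_h),
    src_frag = src_frag, dst_frag = dst_frag,
    site = site, delta = delta, hdelta = as.integer(hdelta),
    cosub = cosub, coprod = coprod, direction = direction
  ), class = "reaction_rule")
  validate_rule(r)
  r
}

#' Validate a reaction rule
#'
#' Checks the BEM invariants: square symmetric site and delta matrices of
#' matching dimension, off-diagonal bond orders in 0..3, no negative bond
#' order and no impossible valence after applying the difference matrix, and
#' non-negative hydrogen counts on both sides.
#'
#' @param rule a `reaction_rule`.
#' @return the rule, invisibly; errors on violation.
#' @export
validate_rule <- function(rule) {
  n <- length(rule$elem)
  fail <- function(msg) {
    stop_carnet(sprintf("rule %s: %s", rule$rule_id, msg),
                "carnet_rule_error")
  }
  if (!all(dim(rule$site) == c(n, n))) fail("site matrix dimension mismatch")
  if (!all(dim(rule$delta) == c(n, n))) fail("delta matrix dimension mismatch")
  off <- rule$site[row(rule$site) != col(rule$site)]
  if (anyNA(off) || any(off < 0 | off > 3)) {
    fail("site off-diagonal bond orders must be in 0..3")
  }
  if (!isSymmetric(unname(rule$site), tol = 0) && # diagonal NAs allowed
      !identical(rule$site[lower.tri(rule$site)],
                 t(rule$site)[lower.tri(rule$site)])) {
    fail("site matrix not symmetric")
  }
  if (!identical(rule$delta, t(rule$delta))) fail("delta matrix not symmetric")
  if (any(diag(rule$delta) != 0)) fail("delta diagonal must be zero")
  prod_bonds <- off_diag(rule$site) + off_diag(rule$delta)
  if (any(prod_bonds < 0)) fail("site + delta yields negative bond order")
  if (any(prod_bonds > 3)) fail("site + delta yields bond order above 3")
  if (length(rule$hdelta) != n) fail("hdelta length mismatch")
  if (any(rule$min_h + rule$hdelta < 0)) {
    fail("hydrogen count would go negative at minimum match")
  }
  for (f in names(rule$cosub)) {
    if (!any(rule$src_frag == f)) fail(sprintf("no atoms tagged %s", f))
  }
  for (f in names(rule$coprod)) {
    if (!any(rule$dst_frag == f)) fail(sprintf("no atoms tagged %s", f))
  }
  invisible(rule)
}

off_diag <- function(m) m[row(m) != col(m)]

#' @export
print.reaction_rule <- function(x, ...) {
  cat(sprintf("<rule %s (EC %s.-, %s): %d pattern atoms, %s>\n",
              x$rule_id, x$ec3, x$direction, length(x$elem), x$name))
  invisible(x)
}

#' Reverse a reaction rule
#'
#' The reverse rule recognizes the product pattern (site + delta) and applies
#' the negated difference matrix; co-substrates and co-products swap roles,
#' as do the fragment labels. Applying a rule and then its reverse at the
#' image site recovers the original substrate.
#'
#' @param rule a `reaction_rule`.
#' @return the reversed `reaction_rule`.
#' @export
reverse_rule <- function(rule) {
  site2 <- rule$site  # diagonal (possibly NA) carried over unchanged
  site2[row(site2) != col(site2)] <-
    off_diag(rule$site) + off_diag(rule$delta)
  # product-side labels become source-side labels: P -> S, Qk -> Ck
  relab_src <- function(x) sub("^P$", "S", sub("^Q", "C", x))
  relab_dst <- function(x) sub("^S$", "P", sub("^C", "Q", x))
  new_rule(
    rule_id = paste0(rule$rule_id, "_rev"),
    ec3 = rule$ec3,
    name = paste(rule$name, "(reverse)"),
    elem = rule$elem, chg = rule$chg,
    min_h = pmax(0L, rule$min_h + rule$hdelta),
    src_frag = relab_src(rule$dst_frag),
    dst_frag = relab_dst(rule$src_frag),
    site = site2, delta = -rule$delta, hdelta = -rule$hdelta,
    cosub = setNames(rule$coprod, relab_src(names(rule$coprod))),
    coprod = setNames(rule$cosub, relab_dst(names(rule$cosub))),
    direction = if (rule$direction == "forward") "reverse" else "forward")
}

#' Read a rule library file
#'
#' Parses the plain-text rule format documented in the package (see the
#' bundled `toy_rules.txt` for a worked library) and validates every rule.
#'
#' @param path rule file path.
#' @return named list of `reaction_rule` objects.
#' @export
read_rules <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  rules <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "RULE ")) {
      stop_carnet(sprintf("expected RULE, got '%s'", lines[i]),
                  "carnet_rule_error")
    }
    rid <- sub("^RULE\\s+", "", lines[i]); i <- i + 1
    ec <- NA_character_; nm <- ""
    atom <- list(); site <- NULL; delta <- NULL; hdelta <- NULL
    cosub <- list(); coprod <- list()
    while (i <= length(lines) && lines[i] != "END") {
      tok <- strsplit(lines[i], "\\s+")[[1]]
      if (tok[1] == "EC") {
        ec <- tok[2]; i <- i + 1
      } else if (tok[1] == "NAME") {
        nm <- paste(tok[-1], collapse = " "); i <- i + 1
      } else if (tok[1] == "ATOM") {
        atom[[as.integer(tok[2])]] <- tok[3:7]; i <- i + 1
      } else if (tok[1] %in% c("SITE", "DELTA")) {
        n <- length(atom)
        m <- matrix(NA_real_, n, n)
        for (r in seq_len(n)) {
          i <- i + 1
          vals <- strsplit(lines[i], "\\s+")[[1]]
          m[r, ] <- suppressWarnings(as.numeric(ifelse(vals == ".", NA, vals)))
        }
        if (tok[1] == "SITE") site <- m else delta <- m
        i <- i + 1
      } else if (tok[1] == "HDELTA") {
        hdelta <- as.integer(tok[-1]); i <- i + 1
      } else if (tok[1] == "COSUB") {
        cosub[[tok[2]]] <- tok[3]; i <- i + 1
      } else if (tok[1] == "COPROD") {
        coprod[[tok[2]]] <- tok[3]; i <- i + 1
      } else {
        stop_carnet(sprintf("rule %s: unknown directive '%s'", rid, tok[1]),
                    "carnet_rule_error")
      }
    }
    i <- i + 1 # END
    am <- do.call(rbind, atom)
    delta[is.na(delta)] <- 0
    rules[[rid]] <- new_rule(
      rule_id = rid, ec3 = ec, name = nm,
      elem = am[, 1], chg = as.integer(am[, 2]), min_h = as.integer(am[, 3]),
      src_frag = am[, 4], dst_frag = am[, 5],
      site = site, delta = delta, hdelta = hdelta,
      cosub = cosub, coprod = coprod)
  }
  rules
}
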