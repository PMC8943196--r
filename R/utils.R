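#' @importFrom stats setNames
#' @importFrom utils head read.delim write.table
NULL

# 32-bit FNV-1a over a string, returned as 8-char hex. Used only to derive
# stable, readable identifiers for novel compounds; not cryptographic.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  # keep h as a double split into 16-bit halves: bitwXor only takes
  # values below 2^31 and FNV offsets/products exceed that
  lo <- 0x9DC5; hi <- 0x811C
  for (b in bytes) {
    lo <- bitwXor(lo, b)
    prod <- lo * 16777619 + ((hi * 16777619) %% 65536) * 65536
    prod <- prod %% 4294967296
    lo <- prod %% 65536
    hi <- (prod - lo) / 65536
  }
  sprintf("%04X%04X", hi, lo)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_carnet <- function(msg, class, ...) {
  stop(structure(class = c(class, "carnet_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

# Deterministic lexicographic comparison helpers (C locale, byte order)
lex_lt <- function(a, b) {
  withCallingHandlers({
    old <- Sys.getlocale("LC_COLLATE")
    on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
    suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
    a < b
  })
}

lex_sort <- function(x) x[order(x, method = "radix")]

# Compare two node-id sequences lexicographically; TRUE if a < b.
seq_lt <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] != b[i]) return(order(c(a[i], b[i]), method = "radix")[1] == 1)
  }
  length(a) < length(b)
}
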