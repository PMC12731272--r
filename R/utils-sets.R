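# Canonical taxa-set helpers and bitset machinery shared across modules.
# Sets of taxa are represented as sorted (C-locale radix order) unique
# character vectors so that set-valued outputs are deterministic and
# directly comparable; internally, subset enumeration uses multi-word
# integer bitmasks (30 payload bits per word, safe for 32-bit R integers).

.WORD_BITS <- 30L

#' Canonicalize a taxa set
#'
#' Sorts and deduplicates a character vector of taxon labels using
#' locale-independent radix order, the canonical representation used for all
#' set-valued results in the package.
#'
#' @param x character vector (or NULL / empty for the empty set).
#' @return sorted unique character vector.
#' @export
canonicalSet <- function(x) {
  if (is.null(x) || length(x) == 0L) return(character())
  sort(unique(as.character(x)), method = "radix")
}

.setKey <- function(x) paste(x, collapse = "\x1f")

.keyList <- function(sets) vapply(sets, .setKey, character(1L))

# order a list of canonical sets by cardinality, then lexicographic key
.orderSets <- function(sets) {
  sizes <- lengths(sets)
  keys <- .keyList(sets)
  sets[order(sizes, keys, method = "radix")]
}

.uniqueSets <- function(sets) {
  if (length(sets) == 0L) return(list())
  sets[!duplicated(.keyList(sets))]
}

# --- bitset helpers -------------------------------------------------------

.nWords <- function(n) max(1L, as.integer(ceiling(n / .WORD_BITS)))

# column bitmask matrix (nWords x length(idxList)); each entry a set of
# indices in 1..n
.masksFromIndices <- function(idxList, n) {
  w <- .nWords(n)
  out <- matrix(0L, nrow = w, ncol = length(idxList))
  for (j in seq_along(idxList)) {
    for (i in idxList[[j]]) {
      word <- (i - 1L) %/% .WORD_BITS + 1L
      bit <- (i - 1L) %% .WORD_BITS
      out[word, j] <- bitwOr(out[word, j], bitwShiftL(1L, bit))
    }
  }
  out
}

.maskOr <- function(a, b) bitwOr(a, b)

.maskIsZero <- function(a) all(a == 0L)

.maskAndNot <- function(a, b) bitwAnd(a, bitwNot(b))

.maskAnd <- function(a, b) bitwAnd(a, b)

# indices of set bits of a single-word mask (used for subset enumeration
# where n <= 30)
.bitsOf <- function(mask, n) which(bitwAnd(bitwShiftR(mask, 0:(n - 1L)), 1L) == 1L)

# seeded evaluation that restores the caller's RNG state
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}
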