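# Organization predicates and enumeration.
#
# An organization is a set of taxa that is closed (trivial here: taxa are
# self-replicators) and self-maintaining (every member's every required food
# resource is produced by some member), and -- when toxins are applied --
# contains no taxon sensitive to a toxin produced within the set.  The empty
# set is always an organization.

#' Is a taxa set self-maintaining?
#'
#' TRUE iff every required resource of every member is produced by some
#' member of the set.  Since one signed cell encodes one relation, a taxon
#' never supplies a resource it itself requires; supply comes from other
#' members (or the quantifier is vacuous when nothing is required).
#'
#' @param s character vector of taxon labels (the empty set is allowed and
#'   is trivially self-maintaining).
#' @param model a [CRTModel-class].
#' @return logical scalar.
#' @examples
#' fig1 <- crtFixture("fig1")
#' isSelfMaintaining(c("b", "c", "d"), fig1)  # TRUE
#' isSelfMaintaining(c("b", "c"), fig1)       # FALSE: f4 (and f1) unproduced
#' @export
isSelfMaintaining <- function(s, model) {
  s <- .checkTaxaSet(s, model)
  if (length(s) == 0L) return(TRUE)
  idx <- match(s, taxa(model))
  mk <- .modelMasks(model)
  req <- .rowOr(mk$req, idx)
  prod <- .rowOr(mk$prod, idx)
  .maskIsZero(.maskAndNot(req, prod))
}

.rowOr <- function(maskMat, idx) {
  out <- rep(0L, nrow(maskMat))
  for (i in idx) out <- bitwOr(out, maskMat[, i])
  out
}

.checkTaxaSet <- function(s, model) {
  s <- canonicalSet(s)
  unknown <- setdiff(s, taxa(model))
  if (length(unknown))
    stop("unknown taxon label: ", paste(unknown, collapse = ", "))
  s
}

#' Toxin conflicts within a taxa set
#'
#' Lists every (producer, toxin, victim) triple violating toxin
#' compatibility inside the set: some member produces a toxin to which
#' another member is sensitive.  An empty result means condition (2) of the
#' organization definition holds.
#'
#' @inheritParams isSelfMaintaining
#' @return data.frame with character columns \code{producer}, \code{toxin},
#'   \code{victim} (zero rows when compatible).
#' @examples
#' toxinConflicts(c("a", "c"), crtFixture("fig1"))  # c -> t1 -> a
#' @export
toxinConflicts <- function(s, model) {
  s <- .checkTaxaSet(s, model)
  tt <- model@toxinTable
  out <- list(producer = character(), toxin = character(),
              victim = character())
  if (length(s) && ncol(tt)) {
    sub <- tt[s, , drop = FALSE]
    for (b in colnames(tt)) {
      producers <- s[sub[, b] == 1L]
      victims <- s[sub[, b] == -1L]
      if (length(producers) && length(victims)) {
        grid <- expand.grid(producer = producers, victim = victims,
                            stringsAsFactors = FALSE)
        out$producer <- c(out$producer, grid$producer)
        out$toxin <- c(out$toxin, rep(b, nrow(grid)))
        out$victim <- c(out$victim, grid$victim)
      }
    }
  }
  data.frame(out, stringsAsFactors = FALSE)
}

#' Organization predicate
#'
#' @inheritParams isSelfMaintaining
#' @param applyToxins logical; when TRUE (default) the set must additionally
#'   be free of internal toxin conflicts.
#' @return logical scalar.
#' @examples
#' fig1 <- crtFixture("fig1")
#' isOrganization(c("a", "b", "c", "e"), fig1, applyToxins = FALSE)  # TRUE
#' isOrganization(c("a", "b", "c", "e"), fig1)                       # FALSE
#' @export
isOrganization <- function(s, model, applyToxins = TRUE) {
  isSelfMaintaining(s, model) &&
    (!applyToxins || nrow(toxinConflicts(s, model)) == 0L)
}

# Per-subset predicate flags for all 2^S subsets, computed by a vectorized
# doubling sweep over taxa.  Subsets are indexed by bitmask + 1 (taxon i of
# taxa(model) is bit i-1).
.subsetFlags <- function(model, maxTaxa = 20L) {
  S <- length(taxa(model))
  if (S > maxTaxa)
    stop(sprintf(paste0("model has %d taxa; brute-force enumeration over 2^%d",
                        " subsets exceeds the cap of %d (use method =",
                        " 'constructive' or raise maxTaxa)"), S, S, maxTaxa))
  mk <- .modelMasks(model)
  n <- bitwShiftL(1L, S)
  wM <- nrow(mk$req); wT <- nrow(mk$tprod)
  reqU <- matrix(0L, wM, n); prodU <- matrix(0L, wM, n)
  tpU <- matrix(0L, wT, n); tsU <- matrix(0L, wT, n)
  if (S > 0L) for (i in seq_len(S)) {
    half <- bitwShiftL(1L, i - 1L)
    src <- seq_len(half)
    dst <- half + src
    reqU[, dst] <- bitwOr(reqU[, src, drop = FALSE], mk$req[, i])
    prodU[, dst] <- bitwOr(prodU[, src, drop = FALSE], mk$prod[, i])
    tpU[, dst] <- bitwOr(tpU[, src, drop = FALSE], mk$tprod[, i])
    tsU[, dst] <- bitwOr(tsU[, src, drop = FALSE], mk$tsens[, i])
  }
  unmet <- matrix(bitwAnd(reqU, bitwNot(prodU)), nrow = wM)
  conflict <- matrix(bitwAnd(tpU, tsU), nrow = wT)
  list(selfMaintaining = colSums(unmet != 0L) == 0L,
       toxinOK = colSums(conflict != 0L) == 0L,
       S = S)
}

.maskToSet <- function(mask, labels) {
  if (mask == 0L) return(character())
  canonicalSet(labels[.bitsOf(mask, length(labels))])
}

.setToMask <- function(s, labels) {
  idx <- match(s, labels)
  m <- 0L
  for (i in idx) m <- bitwOr(m, bitwShiftL(1L, i - 1L))
  m
}

#' Enumerate all organizations of a model
#'
#' Two routes are available.  \code{"bruteforce"} tests the organization
#' predicate on every subset of taxa (vectorized over all 2^S bitmasks;
#' refused above \code{maxTaxa}).  \code{"constructive"} grows minimal
#' self-maintaining sets from per-taxon producer choices, closes the family
#' under pairwise unions to a fixed point, and finally removes sets with
#' internal toxin conflicts; it avoids the full power set and must agree
#' with brute force wherever both run.
#'
#' The empty organization is always included.  Output sets are canonical and
#' ordered by ascending cardinality, then lexicographically.
#'
#' @param model a [CRTModel-class].
#' @param applyToxins logical; filter toxin-conflicted sets (default TRUE).
#' @param method \code{"bruteforce"} or \code{"constructive"}.
#' @param maxTaxa subset-enumeration cap for the brute-force route
#'   (default 20).
#' @return list of character vectors (canonical taxa sets).
#' @examples
#' length(enumerateOrganizations(crtFixture("fig1"), applyToxins = FALSE)) # 10
#' length(enumerateOrganizations(crtFixture("fig1")))                      # 7
#' @export
enumerateOrganizations <- function(model, applyToxins = TRUE,
                                   method = c("bruteforce", "constructive"),
                                   maxTaxa = 20L) {
  method <- match.arg(method)
  if (method == "bruteforce") {
    flags <- .subsetFlags(model, maxTaxa)
    keep <- flags$selfMaintaining & (if (applyToxins) flags$toxinOK else TRUE)
    masks <- which(keep) - 1L
    labels <- taxa(model)
    .orderSets(lapply(masks, .maskToSet, labels = labels))
  } else {
    .enumerateConstructive(model, applyToxins)
  }
}

# Constructive generation: depth-first closure of each taxon under producer
# choices (branching over every producer of the first unmet resource),
# memoized on the taxa bitmask, followed by pairwise union closure (unions
# of self-maintaining sets are self-maintaining) and a final toxin-removal
# pass.  Correctness is defined by equivalence with the brute-force route.
.enumerateConstructive <- function(model, applyToxins = TRUE) {
  labels <- taxa(model)
  S <- length(labels)
  if (S > .WORD_BITS)
    stop("constructive enumeration supports at most ", .WORD_BITS, " taxa")
  mk <- .modelMasks(model)
  pow2 <- bitwShiftL(1L, seq_len(max(S, 1L)) - 1L)
  producersOf <- lapply(seq_len(max(mk$M, 0L)), function(a) {
    word <- (a - 1L) %/% .WORD_BITS + 1L
    bit <- bitwShiftL(1L, (a - 1L) %% .WORD_BITS)
    which(bitwAnd(mk$prod[word, ], bit) != 0L)
  })
  visited <- new.env(parent = emptyenv())
  found <- new.env(parent = emptyenv())
  unionMasks <- function(mask) {
    idx <- .bitsOf(mask, S)
    list(req = .rowOr(mk$req, idx), prod = .rowOr(mk$prod, idx))
  }
  close_ <- function(mask) {
    key <- as.character(mask)
    if (!is.null(visited[[key]])) return(invisible())
    visited[[key]] <- TRUE
    u <- unionMasks(mask)
    unmet <- .maskAndNot(u$req, u$prod)
    if (.maskIsZero(unmet)) {
      found[[key]] <- mask
      return(invisible())
    }
    word <- which(unmet != 0L)[1L]
    bit <- which(bitwAnd(bitwShiftR(unmet[word], 0:(.WORD_BITS - 1L)), 1L) == 1L)[1L]
    a <- (word - 1L) * .WORD_BITS + bit
    for (j in producersOf[[a]]) close_(bitwOr(mask, pow2[j]))
    invisible()
  }
  if (S > 0L) for (i in seq_len(S)) close_(pow2[i])
  fam <- unique(c(0L, unlist(as.list(found), use.names = FALSE)))
  repeat {
    grown <- unique(c(fam, as.vector(outer(fam, fam, bitwOr))))
    if (length(grown) == length(fam)) break
    fam <- grown
  }
  if (applyToxins && mk$T > 0L && length(fam)) {
    wT <- nrow(mk$tprod)
    ok <- rep(TRUE, length(fam))
    tpU <- matrix(0L, wT, length(fam))
    tsU <- matrix(0L, wT, length(fam))
    for (i in seq_len(S)) {
      member <- bitwAnd(fam, pow2[i]) != 0L
      if (any(member)) {
        tpU[, member] <- bitwOr(tpU[, member, drop = FALSE], mk$tprod[, i])
        tsU[, member] <- bitwOr(tsU[, member, drop = FALSE], mk$tsens[, i])
      }
    }
    ok <- colSums(matrix(bitwAnd(tpU, tsU) != 0L, nrow = wT)) == 0L
    fam <- fam[ok]
  }
  .orderSets(lapply(fam, .maskToSet, labels = labels))
}

#' Largest organization generated inside a taxa set
#'
#' Models the rapid action of toxins followed by starvation: first, all taxa
#' sensitive to any toxin produced within the initial set are removed in one
#' pass (they are never re-added, even if the producers later starve); then
#' taxa whose required resources are not supplied by the remaining taxa are
#' removed iteratively, all unsupported taxa per round simultaneously, until
#' a fixed point.  The result is always a toxin-compatible organization and
#' a subset of the input; the operation is idempotent.
#'
#' @param initial character vector of taxon labels.
#' @param model a [CRTModel-class].
#' @return canonical character vector: the generated organization.
#' @examples
#' generateOrganization(c("a", "b", "c", "d", "e"), crtFixture("fig1"))
#' # "b" "c" "d" "e"
#' @export
generateOrganization <- function(initial, model) {
  s <- .checkTaxaSet(initial, model)
  if (length(s) == 0L) return(character())
  mk <- .modelMasks(model)
  labels <- taxa(model)
  idx <- match(s, labels)
  tprodU <- .rowOr(mk$tprod, idx)
  keep <- idx[vapply(idx, function(i)
    .maskIsZero(.maskAnd(mk$tsens[, i], tprodU)), logical(1L))]
  repeat {
    supplied <- .rowOr(mk$prod, keep)
    ok <- vapply(keep, function(i)
      .maskIsZero(.maskAndNot(mk$req[, i], supplied)), logical(1L))
    if (all(ok)) break
    keep <- keep[ok]
  }
  canonicalSet(labels[keep])
}
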