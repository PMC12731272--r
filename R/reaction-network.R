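# Reaction-network view of a CRT model.
#
# The full network keeps resources and toxins explicit: one replicator
# reaction per taxon (consuming its required resources, producing its
# products with a symbolically high coefficient n), one spontaneous-death
# outflow per taxon, and one kill reaction per (sensitive taxon, toxin)
# pair.  The reduced, taxa-only view replaces resources by minimal
# producing sets -- for each taxon, the inclusion-minimal sets of other taxa
# that jointly supply all its required resources.  Enumerating these sets
# is the minimal hitting set problem (NP-hard), hence an exact route with a
# candidate cap and a seeded greedy heuristic.

#' Transform a model into an explicit reaction network
#'
#' @param model a [CRTModel-class].
#' @param n product-side stoichiometric coefficient for resources and
#'   toxins: either the symbolic literal \code{"n"} (default; the analysis
#'   only requires it to be sufficiently high) or a positive integer for
#'   downstream tools needing numbers.
#' @return list of reaction records, each a list with elements \code{kind}
#'   (\code{"replicator"}, \code{"outflow"} or \code{"toxin_kill"}),
#'   \code{educts} and \code{products} (data.frames with \code{species} and
#'   character \code{coeff} columns), and \code{taxon}.
#' @seealso [formatReactions()] for the text rendering.
#' @examples
#' rx <- toReactionNetwork(crtFixture("fig1"))
#' formatReactions(rx)[1:3]
#' @export
toReactionNetwork <- function(model, n = "n") {
  if (!identical(n, "n")) {
    stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
    n <- format(as.integer(n))
  }
  side <- function(species, coeff) data.frame(species = species,
                                              coeff = coeff,
                                              stringsAsFactors = FALSE)
  out <- list()
  for (tx in taxa(model)) {
    p <- taxonProfile(model, tx)
    out[[length(out) + 1L]] <- list(
      kind = "replicator", taxon = tx,
      educts = side(c(tx, p$required), "1"),
      products = side(c(tx, p$produced, p$producedToxins),
                      c("2", rep(n, length(p$produced) +
                                    length(p$producedToxins)))))
  }
  for (tx in taxa(model))
    out[[length(out) + 1L]] <- list(
      kind = "outflow", taxon = tx,
      educts = side(tx, "1"),
      products = side(character(), character()))
  for (tx in taxa(model)) {
    p <- taxonProfile(model, tx)
    for (b in p$sensitiveToxins)
      out[[length(out) + 1L]] <- list(
        kind = "toxin_kill", taxon = tx,
        educts = side(c(tx, b), c("1", "1")),
        products = side(b, "1"))
  }
  out
}

#' Render reactions as text
#'
#' One reaction per line in the form \code{educts -> products} with
#' \code{ + } separators; coefficients other than 1 prefix the species
#' (\code{2 b}, \code{n f3}).
#'
#' @param reactions output of [toReactionNetwork()].
#' @return character vector, one element per reaction.
#' @export
formatReactions <- function(reactions) {
  fmtSide <- function(s) {
    if (nrow(s) == 0L) return("")
    paste(ifelse(s$coeff == "1", s$species, paste(s$coeff, s$species)),
          collapse = " + ")
  }
  vapply(reactions, function(r)
    paste(fmtSide(r$educts), "->", fmtSide(r$products)), character(1L))
}

# All inclusion-minimal subsets of `candidates` (names of coverSets) whose
# covered-label union contains `target`.  Ascending-cardinality subset
# enumeration with superset pruning against already-found minima.
.minimalCovers <- function(coverSets, target) {
  target <- canonicalSet(target)
  if (length(target) == 0L) return(list(character()))
  useful <- names(coverSets)[vapply(coverSets, function(x)
    length(intersect(x, target)) > 0L, logical(1L))]
  if (!all(target %in% unlist(coverSets[useful], use.names = FALSE)))
    return(list())
  n <- length(useful)
  found <- list()
  for (k in seq_len(n)) {
    for (pick in utils::combn(n, k, simplify = FALSE)) {
      cand <- useful[pick]
      if (length(found) && any(vapply(found, function(f) all(f %in% cand),
                                      logical(1L))))
        next
      if (all(target %in% unlist(coverSets[cand], use.names = FALSE)))
        found[[length(found) + 1L]] <- canonicalSet(cand)
    }
    # every cover of size > k is a superset of some minimal cover unless it
    # avoids all found ones; stop early once every useful candidate set of
    # the next size must contain a found minimum -- cheap check skipped,
    # enumeration is already capped upstream
  }
  .orderSets(found)
}

.producedBy <- function(model) {
  prof <- lapply(taxa(model), taxonProfile, model = model)
  names(prof) <- taxa(model)
  lapply(prof, `[[`, "produced")
}

#' Exact minimal producing sets of a taxon
#'
#' All inclusion-minimal sets of supplier taxa whose joint production covers
#' the taxon's required resources (the minimal hitting set computation).
#' Complete but exponential in the number of candidate suppliers, hence the
#' cap.
#'
#' @param model a [CRTModel-class].
#' @param taxon consumer taxon label.
#' @param maxCandidates refuse exact search when more than this many taxa
#'   produce at least one required resource (default 20); the error suggests
#'   the greedy route.
#' @return list of producing-set records (\code{consumer}, \code{suppliers},
#'   \code{covered}); a single empty-supplier record when nothing is
#'   required, an empty list when some required resource has no producer.
#' @examples
#' ps <- minimalProducingSetsExact(crtFixture("fig1"), "b")
#' lapply(ps, `[[`, "suppliers")   # {a,d}, {a,e}, {c,d}
#' @export
minimalProducingSetsExact <- function(model, taxon, maxCandidates = 20L) {
  if (!taxon %in% taxa(model)) stop("unknown taxon label: ", taxon)
  need <- taxonProfile(model, taxon)$required
  prod <- .producedBy(model)
  prod <- prod[setdiff(names(prod), taxon)]
  useful <- sum(vapply(prod, function(x)
    length(intersect(x, need)) > 0L, logical(1L)))
  if (useful > maxCandidates)
    stop(sprintf(paste0("capacity error: %d candidate suppliers exceed the ",
                        "cap of %d; use minimalProducingSetGreedy()"),
                 useful, maxCandidates))
  lapply(.minimalCovers(prod, need), function(s)
    list(consumer = taxon, suppliers = s, covered = need))
}

#' Greedy near-minimal producing set
#'
#' Iteratively adds the supplier covering the largest number of still-unmet
#' required resources, breaking ties by a seeded uniform draw, then prunes
#' redundant suppliers element-wise so the result is locally minimal (no
#' single supplier can be dropped).  Global minimality is not guaranteed.
#'
#' @inheritParams minimalProducingSetsExact
#' @param seed integer seed for tie-breaking.
#' @return one producing-set record (\code{consumer}, \code{suppliers},
#'   \code{covered}).
#' @examples
#' minimalProducingSetGreedy(crtFixture("fig1"), "b", seed = 1)$suppliers
#' @export
minimalProducingSetGreedy <- function(model, taxon, seed = NULL) {
  if (!taxon %in% taxa(model)) stop("unknown taxon label: ", taxon)
  need <- taxonProfile(model, taxon)$required
  prod <- .producedBy(model)
  prod <- prod[setdiff(names(prod), taxon)]
  orphan <- setdiff(need, unlist(prod, use.names = FALSE))
  if (length(orphan))
    stop("infeasible: no taxon produces required resource ",
         paste(orphan, collapse = ", "))
  .withSeed(seed, {
    chosen <- character()
    uncovered <- need
    while (length(uncovered)) {
      gain <- vapply(prod, function(x) length(intersect(x, uncovered)),
                     integer(1L))
      best <- names(gain)[gain == max(gain)]
      pick <- if (length(best) == 1L) best else
        best[sample.int(length(best), 1L)]
      chosen <- c(chosen, pick)
      uncovered <- setdiff(uncovered, prod[[pick]])
    }
    for (el in canonicalSet(chosen)) {
      rest <- setdiff(chosen, el)
      if (all(need %in% unlist(prod[rest], use.names = FALSE)))
        chosen <- rest
    }
    list(consumer = taxon, suppliers = canonicalSet(chosen), covered = need)
  })
}

#' Reduced taxa-only interaction network
#'
#' Replaces explicit resources by replication dependencies: one entry per
#' (taxon, producing set) pair -- a taxon with several minimal producing
#' sets has several replication routes -- plus one directed kill edge from
#' each producer of a toxin to each taxon sensitive to it.
#'
#' @inheritParams minimalProducingSetsExact
#' @param method \code{"exact"} (all minimal producing sets) or
#'   \code{"greedy"} (one near-minimal set per taxon).
#' @param seed seed for greedy tie-breaking.
#' @return list with \code{dependencies} (list of producing-set records) and
#'   \code{toxinEdges} (data.frame with columns \code{producer},
#'   \code{victim}, \code{toxin}).
#' @examples
#' net <- reducedTaxaNetwork(crtFixture("fig1"))
#' net$toxinEdges   # c -> a via t1
#' @export
reducedTaxaNetwork <- function(model, method = c("exact", "greedy"),
                               seed = NULL, maxCandidates = 20L) {
  method <- match.arg(method)
  deps <- list()
  for (tx in taxa(model)) {
    entries <- if (method == "exact")
      minimalProducingSetsExact(model, tx, maxCandidates)
    else list(minimalProducingSetGreedy(model, tx, seed))
    deps <- c(deps, entries)
  }
  edges <- data.frame(producer = character(), victim = character(),
                      toxin = character(), stringsAsFactors = FALSE)
  tt <- model@toxinTable
  for (b in toxins(model)) {
    producers <- taxa(model)[tt[, b] == 1L]
    victims <- taxa(model)[tt[, b] == -1L]
    if (length(producers) && length(victims)) {
      grid <- expand.grid(producer = producers, victim = victims,
                          stringsAsFactors = FALSE)
      grid$toxin <- b
      edges <- rbind(edges, grid)
    }
  }
  list(dependencies = deps, toxinEdges = edges)
}
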