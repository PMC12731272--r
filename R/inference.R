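# Model inference from a measured hierarchy.
#
# Toxin side: non-persistent unions witness pairs of taxa sets that can
# never coexist (taxa impairings); a minimal selection of impairings
# explains all non-persistent unions, and each impairing translates into a
# fresh toxin produced by one side with the other side sensitive (two
# orientations per impairing).  Food side: a heuristic search constructs a
# food table whose implied organization set -- self-maintaining subsets not
# containing both sides of any impairing -- equals the measured set
# exactly, keeping the resource count low.

setMethod("sideA", "Impairing", function(x) x@sideA)
setMethod("sideB", "Impairing", function(x) x@sideB)

.impairingKey <- function(imp) {
  k <- sort(c(.setKey(imp@sideA), .setKey(imp@sideB)), method = "radix")
  paste(k, collapse = "\x1e")
}

#' Find minimal taxa impairings from non-persistent unions
#'
#' For every non-persistent union, all decompositions into two organizations
#' are examined; the pair of set differences seeds a side-wise minimization
#' that yields every minimal pair of disjoint taxa sets jointly absent from
#' all organizations.  Consistency is checked against the complete
#' organization list, and every union must be witnessed by at least one
#' impairing (otherwise the measurements cannot come from a
#' food-and-toxin-table model and an inconsistency error is raised).
#'
#' @param organizations list of canonical taxa sets (the measured /
#'   enumerated organizations).
#' @param nonPersistentUnions list of canonical taxa sets (red nodes).
#' @return list of [Impairing-class] objects (deduplicated, deterministic
#'   order).
#' @examples
#' fig1 <- crtFixture("fig1")
#' orgs <- enumerateOrganizations(fig1)
#' h <- buildExtendedHierarchy(orgs, fig1)
#' reds <- nodeSets(h)[nodeStatus(h) == "non_persistent_union"]
#' findImpairings(orgs, reds)   # ({a}, {c})
#' @export
findImpairings <- function(organizations, nonPersistentUnions) {
  orgs <- .uniqueSets(lapply(organizations, canonicalSet))
  unions <- .uniqueSets(lapply(nonPersistentUnions, canonicalSet))
  someOrgContains <- function(s) any(vapply(orgs, function(o)
    all(s %in% o), logical(1L)))
  found <- list()
  for (U in unions) {
    decomps <- list()
    n <- length(orgs)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j && identical(canonicalSet(union(orgs[[i]], orgs[[j]])), U))
        decomps[[length(decomps) + 1L]] <-
          list(A = canonicalSet(setdiff(orgs[[i]], orgs[[j]])),
               B = canonicalSet(setdiff(orgs[[j]], orgs[[i]])))
    }
    for (d in decomps)
      for (imp in .minimalImpairingPairs(d$A, d$B, someOrgContains))
        found[[length(found) + 1L]] <- imp
  }
  if (length(found))
    found <- found[!duplicated(vapply(found, .impairingKey, character(1L)))]
  # drop non-minimal pairs that a different decomposition refined further
  keep <- vapply(seq_along(found), function(i) {
    !any(vapply(seq_along(found), function(j) {
      if (i == j) return(FALSE)
      .impairingDominates(found[[j]], found[[i]])
    }, logical(1L)))
  }, logical(1L))
  found <- found[keep]
  for (U in unions) {
    witnessed <- any(vapply(found, function(imp)
      all(c(imp@sideA, imp@sideB) %in% U), logical(1L)))
    if (!witnessed)
      stop("inconsistency: non-persistent union {", paste(U, collapse = ","),
           "} is explained by no taxa impairing; the measurements are ",
           "incompatible with a consumer-resource-toxin model")
  }
  found[order(vapply(found, .impairingKey, character(1L)), method = "radix")]
}

# (A2,B2) refines (A1,B1) if its sides are componentwise subsets (in either
# orientation) and at least one inclusion is proper
.impairingDominates <- function(imp2, imp1) {
  sub <- function(x, y) all(x %in% y)
  same <- identical(.impairingKey(imp1), .impairingKey(imp2))
  !same && ((sub(imp2@sideA, imp1@sideA) && sub(imp2@sideB, imp1@sideB)) ||
            (sub(imp2@sideA, imp1@sideB) && sub(imp2@sideB, imp1@sideA)))
}

# all componentwise-minimal non-empty sub-pairs (A', B') of (A, B) such
# that no organization contains A' union B'
.minimalImpairingPairs <- function(A, B, someOrgContains) {
  subsA <- .allNonEmptySubsets(A)
  subsB <- .allNonEmptySubsets(B)
  cand <- list()
  for (a in subsA) for (b in subsB)
    cand[[length(cand) + 1L]] <- list(a = a, b = b,
                                      size = length(a) + length(b))
  cand <- cand[order(vapply(cand, `[[`, integer(1L), "size"))]
  out <- list()
  for (p in cand) {
    dominated <- any(vapply(out, function(f)
      (all(f@sideA %in% p$a) && all(f@sideB %in% p$b)) ||
      (all(f@sideA %in% p$b) && all(f@sideB %in% p$a)), logical(1L)))
    if (dominated) next
    if (!someOrgContains(c(p$a, p$b))) {
      sides <- list(p$a, p$b)
      ord <- order(c(.setKey(p$a), .setKey(p$b)), method = "radix")
      out[[length(out) + 1L]] <- new("Impairing", sideA = sides[[ord[1L]]],
                                     sideB = sides[[ord[2L]]])
    }
  }
  out
}

.allNonEmptySubsets <- function(x) {
  x <- canonicalSet(x)
  if (length(x) > 12L)
    stop("impairing side of ", length(x), " taxa is too large to minimize")
  unlist(lapply(seq_along(x), function(k)
    utils::combn(x, k, simplify = FALSE)), recursive = FALSE)
}

#' Minimum impairing covers of the non-persistent unions
#'
#' Exact set cover: all minimum-cardinality subsets of the impairings such
#' that every non-persistent union contains both sides of some chosen
#' impairing.
#'
#' @param impairings list of [Impairing-class] objects.
#' @param nonPersistentUnions list of canonical taxa sets.
#' @param maxCombinations search cap (capacity error beyond).
#' @return list of covers, each a list of [Impairing-class] objects; a
#'   single empty cover when there are no unions to explain.
#' @export
minimalImpairingCover <- function(impairings, nonPersistentUnions,
                                  maxCombinations = 1e5) {
  unions <- .uniqueSets(lapply(nonPersistentUnions, canonicalSet))
  if (length(unions) == 0L) return(list(list()))
  explains <- vapply(unions, function(U) vapply(impairings, function(imp)
    all(c(imp@sideA, imp@sideB) %in% U), logical(1L)),
    logical(length(impairings)))
  explains <- matrix(explains, nrow = length(impairings))
  if (any(colSums(explains) == 0L))
    stop("a non-persistent union is explained by no given impairing")
  n <- length(impairings)
  tried <- 0
  for (k in seq_len(n)) {
    covers <- list()
    for (pick in utils::combn(n, k, simplify = FALSE)) {
      tried <- tried + 1
      if (tried > maxCombinations)
        stop("capacity error: impairing cover search exceeded ",
             maxCombinations, " combinations")
      if (all(colSums(explains[pick, , drop = FALSE]) > 0L))
        covers[[length(covers) + 1L]] <- impairings[pick]
    }
    if (length(covers)) return(covers)
  }
  stop("no impairing cover found")  # unreachable given the column check
}

#' Translate an impairing cover into toxin-table alternatives
#'
#' Each impairing becomes one fresh toxin with two orientations (side A
#' produces and side B is sensitive, or vice versa); alternatives are the
#' cartesian product of orientations over the cover.  When the organization
#' and union lists are supplied, each alternative is verified to reproduce
#' the input red/green classification: no organization may contain a
#' producer together with a sensitive taxon, and every non-persistent union
#' must.  Impairings with a multi-taxon side are an extrapolation of the
#' pairwise case and are flagged.
#'
#' @param cover list of [Impairing-class] objects (one minimum cover).
#' @param organizations,nonPersistentUnions optional canonical set lists
#'   enabling verification.
#' @param taxaUniverse optional character vector of all taxa for the emitted
#'   table rows (defaults to the union of organization members and
#'   impairing sides).
#' @return list of alternatives; each has \code{assignments} (per toxin:
#'   \code{toxin}, \code{producers}, \code{sensitives}), a signed
#'   \code{toxinTable} matrix, \code{multiTaxonSides} and \code{verified}
#'   (NA when no ground context was supplied).
#' @examples
#' imp <- new("Impairing", sideA = "a", sideB = "c")
#' length(impairingsToToxinTables(list(imp)))   # 2
#' @export
impairingsToToxinTables <- function(cover, organizations = NULL,
                                    nonPersistentUnions = NULL,
                                    taxaUniverse = NULL) {
  k <- length(cover)
  if (is.null(taxaUniverse))
    taxaUniverse <- canonicalSet(c(
      unlist(lapply(organizations %||% list(), identity)),
      unlist(lapply(cover, function(i) c(i@sideA, i@sideB)))))
  orient <- if (k) expand.grid(rep(list(1:2), k)) else
    data.frame(row.names = 1L)
  lapply(seq_len(nrow(orient)), function(r) {
    assignments <- lapply(seq_len(k), function(j) {
      imp <- cover[[j]]
      if (orient[r, j] == 1L)
        list(toxin = paste0("t", j), producers = imp@sideA,
             sensitives = imp@sideB)
      else
        list(toxin = paste0("t", j), producers = imp@sideB,
             sensitives = imp@sideA)
    })
    tab <- matrix(0L, nrow = length(taxaUniverse), ncol = k,
                  dimnames = list(taxaUniverse,
                                  vapply(assignments, `[[`, character(1L),
                                         "toxin")))
    for (j in seq_len(k)) {
      tab[assignments[[j]]$producers, j] <- 1L
      tab[assignments[[j]]$sensitives, j] <- -1L
    }
    killed <- function(s) any(vapply(assignments, function(a)
      length(intersect(s, a$producers)) > 0L &&
      length(intersect(s, a$sensitives)) > 0L, logical(1L))) && k > 0L
    verified <- if (is.null(organizations)) NA else {
      okGreen <- !any(vapply(organizations, killed, logical(1L)))
      okRed <- all(vapply(nonPersistentUnions %||% list(), killed,
                          logical(1L)))
      okGreen && okRed
    }
    list(assignments = assignments, toxinTable = tab,
         multiTaxonSides = any(vapply(cover, function(i)
           length(i@sideA) > 1L || length(i@sideB) > 1L, logical(1L))),
         verified = verified)
  })
}

#' Infer minimal food tables from measured organizations
#'
#' Heuristic reconstruction of a food-resource table whose implied
#' organization set -- the self-maintaining subsets of the taxa universe
#' not containing both sides of any impairing -- equals the measured set
#' exactly.  The procedure follows three phases: (1) every taxon whose
#' singleton is not measured receives a separate required resource, which
#' eliminates the smallest spurious organizations; (2) producers for each
#' requirement are chosen among the minimal hitting sets of the taxon's
#' measured contexts, branching over up to \code{maxSlots} requirement
#' slots per taxon and checking implied-set exactness by exhaustive
#' enumeration; (3) requirement slots with identical producer sets are
#' merged into shared resources.  Resource count is the primary
#' minimization objective, signed-entry count the secondary one.
#'
#' @param measured list of taxa sets (the measured organizations; the empty
#'   organization is always implied and is added if absent).
#' @param impairings list of [Impairing-class] objects constraining joint
#'   occurrence (from [findImpairings()] or prior knowledge).
#' @param taxaUniverse optional character vector fixing the taxa universe
#'   (defaults to the union of the measurements).
#' @param maxSlots maximum requirement slots (distinct required resources)
#'   per taxon before merging (default 3).
#' @param maxSolutions number of minimal tables to return (default 3).
#' @param searchBudget cap on candidate tables evaluated (default 20000).
#' @param seed integer seed for deterministic tie-breaking.
#' @return list with elements \code{solutions} (each with \code{model}, a
#'   food-only [CRTModel-class]; \code{nResources}; \code{nEntries};
#'   \code{exact}; \code{implied}, the implied organization list; and, for
#'   best-effort results, \code{residual} with \code{extra}/\code{missing}
#'   sets), \code{exact} (was any exact table found), \code{phase1Resources}
#'   (separate requirements introduced by phase 1) and
#'   \code{emptyTableImpliedCount} (organizations implied by the empty
#'   table under the impairing constraint).
#' @export
inferFoodTable <- function(measured, impairings = list(),
                           taxaUniverse = NULL, maxSlots = 3L,
                           maxSolutions = 3L, searchBudget = 20000L,
                           seed = 1L) {
  measured <- .uniqueSets(c(list(character()),
                            lapply(measured, canonicalSet)))
  labels <- taxaUniverse %||% canonicalSet(unlist(measured))
  labels <- canonicalSet(labels)
  S <- length(labels)
  if (S > 16L) stop("food-table inference supports at most 16 taxa")
  nSub <- bitwShiftL(1L, S)
  allMasks <- 0:(nSub - 1L)
  measMask <- vapply(measured, .setToMask, integer(1L), labels = labels)
  pow2 <- bitwShiftL(1L, seq_len(max(S, 1L)) - 1L)
  allowed <- rep(TRUE, nSub)
  for (imp in impairings) {
    both <- .setToMask(canonicalSet(c(imp@sideA, imp@sideB)), labels)
    allowed <- allowed & bitwAnd(allMasks, both) != both
  }
  emptyImplied <- sum(allowed)
  inMeas <- allMasks %in% measMask
  if (any(inMeas & !allowed))
    warning("a measured organization violates an impairing constraint")

  requirers <- labels[!vapply(labels, function(tx)
    any(lengths(measured) == 1L & .keyList(measured) == .setKey(tx)),
    logical(1L))]
  phase1 <- length(requirers)

  # member masks per subset for a taxon: bit test vectorized over allMasks
  contains <- function(i) bitwAnd(allMasks, pow2[i]) != 0L

  # per-requirer candidate slots: minimal hitting sets of measured contexts
  slotOptions <- lapply(requirers, function(tx) {
    ctx <- Filter(length, lapply(measured[vapply(measured, function(o)
      tx %in% o, logical(1L))], function(o) setdiff(o, tx)))
    if (length(ctx) == 0L)
      return(list(character()))  # taxon occurs in no measurement: starve it
    ids <- as.character(seq_along(ctx))
    coverSets <- lapply(setdiff(labels, tx), function(j)
      ids[vapply(ctx, function(cc) j %in% cc, logical(1L))])
    names(coverSets) <- setdiff(labels, tx)
    .minimalCovers(coverSets, ids)
  })
  names(slotOptions) <- requirers

  # families: per requirer all subsets of its slot options of size 1..maxSlots
  families <- lapply(slotOptions, function(opts) {
    if (identical(opts, list(character()))) return(list(list(character())))
    n <- length(opts)
    fams <- list()
    for (k in seq_len(min(maxSlots, n)))
      for (pick in utils::combn(n, k, simplify = FALSE))
        fams[[length(fams) + 1L]] <- opts[pick]
    fams[order(vapply(fams, length, integer(1L)),
               vapply(fams, function(f) sum(lengths(f)), integer(1L)))]
  })

  # keep the cartesian family product within the evaluation budget by
  # trimming the longest (worst-ranked) option lists first
  repeat {
    sizes <- vapply(families, length, integer(1L))
    if (length(sizes) == 0L || prod(sizes) <= max(searchBudget, 1L)) break
    worst <- which.max(sizes)
    families[[worst]] <- families[[worst]][seq_len(ceiling(sizes[worst] / 2))]
  }
  idxGrid <- if (length(families) == 0L) data.frame(row.names = 1L) else
    expand.grid(lapply(families, seq_along))
  cost <- vapply(seq_len(nrow(idxGrid)), function(r) {
    fams <- Map(function(f, i) f[[i]], families, unlist(idxGrid[r, ]))
    c(sum(vapply(fams, length, integer(1L))),
      sum(vapply(fams, function(f) sum(lengths(f)) + length(f),
                 integer(1L))))
  }, numeric(2L))
  ord <- .withSeed(seed, {
    jitter <- stats::runif(nrow(idxGrid))
    order(cost[1L, ], cost[2L, ], jitter)
  })
  ord <- ord[seq_len(min(length(ord), searchBudget))]

  evalCandidate <- function(r) {
    implied <- allowed
    for (q in seq_along(requirers)) {
      i <- match(requirers[q], labels)
      inO <- contains(i)
      for (P in families[[q]][[idxGrid[r, q]]]) {
        Pmask <- .setToMask(P, labels)
        implied <- implied & (!inO | bitwAnd(allMasks, Pmask) != 0L)
      }
    }
    implied
  }

  solutions <- list(); bestEffort <- NULL; bestDiff <- Inf
  for (r in ord) {
    implied <- evalCandidate(r)
    impliedMasks <- allMasks[implied]
    if (setequal(impliedMasks, measMask)) {
      fams <- Map(function(f, i) f[[i]], families, unlist(idxGrid[r, ]))
      solutions[[length(solutions) + 1L]] <- .buildFoodSolution(
        fams, requirers, labels, measured, exact = TRUE)
      if (length(solutions) >= maxSolutions) break
    } else if (is.null(bestEffort) ||
               length(union(setdiff(impliedMasks, measMask),
                            setdiff(measMask, impliedMasks))) < bestDiff) {
      bestDiff <- length(union(setdiff(impliedMasks, measMask),
                               setdiff(measMask, impliedMasks)))
      bestEffort <- r
    }
  }
  if (length(solutions) == 0L && !is.null(bestEffort)) {
    r <- bestEffort
    implied <- evalCandidate(r)
    impliedMasks <- allMasks[implied]
    fams <- Map(function(f, i) f[[i]], families, unlist(idxGrid[r, ]))
    sol <- .buildFoodSolution(fams, requirers, labels, measured,
                              exact = FALSE)
    sol$residual <- list(
      extra = lapply(setdiff(impliedMasks, measMask), .maskToSet,
                     labels = labels),
      missing = lapply(setdiff(measMask, impliedMasks), .maskToSet,
                       labels = labels))
    sol$implied <- lapply(sort(impliedMasks), .maskToSet, labels = labels)
    warning("no food table re-implies the measured organizations exactly ",
            "within the search budget; returning a best-effort table (",
            bestDiff, " sets differ)")
    solutions <- list(sol)
  } else if (length(solutions) == 0L) {
    stop("food-table search space is empty")
  }
  ranks <- order(vapply(solutions, `[[`, integer(1L), "nResources"),
                 vapply(solutions, `[[`, integer(1L), "nEntries"))
  list(solutions = solutions[ranks],
       exact = any(vapply(solutions, `[[`, logical(1L), "exact")),
       phase1Resources = phase1,
       emptyTableImpliedCount = emptyImplied)
}

# merge requirement slots with identical producer sets into shared
# resources and emit the signed food table
.buildFoodSolution <- function(fams, requirers, labels, measured, exact) {
  slots <- list()
  for (q in seq_along(requirers))
    for (P in fams[[q]])
      slots[[length(slots) + 1L]] <- list(taxon = requirers[q],
                                          producers = canonicalSet(P))
  groupKey <- vapply(slots, function(s) .setKey(s$producers), character(1L))
  groups <- split(slots, factor(groupKey, levels = unique(groupKey)))
  food <- matrix(0L, nrow = length(labels), ncol = length(groups),
                 dimnames = list(labels,
                                 if (length(groups))
                                   paste0("r", seq_along(groups))
                                 else character()))
  for (g in seq_along(groups)) {
    reqTaxa <- unique(vapply(groups[[g]], `[[`, character(1L), "taxon"))
    producers <- groups[[g]][[1L]]$producers
    stopifnot(length(intersect(reqTaxa, producers)) == 0L)
    food[reqTaxa, g] <- -1L
    food[producers, g] <- 1L
  }
  model <- CRTModel(food)
  list(model = model, nResources = ncol(food),
       nEntries = sum(food != 0L), exact = exact,
       implied = if (exact) measured else NULL)
}
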