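# Measurement experiments and hierarchy reconstruction.
#
# A measurement is a taxa set observed as a stable community composition and
# therefore assumed to be an organization of the unknown underlying model.
# Three sampling schemes are simulated: "novel" (organizations drawn
# uniformly without replacement), "neutral" (uniform draws with
# replacement) and "random" (a random initial taxa set, reduced to the
# organization it generates -- toxin removal first, then iterative
# starvation).  Pairwise unions/intersections of the measured sets that are
# not themselves measured are candidate discoveries; a set that is both is
# provably a true organization.

#' Empty reconstruction state
#'
#' @return a [ReconstructionState-class] with no measurements.
#' @export
newReconstruction <- function() {
  new("ReconstructionState", measured = list(), additionalUnions = list(),
      additionalIntersections = list(), additionalOrganizations = list())
}

setMethod("measuredSets", "ReconstructionState", function(x) x@measured)
setMethod("additionalSets", "ReconstructionState", function(x, category) {
  category <- match.arg(category, c("unions", "intersections", "organizations"))
  switch(category,
         unions = x@additionalUnions,
         intersections = x@additionalIntersections,
         organizations = x@additionalOrganizations)
})

#' Incorporate a measurement into a reconstruction state
#'
#' Adds the measured taxa set (a repeated measurement is a no-op: it cannot
#' change the hierarchy) and recomputes the additional collections as the
#' pairwise unions and intersections over all measured sets that are not
#' measured themselves; sets occurring in both collections are recorded as
#' additional organizations.
#'
#' @param state a [ReconstructionState-class].
#' @param newMeasurement character vector of taxon labels.
#' @return the updated [ReconstructionState-class].
#' @examples
#' st <- updateReconstruction(newReconstruction(), c("a", "b", "d"))
#' st <- updateReconstruction(st, c("b", "c", "d"))
#' additionalSets(st, "unions")          # {a,b,c,d}
#' additionalSets(st, "intersections")   # {b,d}
#' @export
updateReconstruction <- function(state, newMeasurement) {
  m <- canonicalSet(newMeasurement)
  keys <- .keyList(state@measured)
  if (.setKey(m) %in% keys) return(state)
  measured <- c(state@measured, list(m))
  mkeys <- c(keys, .setKey(m))
  unions <- list(); inters <- list()
  n <- length(measured)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      unions[[length(unions) + 1L]] <-
        canonicalSet(union(measured[[i]], measured[[j]]))
      inters[[length(inters) + 1L]] <-
        canonicalSet(intersect(measured[[i]], measured[[j]]))
    }
  }
  unions <- .uniqueSets(unions)
  inters <- .uniqueSets(inters)
  unions <- unions[!(.keyList(unions) %in% mkeys)]
  inters <- inters[!(.keyList(inters) %in% mkeys)]
  addOrg <- unions[.keyList(unions) %in% .keyList(inters)]
  new("ReconstructionState",
      measured = measured,
      additionalUnions = .orderSets(unions),
      additionalIntersections = .orderSets(inters),
      additionalOrganizations = .orderSets(addOrg))
}

#' Draw simulated measurements from a model
#'
#' @param model a [CRTModel-class].
#' @param organizations the toxin-aware organization list of \code{model}
#'   (enumerated on the fly when NULL).
#' @param mode \code{"novel"} (uniform permutation, without replacement;
#'   \code{nDraws} beyond the organization count is capped with a warning),
#'   \code{"neutral"} (uniform with replacement) or \code{"random"} (each
#'   draw starts from a random taxa set -- every taxon included
#'   independently with probability \code{inclusionP} -- and records the
#'   organization it generates; an initial set that collapses to the empty
#'   set counts as a measurement of the empty organization).
#' @param nDraws number of measurements.
#' @param inclusionP inclusion probability for \code{"random"} mode
#'   (default 0.5).
#' @param seed integer seed.
#' @return ordered list of canonical taxa sets.
#' @export
drawMeasurements <- function(model, organizations = NULL,
                             mode = c("novel", "neutral", "random"),
                             nDraws = NULL, inclusionP = 0.5, seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(organizations) && mode != "random")
    organizations <- enumerateOrganizations(model)
  if (mode != "random") {
    organizations <- lapply(organizations, canonicalSet)
    N <- length(organizations)
  }
  if (is.null(nDraws))
    nDraws <- if (mode == "novel") N else stop("nDraws is required")
  stopifnot(nDraws >= 0L, inclusionP >= 0, inclusionP <= 1)
  .withSeed(seed, switch(mode,
    novel = {
      if (nDraws > N) {
        warning(sprintf(paste0("novel mode: nDraws = %d exceeds the %d ",
                               "distinct organizations; capped"), nDraws, N))
        nDraws <- N
      }
      organizations[sample.int(N, N)][seq_len(nDraws)]
    },
    neutral = {
      if (nDraws == 0L) list() else
        organizations[sample.int(N, nDraws, replace = TRUE)]
    },
    random = {
      lab <- taxa(model)
      lapply(seq_len(nDraws), function(k) {
        initial <- lab[stats::runif(length(lab)) < inclusionP]
        generateOrganization(initial, model)
      })
    }))
}

#' Recovery curve of a measurement experiment
#'
#' Runs one simulated experiment against a model with known ground truth
#' and reports, after each measurement, the fraction of true organizations
#' recovered under the chosen counting policy: \code{"measured_only"}
#' (directly measured sets), \code{"plus_additional_orgs"} (also counting
#' additional organizations, which are provably true -- the default), or
#' \code{"plus_all_candidates"} (additionally counting those additional
#' unions/intersections that happen to be true organizations).
#'
#' @inheritParams drawMeasurements
#' @param countPolicy counting policy, see above.
#' @return data.frame with one row per measurement: \code{nMeasurements},
#'   \code{fractionRecovered} (non-decreasing within the run),
#'   \code{nAdditionalUnions}, \code{nAdditionalIntersections},
#'   \code{nAdditionalOrganizations}.
#' @export
recoveryCurve <- function(model, mode = c("novel", "neutral", "random"),
                          nDraws = NULL, inclusionP = 0.5, seed = NULL,
                          countPolicy = c("plus_additional_orgs",
                                          "measured_only",
                                          "plus_all_candidates"),
                          organizations = NULL) {
  mode <- match.arg(mode)
  countPolicy <- match.arg(countPolicy)
  if (is.null(organizations))
    organizations <- enumerateOrganizations(model)
  draws <- drawMeasurements(model, organizations, mode, nDraws, inclusionP,
                            seed)
  # incremental bitmask bookkeeping: per new measurement only the pairs
  # against previously measured sets are formed
  labels <- taxa(model)
  trueMasks <- vapply(lapply(organizations, canonicalSet), .setToMask,
                      integer(1L), labels = labels)
  measured <- integer(); unionsAll <- integer(); intersAll <- integer()
  rows <- vector("list", length(draws))
  for (k in seq_along(draws)) {
    m <- .setToMask(canonicalSet(draws[[k]]), labels)
    if (!(m %in% measured)) {
      if (length(measured)) {
        unionsAll <- unique(c(unionsAll, bitwOr(measured, m)))
        intersAll <- unique(c(intersAll, bitwAnd(measured, m)))
      }
      measured <- c(measured, m)
    }
    addU <- setdiff(unionsAll, measured)
    addI <- setdiff(intersAll, measured)
    addO <- intersect(addU, addI)
    recovered <- switch(countPolicy,
      measured_only = measured,
      plus_additional_orgs = c(measured, addO),
      plus_all_candidates = c(measured, addU, addI))
    rows[[k]] <- data.frame(
      nMeasurements = k,
      fractionRecovered =
        length(intersect(unique(recovered), trueMasks)) / length(trueMasks),
      nAdditionalUnions = length(addU),
      nAdditionalIntersections = length(addI),
      nAdditionalOrganizations = length(addO))
  }
  do.call(rbind, rows)
}

#' False discovery rate of additional candidates
#'
#' Fraction of sets in the chosen additional category that are not true
#' organizations of the ground-truth model.  Without toxins the union FDR
#' is identically zero: every union of organizations is an organization.
#'
#' @param state a [ReconstructionState-class].
#' @param trueOrgs list of canonical taxa sets (ground-truth organizations).
#' @param category \code{"unions"} or \code{"intersections"}.
#' @return numeric scalar in [0, 1], or \code{NA_real_} when the category is
#'   empty (undefined, flagged rather than thrown).
#' @export
falseDiscoveryRate <- function(state, trueOrgs,
                               category = c("unions", "intersections")) {
  category <- match.arg(category)
  sets <- additionalSets(state, category)
  if (length(sets) == 0L) return(NA_real_)
  trueKeys <- .keyList(lapply(trueOrgs, canonicalSet))
  mean(!(.keyList(sets) %in% trueKeys))
}

#' Random-model parameter study of the extended hierarchy
#'
#' Generates \code{replicates} random models at each grid point, enumerates
#' toxin-aware organizations and classifies all pairwise unions and
#' intersections, and tabulates node counts per replicate together with
#' per-point means and standard errors of the mean.  The empty organization
#' is included in all counts.  Replicate \code{r} of grid point \code{i}
#' uses seed \code{seed + (i - 1) * replicates + r}.
#'
#' @param grid data.frame with columns \code{S}, \code{M}, \code{T} and
#'   optionally \code{pFoodProduce}, \code{pFoodRequire},
#'   \code{pToxinProduce}, \code{pToxinSensitive} (defaults 1/3, 1/3, 0.1,
#'   0.1).
#' @param replicates random models per grid point.
#' @param seed integer base seed.
#' @return list with data.frames \code{replicates} (one row per model:
#'   parameters, seed, \code{nOrganizations}, \code{nOrganizationsNoToxins},
#'   \code{nNonPersistentUnions}, \code{nNonPersistentIntersections}) and
#'   \code{summary} (per grid point: mean and standard error of the mean of
#'   each count).
#' @examples
#' st <- runParameterStudy(data.frame(S = 5, M = 4, T = 1),
#'                         replicates = 3, seed = 1)
#' st$summary
#' @export
runParameterStudy <- function(grid, replicates = 100L, seed = 1L) {
  defaults <- data.frame(pFoodProduce = 1 / 3, pFoodRequire = 1 / 3,
                         pToxinProduce = 0.1, pToxinSensitive = 0.1)
  for (nm in names(defaults))
    if (is.null(grid[[nm]])) grid[[nm]] <- defaults[[nm]]
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    for (r in seq_len(replicates)) {
      s <- as.integer(seed + (i - 1L) * replicates + r)
      model <- randomCRTModel(g$S, g$M, g$T, g$pFoodProduce, g$pFoodRequire,
                              g$pToxinProduce, g$pToxinSensitive, seed = s)
      flags <- .subsetFlags(model)
      smMasks <- which(flags$selfMaintaining) - 1L
      orgMasks <- which(flags$selfMaintaining & flags$toxinOK) - 1L
      ext <- .extendedSetMasks(orgMasks)
      rows[[length(rows) + 1L]] <- cbind(
        g, data.frame(
          point = i, replicate = r, seed = s,
          nOrganizations = length(orgMasks),
          nOrganizationsNoToxins = length(smMasks),
          nNonPersistentUnions = length(ext$union),
          nNonPersistentIntersections = length(ext$intersection)))
    }
  }
  reps <- do.call(rbind, rows)
  rownames(reps) <- NULL
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  metrics <- c("nOrganizations", "nOrganizationsNoToxins",
               "nNonPersistentUnions", "nNonPersistentIntersections")
  summ <- do.call(rbind, lapply(split(reps, reps$point), function(d) {
    out <- d[1L, c("point", "S", "M", "T", "pFoodProduce", "pFoodRequire",
                   "pToxinProduce", "pToxinSensitive")]
    for (m in metrics) {
      out[[paste0("mean_", m)]] <- mean(d[[m]])
      out[[paste0("sem_", m)]] <- sem(d[[m]])
    }
    out
  }))
  rownames(summ) <- NULL
  list(replicates = reps, summary = summ)
}
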