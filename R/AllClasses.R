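#' @import methods
NULL

#' Consumer-resource-toxin (CRT) community model
#'
#' A CRT model encodes a microbial community as two sign tables sharing the
#' same taxa rows: a food-resource table (taxa x resources) and a toxin table
#' (taxa x toxins).  In the food table an entry of \code{+1} means the taxon
#' produces the resource, \code{-1} that it requires it for growth, \code{0}
#' neither.  In the toxin table \code{+1} means the taxon produces the toxin,
#' \code{-1} that it is sensitive to it (a single sensitive/producer pair in
#' one set excludes coexistence), \code{0} unaffected.  Quantitative amounts
#' and kinetics are deliberately abstracted away; only the sign structure
#' drives the analysis.
#'
#' Because each taxon/resource pair occupies one signed cell, a taxon can
#' never both produce and require the same resource, nor both produce and be
#' sensitive to the same toxin; the validity method enforces this encoding.
#'
#' @slot foodTable integer matrix over \{-1, 0, 1\} with taxa as row names and
#'   resource labels as column names.
#' @slot toxinTable integer matrix over \{-1, 0, 1\} with the same taxa rows
#'   and toxin labels as column names.  Zero columns encode a toxin-free
#'   model.
#'
#' @seealso [CRTModel()] for the user-facing constructor, [validateModel()]
#'   for a non-throwing validity report, [taxonProfile()] for per-taxon
#'   accessors.
#' @exportClass CRTModel
setClass("CRTModel",
  representation(foodTable = "matrix", toxinTable = "matrix"))

# Structural validity only (slot types); full domain validation -- sign
# domain, duplicate labels, taxa alignment -- is reported by
# validateModel() and enforced by the CRTModel() constructor, so that
# deliberately malformed tables can still be represented for inspection.
setValidity("CRTModel", function(object) {
  msgs <- character()
  if (!is.integer(object@foodTable))
    msgs <- c(msgs, "foodTable must be an integer matrix")
  if (!is.integer(object@toxinTable))
    msgs <- c(msgs, "toxinTable must be an integer matrix")
  if (length(msgs)) msgs else TRUE
})

#' Extended hierarchy of organizations
#'
#' Hasse diagram (cover relation under set inclusion) over all organizations
#' of a model together with their pairwise unions and intersections.  Each
#' node carries a status: \code{"organization"} (green), a
#' \code{"non_persistent_union"} (red; a union of two organizations that is
#' not itself an organization) or a \code{"non_persistent_intersection"}
#' (yellow).  Red nodes only arise in toxin-aware hierarchies: without
#' toxins every union of organizations is again an organization.
#'
#' @slot sets list of character vectors (canonical sorted taxa sets), ordered
#'   by ascending cardinality then lexicographically.
#' @slot status character vector parallel to \code{sets}.
#' @slot edges two-column integer matrix of cover pairs (lower, upper) as
#'   indices into \code{sets}.
#' @slot applyToxins logical scalar; the toxin mode the hierarchy was built
#'   under.
#' @exportClass ExtendedHierarchy
setClass("ExtendedHierarchy",
  representation(sets = "list", status = "character", edges = "matrix",
                 applyToxins = "logical"))

setValidity("ExtendedHierarchy", function(object) {
  msgs <- character()
  if (length(object@sets) != length(object@status))
    msgs <- c(msgs, "sets and status must have equal length")
  bad <- setdiff(unique(object@status),
                 c("organization", "non_persistent_union",
                   "non_persistent_intersection"))
  if (length(bad))
    msgs <- c(msgs, paste0("unknown node status: ", paste(bad, collapse = ", ")))
  if (ncol(object@edges) != 2L)
    msgs <- c(msgs, "edges must be a two-column matrix")
  if (length(object@edges) &&
      (max(object@edges) > length(object@sets) || min(object@edges) < 1L))
    msgs <- c(msgs, "edge indices out of range")
  if (length(msgs)) msgs else TRUE
})

#' Reconstruction state of a measurement experiment
#'
#' Book-keeping for hierarchy reconstruction from measured community
#' compositions.  Measurements are taxa sets assumed to be organizations of
#' an unknown model.  Pairwise unions and intersections of the measured sets
#' that are not themselves measured are tracked as \emph{additional unions} /
#' \emph{additional intersections}; a set appearing in both collections is an
#' \emph{additional organization} and is provably a true organization of the
#' underlying model.
#'
#' @slot measured list of canonical taxa sets (distinct measurements, in
#'   order of first observation).
#' @slot additionalUnions list of canonical taxa sets.
#' @slot additionalIntersections list of canonical taxa sets.
#' @slot additionalOrganizations list of canonical taxa sets (subset of both
#'   collections above).
#' @exportClass ReconstructionState
setClass("ReconstructionState",
  representation(measured = "list", additionalUnions = "list",
                 additionalIntersections = "list",
                 additionalOrganizations = "list"))

#' Taxa impairing
#'
#' An ordered pair of disjoint, non-empty taxa sets that never occur together
#' in any organization: no organization contains \code{sideA} and \code{sideB}
#' jointly.  Impairings are the unit of toxin-table inference -- each one can
#' be realized by a fresh toxin produced by one side and affecting the other.
#'
#' @slot sideA character vector (canonical taxa set).
#' @slot sideB character vector (canonical taxa set).
#' @exportClass Impairing
setClass("Impairing", representation(sideA = "character", sideB = "character"))

setValidity("Impairing", function(object) {
  msgs <- character()
  if (length(object@sideA) == 0L || length(object@sideB) == 0L)
    msgs <- c(msgs, "both impairing sides must be non-empty")
  if (length(intersect(object@sideA, object@sideB)))
    msgs <- c(msgs, "impairing sides must be disjoint")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CRTModel", function(object) {
  cat(sprintf("CRTModel: %d taxa, %d food resources, %d toxins\n",
              nrow(object@foodTable), ncol(object@foodTable),
              ncol(object@toxinTable)))
  cat("  taxa:", paste(head(rownames(object@foodTable), 8L), collapse = ", "),
      if (nrow(object@foodTable) > 8L) "..." else "", "\n")
})

setMethod("show", "ExtendedHierarchy", function(object) {
  tab <- table(factor(object@status,
                      levels = c("organization", "non_persistent_union",
                                 "non_persistent_intersection")))
  cat(sprintf(paste0("ExtendedHierarchy (%s): %d organizations, ",
                     "%d non-persistent unions, %d non-persistent ",
                     "intersections, %d cover edges\n"),
              if (object@applyToxins) "toxin-aware" else "toxin-free",
              tab[[1L]], tab[[2L]], tab[[3L]], nrow(object@edges)))
})

setMethod("show", "ReconstructionState", function(object) {
  cat(sprintf(paste0("ReconstructionState: %d measured sets, ",
                     "%d additional unions, %d additional intersections, ",
                     "%d additional organizations\n"),
              length(object@measured), length(object@additionalUnions),
              length(object@additionalIntersections),
              length(object@additionalOrganizations)))
})

setMethod("show", "Impairing", function(object) {
  cat(sprintf("Impairing: ({%s}, {%s})\n",
              paste(object@sideA, collapse = ","),
              paste(object@sideB, collapse = ",")))
})
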