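#' Taxa labels of a model
#'
#' @param x a [CRTModel-class].
#' @return character vector of taxon labels, in table row order.
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' Food-resource labels of a model
#'
#' @param x a [CRTModel-class].
#' @return character vector of resource labels.
#' @export
setGeneric("resources", function(x) standardGeneric("resources"))

#' Toxin labels of a model
#'
#' @param x a [CRTModel-class].
#' @return character vector of toxin labels (may be empty).
#' @export
setGeneric("toxins", function(x) standardGeneric("toxins"))

#' Food-resource sign table
#'
#' @param x a [CRTModel-class].
#' @return integer matrix (taxa x resources) over \{-1, 0, 1\}.
#' @export
setGeneric("foodTable", function(x) standardGeneric("foodTable"))

#' Toxin sign table
#'
#' @param x a [CRTModel-class].
#' @return integer matrix (taxa x toxins) over \{-1, 0, 1\}.
#' @export
setGeneric("toxinTable", function(x) standardGeneric("toxinTable"))

#' Nodes of an extended hierarchy
#'
#' @param x an [ExtendedHierarchy-class].
#' @return data.frame with columns \code{id}, \code{taxa} (comma-joined
#'   canonical set), \code{size} and \code{status}.
#' @export
setGeneric("hierarchyNodes", function(x) standardGeneric("hierarchyNodes"))

#' Cover edges of an extended hierarchy
#'
#' @param x an [ExtendedHierarchy-class].
#' @return two-column integer matrix of (lower, upper) node indices.
#' @export
setGeneric("hierarchyEdges", function(x) standardGeneric("hierarchyEdges"))

#' Node taxa sets of an extended hierarchy
#'
#' @param x an [ExtendedHierarchy-class].
#' @return list of canonical character vectors.
#' @export
setGeneric("nodeSets", function(x) standardGeneric("nodeSets"))

#' Node statuses of an extended hierarchy
#'
#' @param x an [ExtendedHierarchy-class].
#' @return character vector of node statuses parallel to [nodeSets()].
#' @export
setGeneric("nodeStatus", function(x) standardGeneric("nodeStatus"))

#' Measured sets of a reconstruction state
#'
#' @param x a [ReconstructionState-class].
#' @return list of canonical taxa sets in order of first observation.
#' @export
setGeneric("measuredSets", function(x) standardGeneric("measuredSets"))

#' Additional sets derived from measurements
#'
#' @param x a [ReconstructionState-class].
#' @param category one of \code{"unions"}, \code{"intersections"},
#'   \code{"organizations"}.
#' @return list of canonical taxa sets.
#' @export
setGeneric("additionalSets",
           function(x, category = c("unions", "intersections", "organizations"))
             standardGeneric("additionalSets"))

#' Sides of a taxa impairing
#'
#' @param x an [Impairing-class].
#' @return canonical character vector of taxa.
#' @rdname impairing-sides
#' @export
setGeneric("sideA", function(x) standardGeneric("sideA"))

#' @rdname impairing-sides
#' @export
setGeneric("sideB", function(x) standardGeneric("sideB"))
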