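# Extended hierarchy: organizations plus their pairwise unions and
# intersections, arranged as a Hasse diagram (cover relation of set
# inclusion).  Classification precedence is organization > non-persistent
# union > non-persistent intersection; a set that is simultaneously a
# pairwise union and a pairwise intersection of organizations is provably an
# organization, so the three statuses are mutually exclusive on consistent
# input.  Unions/intersections are taken pairwise over organizations only,
# not iterated over derived sets.

setMethod("nodeSets", "ExtendedHierarchy", function(x) x@sets)
setMethod("nodeStatus", "ExtendedHierarchy", function(x) x@status)
setMethod("hierarchyEdges", "ExtendedHierarchy", function(x) x@edges)
setMethod("hierarchyNodes", "ExtendedHierarchy", function(x) {
  data.frame(
    id = seq_along(x@sets),
    taxa = vapply(x@sets, paste, character(1L), collapse = ","),
    size = lengths(x@sets),
    status = x@status,
    stringsAsFactors = FALSE)
})

# classify organizations + pairwise unions/intersections without building
# cover edges (used by the parameter study, where only counts matter)
.extendedSetMasks <- function(orgMasks) {
  if (length(orgMasks) == 0L)
    return(list(org = integer(), union = integer(), intersection = integer()))
  uni <- unique(as.vector(outer(orgMasks, orgMasks, bitwOr)))
  int <- unique(as.vector(outer(orgMasks, orgMasks, bitwAnd)))
  list(org = orgMasks,
       union = setdiff(uni, orgMasks),
       intersection = setdiff(setdiff(int, orgMasks), uni))
}

#' Build the extended hierarchy of organizations
#'
#' Takes the complete organization set of a model (as produced by
#' [enumerateOrganizations()] under the same toxin mode), adds all pairwise
#' unions and intersections, classifies every node, and computes the Hasse
#' cover relation: an edge (x, y) exists iff x is a proper subset of y with
#' no node strictly in between.
#'
#' @param organizations list of canonical taxa sets; must be exactly the
#'   enumeration output for \code{(model, applyToxins)} -- a listed set
#'   failing the organization predicate raises an integrity error.
#' @param model a [CRTModel-class].
#' @param applyToxins logical; the toxin mode governing the predicate.
#' @return an [ExtendedHierarchy-class].
#' @examples
#' fig1 <- crtFixture("fig1")
#' h <- buildExtendedHierarchy(enumerateOrganizations(fig1), fig1)
#' table(nodeStatus(h))
#' @export
buildExtendedHierarchy <- function(organizations, model, applyToxins = TRUE) {
  labels <- taxa(model)
  if (length(labels) > .WORD_BITS)
    stop("hierarchy construction supports at most ", .WORD_BITS, " taxa")
  orgs <- .uniqueSets(lapply(organizations, canonicalSet))
  bad <- !vapply(orgs, isOrganization, logical(1L), model = model,
                 applyToxins = applyToxins)
  if (any(bad))
    stop("integrity error: input set {",
         paste(orgs[[which(bad)[1L]]], collapse = ","),
         "} is not an organization under the requested toxin mode")
  masks <- vapply(orgs, .setToMask, integer(1L), labels = labels)
  ext <- .extendedSetMasks(masks)
  nodeMasks <- c(ext$org, ext$union, ext$intersection)
  status <- rep(c("organization", "non_persistent_union",
                  "non_persistent_intersection"),
                c(length(ext$org), length(ext$union),
                  length(ext$intersection)))
  sets <- lapply(nodeMasks, .maskToSet, labels = labels)
  ord <- order(lengths(sets), .keyList(sets), method = "radix")
  sets <- sets[ord]; status <- status[ord]; nodeMasks <- nodeMasks[ord]
  edges <- .coverEdges(nodeMasks)
  new("ExtendedHierarchy", sets = sets, status = status, edges = edges,
      applyToxins = applyToxins)
}

# cover relation over distinct bitmasks: strict-subset matrix, pruned by
# boolean matrix product (an intermediate node kills the cover pair)
.coverEdges <- function(masks) {
  n <- length(masks)
  if (n <= 1L)
    return(matrix(integer(), 0L, 2L, dimnames = list(NULL, c("lower", "upper"))))
  sub <- outer(masks, masks, function(a, b)
    bitwAnd(a, bitwNot(b)) == 0L & a != b)
  mid <- (sub %*% sub) > 0L
  cov <- sub & !mid
  idx <- which(cov, arr.ind = TRUE)
  edges <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  dimnames(edges) <- list(NULL, c("lower", "upper"))
  storage.mode(edges) <- "integer"
  edges
}

#' Interaction clusters of organizations
#'
#' The interaction cluster of an organization is the set of its taxa that
#' occur in no strictly contained organization; the organization is always
#' the disjoint union of its cluster and the union of the organizations
#' below it.  A cluster that is itself an organization is \emph{context
#' free} (it can stand alone); otherwise it is \emph{context dependent} and
#' needs additional taxa to persist.
#'
#' @inheritParams buildExtendedHierarchy
#' @param organizations list of canonical taxa sets, closed under the
#'   governing enumeration.
#' @return list with one record per organization; each record is a list with
#'   elements \code{organization}, \code{cluster} (possibly empty) and
#'   \code{kind} (\code{"context_free"} or \code{"context_dependent"}).
#' @examples
#' fig1 <- crtFixture("fig1")
#' cl <- interactionClusters(enumerateOrganizations(fig1, applyToxins = FALSE),
#'                           fig1, applyToxins = FALSE)
#' @export
interactionClusters <- function(organizations, model, applyToxins = TRUE) {
  orgs <- .orderSets(.uniqueSets(lapply(organizations, canonicalSet)))
  keys <- .keyList(orgs)
  lapply(orgs, function(o) {
    below <- orgs[vapply(orgs, function(p)
      length(p) < length(o) && all(p %in% o), logical(1L))]
    covered <- canonicalSet(unlist(below))
    cluster <- canonicalSet(setdiff(o, covered))
    stopifnot(identical(canonicalSet(c(covered, cluster)), o))  # sum rule
    kind <- if (isOrganization(cluster, model, applyToxins))
      "context_free" else "context_dependent"
    list(organization = o, cluster = cluster, kind = kind)
  })
}

#' Elementary organizations
#'
#' Organizations introducing a non-empty interaction cluster.  Every other
#' organization of a closed enumeration equals a union of the elementary
#' ones it contains; this reconstruction property is verified and an
#' integrity error is raised if it fails.
#'
#' @inheritParams interactionClusters
#' @return list of canonical taxa sets (the elementary organizations).
#' @examples
#' fig1 <- crtFixture("fig1")
#' elementaryOrganizations(enumerateOrganizations(fig1), fig1)
#' @export
elementaryOrganizations <- function(organizations, model, applyToxins = TRUE) {
  cl <- interactionClusters(organizations, model, applyToxins)
  elem <- lapply(Filter(function(r) length(r$cluster) > 0L, cl),
                 `[[`, "organization")
  others <- Filter(function(r) length(r$cluster) == 0L, cl)
  for (r in others) {
    contained <- Filter(function(e) all(e %in% r$organization), elem)
    if (!identical(canonicalSet(unlist(contained)), r$organization))
      stop("integrity error: organization {",
           paste(r$organization, collapse = ","),
           "} is not a union of elementary organizations")
  }
  .orderSets(elem)
}

#' Resource-dependency graph of an interaction cluster
#'
#' Undirected graph on the cluster's taxa with an edge wherever one taxon
#' produces a food resource the other requires.  Interaction clusters are
#' provably connected under this relation.
#'
#' @param cluster character vector of taxon labels (a cluster from
#'   [interactionClusters()]).
#' @param model a [CRTModel-class].
#' @return an \pkg{igraph} undirected graph whose vertices are the cluster
#'   taxa.
#' @examples
#' g <- clusterDependencyGraph(c("b", "d"), crtFixture("fig1"))
#' igraph::is_connected(g)
#' @export
clusterDependencyGraph <- function(cluster, model) {
  cluster <- .checkTaxaSet(cluster, model)
  edges <- character()
  if (length(cluster) > 1L) {
    profs <- lapply(cluster, taxonProfile, model = model)
    names(profs) <- cluster
    for (i in seq_along(cluster)) for (j in seq_along(cluster)) {
      if (i < j) {
        a <- cluster[i]; b <- cluster[j]
        if (length(intersect(profs[[a]]$produced, profs[[b]]$required)) ||
            length(intersect(profs[[b]]$produced, profs[[a]]$required)))
          edges <- c(edges, a, b)
      }
    }
  }
  igraph::graph_from_data_frame(
    if (length(edges)) as.data.frame(matrix(edges, ncol = 2L, byrow = TRUE))
    else data.frame(from = character(), to = character()),
    directed = FALSE,
    vertices = data.frame(name = cluster))
}

.STATUS_COLOR <- c(organization = "green", non_persistent_union = "red",
                   non_persistent_intersection = "yellow")

#' Export an extended hierarchy
#'
#' Serializes a hierarchy as Graphviz DOT, GraphML or JSON text.  DOT and
#' GraphML carry a \code{color} attribute (green = organization, red =
#' non-persistent union, yellow = non-persistent intersection); DOT
#' additionally ranks nodes by cardinality so the drawing reads bottom-up
#' like a Hasse diagram.  JSON output round-trips via [importHierarchy()].
#'
#' @param h an [ExtendedHierarchy-class].
#' @param format \code{"dot"}, \code{"graphml"} or \code{"json"}.
#' @param file optional output path.
#' @return the document text (invisibly when written to \code{file}).
#' @export
exportHierarchy <- function(h, format = c("dot", "graphml", "json"),
                            file = NULL) {
  format <- match.arg(format)
  txt <- switch(format,
                dot = .hierarchyDOT(h),
                graphml = .hierarchyGraphML(h),
                json = .hierarchyJSON(h))
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

.nodeLabel <- function(s) paste0("{", paste(s, collapse = ","), "}")

.hierarchyDOT <- function(h) {
  lab <- vapply(h@sets, .nodeLabel, character(1L))
  col <- .STATUS_COLOR[h@status]
  lines <- c("digraph hierarchy {",
             "  rankdir=BT;",
             "  node [style=filled];",
             sprintf("  n%d [label=\"%s\", fillcolor=%s];",
                     seq_along(h@sets), lab, col))
  for (sz in sort(unique(lengths(h@sets))))
    lines <- c(lines, sprintf("  { rank=same; %s }",
                              paste0("n", which(lengths(h@sets) == sz),
                                     collapse = "; ")))
  if (nrow(h@edges))
    lines <- c(lines, sprintf("  n%d -> n%d;", h@edges[, 1L], h@edges[, 2L]))
  paste(c(lines, "}"), collapse = "\n")
}

.hierarchyGraphML <- function(h) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  lab <- esc(vapply(h@sets, .nodeLabel, character(1L)))
  nodes <- sprintf(paste0("    <node id=\"n%d\"><data key=\"label\">%s</data>",
                          "<data key=\"color\">%s</data>",
                          "<data key=\"status\">%s</data></node>"),
                   seq_along(h@sets), lab, .STATUS_COLOR[h@status], h@status)
  edges <- if (nrow(h@edges))
    sprintf("    <edge source=\"n%d\" target=\"n%d\"/>",
            h@edges[, 1L], h@edges[, 2L]) else character()
  paste(c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
          "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
          "  <key id=\"label\" for=\"node\" attr.name=\"label\" attr.type=\"string\"/>",
          "  <key id=\"color\" for=\"node\" attr.name=\"color\" attr.type=\"string\"/>",
          "  <key id=\"status\" for=\"node\" attr.name=\"status\" attr.type=\"string\"/>",
          "  <graph edgedefault=\"directed\">",
          nodes, edges,
          "  </graph>", "</graphml>"), collapse = "\n")
}

.hierarchyJSON <- function(h) {
  doc <- list(
    apply_toxins = h@applyToxins,
    nodes = lapply(seq_along(h@sets), function(i)
      list(taxa = h@sets[[i]], status = h@status[i])),
    edges = if (nrow(h@edges)) unname(h@edges) else matrix(integer(), 0L, 2L))
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, matrix = "rowmajor",
                                digits = NA))
}

#' Import an extended hierarchy from JSON
#'
#' Inverse of [exportHierarchy()] with \code{format = "json"}.
#'
#' @param txt JSON text or path to a JSON file.
#' @return an [ExtendedHierarchy-class].
#' @export
importHierarchy <- function(txt) {
  if (length(txt) == 1L && !grepl("\n", txt) && !grepl("^\\s*\\{", txt) &&
      file.exists(txt))
    txt <- paste(readLines(txt, warn = FALSE), collapse = "\n")
  doc <- jsonlite::fromJSON(txt, simplifyDataFrame = FALSE,
                            simplifyMatrix = TRUE)
  sets <- lapply(doc$nodes, function(n) canonicalSet(unlist(n$taxa)))
  status <- vapply(doc$nodes, `[[`, character(1L), "status")
  edges <- if (length(doc$edges)) {
    e <- as.matrix(doc$edges)
    storage.mode(e) <- "integer"
    dimnames(e) <- list(NULL, c("lower", "upper"))
    e
  } else matrix(integer(), 0L, 2L, dimnames = list(NULL, c("lower", "upper")))
  new("ExtendedHierarchy", sets = sets, status = status, edges = edges,
      applyToxins = isTRUE(doc$apply_toxins))
}
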