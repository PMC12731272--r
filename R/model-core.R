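#' Construct a consumer-resource-toxin model
#'
#' Builds a [CRTModel-class] from a food-resource sign table and an optional
#' toxin sign table.  Entries must lie in \{-1, 0, 1\}: in the food table
#' \code{+1} marks production and \code{-1} a growth requirement; in the
#' toxin table \code{+1} marks production and \code{-1} sensitivity.  Row
#' names carry the taxa, column names the resource/toxin labels; both tables
#' must list the same taxa in the same order.
#'
#' @param foodTable numeric/integer matrix (taxa x resources) with dimnames.
#' @param toxinTable numeric/integer matrix (taxa x toxins) with dimnames;
#'   defaults to a zero-column matrix (toxin-free model).
#' @param validate logical; check validity (default TRUE).
#' @return a [CRTModel-class] object.
#' @examples
#' food <- matrix(c(0, 1, -1, 0), nrow = 2,
#'                dimnames = list(c("a", "b"), c("f1", "f2")))
#' CRTModel(food)
#' @export
CRTModel <- function(foodTable, toxinTable = NULL, validate = TRUE) {
  foodTable <- .asSignMatrix(foodTable)
  if (is.null(toxinTable)) {
    toxinTable <- matrix(integer(), nrow = nrow(foodTable), ncol = 0L,
                         dimnames = list(rownames(foodTable), character()))
  } else {
    toxinTable <- .asSignMatrix(toxinTable)
  }
  obj <- new("CRTModel", foodTable = foodTable, toxinTable = toxinTable)
  if (validate) {
    report <- validateModel(obj)
    if (length(report))
      stop("invalid CRT model:\n  ", paste(report, collapse = "\n  "))
  }
  obj
}

.asSignMatrix <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  if (is.null(rownames(m)))
    rownames(m) <- if (nrow(m)) paste0("s", seq_len(nrow(m))) else character()
  if (is.null(colnames(m)))
    colnames(m) <- if (ncol(m)) paste0("x", seq_len(ncol(m))) else character()
  m
}

#' Validate a CRT model
#'
#' Reports every invariant violation of a model -- out-of-domain entries,
#' duplicate labels, and taxa-dimension mismatches between the two tables --
#' with row/column coordinates.  An empty report means the model is valid.
#' Never throws; use this to inspect untrusted input.
#'
#' @param model a [CRTModel-class] (possibly malformed).
#' @return character vector of violation messages; empty when valid.
#' @examples
#' validateModel(crtFixture("fig1"))   # character(0)
#' @export
validateModel <- function(model) {
  msgs <- character()
  ft <- model@foodTable
  tt <- model@toxinTable
  if (nrow(ft) != nrow(tt))
    msgs <- c(msgs, sprintf(
      "taxa dimension mismatch: food table has %d rows, toxin table %d",
      nrow(ft), nrow(tt)))
  for (nm in c("foodTable", "toxinTable")) {
    m <- slot(model, nm)
    bad <- which(!(m %in% c(-1L, 0L, 1L)) | is.na(m))
    for (b in bad) {
      rc <- arrayInd(b, dim(m))
      msgs <- c(msgs, sprintf(
        "%s entry %s at (%s, %s) is outside {-1, 0, 1}", nm,
        as.character(m[b]),
        rownames(m)[rc[1L]] %||% rc[1L], colnames(m)[rc[2L]] %||% rc[2L]))
    }
  }
  tx <- rownames(ft)
  if (anyDuplicated(tx))
    msgs <- c(msgs, paste0("duplicate taxon labels: ",
                           paste(unique(tx[duplicated(tx)]), collapse = ", ")))
  if (nrow(ft) == nrow(tt) && !identical(tx, rownames(tt)))
    msgs <- c(msgs, "food and toxin tables index different taxa orderings")
  if (ncol(ft) && anyDuplicated(colnames(ft)))
    msgs <- c(msgs, "duplicate resource labels")
  if (ncol(tt) && anyDuplicated(colnames(tt)))
    msgs <- c(msgs, "duplicate toxin labels")
  if (length(intersect(colnames(ft), colnames(tt))))
    msgs <- c(msgs, "resource and toxin labels overlap")
  msgs
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

setMethod("taxa", "CRTModel", function(x) rownames(x@foodTable))
setMethod("resources", "CRTModel", function(x) colnames(x@foodTable) %||% character())
setMethod("toxins", "CRTModel", function(x) colnames(x@toxinTable) %||% character())
setMethod("foodTable", "CRTModel", function(x) x@foodTable)
setMethod("toxinTable", "CRTModel", function(x) x@toxinTable)

#' Per-taxon resource and toxin profile
#'
#' Extracts, for one taxon, the label sets read off its signed table rows:
#' required food resources (row entries of \code{-1}), produced food
#' resources (\code{+1}), produced toxins and sensitive toxins.  Because one
#' signed cell encodes one relation, required and produced resources are
#' disjoint by construction, as are produced and sensitive toxins.
#'
#' @param model a [CRTModel-class].
#' @param taxon a taxon label present in the model.
#' @return named list with character-vector elements \code{required},
#'   \code{produced}, \code{producedToxins}, \code{sensitiveToxins}.
#' @examples
#' taxonProfile(crtFixture("fig1"), "b")$required   # f1 f2 f4
#' @export
taxonProfile <- function(model, taxon) {
  if (!taxon %in% taxa(model))
    stop("unknown taxon label: ", taxon)
  fr <- model@foodTable[taxon, , drop = FALSE]
  tr <- model@toxinTable[taxon, , drop = FALSE]
  prof <- list(
    required = canonicalSet(colnames(fr)[fr == -1L]),
    produced = canonicalSet(colnames(fr)[fr == 1L]),
    producedToxins = canonicalSet(colnames(tr)[tr == 1L]),
    sensitiveToxins = canonicalSet(colnames(tr)[tr == -1L]))
  stopifnot(length(intersect(prof$required, prof$produced)) == 0L,
            length(intersect(prof$producedToxins, prof$sensitiveToxins)) == 0L)
  prof
}

# Internal cached bitmask view of a model used by the enumeration and
# simulation code paths: per-taxon masks of required/produced resources and
# produced/sensitive toxins.
.modelMasks <- function(model) {
  ft <- model@foodTable
  tt <- model@toxinTable
  M <- ncol(ft); T <- ncol(tt)
  req <- .masksFromIndices(apply(ft, 1L, function(r) which(r == -1L),
                                 simplify = FALSE), max(M, 1L))
  prod <- .masksFromIndices(apply(ft, 1L, function(r) which(r == 1L),
                                  simplify = FALSE), max(M, 1L))
  tprod <- .masksFromIndices(apply(tt, 1L, function(r) which(r == 1L),
                                   simplify = FALSE), max(T, 1L))
  tsens <- .masksFromIndices(apply(tt, 1L, function(r) which(r == -1L),
                                   simplify = FALSE), max(T, 1L))
  if (nrow(ft) == 0L) {
    w <- .nWords(max(M, 1L)); wt <- .nWords(max(T, 1L))
    req <- prod <- matrix(0L, w, 0L)
    tprod <- tsens <- matrix(0L, wt, 0L)
  }
  list(req = req, prod = prod, tprod = tprod, tsens = tsens,
       S = nrow(ft), M = M, T = T)
}
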