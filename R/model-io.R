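# Model serialization.
#
# TSV dialect: one header row listing resource labels, then a literal "|"
# marker column, then toxin labels; one row per taxon whose first field is
# the taxon label and whose cells are the literal characters +, - or 0.
# The marker column keeps the two tables visually and programmatically
# separable while remaining hand-editable.  The JSON schema mirrors the
# model fields (taxa/resources/toxins label arrays plus two integer
# matrices).

#' Read a CRT model from TSV or JSON
#'
#' @param source path to a file, or a character scalar holding the document
#'   text itself (anything containing a newline is treated as text).
#' @param format \code{"tsv"} or \code{"json"}.
#' @return a [CRTModel-class].
#' @details Round-trips bit-exactly with [writeCRTModel()].  Malformed cells,
#'   duplicate labels and ragged rows raise parse errors naming the
#'   offending location.
#' @examples
#' fig1 <- readCRTModel(system.file("extdata", "fig1.tsv", package = "cotox"))
#' @export
readCRTModel <- function(source, format = c("tsv", "json")) {
  format <- match.arg(format)
  txt <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source))
    paste(readLines(source, warn = FALSE), collapse = "\n") else
      paste(source, collapse = "\n")
  if (format == "tsv") .parseModelTSV(txt) else .parseModelJSON(txt)
}

.parseModelTSV <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty model document")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  if (header[1L] != "taxon")
    stop("model TSV must start with a 'taxon' header column")
  bar <- which(header == "|")
  if (length(bar) != 1L)
    stop("model TSV header must contain exactly one '|' marker column")
  resCols <- if (bar > 2L) 2L:(bar - 1L) else integer()
  toxCols <- if (bar < length(header)) (bar + 1L):length(header) else integer()
  resLabels <- header[resCols]
  toxLabels <- header[toxCols]
  n <- length(lines) - 1L
  food <- matrix(0L, n, length(resLabels))
  tox <- matrix(0L, n, length(toxLabels))
  taxaLabels <- character(n)
  for (i in seq_len(n)) {
    row <- cells[[i + 1L]]
    if (length(row) != length(header))
      stop(sprintf("ragged row %d: %d fields, expected %d", i, length(row),
                   length(header)))
    taxaLabels[i] <- row[1L]
    vals <- vapply(seq_along(header)[-1L], function(j) {
      if (j == bar) {
        if (row[j] != "|")
          stop(sprintf("row %d ('%s'): marker column must hold '|'", i, row[1L]))
        return(NA_integer_)
      }
      v <- switch(row[j], "+" = 1L, "-" = -1L, "0" = 0L, NA_integer_)
      if (is.na(v))
        stop(sprintf("parse error at (row %d '%s', col %d '%s'): cell '%s'",
                     i, row[1L], j, header[j], row[j]))
      v
    }, integer(1L))
    food[i, ] <- vals[resCols - 1L]
    tox[i, ] <- vals[toxCols - 1L]
  }
  if (anyDuplicated(taxaLabels))
    stop("duplicate taxon label in TSV: ",
         paste(unique(taxaLabels[duplicated(taxaLabels)]), collapse = ", "))
  dimnames(food) <- list(taxaLabels, resLabels)
  dimnames(tox) <- list(taxaLabels, toxLabels)
  CRTModel(food, tox)
}

.parseModelJSON <- function(txt) {
  doc <- jsonlite::fromJSON(txt, simplifyMatrix = TRUE)
  for (f in c("taxa", "resources", "toxins", "food_table", "toxin_table"))
    if (is.null(doc[[f]])) stop("model JSON missing field: ", f)
  tx <- as.character(doc$taxa)
  res <- as.character(doc$resources)
  tox <- as.character(doc$toxins)
  food <- .jsonMatrix(doc$food_table, length(tx), length(res), "food_table")
  toxm <- .jsonMatrix(doc$toxin_table, length(tx), length(tox), "toxin_table")
  dimnames(food) <- list(tx, res)
  dimnames(toxm) <- list(tx, tox)
  CRTModel(food, toxm)
}

.jsonMatrix <- function(x, nr, nc, what) {
  if (is.null(x) || length(x) == 0L || nr == 0L || nc == 0L)
    return(matrix(0L, nr, nc))
  m <- as.matrix(x)
  if (!all(dim(m) == c(nr, nc)))
    stop(sprintf("%s has dimensions %dx%d, expected %dx%d", what,
                 nrow(m), ncol(m), nr, nc))
  storage.mode(m) <- "integer"
  m
}

#' Write a CRT model to TSV or JSON text
#'
#' @param model a [CRTModel-class].
#' @param file optional path; when NULL the document text is returned.
#' @param format \code{"tsv"} or \code{"json"}.
#' @return the document as a character scalar (invisibly when written to
#'   \code{file}).
#' @export
writeCRTModel <- function(model, file = NULL, format = c("tsv", "json")) {
  format <- match.arg(format)
  txt <- if (format == "tsv") .formatModelTSV(model) else
    .formatModelJSON(model)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

.formatModelTSV <- function(model) {
  symOf <- c(`-1` = "-", `0` = "0", `1` = "+")
  header <- c("taxon", resources(model), "|", toxins(model))
  rows <- vapply(seq_along(taxa(model)), function(i) {
    paste(c(taxa(model)[i],
            symOf[as.character(model@foodTable[i, ])],
            "|",
            if (ncol(model@toxinTable))
              symOf[as.character(model@toxinTable[i, ])] else character()),
          collapse = "\t")
  }, character(1L))
  paste(c(paste(header, collapse = "\t"), rows), collapse = "\n")
}

.formatModelJSON <- function(model) {
  doc <- list(
    taxa = taxa(model),
    resources = resources(model),
    toxins = toxins(model),
    food_table = unname(model@foodTable),
    toxin_table = unname(model@toxinTable))
  jsonlite::toJSON(doc, matrix = "rowmajor", auto_unbox = FALSE, digits = NA)
}
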