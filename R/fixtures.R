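#' Built-in example models
#'
#' Small worked-example communities shipped as TSV files (which double as
#' format documentation under \code{inst/extdata}):
#' \describe{
#'   \item{\code{fig1}}{Five taxa (a..e), four food resources (f1..f4) and
#'     one toxin: c produces t1, a is sensitive to it.  Toxin-free
#'     enumeration yields nine non-empty organizations; applying the toxin
#'     leaves six.}
#'   \item{\code{bars_a}, \code{bars_b}, \code{bars_c}}{Three independently
#'     growing strains (A, R, S) whose structure arises purely from
#'     antagonism: no inhibition (a), strong inhibition of both R and S by
#'     A (b), or inhibition of S only (c).}
#' }
#'
#' @param name one of \code{"fig1"}, \code{"bars_a"}, \code{"bars_b"},
#'   \code{"bars_c"}.
#' @return a [CRTModel-class].
#' @examples
#' crtFixture("fig1")
#' @export
crtFixture <- function(name = c("fig1", "bars_a", "bars_b", "bars_c")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "cotox",
                      mustWork = TRUE)
  readCRTModel(path, format = "tsv")
}
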