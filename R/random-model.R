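#' Generate a seeded random CRT model
#'
#' Fills the two sign tables cell-wise: each food cell is \code{+1} with
#' probability \code{pFoodProduce}, \code{-1} with \code{pFoodRequire} and
#' \code{0} otherwise; each toxin cell is \code{+1} with
#' \code{pToxinProduce}, \code{-1} with \code{pToxinSensitive} and \code{0}
#' otherwise.  Cells are drawn row-major so the same seed yields the same
#' model on any platform.  The food-sign default of 1/3 per sign gives every
#' food cell an equal chance of produce / require / neither.
#'
#' @param S,M,T non-negative counts of taxa, food resources and toxins
#'   (\code{T = 0} gives a toxin-free model).
#' @param pFoodProduce,pFoodRequire food sign probabilities
#'   (defaults 1/3 each; their sum must not exceed 1).
#' @param pToxinProduce,pToxinSensitive toxin sign probabilities (sum at
#'   most 1).
#' @param seed integer seed; identical seeds give identical models.
#' @return a [CRTModel-class] with taxa \code{s1..sS}, resources
#'   \code{f1..fM}, toxins \code{t1..tT}.
#' @examples
#' m <- randomCRTModel(10, 10, 5, pToxinProduce = 0.1,
#'                     pToxinSensitive = 0.1, seed = 1)
#' @export
randomCRTModel <- function(S, M, T = 0L,
                           pFoodProduce = 1 / 3, pFoodRequire = 1 / 3,
                           pToxinProduce = 0.1, pToxinSensitive = 0.1,
                           seed = NULL) {
  stopifnot(S >= 0L, M >= 0L, T >= 0L)
  if (pFoodProduce < 0 || pFoodRequire < 0 ||
      pFoodProduce + pFoodRequire > 1 + 1e-12)
    stop("invalid food sign probabilities: pFoodProduce + pFoodRequire > 1")
  if (pToxinProduce < 0 || pToxinSensitive < 0 ||
      pToxinProduce + pToxinSensitive > 1 + 1e-12)
    stop("invalid toxin sign probabilities: pToxinProduce + pToxinSensitive > 1")
  .withSeed(seed, {
    food <- .drawSigns(S, M, pFoodProduce, pFoodRequire)
    tox <- .drawSigns(S, T, pToxinProduce, pToxinSensitive)
    dimnames(food) <- list(if (S) paste0("s", seq_len(S)) else character(),
                           if (M) paste0("f", seq_len(M)) else character())
    dimnames(tox) <- list(rownames(food),
                          if (T) paste0("t", seq_len(T)) else character())
    CRTModel(food, tox)
  })
}

.drawSigns <- function(nr, nc, pPlus, pMinus) {
  u <- if (nr * nc > 0L) stats::runif(nr * nc) else numeric()
  v <- integer(length(u))
  v[u < pPlus] <- 1L
  v[u >= pPlus & u < pPlus + pMinus] <- -1L
  matrix(v, nrow = nr, ncol = nc, byrow = TRUE)
}
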