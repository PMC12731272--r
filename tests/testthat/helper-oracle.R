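# Independent slow oracle used to validate the vectorized enumeration:
# literal subset loop over the power set with plain label-set algebra.
oracleOrganizations <- function(model, applyToxins = TRUE) {
  lab <- taxa(model)
  S <- length(lab)
  profs <- lapply(lab, taxonProfile, model = model)
  names(profs) <- lab
  res <- list()
  for (m in 0:(2^S - 1)) {
    mem <- lab[bitwAnd(bitwShiftR(m, 0:max(S - 1, 0)), 1L)[seq_len(S)] == 1L]
    prodU <- unique(unlist(lapply(mem, function(t) profs[[t]]$produced)))
    reqU <- unique(unlist(lapply(mem, function(t) profs[[t]]$required)))
    ok <- all(reqU %in% prodU)
    if (ok && applyToxins) {
      tp <- unique(unlist(lapply(mem, function(t) profs[[t]]$producedToxins)))
      ts <- unique(unlist(lapply(mem, function(t) profs[[t]]$sensitiveToxins)))
      ok <- length(intersect(tp, ts)) == 0L
    }
    if (ok) res[[length(res) + 1L]] <- canonicalSet(mem)
  }
  orderTaxaSets(res)
}

orderTaxaSets <- function(sets) {
  keys <- vapply(sets, paste, character(1L), collapse = "\x1f")
  sets[order(lengths(sets), keys, method = "radix")]
}

setKeys <- function(sets) vapply(sets, paste, character(1L), collapse = "\x1f")

sameSetList <- function(a, b) identical(sort(setKeys(a)), sort(setKeys(b)))

# small random models for property loops
randomTestModel <- function(seed, S = NULL, M = NULL, T = NULL,
                            pToxin = 0.15) {
  set.seed(seed)
  S <- S %||% sample(3:8, 1)
  M <- M %||% sample(1:5, 1)
  T <- T %||% sample(0:2, 1)
  randomCRTModel(S, M, T, pToxinProduce = pToxin, pToxinSensitive = pToxin,
                 seed = seed + 1000L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
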