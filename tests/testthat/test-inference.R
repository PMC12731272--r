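fig1 <- crtFixture("fig1")
fig1Orgs <- enumerateOrganizations(fig1)
fig1H <- buildExtendedHierarchy(fig1Orgs, fig1)
fig1Reds <- nodeSets(fig1H)[nodeStatus(fig1H) == "non_persistent_union"]

test_that("the worked example yields the single impairing ({a},{c})", {
  imps <- findImpairings(fig1Orgs, fig1Reds)
  expect_length(imps, 1L)
  expect_identical(sideA(imps[[1L]]), "a")
  expect_identical(sideB(imps[[1L]]), "c")

  expect_length(findImpairings(enumerateOrganizations(fig1, FALSE), list()),
                0L)

  barsC <- crtFixture("bars_c")
  orgsC <- enumerateOrganizations(barsC)
  hC <- buildExtendedHierarchy(orgsC, barsC)
  redsC <- nodeSets(hC)[nodeStatus(hC) == "non_persistent_union"]
  impsC <- findImpairings(orgsC, redsC)
  expect_length(impsC, 1L)
  expect_identical(sideA(impsC[[1L]]), "A")
  expect_identical(sideB(impsC[[1L]]), "S")
})

test_that("returned impairings are side-wise minimal and consistent", {
  checkMinimal <- function(imps, orgs) {
    containsBoth <- function(a, b) any(vapply(orgs, function(o)
      all(c(a, b) %in% o), logical(1L)))
    for (imp in imps) {
      expect_false(containsBoth(sideA(imp), sideB(imp)))
      for (drop in sideA(imp)) {
        smaller <- setdiff(sideA(imp), drop)
        if (length(smaller))
          expect_true(containsBoth(smaller, sideB(imp)))
      }
      for (drop in sideB(imp)) {
        smaller <- setdiff(sideB(imp), drop)
        if (length(smaller))
          expect_true(containsBoth(sideA(imp), smaller))
      }
    }
  }
  for (i in 1:20) {
    m <- randomTestModel(1800 + i, T = 2, pToxin = 0.25)
    orgs <- enumerateOrganizations(m)
    h <- buildExtendedHierarchy(orgs, m)
    reds <- nodeSets(h)[nodeStatus(h) == "non_persistent_union"]
    if (length(reds) == 0L) next
    checkMinimal(findImpairings(orgs, reds), orgs)
  }
})

test_that("minimal impairing covers explain every union at minimum size", {
  imps <- findImpairings(fig1Orgs, fig1Reds)
  covers <- minimalImpairingCover(imps, fig1Reds)
  expect_length(covers, 1L)
  expect_length(covers[[1L]], 1L)

  expect_identical(minimalImpairingCover(list(), list()), list(list()))

  # constructed four-taxon instance needing two independent impairings:
  # w,x,y,z all independent; w-x and y-z each mutually exclusive
  food <- matrix(0L, 4, 0, dimnames = list(c("w", "x", "y", "z"), NULL))
  tox <- matrix(c(1L, -1L, 0L, 0L, 0L, 0L, 1L, -1L), 4, 2,
                dimnames = list(c("w", "x", "y", "z"), c("u1", "u2")))
  m4 <- CRTModel(food, tox)
  orgs4 <- enumerateOrganizations(m4)
  h4 <- buildExtendedHierarchy(orgs4, m4)
  reds4 <- nodeSets(h4)[nodeStatus(h4) == "non_persistent_union"]
  imps4 <- findImpairings(orgs4, reds4)
  covers4 <- minimalImpairingCover(imps4, reds4)
  expect_true(all(lengths(covers4) == 2L))
})

test_that("impairing covers translate into verified toxin-table alternatives", {
  imps <- findImpairings(fig1Orgs, fig1Reds)
  covers <- minimalImpairingCover(imps, fig1Reds)
  alts <- impairingsToToxinTables(covers[[1L]], fig1Orgs, fig1Reds)
  expect_length(alts, 2L)
  expect_true(all(vapply(alts, `[[`, logical(1L), "verified")))
  producers <- sort(vapply(alts, function(a)
    a$assignments[[1L]]$producers, character(1L)))
  expect_identical(producers, c("a", "c"))

  expect_length(impairingsToToxinTables(list()), 1L)

  twoImps <- list(new("Impairing", sideA = "w", sideB = "x"),
                  new("Impairing", sideA = "y", sideB = "z"))
  expect_length(impairingsToToxinTables(twoImps), 4L)
})

test_that("toxin inference round-trips on random models", {
  tried <- 0L
  for (i in 1:50) {
    m <- randomTestModel(1900 + i, S = sample(4:8, 1), T = sample(1:2, 1),
                         pToxin = 0.2)
    orgs <- enumerateOrganizations(m)
    h <- buildExtendedHierarchy(orgs, m)
    reds <- nodeSets(h)[nodeStatus(h) == "non_persistent_union"]
    if (length(reds) == 0L) next
    tried <- tried + 1L
    imps <- findImpairings(orgs, reds)
    covers <- minimalImpairingCover(imps, reds)
    verified <- FALSE
    for (cov in covers) {
      alts <- impairingsToToxinTables(cov, orgs, reds)
      if (any(vapply(alts, `[[`, logical(1L), "verified"))) {
        verified <- TRUE
        break
      }
    }
    expect_true(verified, label = paste("model", i))
  }
  expect_gt(tried, 5L)
})

test_that("food-table inference reproduces the worked example exactly", {
  meas <- fig1Orgs
  imp <- list(new("Impairing", sideA = "a", sideB = "c"))
  res <- inferFoodTable(meas, imp, seed = 1)
  expect_identical(res$phase1Resources, 4L)
  expect_true(res$exact)
  sol <- res$solutions[[1L]]
  expect_identical(sol$nResources, 4L)

  # independent re-implication check through the enumeration machinery
  implied <- enumerateOrganizations(sol$model, applyToxins = FALSE)
  implied <- Filter(function(s) !all(c("a", "c") %in% s), implied)
  expect_true(sameSetList(implied, meas))
})

test_that("food-table inference handles the degenerate cases", {
  # everything measured: the empty table is exact
  allSets <- lapply(0:7, function(mask)
    c("a", "b", "c")[bitwAnd(bitwShiftR(mask, 0:2), 1L) == 1L])
  resAll <- inferFoodTable(allSets, taxaUniverse = c("a", "b", "c"))
  expect_true(resAll$exact)
  expect_identical(resAll$solutions[[1L]]$nResources, 0L)
  expect_identical(resAll$phase1Resources, 0L)

  # {empty, {a}} over {a, b}: b needs one resource nobody produces
  res2 <- inferFoodTable(list(character(), "a"),
                         taxaUniverse = c("a", "b"))
  expect_true(res2$exact)
  sol2 <- res2$solutions[[1L]]
  expect_identical(sol2$nResources, 1L)
  expect_identical(unname(foodTable(sol2$model)["b", ]), -1L)
  expect_identical(unname(foodTable(sol2$model)["a", ]), 0L)
})

test_that("inferred food tables re-imply the enumerated organizations of known models", {
  for (i in 1:12) {
    m <- randomTestModel(2000 + i, S = sample(3:5, 1), M = sample(2:3, 1),
                         T = 0)
    orgs <- enumerateOrganizations(m, applyToxins = FALSE)
    res <- inferFoodTable(orgs, taxaUniverse = taxa(m), seed = i)
    expect_true(res$exact, label = paste("toxin-free model", i))
    for (sol in res$solutions) {
      implied <- enumerateOrganizations(sol$model, applyToxins = FALSE)
      expect_true(sameSetList(implied, orgs))
    }
  }

  # with toxins: impairings taken from the generating toxin table (the
  # ground-truth exclusion structure), measured sets from enumeration
  for (i in 1:8) {
    m <- randomTestModel(2100 + i, S = sample(3:5, 1), M = sample(2:3, 1),
                         T = 1, pToxin = 0.35)
    orgs <- enumerateOrganizations(m)
    tt <- toxinTable(m)
    imps <- list()
    for (b in toxins(m)) {
      for (p in taxa(m)[tt[, b] == 1L]) for (v in taxa(m)[tt[, b] == -1L])
        imps[[length(imps) + 1L]] <- new("Impairing", sideA = p, sideB = v)
    }
    res <- inferFoodTable(orgs, imps, taxaUniverse = taxa(m), seed = i)
    expect_true(res$exact, label = paste("toxin model", i))
    sol <- res$solutions[[1L]]
    implied <- enumerateOrganizations(sol$model, applyToxins = FALSE)
    implied <- Filter(function(s) !any(vapply(imps, function(im)
      all(c(sideA(im), sideB(im)) %in% s), logical(1L))), implied)
    expect_true(sameSetList(implied, orgs))
  }
})
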