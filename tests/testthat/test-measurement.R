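fig1 <- crtFixture("fig1")
fig1Orgs <- enumerateOrganizations(fig1)

test_that("measurement draws honour mode semantics and seeding", {
  expect_length(drawMeasurements(fig1, fig1Orgs, "neutral", 0, seed = 1), 0L)

  novel <- drawMeasurements(fig1, fig1Orgs, "novel", seed = 2)
  expect_length(novel, 7L)
  expect_true(sameSetList(novel, fig1Orgs))
  expect_warning(drawMeasurements(fig1, fig1Orgs, "novel", 50, seed = 2),
                 "capped")

  n1 <- drawMeasurements(fig1, fig1Orgs, "neutral", 20, seed = 3)
  n2 <- drawMeasurements(fig1, fig1Orgs, "neutral", 20, seed = 3)
  expect_identical(n1, n2)

  r1 <- drawMeasurements(fig1, mode = "random", nDraws = 30, seed = 4)
  expect_true(all(vapply(r1, function(s)
    isOrganization(s, fig1), logical(1L))))
})

test_that("random encounters record the generated organization of the initial set", {
  # find a seed whose first initial draw is the full community: the
  # measurement must then be the generated organization {b,c,d,e}
  lab <- taxa(fig1)
  hit <- FALSE
  for (s in 1:200) {
    set.seed(s)
    if (all(stats::runif(length(lab)) < 0.5)) {
      meas <- drawMeasurements(fig1, mode = "random", nDraws = 1, seed = s)
      expect_identical(meas[[1L]], c("b", "c", "d", "e"))
      hit <- TRUE
      break
    }
  }
  expect_true(hit)
})

test_that("reconstruction updates derive the expected additional sets", {
  st <- updateReconstruction(newReconstruction(), c("a", "b", "d"))
  st <- updateReconstruction(st, c("b", "c", "d"))
  expect_true(sameSetList(additionalSets(st, "unions"),
                          list(c("a", "b", "c", "d"))))
  expect_true(sameSetList(additionalSets(st, "intersections"),
                          list(c("b", "d"))))
  expect_length(additionalSets(st, "organizations"), 0L)

  st2 <- updateReconstruction(st, c("b", "c", "d"))
  expect_identical(st2, st)

  full <- Reduce(updateReconstruction, fig1Orgs, newReconstruction())
  uni <- additionalSets(full, "unions")
  expect_true(all(c(paste(c("a", "b", "c", "d"), collapse = "\x1f"),
                    paste(c("a", "b", "c", "d", "e"), collapse = "\x1f"))
                  %in% setKeys(uni)))
})

test_that("additional organizations are always true organizations (exhaustive on the example)", {
  n <- length(fig1Orgs)
  trueKeys <- setKeys(fig1Orgs)
  for (mask in 1:(2^n - 1)) {
    chosen <- fig1Orgs[bitwAnd(bitwShiftR(mask, 0:(n - 1L)), 1L) == 1L]
    st <- Reduce(updateReconstruction, chosen, newReconstruction())
    addOrg <- additionalSets(st, "organizations")
    expect_true(all(setKeys(addOrg) %in% trueKeys))
  }
})

test_that("recovery curves are monotone and saturate", {
  rc <- recoveryCurve(fig1, mode = "novel", seed = 5)
  expect_true(all(diff(rc$fractionRecovered) >= 0))
  expect_identical(rc$fractionRecovered[nrow(rc)], 1)
  # novel draws recover exactly k/7 after k draws, plus any additional
  # organizations (which are provably true and not yet measured)
  expect_equal(rc$fractionRecovered * 7,
               rc$nMeasurements + rc$nAdditionalOrganizations)

  for (i in 1:10) {
    m <- randomTestModel(1600 + i)
    rcn <- recoveryCurve(m, mode = "neutral", nDraws = 25, seed = i)
    expect_true(all(diff(rcn$fractionRecovered) >= 0))
    rca <- recoveryCurve(m, mode = "neutral", nDraws = 25, seed = i,
                         countPolicy = "plus_additional_orgs")
    # additional organizations never inflate beyond truth
    expect_true(all(rca$fractionRecovered <= 1))
  }
})

test_that("union FDR is zero without toxins and one on the worked-example pair", {
  st <- updateReconstruction(newReconstruction(), c("a", "b", "d"))
  st <- updateReconstruction(st, c("b", "c", "d"))
  expect_identical(falseDiscoveryRate(st, fig1Orgs, "unions"), 1)
  expect_true(is.na(falseDiscoveryRate(newReconstruction(), fig1Orgs,
                                       "unions")))

  for (i in 1:25) {
    m <- randomTestModel(1700 + i, T = 0)
    orgs <- enumerateOrganizations(m, applyToxins = FALSE)
    if (length(orgs) < 2L) next
    set.seed(i)
    chosen <- orgs[sample(length(orgs), min(length(orgs),
                                            sample(2:5, 1L)))]
    st <- Reduce(updateReconstruction, chosen, newReconstruction())
    fdr <- falseDiscoveryRate(st, orgs, "unions")
    if (!is.na(fdr)) expect_identical(fdr, 0)
  }
})

test_that("neutral draws match the coupon-collector expectation", {
  N <- length(fig1Orgs)
  k <- 10L
  runs <- 200L
  uniq <- vapply(seq_len(runs), function(r)
    length(unique(setKeys(drawMeasurements(fig1, fig1Orgs, "neutral", k,
                                           seed = 2000 + r)))),
    integer(1L))
  expected <- N * (1 - (1 - 1 / N)^k)
  se <- stats::sd(uniq) / sqrt(runs)
  expect_lt(abs(mean(uniq) - expected), 3 * se + 1e-9)
})

test_that("the parameter study tabulates hierarchy counts with a zero-red toxin-free row", {
  st <- runParameterStudy(data.frame(S = c(4, 4), M = c(3, 3), T = c(0, 1)),
                          replicates = 5, seed = 11)
  expect_identical(nrow(st$replicates), 10L)
  noTox <- st$replicates[st$replicates$T == 0, ]
  expect_true(all(noTox$nNonPersistentUnions == 0L))
  expect_true(all(noTox$nOrganizations == noTox$nOrganizationsNoToxins))
  expect_identical(nrow(st$summary), 2L)

  # brute-force cross-check of one tabulated replicate
  one <- st$replicates[st$replicates$T == 1, ][1L, ]
  m <- randomCRTModel(one$S, one$M, one$T, seed = one$seed)
  orgs <- enumerateOrganizations(m)
  expect_identical(one$nOrganizations, length(orgs))
  h <- buildExtendedHierarchy(orgs, m)
  expect_identical(one$nNonPersistentUnions,
                   sum(nodeStatus(h) == "non_persistent_union"))
  expect_identical(one$nNonPersistentIntersections,
                   sum(nodeStatus(h) == "non_persistent_intersection"))
})
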