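fig1 <- crtFixture("fig1")
fig1OrgsTox <- enumerateOrganizations(fig1)
fig1OrgsFree <- enumerateOrganizations(fig1, applyToxins = FALSE)

test_that("the toxin-aware hierarchy has the expected red and yellow nodes", {
  h <- buildExtendedHierarchy(fig1OrgsTox, fig1)
  reds <- nodeSets(h)[nodeStatus(h) == "non_persistent_union"]
  expect_true(sameSetList(reds, list(c("a", "b", "c", "d"),
                                     c("a", "b", "c", "d", "e"))))
  yellows <- nodeSets(h)[nodeStatus(h) == "non_persistent_intersection"]
  expect_true(sameSetList(yellows, list("b", c("a", "b"), c("b", "d"),
                                        c("b", "e"), c("b", "d", "e"))))
  expect_error(buildExtendedHierarchy(list(c("a", "c")), fig1),
               "integrity error")
})

test_that("a toxin-free hierarchy has no non-persistent unions", {
  h <- buildExtendedHierarchy(fig1OrgsFree, fig1, applyToxins = FALSE)
  expect_false(any(nodeStatus(h) == "non_persistent_union"))
  for (i in 1:20) {
    m <- randomTestModel(800 + i, T = 0)
    orgs <- enumerateOrganizations(m, applyToxins = FALSE)
    h <- buildExtendedHierarchy(orgs, m, applyToxins = FALSE)
    expect_false(any(nodeStatus(h) == "non_persistent_union"))
  }
})

test_that("cover edges agree with a quadratic subset-check oracle", {
  checkCovers <- function(h) {
    sets <- nodeSets(h)
    n <- length(sets)
    strictSub <- function(a, b) length(a) < length(b) && all(a %in% b)
    expected <- list()
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (strictSub(sets[[i]], sets[[j]])) {
        between <- any(vapply(seq_len(n), function(k)
          k != i && k != j && strictSub(sets[[i]], sets[[k]]) &&
            strictSub(sets[[k]], sets[[j]]), logical(1L)))
        if (!between) expected[[length(expected) + 1L]] <- c(i, j)
      }
    }
    got <- hierarchyEdges(h)
    expmat <- if (length(expected)) do.call(rbind, expected) else
      matrix(integer(), 0L, 2L)
    expect_identical(unname(got[order(got[, 1], got[, 2]), , drop = FALSE]),
                     unname(expmat))
  }
  checkCovers(buildExtendedHierarchy(fig1OrgsTox, fig1))
  for (i in 1:8) {
    m <- randomTestModel(900 + i)
    orgs <- enumerateOrganizations(m)
    checkCovers(buildExtendedHierarchy(orgs, m))
  }
})

test_that("no organization sits above a non-persistent union on any upward path", {
  reachableUp <- function(h) {
    n <- length(nodeSets(h))
    adj <- matrix(FALSE, n, n)
    e <- hierarchyEdges(h)
    adj[e] <- TRUE
    reach <- adj
    repeat {
      nxt <- reach | (reach %*% adj > 0)
      if (identical(nxt, reach)) break
      reach <- nxt
    }
    reach
  }
  models <- c(list(fig1), lapply(1:40, function(i)
    randomTestModel(1000 + i, pToxin = 0.25)))
  for (m in models) {
    orgs <- enumerateOrganizations(m)
    h <- buildExtendedHierarchy(orgs, m)
    reach <- reachableUp(h)
    redIdx <- which(nodeStatus(h) == "non_persistent_union")
    greenIdx <- which(nodeStatus(h) == "organization")
    expect_false(any(reach[redIdx, greenIdx]))
  }
})

test_that("interaction clusters follow the sum rule and the printed classification", {
  cl <- interactionClusters(fig1OrgsFree, fig1, applyToxins = FALSE)
  byOrg <- setNames(cl, setKeys(lapply(cl, `[[`, "organization")))
  k <- function(...) paste(c(...), collapse = "\x1f")

  expect_identical(byOrg[[k("a", "b", "c", "e")]]$cluster, "c")
  expect_identical(byOrg[[k("a", "b", "c", "e")]]$kind, "context_dependent")
  expect_identical(byOrg[[k("b", "c", "d")]]$cluster, c("b", "c", "d"))
  expect_identical(byOrg[[k("b", "c", "d")]]$kind, "context_free")
  expect_identical(byOrg[[k("a", "b", "c", "d", "e")]]$cluster, character())

  nonEmpty <- Filter(function(r) length(r$cluster) > 0L, cl)
  cf <- Filter(function(r) r$kind == "context_free", nonEmpty)
  cd <- Filter(function(r) r$kind == "context_dependent", nonEmpty)
  expect_true(sameSetList(lapply(cf, `[[`, "cluster"),
                          list("a", c("b", "c", "d"))))
  expect_length(unique(setKeys(lapply(cd, `[[`, "cluster"))), 4L)
  expect_true(sameSetList(unique(lapply(cd, `[[`, "cluster")),
                          list(c("b", "d"), c("b", "e"), "c", "e")))
})

test_that("elementary organizations rebuild the rest by unions", {
  elemFree <- elementaryOrganizations(fig1OrgsFree, fig1,
                                      applyToxins = FALSE)
  expect_true(sameSetList(elemFree, list(
    "a", c("a", "b", "d"), c("a", "b", "e"), c("b", "c", "d"),
    c("a", "b", "c", "e"), c("b", "c", "d", "e"))))

  elemTox <- elementaryOrganizations(fig1OrgsTox, fig1)
  expect_true(sameSetList(elemTox, list(
    "a", c("a", "b", "d"), c("a", "b", "e"), c("b", "c", "d"),
    c("b", "c", "d", "e"))))

  expect_length(elementaryOrganizations(list(character()), fig1), 0L)
})

test_that("every interaction cluster is connected by resource dependencies", {
  g <- clusterDependencyGraph(c("b", "d"), fig1)
  expect_identical(igraph::ecount(g), 1)
  expect_true(igraph::is_connected(g))
  g1 <- clusterDependencyGraph("c", fig1)
  expect_identical(igraph::vcount(g1), 1)
  expect_true(igraph::is_connected(g1))
  g3 <- clusterDependencyGraph(c("b", "c", "d"), fig1)
  expect_true(igraph::is_connected(g3))

  for (i in 1:60) {
    m <- randomTestModel(1100 + i, T = 0)
    orgs <- enumerateOrganizations(m, applyToxins = FALSE)
    cl <- interactionClusters(orgs, m, applyToxins = FALSE)
    for (r in cl) {
      if (length(r$cluster) == 0L) next
      expect_true(igraph::is_connected(clusterDependencyGraph(r$cluster, m)))
    }
  }
})

test_that("hierarchy exports carry colors and the JSON round-trips", {
  h <- buildExtendedHierarchy(fig1OrgsTox, fig1)
  dot <- exportHierarchy(h, "dot")
  expect_identical(lengths(regmatches(dot, gregexpr("fillcolor=red", dot))),
                   2L)
  expect_match(dot, "rank=same")
  gml <- exportHierarchy(h, "graphml")
  expect_match(gml, "<graphml")

  h2 <- importHierarchy(exportHierarchy(h, "json"))
  expect_identical(nodeSets(h2), nodeSets(h))
  expect_identical(nodeStatus(h2), nodeStatus(h))
  expect_identical(hierarchyEdges(h2), hierarchyEdges(h))

  m <- randomTestModel(1201)
  hr <- buildExtendedHierarchy(enumerateOrganizations(m), m)
  hr2 <- importHierarchy(exportHierarchy(hr, "json"))
  expect_identical(nodeSets(hr2), nodeSets(hr))
  expect_identical(hierarchyEdges(hr2), hierarchyEdges(hr))

  hEmpty <- buildExtendedHierarchy(list(character()), fig1)
  expect_length(nodeSets(hEmpty), 1L)
  expect_identical(nrow(hierarchyEdges(hEmpty)), 0L)
})
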