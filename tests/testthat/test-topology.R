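test_that("BFS distances match Floyd-Warshall on random graphs", {
  for (s in 1:10) {
    net <- randomGraph(sample(4:8, 1), runif(1, 0.2, 0.7), s)
    expect_identical(shortestPaths(net), floydWarshall(net))
  }
})

test_that("distances handle paths and disconnected graphs", {
  d <- shortestPaths(fixtureGraph("path", 3))
  expect_identical(d["v1", "v3"], 2L)
  expect_identical(d, t(d))
  expect_true(all(diag(d) == 0L))
  two <- PPANetwork(c("A", "B", "C", "X", "Y", "Z"),
                    rbind(c("A", "B"), c("B", "C"), c("A", "C"),
                          c("X", "Y"), c("Y", "Z"), c("X", "Z")))
  d2 <- shortestPaths(two)
  expect_true(all(is.na(d2[1:3, 4:6])))
})

test_that("diameter and path length match closed forms", {
  expect_equal(diameterAndPathLength(fixtureGraph("path", 3)),
               list(D = 2L, L = 4 / 3))
  expect_equal(diameterAndPathLength(fixtureGraph("clique", 6)),
               list(D = 1L, L = 1))
  # star with 5 leaves: 10 ordered pairs at distance 1, 20 at 2
  expect_equal(diameterAndPathLength(fixtureGraph("star", 5))$L, 5 / 3)
  expect_error(diameterAndPathLength(PPANetwork(c("A", "B"))),
               "no connected pairs")
  # L averages mutually reachable pairs only: isolated nodes change nothing
  tri <- fixtureGraph("clique", 3)
  triPlus <- PPANetwork(c(nodes(tri), "zz"), edges(tri))
  expect_equal(diameterAndPathLength(triPlus), diameterAndPathLength(tri))
})

test_that("clustering matches brute-force triangle counting", {
  for (s in 1:10) {
    net <- randomGraph(sample(4:8, 1), runif(1, 0.2, 0.8), s + 100)
    expect_equal(clusteringCoefficients(net)$ci, bruteClustering(net))
  }
  expect_equal(clusteringCoefficients(fixtureGraph("clique", 3))$global, 1)
  expect_true(all(clusteringCoefficients(fixtureGraph("cycle", 4))$ci == 0))
  # k < 2 nodes are excluded from the global mean, not counted as zero
  star <- fixtureGraph("star", 4)
  expect_identical(sum(!is.na(clusteringCoefficients(star)$ci)), 1L)
})

test_that("per-degree C(k) curve is weighted-mean consistent", {
  net <- projectNetwork(generateMembership(membershipGenConfig(
    n_targets = 60, n_pathways = 20, mean = 6, isolated_fraction = 0.15,
    seed = 2)))
  cl <- clusteringCoefficients(net)
  expect_equal(sum(cl$ck_curve$count * cl$ck_curve$meanC),
               sum(cl$ci, na.rm = TRUE))
  expect_equal(sum(cl$ck_curve$count), sum(!is.na(cl$ci)))
})

test_that("C(k) exponent fit recovers exact power laws", {
  curve <- data.frame(k = c(2, 4, 8, 16), meanC = c(2, 4, 8, 16)^-0.71)
  fit <- fitCkExponent(curve)
  expect_equal(fit$exponent, 0.71, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  flat <- data.frame(k = c(2, 4, 8), meanC = 0.5)
  expect_equal(fitCkExponent(flat)$exponent, 0, tolerance = 1e-12)
  expect_error(fitCkExponent(data.frame(k = c(1, 2, 3),
                                        meanC = c(0.5, 0.4, 0))),
               "at least 3")
})

test_that("Knn and assortativity match closed forms and the Pearson form", {
  st <- knnAssortativity(fixtureGraph("star", 3))
  expect_identical(unname(st$knn["hub"]), 1)
  expect_true(all(st$knn[c("v1", "v2", "v3")] == 3))
  expect_equal(st$r, -1)               # hand-evaluated: (3 - 4) / (5 - 4)
  k4 <- knnAssortativity(fixtureGraph("clique", 4))
  expect_false(k4$r_defined)           # zero endpoint-degree variance
  expect_true(is.na(k4$r))
  for (s in 1:10) {
    net <- randomGraph(sample(5:8, 1), runif(1, 0.3, 0.8), s + 200)
    if (numEdges(net) == 0) next
    ka <- knnAssortativity(net)
    po <- pearsonAssortativity(net)
    if (ka$r_defined) expect_equal(ka$r, unname(po))
  }
})

test_that("assortativity of an Erdos-Renyi graph is near zero", {
  rs <- vapply(1:10, function(s) {
    net <- randomGraph(500, 0.05, s + 300)
    knnAssortativity(net)$r
  }, 0)
  expect_true(all(abs(rs) < 0.1))
})

test_that("metrics agree with igraph on random graphs", {
  skip_if_not_installed("igraph")
  for (s in 1:6) {
    net <- randomGraph(sample(6:9, 1), 0.4, s + 400)
    if (numEdges(net) < 2) next
    g <- asIgraph(net)
    d <- shortestPaths(net)
    dg <- igraph::distances(g)
    dg[is.infinite(dg)] <- NA
    expect_equal(unname(d), unname(dg[nodes(net), nodes(net)]))
    ci <- clusteringCoefficients(net)$ci
    ti <- igraph::transitivity(g, type = "local", isolates = "NaN")
    names(ti) <- igraph::V(g)$name
    expect_equal(ci[!is.na(ci)], ti[names(ci[!is.na(ci)])])
    ka <- knnAssortativity(net)
    if (ka$r_defined)
      expect_equal(ka$r, igraph::assortativity_degree(g))
    knn_ig <- igraph::knn(g)$knn
    expect_equal(ka$knn[!is.na(ka$knn)],
                 knn_ig[names(ka$knn[!is.na(ka$knn)])])
  }
})

test_that("summary invariants hold and are relabelling-invariant", {
  net <- projectNetwork(generateMembership(membershipGenConfig(
    n_targets = 40, n_pathways = 14, mean = 5, isolated_fraction = 0.2,
    seed = 9)))
  s <- networkSummary(net)
  dd <- s@degreeDistribution
  expect_identical(sum(dd$count), s@N)
  expect_equal(sum(dd$pk), 100)
  expect_identical(sum(dd$k * dd$count), 2L * s@E)
  expect_gte(s@diameter, ceiling(s@avgPathLength))
  expect_lte(s@avgPathLength, s@diameter)
  # relabelling leaves C and L unchanged
  perm <- setNames(sprintf("z%02d", seq_along(nodes(net))), nodes(net))
  e <- edges(net)
  relab <- PPANetwork(unname(perm), cbind(perm[e[, 1]], perm[e[, 2]]))
  s2 <- networkSummary(relab)
  expect_equal(s2@clustering, s@clustering)
  expect_equal(s2@avgPathLength, s@avgPathLength)
  expect_equal(s2@assortativity, s@assortativity)
})
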