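test_that("degree-factor hub rule reproduces the printed five-hub outcome", {
  k <- degreeMultiset(printedDegreeTable())
  hubs <- identifyHubs(k, "degree_factor", 2.5)
  expect_identical(nrow(hubs), 5L)
  expect_identical(hubs$k, c(63L, 53L, 53L, 51L, 51L))
})

test_that("hub rules handle cliques, stars and ties", {
  expect_identical(nrow(identifyHubs(fixtureGraph("clique", 6))), 0L)
  st <- identifyHubs(fixtureGraph("star", 9))   # <k> = 1.8, cut 4.5
  expect_identical(st$node, "hub")
  # top_n includes boundary ties
  k <- setNames(c(9L, 7L, 7L, 3L, 1L), letters[1:5])
  expect_identical(identifyHubs(k, "top_n", 2)$node, c("a", "b", "c"))
  expect_error(identifyHubs(k, param = 0), "positive")
})

test_that("hubs under degree_factor grow as the factor shrinks", {
  k <- degreeMultiset(printedDegreeTable())
  prev <- character()
  for (f in c(3, 2.5, 2, 1.5, 1)) {
    cur <- identifyHubs(k, "degree_factor", f)$node
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("robust-z outliers recover a planted inflated set", {
  set.seed(42)
  n <- 100
  ci <- data.frame(node = sprintf("n%03d", 1:n),
                   cd = c(runif(94, 0.28, 0.32), runif(6, 0.5, 0.6)),
                   cb = c(runif(94, 0.008, 0.012), runif(6, 0.03, 0.09)),
                   cc = c(runif(94, 0.49, 0.51), runif(6, 0.52, 0.58)))
  out <- detectCentralOutliers(ci, 2.5)
  expect_setequal(out$node, sprintf("n%03d", 95:100))
  expect_true(all(diff(out$max_z) <= 0))
})

test_that("outlier detection guards degenerate and tiny inputs", {
  flat <- data.frame(node = letters[1:6], cd = 0.5, cb = 0.1, cc = 0.5)
  expect_identical(nrow(detectCentralOutliers(flat)), 0L)
  # flat distribution plus one distinct high node: flagged via the MAD guard
  up <- rbind(flat, data.frame(node = "z", cd = 0.9, cb = 0.1, cc = 0.5))
  expect_identical(detectCentralOutliers(up)$node, "z")
  expect_error(detectCentralOutliers(flat[1:4, ]), "at least 5")
  # nodes with undefined closeness do not enter the z computation
  withNA <- rbind(flat, data.frame(node = "iso", cd = 0, cb = 0, cc = NA))
  expect_identical(nrow(detectCentralOutliers(withNA)), 0L)
})

test_that("outliers are invariant to adding nodes at the median", {
  set.seed(7)
  ci <- data.frame(node = sprintf("n%02d", 1:20),
                   cd = runif(20), cb = runif(20), cc = runif(20))
  ci$cd[1] <- 5; ci$cb[1] <- 5; ci$cc[1] <- 5
  base <- detectCentralOutliers(ci, 2.5)
  atMedian <- data.frame(node = c("m1", "m2"),
                         cd = median(ci$cd), cb = median(ci$cb),
                         cc = median(ci$cc))
  expect_identical(detectCentralOutliers(rbind(ci, atMedian), 2.5)$node,
                   base$node)
})

test_that("key targets are the outlier set; hub overlap is reported", {
  hubs <- data.frame(node = c("B", "C"), k = c(10L, 9L))
  out <- data.frame(node = c("A", "B"), max_z = c(4, 3))
  keys <- selectKeyTargets(hubs, out)
  expect_identical(keys$key_targets, c("A", "B"))
  expect_identical(keys$hub_overlap, "B")
  expect_warning(empty <- selectKeyTargets(hubs, out[0, ]), "empty")
  expect_identical(empty$status, "empty")
  expect_length(empty$key_targets, 0L)
})

test_that("six outliers with five hubs mirrors the published configuration", {
  hubs <- data.frame(node = c("PGH2", "MAPK1", "MAPK3", "GNAS", "PRKCA"),
                     k = c(63L, 53L, 53L, 51L, 51L))
  out <- data.frame(node = c("PGH2", "GNAS", "MAPK1", "MAPK3", "PRKCA",
                             "MAOA"),
                    max_z = 6:1)
  keys <- selectKeyTargets(hubs, out)
  expect_length(keys$key_targets, 6L)
  expect_length(keys$hub_overlap, 5L)
  expect_false("MAOA" %in% keys$hub_overlap)
})

test_that("neighbour coverage counts the union minus the keys", {
  st <- fixtureGraph("star", 4)
  cov <- neighborCoverage(st, "hub")
  expect_identical(cov$count, 4L)
  expect_equal(cov$percent, 100 * 4 / 5)
  expect_identical(neighborCoverage(st, character())$count, 0L)
  expect_equal(neighborCoverage(st, character())$percent, 0)
  # union bound: count <= sum of key degrees
  net <- randomGraph(12, 0.3, 900)
  keys <- nodes(net)[1:3]
  expect_lte(neighborCoverage(net, keys)$count,
             sum(degrees(net)[keys]))
  expect_error(neighborCoverage(st, "nope"), "nodes of the network")
})
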