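test_that("membership generator honours counts, sizes and the isolated set", {
  cfg <- membershipGenConfig(n_targets = 118, n_pathways = 86, mean = 8,
                             attachment_bias = 1, isolated_fraction = 0.23,
                             seed = 7)
  mem <- generateMembership(cfg)
  expect_length(targets(mem), 118L)
  expect_length(pathways(mem), 86L)
  sizes <- lengths(pathways(mem))
  expect_true(all(sizes >= 3))
  # exactly round(0.23 * 118) = 27 targets pathway-less, the last ids
  members <- unique(unlist(pathways(mem), use.names = FALSE))
  orphans <- setdiff(targets(mem), members)
  expect_length(orphans, 27L)
  expect_identical(sort(orphans), sort(targets(mem))[92:118])
  net <- projectNetwork(mem)
  expect_identical(numNodes(net), 118L)
  expect_identical(sum(degrees(net) == 0L), 27L)
})

test_that("generation is deterministic for a fixed seed", {
  cfg <- membershipGenConfig(n_targets = 40, n_pathways = 12, mean = 5,
                             isolated_fraction = 0.2, seed = 11)
  expect_identical(generateMembership(cfg), generateMembership(cfg))
  ccfg <- compoundGenConfig(6, "uniform", min_hits = 2, max_hits = 5,
                            seed = 11)
  t <- targets(generateMembership(cfg))
  expect_identical(links(generateCompoundTargets(ccfg, t)),
                   links(generateCompoundTargets(ccfg, t)))
})

test_that("different seeds give different link sets", {
  t <- sprintf("T%02d", 1:30)
  c1 <- generateCompoundTargets(
    compoundGenConfig(5, "uniform", min_hits = 3, max_hits = 8, seed = 1), t)
  c2 <- generateCompoundTargets(
    compoundGenConfig(5, "uniform", min_hits = 3, max_hits = 8, seed = 2), t)
  expect_false(identical(links(c1), links(c2)))
})

test_that("compound generator respects hit bounds and degenerate configs", {
  t <- sprintf("T%02d", 1:40)
  cmap <- generateCompoundTargets(
    compoundGenConfig(13, "uniform", min_hits = 5, max_hits = 15, seed = 1), t)
  hits <- table(links(cmap)$compound)
  expect_length(hits, 13L)
  expect_true(all(hits >= 5 & hits <= 15))
  expect_identical(nrow(links(generateCompoundTargets(
    compoundGenConfig(0), t))), 0L)
  expect_error(generateCompoundTargets(compoundGenConfig(3), character()),
               "empty")
  # poisson law truncates to >= 1 link per compound
  cmap2 <- generateCompoundTargets(
    compoundGenConfig(20, "poisson", mean = 0.2, seed = 3), t)
  expect_true(all(table(links(cmap2)$compound) >= 1))
  expect_length(unique(links(cmap2)$compound), 20L)
})

test_that("infeasible membership configs error", {
  expect_error(membershipGenConfig(n_targets = 10, min_size = 3,
                                   max_size = 11), "max_size")
  expect_error(membershipGenConfig(n_targets = 10, min_size = 8,
                                   max_size = 5), "min_size")
  # capacity cannot cover the non-isolated targets
  cfg <- membershipGenConfig(n_targets = 100, n_pathways = 2, mean = 4,
                             min_size = 3, max_size = 5,
                             isolated_fraction = 0, seed = 1)
  expect_error(generateMembership(cfg), "infeasible")
})

test_that("attachment bias raises the maximum projected degree", {
  maxk <- function(bias) {
    vapply(1:20, function(s) {
      cfg <- membershipGenConfig(n_targets = 60, n_pathways = 25, mean = 6,
                                 attachment_bias = bias,
                                 isolated_fraction = 0.1, seed = s)
      max(degrees(projectNetwork(generateMembership(cfg))))
    }, 0)
  }
  expect_gt(mean(maxk(3)), mean(maxk(0)))
})

test_that("projected memberships cluster above degree-matched rewirings", {
  skip_if_not_installed("igraph")
  for (s in 1:5) {
    cfg <- membershipGenConfig(n_targets = 50, n_pathways = 15, mean = 6,
                               isolated_fraction = 0.1, seed = s)
    net <- projectNetwork(generateMembership(cfg))
    cObs <- clusteringCoefficients(net)$global
    g <- asIgraph(net)
    set.seed(s)
    gR <- igraph::rewire(g, igraph::keeping_degseq(niter = 20 * numEdges(net)))
    cRand <- igraph::transitivity(gR, type = "localaverage", isolates = "NaN")
    expect_gte(cObs, cRand)
  }
})

test_that("fixture graphs match their closed forms", {
  cl4 <- fixtureGraph("clique", 4)
  expect_identical(numEdges(cl4), 6L)
  expect_true(all(degrees(cl4) == 3L))
  st <- fixtureGraph("star", 5)
  expect_identical(unname(degrees(st)["hub"]), 5L)
  expect_identical(sum(degrees(st) == 1L), 5L)
  expect_identical(numEdges(fixtureGraph("path", 4)), 3L)
  cy <- fixtureGraph("cycle", 5)
  expect_true(all(degrees(cy) == 2L))
  expect_error(fixtureGraph("moebius", 5))
})

test_that("hierarchical fixture has the replica structure and decaying C(k)", {
  h <- fixtureGraph("hierarchical", 4, 3)
  expect_identical(numNodes(h), 64L)
  # brute-force per-degree clustering must decrease with degree
  ci <- bruteClustering(h)
  k <- degrees(h)
  curve <- tapply(ci[!is.na(ci)], k[!is.na(ci)], mean)
  expect_true(all(diff(curve[order(as.integer(names(curve)))]) < 0))
  # bias=0 degenerate: all pathways singletons -> projection has no edges
  cfg <- membershipGenConfig(n_targets = 5, n_pathways = 5, min_size = 1,
                             max_size = 1, attachment_bias = 0,
                             isolated_fraction = 0, seed = 1)
  expect_identical(numEdges(projectNetwork(generateMembership(cfg))), 0L)
})
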