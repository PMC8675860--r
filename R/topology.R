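# Global and per-node topology: shortest paths, diameter, average path
# length, clustering and its per-degree scaling C(k), average
# nearest-neighbour degree Knn and degree assortativity.  All metrics are
# computed directly on the adjacency structure; nothing here delegates to
# a graph library, so every convention (which pairs enter L, which nodes
# enter C, how ties and undefined values are handled) is explicit.

#' All-pairs shortest path lengths
#'
#' Breadth-first search from every node.  `d[i, i] = 0`; unreachable pairs
#' carry `NA` (an explicit missing marker, never a numeric sentinel), so
#' downstream averages cannot silently absorb them.
#'
#' @param net a [PPANetwork-class].
#' @return A symmetric integer matrix with node labels as dimnames.
#' @examples
#' shortestPaths(fixtureGraph("path", 3))["v1", "v3"]  # 2
#' @export
shortestPaths <- function(net) {
  stopifnot(is(net, "PPANetwork"))
  n <- numNodes(net)
  adj <- .adjList(net)
  d <- matrix(NA_integer_, n, n, dimnames = list(net@nodes, net@nodes))
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    frontier <- s
    depth <- 0L
    while (length(frontier)) {
      depth <- depth + 1L
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[is.na(dist[nxt])]
      dist[nxt] <- depth
      frontier <- nxt
    }
    d[s, ] <- dist
  }
  d
}

#' Diameter and average path length
#'
#' Diameter `D` is the largest finite shortest-path length.  `L` is the
#' mean of `d_ij` over all ordered pairs `i != j` that are mutually
#' reachable — the restriction that makes the average well defined on a
#' network carrying isolated nodes and several components.
#'
#' @param net a [PPANetwork-class] with at least one edge.
#' @return A list with elements `D` (integer) and `L` (numeric).
#' @examples
#' diameterAndPathLength(fixtureGraph("path", 3))  # D = 2, L = 4/3
#' @export
diameterAndPathLength <- function(net) {
  d <- shortestPaths(net)
  off <- d[row(d) != col(d)]
  finite <- off[!is.na(off)]
  if (!length(finite)) stop("no connected pairs")
  list(D = max(finite), L = mean(finite))
}

#' Local clustering coefficients and the C(k) curve
#'
#' For each node `i` with degree `k_i >= 2`, `C_i = 2 e_i / (k_i (k_i -
#' 1))` where `e_i` counts edges among `i`'s neighbours; nodes with fewer
#' than two neighbours have no defined clustering and carry `NA`.  The
#' global coefficient is the mean over nodes with defined `C_i`, and the
#' `C(k)` curve holds the per-degree mean of `C_i`.
#'
#' @param net a [PPANetwork-class].
#' @return A list: `ci` (named numeric, `NA` where undefined), `global`
#'   (numeric, `NA` when no node qualifies), `ck_curve` (data.frame with
#'   columns `k`, `count`, `meanC`).
#' @examples
#' clusteringCoefficients(fixtureGraph("clique", 3))$global  # 1
#' @export
clusteringCoefficients <- function(net) {
  stopifnot(is(net, "PPANetwork"))
  adj <- .adjList(net)
  n <- numNodes(net)
  k <- lengths(adj)
  ci <- rep(NA_real_, n)
  names(ci) <- net@nodes
  adjSets <- adj   # sorted integer vectors; membership via findInterval
  for (i in which(k >= 2L)) {
    nb <- adj[[i]]
    ei <- 0L
    for (a in seq_len(length(nb) - 1L)) {
      rest <- nb[(a + 1L):length(nb)]
      ei <- ei + sum(rest %in% adjSets[[nb[a]]])
    }
    ci[i] <- 2 * ei / (k[i] * (k[i] - 1))
  }
  defined <- !is.na(ci)
  ks <- sort(unique(k[defined]))
  ck <- data.frame(k = ks,
                   count = vapply(ks, function(kk)
                     sum(k == kk & defined), 0L),
                   meanC = vapply(ks, function(kk)
                     mean(ci[k == kk & defined]), 0))
  list(ci = ci,
       global = if (any(defined)) mean(ci[defined]) else NA_real_,
       ck_curve = ck)
}

#' Fit the power-law decay exponent of C(k)
#'
#' Ordinary least squares of `log10(meanC)` on `log10(k)` over curve
#' points with `k >= 2` and `meanC > 0`.  The exponent is reported as the
#' negated slope, so a decaying `C(k) ~ k^-a` yields a positive `a`.
#'
#' @param ck_curve data.frame with columns `k` and `meanC`, as returned by
#'   [clusteringCoefficients()].
#' @return A list with `exponent` and `r_squared`.
#' @examples
#' curve <- data.frame(k = c(2, 4, 8, 16), meanC = c(2, 4, 8, 16)^-0.71)
#' fitCkExponent(curve)$exponent  # 0.71
#' @export
fitCkExponent <- function(ck_curve) {
  ok <- ck_curve$k >= 2 & ck_curve$meanC > 0
  if (sum(ok) < 3L)
    stop("need at least 3 curve points with k >= 2 and mean C > 0")
  x <- log10(ck_curve$k[ok])
  y <- log10(ck_curve$meanC[ok])
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(exponent = -unname(stats::coef(fit)[2L]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1)
}

#' Average nearest-neighbour degree and assortativity
#'
#' `Knn_i` is the mean degree of node `i`'s neighbours (undefined, `NA`,
#' for isolated nodes); the `Knn(k)` curve is its per-degree mean, whose
#' trend in `k` diagnoses degree correlations.  The assortativity
#' coefficient `r` is the Pearson-type correlation of the degrees at the
#' two ends of each edge, in the symmetrised edge-sum form
#' \deqn{r = \frac{E^{-1}\sum_i x_i y_i - [E^{-1}\sum_i \frac{1}{2}(x_i+y_i)]^2}
#'            {E^{-1}\sum_i \frac{1}{2}(x_i^2+y_i^2) - [E^{-1}\sum_i \frac{1}{2}(x_i+y_i)]^2}}
#' with each undirected edge entered once.  When all edges join
#' equal-degree endpoints the denominator vanishes and `r` is reported as
#' undefined rather than NaN.
#'
#' @param net a [PPANetwork-class] with at least one edge.
#' @return A list: `knn` (named numeric), `knn_curve` (data.frame `k`,
#'   `count`, `meanKnn`), `r` (numeric, `NA` when undefined), `r_defined`
#'   (logical).
#' @examples
#' knnAssortativity(fixtureGraph("star", 3))$r  # -1
#' @export
knnAssortativity <- function(net) {
  stopifnot(is(net, "PPANetwork"))
  if (numEdges(net) == 0L) stop("network has no edges")
  adj <- .adjList(net)
  k <- lengths(adj)
  knn <- rep(NA_real_, numNodes(net))
  names(knn) <- net@nodes
  for (i in which(k > 0L)) knn[i] <- mean(k[adj[[i]]])
  defined <- !is.na(knn)
  ks <- sort(unique(k[defined]))
  curve <- data.frame(k = ks,
                      count = vapply(ks, function(kk)
                        sum(k == kk & defined), 0L),
                      meanKnn = vapply(ks, function(kk)
                        mean(knn[k == kk & defined]), 0))
  x <- k[match(net@edges[, 1L], net@nodes)]
  y <- k[match(net@edges[, 2L], net@nodes)]
  E <- length(x)
  m1 <- sum((x + y) / 2) / E
  num <- sum(x * y) / E - m1^2
  den <- sum((x^2 + y^2) / 2) / E - m1^2
  if (den <= .Machine$double.eps * max(1, sum(x^2 + y^2) / E)) {
    r <- NA_real_; r_defined <- FALSE
  } else {
    r <- num / den; r_defined <- TRUE
  }
  list(knn = knn, knn_curve = curve, r = r, r_defined = r_defined)
}

#' Degree distribution table
#'
#' @param net a [PPANetwork-class].
#' @return data.frame with columns `k` (descending), `count`, and `pk`
#'   (percent of nodes with that degree).
#' @export
degreeDistribution <- function(net) {
  k <- degrees(net)
  ks <- sort(unique(k), decreasing = TRUE)
  count <- vapply(ks, function(kk) sum(k == kk), 0L)
  data.frame(k = as.integer(ks), count = count,
             pk = 100 * count / length(k))
}

#' Full topological summary of a PPA network
#'
#' Bundles node/edge counts, diameter, average path length (over mutually
#' reachable ordered pairs), global clustering (over nodes with degree >=
#' 2), average degree, assortativity, the degree distribution and the
#' per-degree C(k) and Knn(k) curves, plus the fitted C(k) decay exponent
#' when at least three curve points qualify.
#'
#' @param net a [PPANetwork-class] with at least one edge.
#' @return A [NetworkSummary-class].
#' @examples
#' networkSummary(fixtureGraph("hierarchical", 4, 2))
#' @export
networkSummary <- function(net) {
  stopifnot(is(net, "PPANetwork"))
  dl <- diameterAndPathLength(net)
  cl <- clusteringCoefficients(net)
  ka <- knnAssortativity(net)
  fit <- tryCatch(fitCkExponent(cl$ck_curve),
                  error = function(e) list(exponent = NA_real_,
                                           r_squared = NA_real_))
  new("NetworkSummary",
      N = numNodes(net), E = numEdges(net),
      diameter = as.integer(dl$D), avgPathLength = dl$L,
      clustering = cl$global,
      avgDegree = 2 * numEdges(net) / numNodes(net),
      assortativity = ka$r, assortativityDefined = ka$r_defined,
      degreeDistribution = degreeDistribution(net),
      ckCurve = cl$ck_curve, knnCurve = ka$knn_curve,
      ckExponent = fit$exponent, ckRsquared = fit$r_squared)
}
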