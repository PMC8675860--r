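# Independent oracles for the graph metrics, deliberately implemented by
# different algorithms than the package (Floyd-Warshall instead of BFS,
# explicit triangle counting, exhaustive shortest-path enumeration,
# doubled-edge Pearson correlation), plus an igraph bridge used as a
# second, external oracle.

randomGraph <- function(n, p, seed) {
  set.seed(seed)
  v <- sprintf("g%02d", seq_len(n))
  pairs <- t(combn(v, 2))
  keep <- runif(nrow(pairs)) < p
  PPANetwork(v, if (any(keep)) pairs[keep, , drop = FALSE] else NULL)
}

adjMatrix <- function(net) {
  v <- nodes(net)
  a <- matrix(0L, length(v), length(v), dimnames = list(v, v))
  e <- edges(net)
  if (nrow(e)) {
    a[e] <- 1L
    a[e[, c(2, 1), drop = FALSE]] <- 1L
  }
  a
}

# Floyd-Warshall all-pairs distances; NA for unreachable
floydWarshall <- function(net) {
  a <- adjMatrix(net)
  n <- nrow(a)
  d <- ifelse(a == 1L, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n))
    d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
  d[is.infinite(d)] <- NA
  storage.mode(d) <- "integer"
  dimnames(d) <- dimnames(a)
  d
}

# local clustering by explicit neighbour-pair counting on the adjacency
# matrix; NA where degree < 2
bruteClustering <- function(net) {
  a <- adjMatrix(net)
  k <- rowSums(a)
  ci <- rep(NA_real_, nrow(a))
  names(ci) <- rownames(a)
  for (i in which(k >= 2)) {
    nb <- which(a[i, ] == 1L)
    ei <- sum(a[nb, nb]) / 2
    ci[i] <- 2 * ei / (k[i] * (k[i] - 1))
  }
  ci
}

# exhaustive betweenness: enumerate every shortest path between every
# ordered pair by walking down the distance gradient
bruteBetweenness <- function(net) {
  a <- adjMatrix(net)
  d <- floydWarshall(net)
  n <- nrow(a)
  allPaths <- function(j, k) {
    if (j == k) return(list(j))
    out <- list()
    for (w in which(a[j, ] == 1L))
      if (!is.na(d[w, k]) && !is.na(d[j, k]) && d[w, k] == d[j, k] - 1L)
        out <- c(out, lapply(allPaths(w, k), function(p) c(j, p)))
    out
  }
  cb <- numeric(n)
  names(cb) <- rownames(a)
  if (n < 3) return(cb)
  for (j in seq_len(n - 1)) for (k in (j + 1):n) {
    if (is.na(d[j, k])) next
    paths <- allPaths(j, k)
    inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
    if (length(inner)) {
      tab <- table(inner)
      idx <- as.integer(names(tab))
      cb[idx] <- cb[idx] + as.numeric(tab) / length(paths)
    }
  }
  cb / ((n - 1) * (n - 2) / 2)
}

# assortativity as the plain Pearson correlation of endpoint degrees with
# every edge listed in both directions
pearsonAssortativity <- function(net) {
  k <- degrees(net)
  e <- edges(net)
  x <- c(k[e[, 1]], k[e[, 2]])
  y <- c(k[e[, 2]], k[e[, 1]])
  suppressWarnings(cor(x, y))
}

asIgraph <- function(net) {
  igraph::graph_from_data_frame(as.data.frame(edges(net)),
                                directed = FALSE,
                                vertices = nodes(net))
}

# the published degree distribution of the 118-protein AGI target
# association network, shipped as a plain-text fixture
printedDegreeTable <- function() {
  read.delim(system.file("extdata", "ppa_degree_distribution.tsv",
                         package = "ppanet"))
}

# expand a (k, count) table into a named degree vector
degreeMultiset <- function(tab) {
  k <- rep(tab$k, tab$count)
  names(k) <- sprintf("n%03d", seq_along(k))
  k
}
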