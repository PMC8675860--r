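# The three node-centrality indices: degree, betweenness (Brandes'
# accumulation, pair-normalised, endpoints excluded) and closeness with
# the Wasserman-Faust component scaling so that disconnected networks
# still yield comparable values.

#' Degree centrality
#'
#' `C_d(i) = k_i / (N - 1)`: the fraction of other nodes adjacent to `i`.
#'
#' @param net a [PPANetwork-class] with at least two nodes.
#' @return A named numeric vector in `[0, 1]`.
#' @examples
#' degreeCentrality(fixtureGraph("star", 5))  # hub: 1, leaves: 0.2
#' @export
degreeCentrality <- function(net) {
  stopifnot(is(net, "PPANetwork"))
  n <- numNodes(net)
  if (n < 2L) stop("degree centrality needs at least two nodes")
  degrees(net) / (n - 1)
}

#' Betweenness centrality
#'
#' For each node `i`, the sum over unordered pairs `{j, k}` (both distinct
#' from `i`) of the fraction of shortest `j`-`k` paths passing through
#' `i`, normalised by the pair count `(N - 1)(N - 2) / 2`.  Endpoints are
#' excluded; pairs in different components contribute nothing.  Computed
#' with Brandes' dependency accumulation (exact, no sampling).
#'
#' @param net a [PPANetwork-class].
#' @return A named numeric vector (zero for isolated and leaf nodes).
#' @examples
#' betweennessCentrality(fixtureGraph("path", 3))  # middle node: 1
#' @export
betweennessCentrality <- function(net) {
  stopifnot(is(net, "PPANetwork"))
  n <- numNodes(net)
  cb <- numeric(n)
  names(cb) <- net@nodes
  if (n < 3L || numEdges(net) == 0L) return(cb)
  adj <- .adjList(net)
  for (s in seq_len(n)) {
    # single-source shortest paths with path counts
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    order_visited <- integer(0)
    preds <- vector("list", n)
    frontier <- s
    while (length(frontier)) {
      order_visited <- c(order_visited, frontier)
      nxt <- integer(0)
      for (v in frontier) for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
      frontier <- unique(nxt)
    }
    # dependency accumulation in reverse visitation order
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]])
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (w != s) cb[w] <- cb[w] + delta[w]
    }
  }
  # each unordered pair counted from both endpoints -> halve, then
  # normalise by the number of pairs
  cb / 2 / ((n - 1) * (n - 2) / 2)
}

#' Closeness centrality
#'
#' On a connected graph, `C_c(i) = (N - 1) / sum_j d_ij`.  On a graph with
#' several components the literal form is undefined, so the
#' Wasserman-Faust component scaling is used: with `R_i` the number of
#' nodes reachable from `i`,
#' `C_c(i) = (R_i / sum d_ij) * (R_i / (N - 1))` — the within-component
#' closeness damped by the component's share of the network.  The two
#' coincide exactly on connected graphs.  Isolated nodes have no defined
#' closeness and carry `NA`.
#'
#' @param net a [PPANetwork-class] with at least two nodes.
#' @return A named numeric vector with `NA` for isolated nodes.
#' @examples
#' closenessCentrality(fixtureGraph("path", 3))  # middle: 1, ends: 2/3
#' @export
closenessCentrality <- function(net) {
  stopifnot(is(net, "PPANetwork"))
  n <- numNodes(net)
  if (n < 2L) stop("closeness centrality needs at least two nodes")
  d <- shortestPaths(net)
  cc <- rep(NA_real_, n)
  names(cc) <- net@nodes
  for (i in seq_len(n)) {
    di <- d[i, -i]
    reach <- di[!is.na(di)]
    if (!length(reach)) next               # isolated: undefined
    cc[i] <- (length(reach) / sum(reach)) * (length(reach) / (n - 1))
  }
  cc
}

#' All three centrality indices
#'
#' @param net a [PPANetwork-class] with at least two nodes.
#' @return data.frame with columns `node`, `cd`, `cb`, `cc` (one row per
#'   node, in node order; `cc` is `NA` for isolated nodes).
#' @examples
#' centralityIndices(fixtureGraph("star", 4))
#' @export
centralityIndices <- function(net) {
  data.frame(node = nodes(net),
             cd = unname(degreeCentrality(net)),
             cb = unname(betweennessCentrality(net)),
             cc = unname(closenessCentrality(net)),
             stringsAsFactors = FALSE)
}
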