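#' Accessors for ppanet containers
#'
#' Small accessor layer over the S4 slots: node and edge views of a
#' [PPANetwork-class], pathway and target views of a
#' [MembershipTable-class], and compound/link views of a
#' [CompoundTargetMap-class].
#'
#' @param x a ppanet object.
#' @return `nodes`/`targets`/`compounds` return character vectors;
#'   `edges` a two-column character matrix; `numNodes`/`numEdges` single
#'   integers; `degrees` a named integer vector; `pathways` a named list;
#'   `links` a data.frame.
#' @name accessors
#' @aliases nodes edges numNodes numEdges degrees pathways targets
#'   compounds links
#' @examples
#' net <- fixtureGraph("clique", 4)
#' numEdges(net)   # 6
#' degrees(net)    # all 3
NULL

#' @rdname accessors
#' @export
setMethod("nodes", "PPANetwork", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("edges", "PPANetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("numNodes", "PPANetwork", function(x) length(x@nodes))

#' @rdname accessors
#' @export
setMethod("numEdges", "PPANetwork", function(x) nrow(x@edges))

#' @rdname accessors
#' @export
setMethod("degrees", "PPANetwork", function(x) {
  k <- integer(length(x@nodes))
  names(k) <- x@nodes
  if (nrow(x@edges)) {
    tab <- table(factor(as.vector(x@edges), levels = x@nodes))
    k[] <- as.integer(tab)
  }
  k
})

#' @rdname accessors
#' @export
setMethod("pathways", "MembershipTable", function(x) x@pathways)

#' @rdname accessors
#' @export
setMethod("targets", "MembershipTable", function(x) x@targets)

#' @rdname accessors
#' @export
setMethod("compounds", "CompoundTargetMap", function(x) x@compounds)

#' @rdname accessors
#' @export
setMethod("links", "CompoundTargetMap", function(x) x@links)

#' @rdname accessors
#' @export
setMethod("nodes", "CoreSubnetwork", function(x)
  c(x@compounds, x@targets, x@pathways))

#' @rdname accessors
#' @export
setMethod("edges", "CoreSubnetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("numNodes", "CoreSubnetwork", function(x)
  length(x@compounds) + length(x@targets) + length(x@pathways))

#' @rdname accessors
#' @export
setMethod("numEdges", "CoreSubnetwork", function(x) nrow(x@edges))

setMethod("show", "MembershipTable", function(object) {
  cat(sprintf("MembershipTable: %d pathways over %d targets\n",
              length(object@pathways), length(object@targets)))
  sizes <- vapply(object@pathways, length, 0L)
  if (length(sizes))
    cat(sprintf("  pathway sizes: min %d, median %s, max %d\n",
                min(sizes), format(stats::median(sizes)), max(sizes)))
  orphans <- sum(!(object@targets %in% unlist(object@pathways,
                                              use.names = FALSE)))
  cat(sprintf("  targets with no pathway: %d\n", orphans))
})

setMethod("show", "CompoundTargetMap", function(object) {
  cat(sprintf("CompoundTargetMap: %d compounds, %d links, %d distinct targets\n",
              length(object@compounds), nrow(object@links),
              length(unique(object@links$target))))
})

setMethod("show", "PPANetwork", function(object) {
  k <- degrees(object)
  cat(sprintf("PPANetwork: %d nodes, %d edges\n",
              length(object@nodes), nrow(object@edges)))
  if (length(k))
    cat(sprintf("  degree: mean %.2f, max %d, isolated %d\n",
                mean(k), max(k), sum(k == 0L)))
})

setMethod("show", "CoreSubnetwork", function(object) {
  cat(sprintf(
    "CoreSubnetwork: %d compounds + %d targets + %d pathways = %d nodes, %d edges\n",
    length(object@compounds), length(object@targets),
    length(object@pathways), numNodes(object), nrow(object@edges)))
})

setMethod("show", "NetworkSummary", function(object) {
  cat(sprintf("NetworkSummary: N = %d, E = %d, <k> = %.2f\n",
              object@N, object@E, object@avgDegree))
  cat(sprintf("  diameter D = %d, average path length L = %.3f\n",
              object@diameter, object@avgPathLength))
  cat(sprintf("  clustering C = %.3f; C(k) exponent = %.3f (r2 = %.3f)\n",
              object@clustering, object@ckExponent, object@ckRsquared))
  if (object@assortativityDefined)
    cat(sprintf("  assortativity r = %.3f\n", object@assortativity))
  else cat("  assortativity r: undefined (zero endpoint-degree variance)\n")
})

# adjacency list of integer neighbour indices, in node order
.adjList <- function(net) {
  n <- length(net@nodes)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer()
  if (nrow(net@edges)) {
    i1 <- match(net@edges[, 1L], net@nodes)
    i2 <- match(net@edges[, 2L], net@nodes)
    for (r in seq_along(i1)) {
      adj[[i1[r]]] <- c(adj[[i1[r]]], i2[r])
      adj[[i2[r]]] <- c(adj[[i2[r]]], i1[r])
    }
    adj <- lapply(adj, sort)
  }
  adj
}
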