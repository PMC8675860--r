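#' @import methods
NULL

#' Bipartite target-pathway membership
#'
#' Stores the two-mode incidence between protein targets and enriched
#' pathways: a named list of pathway member sets plus the full ordered
#' target universe.  Targets listed with no pathway are legal members of
#' the universe; after projection they become isolated nodes.
#'
#' @slot pathways named list; each element is a character vector of member
#'   target ids, the name is the pathway id.
#' @slot targets character; the ordered (lexicographic) target universe.
#'
#' @seealso [readMembership()], [filterPathways()], [projectNetwork()]
#' @export
setClass("MembershipTable",
  representation(pathways = "list", targets = "character"))

setValidity("MembershipTable", function(object) {
  p <- object@pathways
  msg <- character()
  if (length(p)) {
    if (is.null(names(p)) || anyDuplicated(names(p)))
      msg <- c(msg, "pathway ids must be unique and named")
    if (any(vapply(p, length, 0L) == 0L))
      msg <- c(msg, "empty pathway member sets are not allowed")
    if (any(vapply(p, anyDuplicated, 0L) > 0L))
      msg <- c(msg, "duplicate members within a pathway")
    all_members <- unique(unlist(p, use.names = FALSE))
    if (!all(all_members %in% object@targets))
      msg <- c(msg, "every pathway member must appear in the target set")
  }
  if (anyDuplicated(object@targets))
    msg <- c(msg, "target ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a MembershipTable
#'
#' @param pathways named list of character vectors (pathway id -> member
#'   target ids).  Members are de-duplicated and sorted.
#' @param targets optional character vector of target ids; defaults to the
#'   union of all members.  Extra ids declare pathway-less targets.
#' @return A [MembershipTable-class] object.
#' @examples
#' MembershipTable(list(P1 = c("A", "B", "C")), targets = c("A", "B", "C", "D"))
#' @export
MembershipTable <- function(pathways = list(), targets = NULL) {
  pathways <- lapply(pathways, function(m) sort(unique(trimws(m))))
  members <- unique(unlist(pathways, use.names = FALSE))
  if (is.null(targets)) targets <- members
  targets <- sort(unique(trimws(c(targets, members))))
  new("MembershipTable", pathways = pathways, targets = targets)
}

#' Compound-target links
#'
#' The bipartite relation between chemical constituents and the proteins
#' they are predicted or known to bind.
#'
#' @slot links data.frame with character columns `compound` and `target`,
#'   one row per unique link.
#' @slot compounds character; ordered compound universe (may include
#'   compounds with zero links only through the constructor's `compounds`
#'   argument).
#' @export
setClass("CompoundTargetMap",
  representation(links = "data.frame", compounds = "character"))

setValidity("CompoundTargetMap", function(object) {
  msg <- character()
  if (!identical(colnames(object@links), c("compound", "target")))
    msg <- c(msg, "links must have columns compound, target")
  else {
    if (anyDuplicated(object@links))
      msg <- c(msg, "duplicate compound-target pairs")
    if (nrow(object@links) && !all(object@links$compound %in% object@compounds))
      msg <- c(msg, "every linked compound must appear in the compound set")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CompoundTargetMap
#'
#' @param links data.frame (or two-column matrix) of compound, target pairs.
#' @param compounds optional compound universe; defaults to the compounds
#'   present in `links`.
#' @return A [CompoundTargetMap-class] object.
#' @export
CompoundTargetMap <- function(links = data.frame(compound = character(),
                                                 target = character()),
                              compounds = NULL) {
  links <- as.data.frame(links)
  colnames(links) <- c("compound", "target")
  links$compound <- trimws(as.character(links$compound))
  links$target <- trimws(as.character(links$target))
  links <- unique(links)
  links <- links[order(links$compound, links$target), , drop = FALSE]
  rownames(links) <- NULL
  if (is.null(compounds)) compounds <- links$compound
  compounds <- sort(unique(trimws(c(compounds, links$compound))))
  new("CompoundTargetMap", links = links, compounds = compounds)
}

#' Pathway-based protein-protein association network
#'
#' An undirected simple graph over protein targets in which an edge joins
#' two proteins that share at least one pathway.  Nodes are kept in
#' lexicographic order; edges are stored once, smaller label first, rows
#' sorted — so two networks with equal node and edge sets are identical
#' objects.  Isolated nodes (targets with no surviving pathway) are
#' first-class nodes.
#'
#' @slot nodes character; lexicographically sorted node labels.
#' @slot edges two-column character matrix, one row per undirected edge.
#' @slot sharedCount integer; per-edge number of shared pathways (metadata
#'   only; every analysis treats the graph as unweighted).  Zero-length
#'   when unknown.
#' @export
setClass("PPANetwork",
  representation(nodes = "character", edges = "matrix",
                 sharedCount = "integer"))

setValidity("PPANetwork", function(object) {
  e <- object@edges
  msg <- character()
  if (ncol(e) != 2L) return("edges must be a two-column matrix")
  if (nrow(e)) {
    if (!all(e %in% object@nodes))
      msg <- c(msg, "edge endpoints must be nodes")
    if (any(e[, 1L] == e[, 2L])) msg <- c(msg, "self-loops are not allowed")
    if (any(e[, 1L] > e[, 2L]))
      msg <- c(msg, "edges must be stored smaller label first")
    if (anyDuplicated(paste(e[, 1L], e[, 2L], sep = "\r")))
      msg <- c(msg, "multi-edges are not allowed")
  }
  if (is.unsorted(object@nodes, strictly = TRUE))
    msg <- c(msg, "nodes must be unique and lexicographically sorted")
  if (length(object@sharedCount) && length(object@sharedCount) != nrow(e))
    msg <- c(msg, "sharedCount must be empty or one value per edge")
  if (length(msg)) msg else TRUE
})

#' Construct a PPANetwork
#'
#' Canonicalises input: node labels are sorted, each edge is stored once
#' with the smaller label first, edge rows are sorted.
#'
#' @param nodes character vector of node labels (isolated nodes allowed).
#' @param edges two-column character matrix or data.frame of endpoints.
#' @param sharedCount optional integer vector of shared-pathway counts,
#'   aligned with `edges` before canonicalisation.
#' @return A [PPANetwork-class] object.
#' @examples
#' net <- PPANetwork(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' numNodes(net)
#' @export
PPANetwork <- function(nodes = character(), edges = NULL, sharedCount = NULL) {
  nodes <- sort(unique(trimws(nodes)))
  if (is.null(edges) || NROW(edges) == 0L) {
    e <- matrix(character(), 0L, 2L)
    sc <- integer()
  } else {
    e <- as.matrix(edges)
    storage.mode(e) <- "character"
    e[] <- trimws(e)
    swap <- e[, 1L] > e[, 2L]
    e[swap, ] <- e[swap, c(2L, 1L)]
    key <- paste(e[, 1L], e[, 2L], sep = "\r")
    keep <- !duplicated(key)
    e <- e[keep, , drop = FALSE]
    sc <- if (is.null(sharedCount)) integer() else as.integer(sharedCount)[keep]
    o <- order(e[, 1L], e[, 2L])
    e <- e[o, , drop = FALSE]
    if (length(sc)) sc <- sc[o]
    nodes <- sort(unique(c(nodes, as.vector(e))))
  }
  dimnames(e) <- NULL
  new("PPANetwork", nodes = nodes, edges = e,
      sharedCount = if (is.null(sharedCount)) integer() else sc)
}

#' Tripartite compound-target-pathway core subnetwork
#'
#' The extract around the key targets: main active constituents, the key
#' targets themselves, and the critical pathways, with typed edges
#' (compound-target and target-pathway only).
#'
#' @slot compounds,targets,pathways character; the three node layers.
#' @slot edges data.frame with columns `from`, `to`, `type`
#'   (`"compound-target"` or `"target-pathway"`).
#' @export
setClass("CoreSubnetwork",
  representation(compounds = "character", targets = "character",
                 pathways = "character", edges = "data.frame"))

setValidity("CoreSubnetwork", function(object) {
  e <- object@edges
  msg <- character()
  if (!identical(colnames(e), c("from", "to", "type")))
    return("edges must have columns from, to, type")
  ct <- e[e$type == "compound-target", , drop = FALSE]
  tp <- e[e$type == "target-pathway", , drop = FALSE]
  if (nrow(ct) + nrow(tp) != nrow(e))
    msg <- c(msg, "edge type must be compound-target or target-pathway")
  if (!all(ct$from %in% object@compounds) || !all(ct$to %in% object@targets))
    msg <- c(msg, "compound-target edges must join a compound to a target")
  if (!all(tp$from %in% object@targets) || !all(tp$to %in% object@pathways))
    msg <- c(msg, "target-pathway edges must join a target to a pathway")
  if (length(msg)) msg else TRUE
})

#' Global topology summary of a PPA network
#'
#' Holds the whole-network statistics: node and edge counts, diameter,
#' average path length over mutually reachable ordered pairs, global
#' clustering coefficient (mean over nodes of degree >= 2), average degree,
#' assortativity, the degree distribution, the per-degree C(k) and Knn(k)
#' curves, and the fitted C(k) power-law exponent.
#'
#' @slot N,E integer; node and edge counts.
#' @slot diameter integer; maximum finite shortest-path length.
#' @slot avgPathLength numeric; mean d_ij over mutually reachable ordered
#'   pairs.
#' @slot clustering numeric; mean local clustering over nodes with k >= 2.
#' @slot avgDegree numeric; 2E/N.
#' @slot assortativity numeric; degree assortativity r, `NA` when undefined
#'   (see `assortativityDefined`).
#' @slot assortativityDefined logical; `FALSE` when the endpoint-degree
#'   variance is zero and r has no value.
#' @slot degreeDistribution data.frame with columns `k`, `count`, `pk`
#'   (percent of nodes).
#' @slot ckCurve,knnCurve data.frame with columns `k` and the per-degree
#'   mean of C_i resp. Knn_i.
#' @slot ckExponent numeric; fitted power-law decay exponent of C(k)
#'   (positive for decay), `NA` when too few points qualify.
#' @slot ckRsquared numeric; r-squared of the log-log fit.
#' @export
setClass("NetworkSummary",
  representation(N = "integer", E = "integer", diameter = "integer",
                 avgPathLength = "numeric", clustering = "numeric",
                 avgDegree = "numeric", assortativity = "numeric",
                 assortativityDefined = "logical",
                 degreeDistribution = "data.frame",
                 ckCurve = "data.frame", knnCurve = "data.frame",
                 ckExponent = "numeric", ckRsquared = "numeric"))
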