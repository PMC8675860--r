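#' Drop under-sized pathways
#'
#' Removes pathways with fewer than `min_size` members.  The target
#' universe is unchanged: targets whose every pathway is dropped remain in
#' the table and will project to isolated nodes.  The default of 3 excludes
#' pathways holding only one or two proteins, the usual enrichment-table
#' cleaning step for association networks.
#'
#' @param mem a [MembershipTable-class].
#' @param min_size minimum retained pathway size (>= 1).
#' @return A filtered [MembershipTable-class].
#' @examples
#' mem <- MembershipTable(list(P1 = c("A", "B", "C"), P2 = c("D", "E")))
#' length(pathways(filterPathways(mem, 3)))  # 1; D and E stay as targets
#' @export
filterPathways <- function(mem, min_size = 3L) {
  stopifnot(is(mem, "MembershipTable"))
  if (min_size < 1L) stop("min_size must be >= 1")
  keep <- vapply(mem@pathways, length, 0L) >= min_size
  new("MembershipTable", pathways = mem@pathways[keep],
      targets = mem@targets)
}

#' Project shared pathway membership into a PPA network
#'
#' One-mode projection of the bipartite membership: nodes are all targets
#' (pathway-less ones included, as isolated nodes); an undirected edge
#' joins two targets that co-occur in at least one pathway.  The graph is
#' simple and unweighted — a pair sharing several pathways still yields a
#' single edge — but the shared-pathway count is kept as per-edge metadata
#' for reporting.
#'
#' @param mem a [MembershipTable-class], normally already passed through
#'   [filterPathways()].
#' @return A [PPANetwork-class].
#' @examples
#' mem <- MembershipTable(list(P1 = c("A", "B", "C"), P2 = c("B", "C", "D")))
#' numEdges(projectNetwork(mem))  # 5: AB, AC, BC, BD, CD
#' @export
projectNetwork <- function(mem) {
  stopifnot(is(mem, "MembershipTable"))
  pairs <- lapply(mem@pathways, function(m) {
    if (length(m) < 2L) return(NULL)
    t(utils::combn(sort(m), 2L))     # within a pathway: a clique
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || !nrow(pairs))
    return(PPANetwork(mem@targets))
  key <- paste(pairs[, 1L], pairs[, 2L], sep = "\r")
  shared <- table(key)
  first <- !duplicated(key)
  PPANetwork(mem@targets, pairs[first, , drop = FALSE],
             sharedCount = as.integer(shared[key[first]]))
}
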