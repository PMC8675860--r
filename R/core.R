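# Core-subnetwork extraction: the critical pathways covering the key
# targets, the main active constituents hitting them, and the tripartite
# compound-target-pathway extract around them.

#' Critical pathways for a key-target set
#'
#' Pathways ranked by how many key targets they contain; a pathway is
#' retained when its coverage fraction (key targets contained / key
#' targets) reaches `min_coverage`.  The default 1.0 keeps only pathways
#' containing every key target — the rule that singles out one critical
#' pathway when all key targets co-occur in it.
#'
#' @param mem a [MembershipTable-class].
#' @param key_targets non-empty character vector.
#' @param min_coverage fraction in `(0, 1]`.
#' @return data.frame with columns `pathway`, `n_key` (key targets
#'   contained), `coverage` (fraction), sorted by `n_key` descending then
#'   pathway id; possibly zero rows.
#' @export
criticalPathways <- function(mem, key_targets, min_coverage = 1.0) {
  stopifnot(is(mem, "MembershipTable"))
  if (!length(key_targets)) stop("key_targets must be non-empty")
  if (min_coverage <= 0 || min_coverage > 1)
    stop("min_coverage must be in (0, 1]")
  nk <- vapply(mem@pathways, function(m) sum(key_targets %in% m), 0L)
  cov <- nk / length(key_targets)
  keep <- which(cov >= min_coverage)
  out <- data.frame(pathway = names(mem@pathways)[keep],
                    n_key = as.integer(nk[keep]),
                    coverage = unname(cov[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_key, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Main active constituents
#'
#' Compounds with at least one link to a key target, sorted by their
#' number of key-target links (descending, then lexicographically).
#'
#' @param map a [CompoundTargetMap-class].
#' @param key_targets character vector.
#' @return data.frame with columns `compound`, `n_key_links`.
#' @export
mainConstituents <- function(map, key_targets) {
  stopifnot(is(map, "CompoundTargetMap"))
  l <- map@links[map@links$target %in% key_targets, , drop = FALSE]
  if (!nrow(l))
    return(data.frame(compound = character(), n_key_links = integer(),
                      stringsAsFactors = FALSE))
  tab <- table(l$compound)
  out <- data.frame(compound = names(tab), n_key_links = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_key_links, out$compound), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the tripartite core subnetwork
#'
#' Nodes are the main constituents, the key targets, and the critical
#' pathways; edges are the compound-to-key-target links and the
#' key-target-to-critical-pathway memberships.  Compounds never connect to
#' pathways directly.  `node_count = |compounds| + |targets| + |pathways|`
#' and `edge_count` splits exactly into the two edge types.
#'
#' @param map a [CompoundTargetMap-class].
#' @param mem a [MembershipTable-class].
#' @param key_targets character vector.
#' @param min_coverage critical-pathway coverage threshold, see
#'   [criticalPathways()].
#' @return A [CoreSubnetwork-class]; a warning is raised when the core has
#'   neither constituents nor critical pathways.
#' @examples
#' mem <- MembershipTable(list(P1 = c("A", "B", "C")))
#' map <- CompoundTargetMap(data.frame(compound = "c1", target = "A"))
#' buildCore(map, mem, key_targets = "A")  # 3 nodes, 2 edges
#' @export
buildCore <- function(map, mem, key_targets, min_coverage = 1.0) {
  const <- mainConstituents(map, key_targets)
  crit <- criticalPathways(mem, key_targets, min_coverage)
  if (!nrow(const) && !nrow(crit))
    warning("empty core: no constituent hits a key target and no pathway reaches coverage")
  ct <- map@links[map@links$compound %in% const$compound &
                    map@links$target %in% key_targets, , drop = FALSE]
  ctEdges <- if (nrow(ct))
    data.frame(from = ct$compound, to = ct$target, type = "compound-target",
               stringsAsFactors = FALSE)
  else data.frame(from = character(), to = character(), type = character(),
                  stringsAsFactors = FALSE)
  tpEdges <- do.call(rbind, c(list(ctEdges[0, ]), lapply(crit$pathway,
    function(p) {
      inP <- key_targets[key_targets %in% mem@pathways[[p]]]
      if (!length(inP)) return(NULL)
      data.frame(from = inP, to = p, type = "target-pathway",
                 stringsAsFactors = FALSE)
    })))
  edges <- rbind(ctEdges, tpEdges)
  rownames(edges) <- NULL
  new("CoreSubnetwork",
      compounds = const$compound,
      targets = sort(unique(key_targets)),
      pathways = crit$pathway,
      edges = edges)
}
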