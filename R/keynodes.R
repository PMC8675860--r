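# Hub identification, robust-z centrality outliers, key-target selection
# and the neighbour-coverage statistic.  The published analyses of this
# kind pick hubs and "abnormal" centrality values by inspection; here both
# rules are explicit and parameterised so the selection is auditable.

#' Identify hub nodes
#'
#' `degree_factor` (default, `param = 2.5`): hubs are nodes whose degree
#' exceeds `param` times the network's average degree.  `top_n`: the
#' `param` highest-degree nodes, with all ties at the boundary included.
#' Output is ordered by degree descending, then lexicographically.
#'
#' @param x a [PPANetwork-class], or a named integer vector of degrees.
#' @param rule `"degree_factor"` or `"top_n"`.
#' @param param positive rule parameter (factor, or n).
#' @return data.frame with columns `node`, `k`.
#' @examples
#' identifyHubs(fixtureGraph("star", 9))  # <k> = 1.8, threshold 4.5: the hub
#' @export
identifyHubs <- function(x, rule = c("degree_factor", "top_n"), param = 2.5) {
  rule <- match.arg(rule)
  if (param <= 0) stop("param must be positive")
  k <- if (is(x, "PPANetwork")) degrees(x) else x
  stopifnot(!is.null(names(k)))
  sel <- if (rule == "degree_factor") {
    names(k)[k > param * mean(k)]
  } else {
    if (length(k) <= param) names(k)
    else names(k)[k >= sort(k, decreasing = TRUE)[ceiling(param)]]
  }
  out <- data.frame(node = sel, k = as.integer(k[sel]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$k, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect centrality outliers by robust z-score
#'
#' For each index (degree, betweenness, closeness), a robust z-score is
#' computed over nodes with defined values: `z = (value - median) /
#' (1.4826 * MAD)`, the 1.4826 factor making the MAD a consistent normal
#' scale estimate.  A node is an outlier when `z > z_threshold` for at
#' least one index.  When an index's MAD is zero (more than half the
#' values tie), the index carries no robust scale: values equal to the
#' median score 0 and values above it score `Inf`, so a lone node distinct
#' from an otherwise flat distribution is still flagged.
#'
#' @param ci data.frame from [centralityIndices()] (columns `node`, `cd`,
#'   `cb`, `cc`); at least 5 nodes must have all three indices defined.
#' @param z_threshold positive threshold (default 2.5).
#' @return data.frame of outliers with per-index z-scores (`z_cd`, `z_cb`,
#'   `z_cc`) and `max_z`, sorted by `max_z` descending.
#' @export
detectCentralOutliers <- function(ci, z_threshold = 2.5) {
  stopifnot(is.data.frame(ci), all(c("node", "cd", "cb", "cc") %in% names(ci)))
  if (z_threshold <= 0) stop("z_threshold must be positive")
  defined <- stats::complete.cases(ci[, c("cd", "cb", "cc")])
  if (sum(defined) < 5L)
    stop("need at least 5 nodes with all centrality indices defined")
  sub <- ci[defined, , drop = FALSE]
  robustZ <- function(v) {
    med <- stats::median(v)
    s <- 1.4826 * stats::median(abs(v - med))
    if (s > 0) (v - med) / s
    else ifelse(v > med, Inf, ifelse(v < med, -Inf, 0))
  }
  z <- data.frame(node = sub$node,
                  z_cd = robustZ(sub$cd),
                  z_cb = robustZ(sub$cb),
                  z_cc = robustZ(sub$cc),
                  stringsAsFactors = FALSE)
  z$max_z <- pmax(z$z_cd, z$z_cb, z$z_cc)
  out <- z[z$z_cd > z_threshold | z$z_cb > z_threshold |
             z$z_cc > z_threshold, , drop = FALSE]
  out <- out[order(-out$max_z, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select key targets
#'
#' Key targets are the centrality-outlier set; the overlap with the hub
#' list is reported alongside (in the published configuration this module
#' emulates, six central nodes were key targets, five of them hubs).
#'
#' @param hubs data.frame from [identifyHubs()].
#' @param central_outliers data.frame from [detectCentralOutliers()].
#' @return A list: `key_targets` (character, outlier order), `hub_overlap`
#'   (character), `status` (`"ok"` or `"empty"`); an empty outlier set
#'   raises a warning.
#' @export
selectKeyTargets <- function(hubs, central_outliers) {
  key <- central_outliers$node
  if (!length(key)) {
    warning("no centrality outliers: key target set is empty")
    return(list(key_targets = character(), hub_overlap = character(),
                status = "empty"))
  }
  list(key_targets = key,
       hub_overlap = key[key %in% hubs$node],
       status = "ok")
}

#' Neighbour coverage of the key targets
#'
#' The number of distinct nodes directly linked to at least one key target
#' (the key targets themselves excluded) and the percentage of all nodes
#' they represent.
#'
#' @param net a [PPANetwork-class].
#' @param key_targets character vector, a subset of `nodes(net)`.
#' @return A list with `count` (integer) and `percent` (numeric,
#'   `100 * count / N`, unrounded).
#' @examples
#' neighborCoverage(fixtureGraph("star", 4), "hub")  # 4 of 5 nodes: 80%
#' @export
neighborCoverage <- function(net, key_targets) {
  stopifnot(is(net, "PPANetwork"))
  if (!all(key_targets %in% net@nodes))
    stop("key_targets must be nodes of the network")
  if (!length(key_targets))
    return(list(count = 0L, percent = 0))
  e <- net@edges
  hit <- c(e[e[, 1L] %in% key_targets, 2L],
           e[e[, 2L] %in% key_targets, 1L])
  nb <- setdiff(unique(hit), key_targets)
  list(count = length(nb), percent = 100 * length(nb) / numNodes(net))
}
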