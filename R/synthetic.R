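# Deterministic generators for bipartite memberships, compound-target maps
# and closed-form fixture graphs.  All randomness flows through R's
# Mersenne-Twister, locally seeded, so a config + seed pins the output.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

.idSeq <- function(prefix, n) sprintf("%s%0*d", prefix, nchar(n), seq_len(n))

#' Configuration for the membership generator
#'
#' @param n_targets,n_pathways positive integers.
#' @param pathway_size_law `"poisson"` (parameter `mean`) or `"power"`
#'   (parameter `exponent` of the discrete power law on
#'   `min_size:max_size`).
#' @param mean,exponent law parameters (see above).
#' @param min_size,max_size inclusive bounds on pathway sizes; sizes are
#'   drawn from the law truncated to this range.
#' @param attachment_bias non-negative real; a target's weight for joining
#'   a further pathway is `(current membership count + 1)^attachment_bias`,
#'   so `0` is uniform and `1` is linear preferential attachment.
#' @param isolated_fraction fraction in `[0, 1)` of targets that receive no
#'   membership at all; the last `round(f * n_targets)` ids in sorted order
#'   are designated isolated, so the isolated set is reproducible.
#' @param seed integer seed.
#' @return A list of class `MembershipGenConfig`.
#' @export
membershipGenConfig <- function(n_targets = 118L, n_pathways = 86L,
                                pathway_size_law = c("poisson", "power"),
                                mean = 8, exponent = 2.5,
                                min_size = 3L, max_size = NULL,
                                attachment_bias = 1.0,
                                isolated_fraction = 0.23,
                                seed = 1L) {
  pathway_size_law <- match.arg(pathway_size_law)
  if (n_targets < 1L || n_pathways < 0L) stop("counts must be positive")
  if (is.null(max_size)) max_size <- n_targets
  if (min_size < 1L) stop("min_size must be >= 1")
  if (max_size > n_targets) stop("max_size cannot exceed n_targets")
  if (min_size > max_size) stop("infeasible config: min_size > max_size")
  if (attachment_bias < 0) stop("attachment_bias must be >= 0")
  if (isolated_fraction < 0 || isolated_fraction >= 1)
    stop("isolated_fraction must be in [0, 1)")
  structure(list(n_targets = as.integer(n_targets),
                 n_pathways = as.integer(n_pathways),
                 pathway_size_law = pathway_size_law,
                 mean = mean, exponent = exponent,
                 min_size = as.integer(min_size),
                 max_size = as.integer(max_size),
                 attachment_bias = attachment_bias,
                 isolated_fraction = isolated_fraction,
                 seed = as.integer(seed)),
            class = "MembershipGenConfig")
}

.drawSizes <- function(cfg) {
  rng <- cfg$min_size:cfg$max_size
  if (cfg$pathway_size_law == "poisson") {
    # truncated Poisson via inverse-CDF on the admissible range
    p <- stats::dpois(rng, cfg$mean)
    if (sum(p) <= 0) p <- rep(1, length(rng))
  } else {
    p <- rng^(-cfg$exponent)
  }
  rng[sample.int(length(rng), cfg$n_pathways, replace = TRUE,
                 prob = p / sum(p))]
}

#' Generate a synthetic bipartite membership table
#'
#' Emulates an enriched target-pathway table: pathway sizes are drawn from
#' the configured law (truncated to `[min_size, max_size]`), a designated
#' fraction of targets stays pathway-less, and membership overlap is
#' controlled by preferential attachment.  Generation is coverage-first:
#' every non-isolated target is seeded into one pathway with free capacity,
#' then remaining pathway slots are filled by sampling targets without
#' replacement with weight `(memberships + 1)^attachment_bias`.  Exactly
#' `round(isolated_fraction * n_targets)` targets end with no membership.
#'
#' @param cfg a [membershipGenConfig()] list.
#' @return A [MembershipTable-class]; deterministic for a fixed config.
#' @examples
#' cfg <- membershipGenConfig(n_targets = 20, n_pathways = 6, mean = 4,
#'                            isolated_fraction = 0.2, seed = 7)
#' generateMembership(cfg)
#' @export
generateMembership <- function(cfg) {
  stopifnot(inherits(cfg, "MembershipGenConfig"))
  tid <- .idSeq("T", cfg$n_targets)
  n_iso <- round(cfg$isolated_fraction * cfg$n_targets)
  eligible <- tid[seq_len(cfg$n_targets - n_iso)]   # isolated = last ids
  if (cfg$min_size > length(eligible))
    stop("infeasible config: min_size exceeds the non-isolated target count")
  pid <- .idSeq("P", cfg$n_pathways)
  .withSeed(cfg$seed, {
    sizes <- if (cfg$n_pathways) pmin(.drawSizes(cfg), length(eligible))
             else integer()
    if (sum(sizes) < length(eligible))
      stop("infeasible config: total pathway capacity ", sum(sizes),
           " cannot cover ", length(eligible), " non-isolated targets")
    members <- lapply(sizes, function(s) character(0))
    count <- stats::setNames(integer(length(eligible)), eligible)
    # coverage pass: each eligible target joins one pathway with room
    for (t in sample(eligible)) {
      room <- which(vapply(members, length, 0L) < sizes)
      p <- if (length(room) == 1L) room else sample(room, 1L)
      members[[p]] <- c(members[[p]], t)
      count[t] <- count[t] + 1L
    }
    # fill pass: preferential attachment on current membership counts
    for (p in seq_along(members)) {
      free <- sizes[p] - length(members[[p]])
      if (free <= 0L) next
      pool <- setdiff(eligible, members[[p]])
      w <- (count[pool] + 1)^cfg$attachment_bias
      pick <- pool[sample.int(length(pool), free, prob = w / sum(w))]
      members[[p]] <- c(members[[p]], pick)
      count[pick] <- count[pick] + 1L
    }
    names(members) <- pid
    MembershipTable(members, targets = tid)
  })
}

#' Configuration for the compound-target generator
#'
#' @param n_compounds non-negative integer.
#' @param hits_law `"poisson"` (parameter `mean`) or `"uniform"`
#'   (parameters `min_hits`, `max_hits`); per-compound link counts are
#'   truncated to at least 1.
#' @param mean,min_hits,max_hits law parameters.
#' @param seed integer seed.
#' @return A list of class `CompoundGenConfig`.
#' @export
compoundGenConfig <- function(n_compounds = 13L,
                              hits_law = c("poisson", "uniform"),
                              mean = 10, min_hits = 5L, max_hits = 15L,
                              seed = 1L) {
  hits_law <- match.arg(hits_law)
  if (n_compounds < 0L) stop("n_compounds must be >= 0")
  if (min_hits < 1L || max_hits < min_hits) stop("invalid hit bounds")
  structure(list(n_compounds = as.integer(n_compounds), hits_law = hits_law,
                 mean = mean, min_hits = as.integer(min_hits),
                 max_hits = as.integer(max_hits), seed = as.integer(seed)),
            class = "CompoundGenConfig")
}

#' Generate synthetic compound-target links
#'
#' Each compound draws its hit count from the configured law (truncated to
#' `>= 1` and to the target-universe size) and samples that many distinct
#' targets uniformly.
#'
#' @param cfg a [compoundGenConfig()] list.
#' @param targets character vector of target ids (non-empty unless
#'   `n_compounds` is 0).
#' @return A [CompoundTargetMap-class]; deterministic for a fixed config.
#' @export
generateCompoundTargets <- function(cfg, targets) {
  stopifnot(inherits(cfg, "CompoundGenConfig"))
  if (cfg$n_compounds == 0L) return(CompoundTargetMap())
  targets <- unique(as.character(targets))
  if (!length(targets)) stop("target set is empty")
  cid <- .idSeq("C", cfg$n_compounds)
  .withSeed(cfg$seed, {
    hits <- switch(cfg$hits_law,
      poisson = pmax(1L, stats::rpois(cfg$n_compounds, cfg$mean)),
      uniform = sample(cfg$min_hits:cfg$max_hits, cfg$n_compounds,
                       replace = TRUE))
    hits <- pmin(hits, length(targets))
    rows <- lapply(seq_along(cid), function(i)
      data.frame(compound = cid[i],
                 target = sample(targets, hits[i]),
                 stringsAsFactors = FALSE))
    CompoundTargetMap(do.call(rbind, rows), compounds = cid)
  })
}

#' Closed-form fixture graphs
#'
#' Deterministic graphs with known topology, used to pin down every metric
#' against closed forms: `clique(n)`, `star(n)` (`n` leaves around one
#' hub), `path(n)`, `cycle(n)`, and `hierarchical(b, levels)` — the
#' recursive replica construction whose per-degree clustering C(k) decays
#' as a power law.  The hierarchical graph starts from a fully connected
#' seed of `b` nodes; at each further level the whole structure is copied
#' `b - 1` times and the copies' peripheral nodes are wired to the original
#' hub, giving `b^levels` nodes.
#'
#' @param kind `"clique"`, `"star"`, `"path"`, `"cycle"` or
#'   `"hierarchical"`.
#' @param size clique/star/path/cycle size (for `star`, the number of
#'   leaves), or the module size `b` for `hierarchical`.
#' @param levels number of hierarchy levels (`hierarchical` only).
#' @return A [PPANetwork-class].
#' @examples
#' fixtureGraph("star", 5)              # hub degree 5
#' fixtureGraph("hierarchical", 4, 2)   # 16 nodes
#' @export
fixtureGraph <- function(kind = c("clique", "star", "path", "cycle",
                                  "hierarchical"),
                         size, levels = 2L) {
  kind <- match.arg(kind)
  lbl <- function(n) .idSeq("v", n)
  switch(kind,
    clique = {
      stopifnot(size >= 1L)
      v <- lbl(size)
      e <- if (size > 1L) t(utils::combn(v, 2L)) else NULL
      PPANetwork(v, e)
    },
    star = {
      stopifnot(size >= 1L)
      v <- c("hub", lbl(size))
      PPANetwork(v, cbind("hub", lbl(size)))
    },
    path = {
      stopifnot(size >= 1L)
      v <- lbl(size)
      e <- if (size > 1L) cbind(v[-size], v[-1L]) else NULL
      PPANetwork(v, e)
    },
    cycle = {
      stopifnot(size >= 3L)
      v <- lbl(size)
      PPANetwork(v, rbind(cbind(v[-size], v[-1L]), c(v[1L], v[size])))
    },
    hierarchical = .hierarchicalGraph(size, levels))
}

# Recursive b-replica hierarchical graph: K_b seed with hub = node 1;
# each level copies the structure b-1 times and wires the copies'
# peripheral nodes to the original hub.  Integer node indices throughout;
# labels assigned at the end (zero-padded, so lexicographic = numeric).
.hierarchicalGraph <- function(b, levels) {
  stopifnot(b >= 2L, levels >= 1L)
  n <- b
  e <- t(utils::combn(seq_len(b), 2L))
  periph <- if (b > 1L) 2:b else integer()
  if (levels > 1L) for (l in 2:levels) {
    eCopies <- lapply(seq_len(b - 1L), function(copy) e + n * copy)
    newPeriph <- unlist(lapply(seq_len(b - 1L),
                               function(copy) periph + n * copy))
    e <- rbind(e, do.call(rbind, eCopies),
               cbind(rep(1L, length(newPeriph)), newPeriph))
    periph <- newPeriph
    n <- b * n
  }
  v <- sprintf("n%0*d", nchar(n), seq_len(n))
  PPANetwork(v, cbind(v[e[, 1L]], v[e[, 2L]]))
}
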