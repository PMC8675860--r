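# End-to-end orchestration: input (files or simulation) -> pathway filter
# -> projection -> topology -> centrality -> key nodes -> core subnetwork,
# with a machine-readable JSON report echoing every convention applied.

#' Assemble a pipeline run configuration
#'
#' Exactly one of `membership_path`/`compounds_path` (file mode) or
#' `simulate` (generator mode) must be supplied.
#'
#' @param membership_path,membership_format,compounds_path input files;
#'   `membership_format` is `"gmt"` or `"tsv"`.
#' @param simulate list with elements `membership` (arguments for
#'   [membershipGenConfig()]) and `compounds` (arguments for
#'   [compoundGenConfig()]).
#' @param min_pathway_size pathway filter threshold (default 3).
#' @param hub_rule,hub_param hub rule, see [identifyHubs()].
#' @param z_threshold outlier threshold, see [detectCentralOutliers()].
#' @param min_coverage critical-pathway threshold, see
#'   [criticalPathways()].
#' @param outdir output directory (created if missing), or `NULL` to skip
#'   file output.
#' @param seed integer; seeds the generators in simulate mode (overrides
#'   seeds given inside `simulate`).
#' @return A list of class `RunConfig`.
#' @export
runConfig <- function(membership_path = NULL, membership_format = "gmt",
                      compounds_path = NULL, simulate = NULL,
                      min_pathway_size = 3L,
                      hub_rule = "degree_factor", hub_param = 2.5,
                      z_threshold = 2.5, min_coverage = 1.0,
                      outdir = NULL, seed = 1L) {
  file_mode <- !is.null(membership_path)
  if (file_mode == !is.null(simulate))
    stop("exactly one of input paths or a simulate block must be given")
  if (min_pathway_size < 1L || hub_param <= 0 || z_threshold <= 0 ||
      min_coverage <= 0)
    stop("all thresholds must be positive")
  structure(list(membership_path = membership_path,
                 membership_format = membership_format,
                 compounds_path = compounds_path, simulate = simulate,
                 min_pathway_size = as.integer(min_pathway_size),
                 hub_rule = hub_rule, hub_param = hub_param,
                 z_threshold = z_threshold, min_coverage = min_coverage,
                 outdir = outdir, seed = as.integer(seed)),
            class = "RunConfig")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [runConfig()].
#'
#' @param path YAML file path.
#' @return A `RunConfig` list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(runConfig, y)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full PPA-network pipeline
#'
#' Reads or simulates the membership and compound tables, filters
#' under-sized pathways, projects the PPA network, computes the topology
#' summary, the three centrality indices, hubs, centrality outliers, key
#' targets and neighbour coverage, and extracts the core subnetwork.  When
#' `outdir` is set, writes `report.json`, the network in Pajek / GraphML /
#' edge-list form, per-node metric TSVs, the C(k) and Knn(k) curves, and
#' the core subnetwork as typed GraphML.  Identical configs (including
#' seed) give byte-identical reports.
#'
#' @param cfg a `RunConfig` from [runConfig()] or [readRunConfig()], or a
#'   YAML path.
#' @return The report, an `AnalysisReport` list (JSON-shaped), invisibly
#'   when `outdir` is set.  Its `status` field is `"ok"` or `"warning"`
#'   (empty key-target set or empty core).
#' @examples
#' cfg <- runConfig(simulate = list(
#'   membership = list(n_targets = 30, n_pathways = 10, mean = 5,
#'                     isolated_fraction = 0.1),
#'   compounds = list(n_compounds = 4)), seed = 7)
#' rep <- runPipeline(cfg)
#' rep$summary$N
#' @export
runPipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  stopifnot(inherits(cfg, "RunConfig"))
  status <- "ok"

  if (!is.null(cfg$simulate)) {
    memArgs <- cfg$simulate$membership
    memArgs$seed <- cfg$seed
    mem <- .stage("simulate", generateMembership(
      do.call(membershipGenConfig, memArgs)))
    cmpArgs <- cfg$simulate$compounds
    cmpArgs$seed <- cfg$seed + 1L
    cmap <- .stage("simulate", generateCompoundTargets(
      do.call(compoundGenConfig, cmpArgs), targets(mem)))
  } else {
    mem <- .stage("read", readMembership(cfg$membership_path,
                                         cfg$membership_format))
    cmap <- if (is.null(cfg$compounds_path)) CompoundTargetMap()
            else .stage("read", readCompoundTargets(cfg$compounds_path))
  }

  memF <- .stage("filter_pathways", filterPathways(mem, cfg$min_pathway_size))
  net <- .stage("project", projectNetwork(memF))
  summ <- .stage("topology", networkSummary(net))
  cl <- clusteringCoefficients(net)
  ka <- knnAssortativity(net)
  ci <- .stage("centrality", centralityIndices(net))
  hubs <- .stage("key_nodes", identifyHubs(net, cfg$hub_rule, cfg$hub_param))
  # too few nodes with defined indices: no outlier analysis, empty key set
  outliers <- if (sum(stats::complete.cases(ci[, c("cd", "cb", "cc")])) < 5L) {
    status <- "warning"
    data.frame(node = character(), z_cd = numeric(), z_cb = numeric(),
               z_cc = numeric(), max_z = numeric(), stringsAsFactors = FALSE)
  } else .stage("key_nodes", detectCentralOutliers(ci, cfg$z_threshold))
  keys <- withCallingHandlers(
    selectKeyTargets(hubs, outliers),
    warning = function(w) { status <<- "warning"; invokeRestart("muffleWarning") })
  cov <- .stage("key_nodes", neighborCoverage(net, keys$key_targets))
  core <- if (length(keys$key_targets)) {
    withCallingHandlers(
      .stage("core", buildCore(cmap, memF, keys$key_targets,
                               cfg$min_coverage)),
      warning = function(w) { status <<- "warning"; invokeRestart("muffleWarning") })
  } else NULL

  finiteOrNA <- function(x) ifelse(is.finite(x), x, NA_real_)
  report <- list(
    status = status,
    summary = list(
      N = summ@N, E = summ@E, diameter = summ@diameter,
      avg_path_length = summ@avgPathLength,
      clustering = summ@clustering, avg_degree = summ@avgDegree,
      assortativity = if (summ@assortativityDefined) summ@assortativity
                      else NULL,
      assortativity_defined = summ@assortativityDefined,
      ck_exponent = finiteOrNA(summ@ckExponent),
      ck_r_squared = finiteOrNA(summ@ckRsquared)),
    degree_distribution = summ@degreeDistribution,
    ck_curve = summ@ckCurve,
    knn_curve = summ@knnCurve,
    key_nodes = list(
      hubs = hubs,
      central_outliers = data.frame(
        node = outliers$node,
        max_z = finiteOrNA(outliers$max_z),
        stringsAsFactors = FALSE),
      key_targets = keys$key_targets,
      hub_overlap = keys$hub_overlap,
      neighbor_coverage = list(count = cov$count,
                               percent = round(cov$percent, 1))),
    core = if (!is.null(core)) list(
      compounds = core@compounds, targets = core@targets,
      pathways = core@pathways,
      node_count = numNodes(core), edge_count = numEdges(core)),
    provenance = list(
      package = "ppanet",
      version = as.character(utils::packageVersion("ppanet")),
      seed = cfg$seed,
      config = cfg[setdiff(names(cfg), "outdir")],
      conventions = list(
        path_length = "mean over mutually reachable ordered pairs",
        clustering_average = "nodes with degree >= 2 only",
        betweenness = "Brandes; endpoints excluded; normalised by (N-1)(N-2)/2",
        closeness = "Wasserman-Faust component scaling",
        assortativity = "edge-sum Pearson form, each undirected edge once",
        ck_fit = "OLS on log10-log10, points with k >= 2 and mean C > 0",
        edges = "unweighted; shared-pathway counts kept as metadata")))

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(cfg$outdir, f)
    jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    writeNetwork(net, p("network.net"), "pajek")
    writeNetwork(net, p("network.graphml"), "graphml")
    writeNetwork(net, p("network_edges.tsv"), "edgelist")
    k <- degrees(net)
    utils::write.table(
      data.frame(node = nodes(net), k = as.integer(k),
                 ci = unname(cl$ci), knn = unname(ka$knn)),
      p("node_metrics.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ci, p("centrality.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(outliers, p("outlier_zscores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(summ@ckCurve, p("ck_curve.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(summ@knnCurve, p("knn_curve.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(core)) writeCoreGraphml(core, p("core.graphml"))
    return(invisible(report))
  }
  report
}
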