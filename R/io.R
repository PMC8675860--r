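#' Read a target-pathway membership table
#'
#' Parses either the GMT gene-set format (one pathway per line:
#' `pathway_id <TAB> description <TAB> member1 <TAB> member2 ...`) or a
#' two-column TSV with header `target_id`, `pathway_id` (one membership
#' pair per row).  In the TSV dialect a row with an empty pathway field
#' declares a pathway-less target: it joins the target universe and will
#' project to an isolated node.
#'
#' Labels are whitespace-trimmed and case-sensitive.  Memberships are
#' de-duplicated; the result is independent of input row order.
#'
#' @param path file path.
#' @param format `"gmt"` or `"tsv"`.
#' @return A [MembershipTable-class].
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("hsa04726\tserotonergic\tPGH2\tGNAS", f)
#' readMembership(f, "gmt")
#' @export
readMembership <- function(path, format = c("gmt", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "gmt") {
    if (!length(lines)) stop("no pathways parsed from ", path)
    sets <- list()
    for (i in seq_along(lines)) {
      f <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1]])
      if (length(f) < 3L || !nzchar(f[1L]))
        stop("malformed GMT line ", i, ": expected id, description, members")
      id <- f[1L]
      members <- sort(unique(f[-(1:2)][nzchar(f[-(1:2)])]))
      if (!length(members)) stop("malformed GMT line ", i, ": no members")
      if (!is.null(sets[[id]])) {
        if (!identical(sets[[id]], members))
          stop("duplicate pathway id with conflicting members: ", id)
      } else sets[[id]] <- members
    }
    MembershipTable(sets)
  } else {
    if (length(lines) < 1L) stop("no pathways parsed from ", path)
    header <- trimws(strsplit(lines[[1L]], "\t", fixed = TRUE)[[1]])
    if (length(header) < 2L)
      stop("malformed TSV line 1: expected header target_id<TAB>pathway_id")
    body <- lines[-1L]
    tgt <- character(length(body)); pw <- character(length(body))
    for (i in seq_along(body)) {
      f <- trimws(strsplit(body[[i]], "\t", fixed = TRUE)[[1]])
      if (length(f) < 1L || !nzchar(f[1L]))
        stop("malformed TSV line ", i + 1L, ": missing target id")
      if (length(f) > 2L)
        stop("malformed TSV line ", i + 1L, ": more than two columns")
      tgt[i] <- f[1L]
      pw[i] <- if (length(f) == 2L) f[2L] else ""
    }
    with_pw <- nzchar(pw)
    sets <- lapply(split(tgt[with_pw], pw[with_pw]),
                   function(m) sort(unique(m)))
    if (!length(sets) && !length(tgt)) stop("no pathways parsed from ", path)
    MembershipTable(sets, targets = unique(tgt))
  }
}

#' Read a compound-target table
#'
#' Two-column TSV with header `compound_id`, `target_id`; duplicate rows
#' collapse to one link.
#'
#' @param path file path.
#' @return A [CompoundTargetMap-class].
#' @export
readCompoundTargets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          blank.lines.skip = TRUE)
  if (ncol(df) < 2L) stop("expected two columns: compound_id, target_id")
  CompoundTargetMap(df[, 1:2])
}

#' Write a PPA network to a standard graph format
#'
#' `pajek`: `*Vertices N`, then 1-based `id "label"` lines with vertices in
#' lexicographic label order, then `*Edges` with 1-based endpoint pairs.
#' `edgelist`: TSV of label pairs, lexicographically smaller label first,
#' rows sorted; an isolated node is written as a row with an empty second
#' column so that round-tripping preserves the node set.  `graphml`:
#' standard GraphML with node ids equal to labels.
#'
#' For every format, `readNetwork(writeNetwork(net))` reproduces `net`
#' exactly (node set, edge set, labels).
#'
#' @param net a [PPANetwork-class].
#' @param path output file path.
#' @param format `"pajek"`, `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(net, path, format = c("pajek", "graphml", "edgelist")) {
  format <- match.arg(format)
  stopifnot(is(net, "PPANetwork"))
  v <- net@nodes            # already lexicographically sorted
  e <- net@edges
  out <- switch(format,
    pajek = {
      idx1 <- match(e[, 1L], v); idx2 <- match(e[, 2L], v)
      c(sprintf("*Vertices %d", length(v)),
        sprintf("%d \"%s\"", seq_along(v), v),
        "*Edges",
        if (nrow(e)) sprintf("%d %d", idx1, idx2) else character())
    },
    edgelist = {
      iso <- setdiff(v, as.vector(e))
      sort(c(if (nrow(e)) paste(e[, 1L], e[, 2L], sep = "\t"),
             if (length(iso)) paste0(iso, "\t")))
    },
    graphml = return(.writeGraphml(v, e, path)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

.graphmlHeader <- paste0(
  '<?xml version="1.0" encoding="UTF-8"?>\n',
  '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">')

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

.writeGraphml <- function(v, e, path, nodeType = NULL) {
  lines <- c(.graphmlHeader,
    if (!is.null(nodeType))
      '  <key id="type" for="node" attr.name="type" attr.type="string"/>',
    '  <graph edgedefault="undirected">')
  for (i in seq_along(v)) {
    if (is.null(nodeType))
      lines <- c(lines, sprintf('    <node id="%s"/>', .xmlEscape(v[i])))
    else
      lines <- c(lines, sprintf(
        '    <node id="%s"><data key="type">%s</data></node>',
        .xmlEscape(v[i]), nodeType[i]))
  }
  if (nrow(e))
    lines <- c(lines, sprintf('    <edge source="%s" target="%s"/>',
                              .xmlEscape(e[, 1L]), .xmlEscape(e[, 2L])))
  lines <- c(lines, "  </graph>", "</graphml>")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a network written by [writeNetwork()]
#'
#' @param path file path.
#' @param format `"pajek"`, `"graphml"` or `"edgelist"`.
#' @return A [PPANetwork-class].
#' @export
readNetwork <- function(path, format = c("pajek", "graphml", "edgelist")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
    pajek = {
      lines <- readLines(path, warn = FALSE)
      vhead <- grep("^\\*Vertices", lines, ignore.case = TRUE)
      ehead <- grep("^\\*Edges", lines, ignore.case = TRUE)
      if (!length(vhead) || !length(ehead))
        stop("not a Pajek file: missing *Vertices/*Edges section")
      n <- as.integer(sub("^\\*Vertices\\s+", "", lines[vhead[1L]],
                          ignore.case = TRUE))
      vlines <- lines[(vhead[1L] + 1L):(ehead[1L] - 1L)]
      vlines <- vlines[nzchar(trimws(vlines))]
      if (length(vlines) != n) stop("Pajek vertex count mismatch")
      m <- regmatches(vlines, regexec('^\\s*(\\d+)\\s+"(.*)"\\s*$', vlines))
      if (any(vapply(m, length, 0L) != 3L))
        stop("malformed Pajek vertex line")
      labels <- character(n)
      labels[as.integer(vapply(m, `[`, "", 2L))] <-
        vapply(m, `[`, "", 3L)
      elines <- if (ehead[1L] < length(lines))
        lines[(ehead[1L] + 1L):length(lines)] else character()
      elines <- elines[nzchar(trimws(elines))]
      e <- if (length(elines)) {
        parts <- strsplit(trimws(elines), "\\s+")
        cbind(labels[as.integer(vapply(parts, `[`, "", 1L))],
              labels[as.integer(vapply(parts, `[`, "", 2L))])
      } else NULL
      PPANetwork(labels, e)
    },
    edgelist = {
      lines <- readLines(path, warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      parts <- strsplit(lines, "\t", fixed = TRUE)
      iso <- vapply(parts, function(p) length(p) < 2L || !nzchar(p[2L]),
                    logical(1))
      e <- if (any(!iso))
        do.call(rbind, lapply(parts[!iso], function(p) p[1:2])) else NULL
      PPANetwork(c(vapply(parts, `[`, "", 1L)), e)
    },
    graphml = {
      doc <- xml2::read_xml(path)
      ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
      nv <- xml2::xml_find_all(doc, ".//g:node", ns)
      ne <- xml2::xml_find_all(doc, ".//g:edge", ns)
      v <- xml2::xml_attr(nv, "id")
      e <- if (length(ne))
        cbind(xml2::xml_attr(ne, "source"), xml2::xml_attr(ne, "target"))
      else NULL
      PPANetwork(v, e)
    })
}

#' Write a membership table
#'
#' GMT output carries one pathway per line; TSV output carries one
#' `target_id`, `pathway_id` pair per row (header included) with
#' pathway-less targets as empty-pathway rows, so read/write round-trips.
#'
#' @param mem a [MembershipTable-class].
#' @param path output file path.
#' @param format `"gmt"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
writeMembership <- function(mem, path, format = c("gmt", "tsv")) {
  format <- match.arg(format)
  stopifnot(is(mem, "MembershipTable"))
  ids <- sort(names(mem@pathways))
  if (format == "gmt") {
    lines <- vapply(ids, function(id)
      paste(c(id, "na", mem@pathways[[id]]), collapse = "\t"), "")
  } else {
    rows <- character()
    for (id in ids)
      rows <- c(rows, paste(mem@pathways[[id]], id, sep = "\t"))
    orphans <- setdiff(mem@targets,
                       unlist(mem@pathways, use.names = FALSE))
    lines <- c("target_id\tpathway_id", sort(rows),
               if (length(orphans)) paste0(sort(orphans), "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a core subnetwork as typed GraphML
#'
#' Emits GraphML with a string node attribute `type` taking values
#' `compound`, `target` or `pathway`.
#'
#' @param core a [CoreSubnetwork-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCoreGraphml <- function(core, path) {
  stopifnot(is(core, "CoreSubnetwork"))
  v <- c(core@compounds, core@targets, core@pathways)
  types <- rep(c("compound", "target", "pathway"),
               c(length(core@compounds), length(core@targets),
                 length(core@pathways)))
  e <- as.matrix(core@edges[, c("from", "to")])
  storage.mode(e) <- "character"
  .writeGraphml(v, e, path, nodeType = types)
}
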