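#' Read a vascular graph from the exchange format
#'
#' The normative exchange format is a JSON document
#' `{"nodes":[{"id","x","y","z"},...], "edges":[{"id","from","to","radius"},...],
#' "roots":[ids]}` with coordinates and radii in mm.  An equivalent two-file
#' CSV dialect stores the node and edge tables as `<stem>.nodes.csv` and
#' `<stem>.edges.csv` with the same column headers; root node ids are marked
#' in an optional `root` column of the node table.
#'
#' @param path file path.  For `format = "csv"` either of the two file names
#'   or the common stem.
#' @param format `"json"` (default, inferred from a `.json` extension) or
#'   `"csv"`.
#' @return a [raw_vascular_graph()].
#' @seealso [write_graph()], [correct_graph()]
#' @export
read_graph <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    if (!file.exists(path)) stop("file not found: ", path)
    doc <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
                    error = function(e) stop("malformed JSON in '", path,
                                             "': ", conditionMessage(e)))
    for (part in c("nodes", "edges"))
      if (is.null(doc[[part]])) stop("malformed graph file: missing '", part, "'")
    nodes <- if (length(doc$nodes)) as.data.frame(doc$nodes)
             else data.frame(id = character(), x = numeric(), y = numeric(),
                             z = numeric())
    edges <- if (length(doc$edges)) as.data.frame(doc$edges)
             else data.frame(id = character(), from = character(),
                             to = character(), radius = numeric())
    roots <- as.character(unlist(doc$roots))
    raw_vascular_graph(nodes, edges, roots)
  } else {
    stem <- sub("\\.(nodes|edges)\\.csv$", "", path)
    nf <- paste0(stem, ".nodes.csv"); ef <- paste0(stem, ".edges.csv")
    if (!file.exists(nf)) stop("file not found: ", nf)
    if (!file.exists(ef)) stop("file not found: ", ef)
    nodes <- utils::read.csv(nf, stringsAsFactors = FALSE,
                             colClasses = c(id = "character"))
    edges <- utils::read.csv(ef, stringsAsFactors = FALSE,
                             colClasses = c(id = "character",
                                            from = "character",
                                            to = "character"))
    roots <- if ("root" %in% names(nodes)) nodes$id[as.logical(nodes$root)]
             else character()
    nodes$root <- NULL
    raw_vascular_graph(nodes, edges, roots)
  }
}

#' Write a vascular graph or tree in the exchange format
#'
#' Output is canonical: node and edge records are each sorted by id, so the
#' same graph always yields byte-identical files.
#'
#' @param graph a `raw_vascular_graph` or `vascular_tree`.
#' @param path output path (for CSV, the stem; `.nodes.csv`/`.edges.csv` are
#'   appended).
#' @param format `"json"` (default by extension) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  nodes <- graph$nodes; edges <- graph$edges
  if (nrow(nodes) && any(!is.finite(as.matrix(nodes[, c("x", "y", "z")]))))
    stop("non-finite node position")
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  edges <- edges[order(edges$id), , drop = FALSE]
  roots <- if (inherits(graph, "vascular_tree")) graph$root else graph$roots
  roots <- sort(as.character(roots))
  if (format == "json") {
    doc <- list(
      nodes = data.frame(id = nodes$id, x = nodes$x, y = nodes$y, z = nodes$z),
      edges = data.frame(id = edges$id, from = edges$from, to = edges$to,
                         radius = edges$radius),
      roots = roots)
    json <- jsonlite::toJSON(doc, dataframe = "rows", digits = NA,
                             auto_unbox = FALSE, pretty = TRUE)
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(json, con)
  } else {
    stem <- sub("\\.(nodes|edges)\\.csv$", "", path)
    nodes$root <- nodes$id %in% roots
    utils::write.csv(nodes, paste0(stem, ".nodes.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(edges[, c("id", "from", "to", "radius")],
                     paste0(stem, ".edges.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

#' Read a corrected vascular tree from the exchange format
#'
#' Convenience wrapper: reads a graph that is already strictly bifurcative
#' (e.g. one written by [write_graph()] after [correct_graph()]) and returns
#' it as a validated [vascular_tree()].  The declared root (first entry of
#' `roots`) is used.
#'
#' @inheritParams read_graph
#' @return a `vascular_tree`.
#' @export
read_tree <- function(path, format = c("auto", "json", "csv")) {
  g <- read_graph(path, format)
  root <- if (length(g$roots)) g$roots[[1L]] else {
    cand <- setdiff(g$nodes$id, g$edges$to)
    cand <- cand[cand %in% g$edges$from]
    if (length(cand) != 1L) stop("cannot infer a unique root node")
    cand
  }
  vascular_tree(g$nodes, g$edges, root)
}

#' Export a tree as VTK legacy polylines (non-normative, for visualisation)
#'
#' @param tree a `vascular_tree` or `raw_vascular_graph`.
#' @param path output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(tree, path) {
  ni <- node_lookup(tree)
  P <- node_positions(tree)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "vascular tree", "ASCII",
               "DATASET POLYDATA", paste("POINTS", nrow(P), "double")), con)
  writeLines(apply(P, 1L, function(p) paste(format(p, digits = 12), collapse = " ")), con)
  ne <- nrow(tree$edges)
  writeLines(paste("LINES", ne, 3L * ne), con)
  writeLines(paste(2L, ni[tree$edges$from] - 1L, ni[tree$edges$to] - 1L), con)
  writeLines(c(paste("CELL_DATA", ne), "SCALARS radius double 1",
               "LOOKUP_TABLE default",
               format(tree$edges$radius, digits = 12)), con)
  invisible(path)
}

#' Export a tree as a DOT digraph (non-normative, for visualisation)
#'
#' @inheritParams write_vtk
#' @return `path`, invisibly.
#' @export
write_dot <- function(tree, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("digraph vasculature {", con)
  writeLines(sprintf("  \"%s\" -> \"%s\" [label=\"r=%.3g\"];",
                     tree$edges$from, tree$edges$to, tree$edges$radius), con)
  writeLines("}", con)
  invisible(path)
}
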