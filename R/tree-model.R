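#' @useDynLib vasctree, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm quantile sd setNames
#' @importFrom utils combn head tail
NULL

#' Construct a raw vascular graph
#'
#' A raw vascular graph is the direct in-memory image of a skeletonised
#' vascular network as extracted from image data: nodes with 3-D positions
#' (mm) and directed edges (initial -> terminal, in flow direction) with
#' radii (mm).  No structural guarantees are made: monofurcations,
#' multifurcations, parallel parent edges, several declared roots and
#' isolated nodes may all be present.  Use [correct_graph()] to repair it
#' into a strictly bifurcative [vascular_tree()].
#'
#' @param nodes data frame with columns `id`, `x`, `y`, `z` (positions in mm).
#' @param edges data frame with columns `id`, `from`, `to`, `radius` (mm).
#'   An optional logical column `trivial` flags zero-length bookkeeping edges.
#' @param roots character vector of declared root node ids (may be empty).
#' @return An object of class `raw_vascular_graph`.
#' @seealso [correct_graph()], [read_graph()]
#' @export
raw_vascular_graph <- function(nodes, edges, roots = character()) {
  g <- structure(list(nodes = normalize_nodes(nodes),
                      edges = normalize_edges(edges),
                      roots = as.character(roots)),
                 class = "raw_vascular_graph")
  check_referential(g)
  g
}

#' Construct a vascular tree
#'
#' A vascular tree is a strictly bifurcative rooted geometric tree: every
#' edge has exactly zero or two daughter edges, a single edge is incident to
#' the root node, the edge set is acyclic and every node is reachable from
#' the root.  Edges are straight cylinders; lengths are always derived from
#' the endpoint positions and never stored.
#'
#' @inheritParams raw_vascular_graph
#' @param root id of the root node.
#' @param validate check all invariants (default `TRUE`).
#' @return An object of class `vascular_tree`.
#' @export
vascular_tree <- function(nodes, edges, root, validate = TRUE) {
  tr <- structure(list(nodes = normalize_nodes(nodes),
                       edges = normalize_edges(edges),
                       root = as.character(root)),
                  class = "vascular_tree")
  if (validate) validate_vascular_tree(tr)
  tr
}

normalize_nodes <- function(nodes) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  need <- c("id", "x", "y", "z")
  if (!all(need %in% names(nodes)))
    stop("node table must have columns id, x, y, z")
  nodes <- nodes[, need, drop = FALSE]
  nodes$id <- as.character(nodes$id)
  for (cc in c("x", "y", "z")) nodes[[cc]] <- as.numeric(nodes[[cc]])
  if (anyDuplicated(nodes$id))
    stop("duplicated node id: ", nodes$id[duplicated(nodes$id)][1L])
  if (nrow(nodes) && any(!is.finite(as.matrix(nodes[, c("x", "y", "z")]))))
    stop("non-finite node position")
  rownames(nodes) <- NULL
  nodes
}

normalize_edges <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need <- c("id", "from", "to", "radius")
  if (!all(need %in% names(edges)))
    stop("edge table must have columns id, from, to, radius")
  trivial <- if ("trivial" %in% names(edges)) as.logical(edges$trivial)
             else rep(FALSE, nrow(edges))
  edges <- edges[, need, drop = FALSE]
  edges$radius <- as.numeric(edges$radius)
  for (cc in c("id", "from", "to")) edges[[cc]] <- as.character(edges[[cc]])
  edges$trivial <- trivial
  if (anyDuplicated(edges$id))
    stop("duplicated edge id: ", edges$id[duplicated(edges$id)][1L])
  if (nrow(edges) && any(!is.finite(edges$radius) | edges$radius < 0))
    stop("edge radius must be finite and >= 0")
  rownames(edges) <- NULL
  edges
}

check_referential <- function(g) {
  bad <- setdiff(c(g$edges$from, g$edges$to), g$nodes$id)
  if (length(bad)) stop("edge endpoint refers to unknown node: ", bad[1L])
  if (length(g$roots)) {
    bad <- setdiff(g$roots, g$nodes$id)
    if (length(bad)) stop("declared root is not a node: ", bad[1L])
  }
  invisible(TRUE)
}

## ---- internal index helpers ------------------------------------------------

node_lookup <- function(tree) {
  setNames(seq_len(nrow(tree$nodes)), tree$nodes$id)
}

node_positions <- function(tree) {
  as.matrix(tree$nodes[, c("x", "y", "z")])
}

#' Edge lengths of a tree or graph
#'
#' Euclidean distance between the endpoint positions of every edge, in mm.
#'
#' @param tree a `vascular_tree` or `raw_vascular_graph`.
#' @return numeric vector, one entry per edge (in edge-table order).
#' @export
edge_lengths <- function(tree) {
  if (!nrow(tree$edges)) return(numeric())
  ni <- node_lookup(tree)
  P <- node_positions(tree)
  a <- P[ni[tree$edges$from], , drop = FALSE]
  b <- P[ni[tree$edges$to], , drop = FALSE]
  sqrt(rowSums((a - b)^2))
}

## edge index of the single edge leaving the root node
root_edge_index <- function(tree) {
  which(tree$edges$from == tree$root)
}

## list: for each edge, integer indices of its daughter edges
edge_children <- function(tree) {
  if (!nrow(tree$edges)) return(list())
  ch <- lapply(seq_len(nrow(tree$edges)), function(i) integer())
  m <- match(tree$edges$from, tree$edges$to)  # parent edge per edge
  for (i in seq_len(nrow(tree$edges))) {
    p <- m[i]
    if (!is.na(p)) ch[[p]] <- c(ch[[p]], i)
  }
  ch
}

## integer vector: parent edge index per edge (NA for the root edge)
edge_parents <- function(tree) {
  match(tree$edges$from, tree$edges$to)
}

## edges in post-order (daughters before parents); assumes valid tree
postorder_edges <- function(tree) {
  ch <- edge_children(tree)
  re <- root_edge_index(tree)
  n <- nrow(tree$edges)
  out <- integer(n); k <- 0L
  stack <- c(re); state <- integer(n)  # 0 unvisited, 1 expanded
  while (length(stack)) {
    e <- stack[length(stack)]
    if (state[e] == 0L) {
      state[e] <- 1L
      if (length(ch[[e]])) stack <- c(stack, ch[[e]])
    } else {
      stack <- stack[-length(stack)]
      if (state[e] == 1L) { k <- k + 1L; out[k] <- e; state[e] <- 2L }
    }
  }
  out[seq_len(k)]
}

#' Validate the invariants of a vascular tree
#'
#' Checks strict bifurcativity (every edge has 0 or 2 daughter edges), the
#' single root edge, acyclicity, reachability of every node from the root,
#' unique ids, referential integrity and finite geometry.
#'
#' @param tree object to validate.
#' @return `TRUE` invisibly; signals an error describing the first violated
#'   invariant otherwise.
#' @export
validate_vascular_tree <- function(tree) {
  stopifnot(inherits(tree, "vascular_tree"))
  check_referential(tree)
  if (!nrow(tree$edges)) stop("vascular tree must have at least one edge")
  if (!(tree$root %in% tree$nodes$id)) stop("root node not present")
  inc <- sum(tree$edges$from == tree$root) + sum(tree$edges$to == tree$root)
  if (inc != 1L || length(root_edge_index(tree)) != 1L)
    stop("root node must have exactly one incident (daughter) edge")
  ndaught <- tabulate(match(tree$edges$from, tree$edges$to),
                      nbins = nrow(tree$edges))
  if (!all(ndaught %in% c(0L, 2L)))
    stop("tree is not strictly bifurcative (edge with ",
         ndaught[which(!(ndaught %in% c(0L, 2L)))[1L]], " daughters)")
  nparent <- tabulate(match(tree$edges$to, tree$edges$from),
                      nbins = nrow(tree$edges))
  if (any(table(tree$edges$to) > 1L))
    stop("node with more than one parent edge")
  ## reachability + acyclicity: walk from root
  po <- tryCatch(postorder_edges(tree), error = function(e) NULL)
  if (is.null(po) || length(po) != nrow(tree$edges))
    stop("not all edges reachable from the root (or cycle present)")
  reach_nodes <- unique(c(tree$root, tree$edges$to))
  if (!setequal(reach_nodes, tree$nodes$id))
    stop("isolated or unreachable node present")
  len <- edge_lengths(tree)
  if (any(len == 0 & !tree$edges$trivial & tree$edges$from != tree$edges$to)) {
    ## zero-length edges must be flagged trivial
    stop("zero-length edge not flagged trivial: ",
         tree$edges$id[which(len == 0 & !tree$edges$trivial)[1L]])
  }
  if (any(tree$edges$from == tree$edges$to))
    stop("self-loop edge present")
  invisible(TRUE)
}

#' @export
print.vascular_tree <- function(x, ...) {
  len <- edge_lengths(x)
  cat("Vascular tree: ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (", sum(len == 0), " trivial), root node '", x$root, "'\n",
      sep = "")
  cat("  leaf edges: ", sum(!(x$edges$to %in% x$edges$from)),
      ";  total length: ", format(sum(len), digits = 6), " mm\n", sep = "")
  invisible(x)
}

#' @export
print.raw_vascular_graph <- function(x, ...) {
  cat("Raw vascular graph: ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges, ", length(x$roots), " declared root(s)\n", sep = "")
  invisible(x)
}

## leaf edges: edges whose terminal node has no daughters
leaf_edges <- function(tree) {
  which(!(tree$edges$to %in% tree$edges$from))
}

## deterministic fresh-id generator given existing ids and a stem
fresh_ids <- function(existing, stem, n) {
  out <- character(n); k <- 1L; i <- 1L
  while (k <= n) {
    cand <- paste0(stem, i)
    if (!(cand %in% existing)) { out[k] <- cand; existing <- c(existing, cand); k <- k + 1L }
    i <- i + 1L
  }
  out
}

## run code with a private, seeded RNG stream; restores global state
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}
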