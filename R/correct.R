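#' Repair a raw vascular graph into a strictly bifurcative tree
#'
#' Skeletonised vascular networks routinely violate the strictly bifurcative
#' tree structure required by the morphometric analysis: self-loop edges,
#' parallel parent edges, nodes with several parent edges (improper loops),
#' monofurcations, multifurcations, isolated nodes and multiple root nodes
#' may all occur.  `correct_graph()` applies a fixed sequence of repairs:
#'
#' 1. edges whose initial and terminal node coincide are removed;
#' 2. parallel parent edges sharing one initial node are merged into a
#'    single edge whose radius preserves the total cross-section area,
#'    \eqn{r = \sqrt{\sum r_i^2}};
#' 3. of several parent edges with distinct initial nodes, only one of
#'    maximal radius is kept (ties: smallest edge id);
#' 4. monofurcations are removed, the merged edge taking the arithmetic mean
#'    of the two radii;
#' 5. k-furcations (k > 2) are split into k-1 bifurcations by inserting
#'    zero-length "trivial" edges at the same position, so the geometry is
#'    unchanged; trivial edges carry the radius of the incoming parent edge;
#' 6. isolated nodes are removed;
#' 7. root nodes with two daughter edges receive a trivial trunk edge so the
#'    root has a single incident edge; if several root components remain,
#'    the component with the most edges is returned (ties: smallest root id).
#'
#' Proper loops (directed cycles) are not repairable and raise an error.
#'
#' @param graph a [raw_vascular_graph()].
#' @return a list with elements `tree` (a validated [vascular_tree()]) and
#'   `log` (a `correction_log`: one record per repair, replayable with
#'   [replay_corrections()]).
#' @examples
#' nodes <- data.frame(id = c("a", "b", "c"), x = c(0, 0, 0),
#'                     y = c(0, -1, -2), z = 0)
#' edges <- data.frame(id = c("e1", "e2"), from = c("a", "b"),
#'                     to = c("b", "c"), radius = c(2, 4))
#' g <- raw_vascular_graph(nodes, edges, roots = "a")
#' res <- correct_graph(g)   # monofurcation at "b" merged, radius (2+4)/2 = 3
#' res$tree$edges$radius
#' @export
correct_graph <- function(graph) {
  stopifnot(inherits(graph, "raw_vascular_graph"))
  if (!nrow(graph$edges)) stop("cannot correct an empty graph (no edges)")
  nodes <- graph$nodes; edges <- graph$edges
  log <- list()
  note <- function(...) log[[length(log) + 1L]] <<- list(...)

  ## (1) remove existing trivial self-loop edges
  self <- edges$from == edges$to
  if (any(self)) {
    note(kind = "remove_self_loops", edges = edges$id[self])
    edges <- edges[!self, , drop = FALSE]
  }
  if (!nrow(edges)) stop("graph contains no usable edges after removing self-loops")

  ## proper loops (nontrivial directed cycles) cannot be repaired
  if (has_directed_cycle(edges)) stop("proper loop (directed cycle) detected")

  ## (2) merge parallel parent edges sharing one initial node
  key <- paste(edges$from, edges$to, sep = "\r")
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    idx <- idx[order(edges$id[idx])]
    r <- edges$radius[idx]
    rnew <- sqrt(sum(r^2))
    note(kind = "merge_parallel", kept = edges$id[idx[1L]],
         removed = edges$id[idx[-1L]], radius_before = r, radius_after = rnew)
    edges$radius[idx[1L]] <- rnew
    edges <- edges[-idx[-1L], , drop = FALSE]
    key <- paste(edges$from, edges$to, sep = "\r")
  }

  ## (3) several parent edges with distinct initial nodes: keep max radius
  repeat {
    tab <- table(edges$to)
    multi <- sort(names(tab)[tab > 1L])
    if (!length(multi)) break
    v <- multi[[1L]]
    idx <- which(edges$to == v)
    keep <- idx[order(-edges$radius[idx], edges$id[idx])][1L]
    drop <- setdiff(idx, keep)
    note(kind = "drop_extra_parents", node = v, kept = edges$id[keep],
         removed = edges$id[drop])
    edges <- edges[-drop, , drop = FALSE]
  }

  ## (4) remove monofurcations (cascading), nodes in ascending id order
  repeat {
    ndaught <- table(factor(edges$from, levels = nodes$id))
    nparent <- table(factor(edges$to, levels = nodes$id))
    mono <- sort(nodes$id[ndaught == 1L & nparent == 1L])
    if (!length(mono)) break
    v <- mono[[1L]]
    pi <- which(edges$to == v); di <- which(edges$from == v)
    rnew <- mean(c(edges$radius[pi], edges$radius[di]))
    note(kind = "merge_monofurcation", node = v, parent = edges$id[pi],
         daughter = edges$id[di],
         radius_before = c(edges$radius[pi], edges$radius[di]),
         radius_after = rnew, new_to = edges$to[di])
    edges$to[pi] <- edges$to[di]
    edges$radius[pi] <- rnew
    edges <- edges[-di, , drop = FALSE]
    nodes <- nodes[nodes$id != v, , drop = FALSE]
  }

  ## (5) split k-furcations (k > 2) by inserting trivial edges
  repeat {
    ndaught <- table(factor(edges$from, levels = nodes$id))
    multi <- sort(nodes$id[ndaught > 2L])
    if (!length(multi)) break
    v <- multi[[1L]]
    daughters <- which(edges$from == v)
    daughters <- daughters[order(edges$id[daughters])]
    k <- length(daughters)
    pin <- which(edges$to == v)
    rtriv <- if (length(pin)) edges$radius[pin[1L]]
             else sqrt(sum(edges$radius[daughters]^2))
    newn <- fresh_ids(nodes$id, paste0(v, ".s"), k - 2L)
    newe <- fresh_ids(edges$id, paste0(v, ".t"), k - 2L)
    note(kind = "split_multifurcation", node = v,
         daughters = edges$id[daughters], new_nodes = newn,
         new_edges = newe, trivial_radius = rtriv)
    pos <- nodes[nodes$id == v, c("x", "y", "z")]
    chain <- c(v, newn)
    dids <- edges$id[daughters]
    for (j in seq_len(k - 2L)) {
      nodes <- rbind(nodes, data.frame(id = newn[j], x = pos$x, y = pos$y,
                                       z = pos$z))
      edges <- rbind(edges, data.frame(id = newe[j], from = chain[j],
                                       to = chain[j + 1L], radius = rtriv,
                                       trivial = TRUE))
      ## daughter j stays at chain[j]; the rest move down the trivial chain
      edges$from[edges$id %in% dids[seq.int(j + 1L, k)]] <- chain[j + 1L]
    }
  }

  ## (6) remove isolated nodes
  used <- unique(c(edges$from, edges$to))
  iso <- setdiff(nodes$id, used)
  if (length(iso)) {
    note(kind = "remove_isolated", nodes = sort(iso))
    nodes <- nodes[nodes$id %in% used, , drop = FALSE]
  }

  ## (7) fix roots: one incident daughter edge each, then pick primary
  parents <- unique(edges$to)
  root_ids <- sort(setdiff(unique(edges$from), parents))
  for (v in root_ids) {
    kd <- sum(edges$from == v)
    if (kd >= 2L) {
      rtriv <- sqrt(sum(edges$radius[edges$from == v]^2))
      nid <- fresh_ids(nodes$id, paste0(v, ".r"), 1L)
      eid <- fresh_ids(edges$id, paste0(v, ".tr"), 1L)
      pos <- nodes[nodes$id == v, c("x", "y", "z")]
      note(kind = "add_root_trunk", root = v, new_root = nid,
           new_edge = eid, radius = rtriv)
      nodes <- rbind(nodes, data.frame(id = nid, x = pos$x, y = pos$y, z = pos$z))
      edges <- rbind(edges, data.frame(id = eid, from = nid, to = v,
                                       radius = rtriv, trivial = TRUE))
      root_ids[root_ids == v] <- nid
    }
  }
  ## component sizes per root
  comp_edges <- lapply(root_ids, function(v) reachable_edges(edges, v))
  sizes <- vapply(comp_edges, length, integer(1L))
  primary <- root_ids[order(-sizes, root_ids)][1L]
  if (length(root_ids) > 1L)
    note(kind = "select_component", root = primary,
         dropped_roots = setdiff(root_ids, primary))
  keep <- comp_edges[[which(root_ids == primary)]]
  edges <- edges[keep, , drop = FALSE]
  nodes <- nodes[nodes$id %in% c(primary, edges$to, edges$from), , drop = FALSE]

  len0 <- edge_lengths(list(nodes = nodes, edges = edges)) == 0
  if (!"trivial" %in% names(edges)) edges$trivial <- FALSE
  edges$trivial <- edges$trivial | len0

  tree <- vascular_tree(nodes, edges, primary)
  list(tree = tree, log = structure(log, class = "correction_log"))
}

#' @export
print.correction_log <- function(x, ...) {
  kinds <- vapply(x, function(e) e$kind, character(1L))
  cat("Correction log with", length(x), "repairs\n")
  if (length(kinds)) print(table(kinds))
  invisible(x)
}

## indices of edges reachable from node v (directed, parent -> daughter)
reachable_edges <- function(edges, v) {
  out <- integer(); frontier <- v
  while (length(frontier)) {
    idx <- which(edges$from %in% frontier)
    idx <- setdiff(idx, out)
    if (!length(idx)) break
    out <- c(out, idx)
    frontier <- edges$to[idx]
  }
  sort(out)
}

has_directed_cycle <- function(edges) {
  ids <- unique(c(edges$from, edges$to))
  indeg <- table(factor(edges$to, levels = ids))
  alive <- rep(TRUE, nrow(edges))
  queue <- ids[indeg == 0L]
  removed_nodes <- character()
  indeg <- as.vector(indeg); names(indeg) <- ids
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    out <- which(alive & edges$from == v)
    for (i in out) {
      alive[i] <- FALSE
      w <- edges$to[i]
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
    removed_nodes <- c(removed_nodes, v)
  }
  any(alive)
}

#' Replay a correction log on a raw graph
#'
#' Mechanically re-applies every logged repair (using the recorded ids and
#' radii, making no decisions of its own) and returns the resulting tree.
#' Replaying the log of [correct_graph()] on the original raw graph
#' reproduces the corrected tree exactly.
#'
#' @param graph the original [raw_vascular_graph()].
#' @param log a `correction_log`.
#' @return a [vascular_tree()].
#' @export
replay_corrections <- function(graph, log) {
  nodes <- graph$nodes; edges <- graph$edges
  root <- NULL
  for (e in log) {
    switch(e$kind,
      remove_self_loops = {
        edges <- edges[!(edges$id %in% e$edges), , drop = FALSE]
      },
      merge_parallel = {
        edges$radius[edges$id == e$kept] <- e$radius_after
        edges <- edges[!(edges$id %in% e$removed), , drop = FALSE]
      },
      drop_extra_parents = {
        edges <- edges[!(edges$id %in% e$removed), , drop = FALSE]
      },
      merge_monofurcation = {
        i <- which(edges$id == e$parent)
        edges$to[i] <- e$new_to
        edges$radius[i] <- e$radius_after
        edges <- edges[edges$id != e$daughter, , drop = FALSE]
        nodes <- nodes[nodes$id != e$node, , drop = FALSE]
      },
      split_multifurcation = {
        pos <- nodes[nodes$id == e$node, c("x", "y", "z")]
        chain <- c(e$node, e$new_nodes)
        k <- length(e$daughters)
        for (j in seq_len(k - 2L)) {
          nodes <- rbind(nodes, data.frame(id = e$new_nodes[j], x = pos$x,
                                           y = pos$y, z = pos$z))
          edges <- rbind(edges, data.frame(id = e$new_edges[j],
                                           from = chain[j], to = chain[j + 1L],
                                           radius = e$trivial_radius,
                                           trivial = TRUE))
          mv <- e$daughters[seq.int(j + 1L, k)]
          edges$from[edges$id %in% mv] <- chain[j + 1L]
        }
      },
      remove_isolated = {
        nodes <- nodes[!(nodes$id %in% e$nodes), , drop = FALSE]
      },
      add_root_trunk = {
        pos <- nodes[nodes$id == e$root, c("x", "y", "z")]
        nodes <- rbind(nodes, data.frame(id = e$new_root, x = pos$x,
                                         y = pos$y, z = pos$z))
        edges <- rbind(edges, data.frame(id = e$new_edge, from = e$new_root,
                                         to = e$root, radius = e$radius,
                                         trivial = TRUE))
      },
      select_component = {
        root <- e$root
        keep <- reachable_edges(edges, root)
        edges <- edges[keep, , drop = FALSE]
        nodes <- nodes[nodes$id %in% c(root, edges$from, edges$to), , drop = FALSE]
      },
      stop("unknown correction kind: ", e$kind))
  }
  if (is.null(root)) {
    root <- sort(setdiff(unique(edges$from), unique(edges$to)))[1L]
    keep <- reachable_edges(edges, root)
    edges <- edges[keep, , drop = FALSE]
    nodes <- nodes[nodes$id %in% c(root, edges$from, edges$to), , drop = FALSE]
  }
  len0 <- edge_lengths(list(nodes = nodes, edges = edges)) == 0
  if (!"trivial" %in% names(edges)) edges$trivial <- FALSE
  edges$trivial <- edges$trivial | len0
  vascular_tree(nodes, edges, root)
}
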