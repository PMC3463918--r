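#' Strahler orders of the edges of a vascular tree
#'
#' Strahler (stream) ordering is nondecreasing from the leaves to the root:
#' leaf edges have order 1; a parent edge takes the larger of its daughters'
#' orders when they differ and the common order plus one when they are
#' equal.  Trivial (zero-length) edges participate like any other edge.
#'
#' @param tree a [vascular_tree()].
#' @return named integer vector, one entry per edge keyed by edge id.
#' @seealso [strahler_star_orders()]
#' @export
strahler_orders <- function(tree) {
  stopifnot(inherits(tree, "vascular_tree"))
  ch <- edge_children(tree)
  ord <- integer(nrow(tree$edges))
  for (e in postorder_edges(tree)) {
    if (!length(ch[[e]])) {
      ord[e] <- 1L
    } else {
      d <- ord[ch[[e]]]
      ord[e] <- if (d[1L] == d[2L]) d[1L] + 1L else max(d)
    }
  }
  setNames(ord, tree$edges$id)
}

#' Strahler* orders (root-normalised Strahler orders)
#'
#' The Strahler* order of an edge is the difference between the Strahler
#' order of the root edge and that of the edge itself, so the root edge has
#' order 0 and orders increase towards the leaves.  This normalisation makes
#' trees resolved to different levels of detail comparable: edges of equal
#' Strahler* order play the same structural role relative to the root.
#'
#' @inheritParams strahler_orders
#' @return named integer vector keyed by edge id; the root edge maps to 0.
#' @export
strahler_star_orders <- function(tree) {
  s <- strahler_orders(tree)
  root <- s[[root_edge_index(tree)]]
  root - s
}

#' Connectivity histogram between Strahler* orders
#'
#' Counts parent-daughter edge pairs by the pair (parent order s', daughter
#' order s) of their Strahler* orders.  For a population of trees the
#' per-tree count matrices are averaged entrywise (each tree contributing
#' equally).  Percentages normalise by the total number of parent-daughter
#' pairs, per tree, and therefore sum to 100.
#'
#' @param trees a single `vascular_tree` or a list of them.
#' @return object of class `connectivity_histogram`: a list with matrices
#'   `counts` (average per-tree pair counts) and `percent`, rows indexed by
#'   the parent order, columns by the daughter order.
#' @export
connectivity_histogram <- function(trees) {
  if (inherits(trees, "vascular_tree")) trees <- list(trees)
  stopifnot(length(trees) > 0L)
  per_tree <- lapply(trees, function(tr) {
    ss <- strahler_star_orders(tr)
    par <- edge_parents(tr)
    keep <- !is.na(par)
    data.frame(sp = ss[par[keep]], sd = ss[keep])
  })
  smax <- max(0L, unlist(lapply(per_tree, function(d) c(d$sp, d$sd))))
  dims <- list(parent = as.character(0:smax), daughter = as.character(0:smax))
  counts <- matrix(0, smax + 1L, smax + 1L, dimnames = dims)
  percent <- matrix(0, smax + 1L, smax + 1L, dimnames = dims)
  for (d in per_tree) {
    m <- matrix(0, smax + 1L, smax + 1L)
    if (nrow(d)) for (i in seq_len(nrow(d)))
      m[d$sp[i] + 1L, d$sd[i] + 1L] <- m[d$sp[i] + 1L, d$sd[i] + 1L] + 1
    counts <- counts + m / length(per_tree)
    if (sum(m) > 0) percent <- percent + 100 * (m / sum(m)) / length(per_tree)
  }
  structure(list(counts = counts, percent = percent,
                 n_trees = length(per_tree)),
            class = "connectivity_histogram")
}

#' @export
print.connectivity_histogram <- function(x, ...) {
  cat("Connectivity histogram over", x$n_trees, "tree(s)\n")
  cat("average parent-daughter pair counts (rows: parent Strahler*):\n")
  print(round(x$counts, 3))
  invisible(x)
}

#' Order census of a tree population
#'
#' For every Strahler* order `s`, reports how many trees of the population
#' have at least one edge of that order (`n_s`) and the mean number of such
#' edges among those trees.  `n_s` drives the order cutoff of the similarity
#' averaging (see [average_over_orders()]).
#'
#' @param trees list of `vascular_tree` objects (a single tree is accepted).
#' @return data frame with columns `order`, `n_trees`, `mean_edges`.
#' @export
order_census <- function(trees) {
  if (inherits(trees, "vascular_tree")) trees <- list(trees)
  if (!length(trees)) stop("empty population")
  per_tree <- lapply(trees, function(tr) table(strahler_star_orders(tr)))
  smax <- max(unlist(lapply(per_tree, function(t) as.integer(names(t)))))
  out <- data.frame(order = 0:smax, n_trees = 0L, mean_edges = NA_real_)
  for (s in 0:smax) {
    cnt <- vapply(per_tree, function(t) {
      v <- t[as.character(s)]
      if (is.na(v)) 0L else as.integer(v)
    }, integer(1L))
    out$n_trees[s + 1L] <- sum(cnt > 0L)
    out$mean_edges[s + 1L] <- if (any(cnt > 0L)) mean(cnt[cnt > 0L]) else NA_real_
  }
  out
}
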