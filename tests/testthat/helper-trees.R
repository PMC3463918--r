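# Fixture builders and independent oracles shared across the suite.
# Everything here is deliberately written in the most naive way possible so
# that it stays independent of the package's own code paths.

## random strictly bifurcative geometric tree, built edge by edge in plain R
rand_valid_tree <- function(seed, n_leaves = NULL, max_leaves = 32) {
  set.seed(seed)
  if (is.null(n_leaves)) n_leaves <- sample(2:max_leaves, 1L)
  nodes <- data.frame(id = c("r", "t1"), x = c(0, 0), y = c(0, -10), z = c(0, 0),
                      stringsAsFactors = FALSE)
  edges <- data.frame(id = "e1", from = "r", to = "t1", radius = 4,
                      stringsAsFactors = FALSE)
  leaves <- "e1"
  k <- 1L
  while (length(leaves) < n_leaves) {
    pick <- sample(leaves, 1L)
    at <- edges$to[edges$id == pick]
    p <- as.numeric(nodes[nodes$id == at, c("x", "y", "z")])
    r <- edges$radius[edges$id == pick]
    ids <- paste0("e", k + 1:2); nids <- paste0("t", k + 1:2)
    k <- k + 2L
    for (j in 1:2) {
      q <- p + rnorm(3, sd = 3) - c(0, 2, 0)
      nodes <- rbind(nodes, data.frame(id = nids[j], x = q[1], y = q[2], z = q[3]))
      edges <- rbind(edges, data.frame(id = ids[j], from = at, to = nids[j],
                                       radius = r * runif(1, 0.5, 0.95)))
    }
    leaves <- c(setdiff(leaves, pick), ids)
  }
  vascular_tree(nodes, edges, "r")
}

## brute-force recursive Strahler oracle (memo-free, plain recursion)
oracle_strahler <- function(tree) {
  kids <- function(eid) tree$edges$id[tree$edges$from == tree$edges$to[tree$edges$id == eid]]
  rec <- function(eid) {
    d <- kids(eid)
    if (!length(d)) return(1L)
    s <- vapply(d, rec, integer(1L))
    if (s[1L] == s[2L]) s[1L] + 1L else max(s)
  }
  root_eid <- tree$edges$id[tree$edges$from == tree$root]
  out <- vapply(tree$edges$id, rec, integer(1L))
  names(out) <- tree$edges$id
  out
}

## seeded corruption of a valid tree into a defective raw skeleton graph
corrupt_tree <- function(tree, seed) {
  set.seed(seed)
  nodes <- tree$nodes; edges <- tree$edges[, c("id", "from", "to", "radius")]
  fresh <- function(stem, n = 1L) paste0(stem, seed, "_", seq_len(n), "_", sample(1e6, n))
  ## monofurcations: split some edges by inserting a pass-through node
  for (i in sample(nrow(edges), min(3L, nrow(edges)))) {
    nid <- fresh("mono"); eid <- fresh("me")
    a <- as.numeric(nodes[nodes$id == edges$from[i], c("x", "y", "z")])
    b <- as.numeric(nodes[nodes$id == edges$to[i], c("x", "y", "z")])
    m <- (a + b) / 2
    nodes <- rbind(nodes, data.frame(id = nid, x = m[1], y = m[2], z = m[3]))
    edges <- rbind(edges, data.frame(id = eid, from = nid, to = edges$to[i],
                                     radius = edges$radius[i] * runif(1, 0.8, 1.2)))
    edges$to[i] <- nid
  }
  ## parallel parent edges (same initial node)
  for (i in sample(nrow(edges), min(2L, nrow(edges)))) {
    eid <- fresh("par")
    edges <- rbind(edges, data.frame(id = eid, from = edges$from[i],
                                     to = edges$to[i],
                                     radius = edges$radius[i] * runif(1, 0.3, 1)))
  }
  ## an extra parent edge into a leaf node (improper loop, acyclic)
  leaf_nodes <- setdiff(edges$to, edges$from)
  if (length(leaf_nodes) >= 2L) {
    v <- sample(leaf_nodes, 1L)
    u <- sample(setdiff(nodes$id, v), 1L)
    edges <- rbind(edges, data.frame(id = fresh("xp"), from = u, to = v,
                                     radius = runif(1, 0.1, 2)))
  }
  ## multifurcation: extra daughters at a random internal node
  internal <- intersect(edges$from, edges$to)
  if (length(internal)) {
    v <- sample(internal, 1L)
    for (j in seq_len(sample(1:2, 1L))) {
      nid <- fresh("ml"); eid <- fresh("md")
      p <- as.numeric(nodes[nodes$id == v, c("x", "y", "z")])
      q <- p + rnorm(3)
      nodes <- rbind(nodes, data.frame(id = nid, x = q[1], y = q[2], z = q[3]))
      edges <- rbind(edges, data.frame(id = eid, from = v, to = nid,
                                       radius = runif(1, 0.1, 1)))
    }
  }
  ## self-loop, isolated node, spurious second root component
  v <- sample(nodes$id, 1L)
  edges <- rbind(edges, data.frame(id = fresh("loop"), from = v, to = v,
                                   radius = 1))
  iso <- fresh("iso")
  nodes <- rbind(nodes, data.frame(id = iso, x = 99, y = 99, z = 99))
  r2 <- fresh("r2"); r2t <- fresh("r2t")
  nodes <- rbind(nodes, data.frame(id = c(r2, r2t), x = c(50, 50),
                                   y = c(0, -5), z = c(0, 0)))
  edges <- rbind(edges, data.frame(id = fresh("r2e"), from = r2, to = r2t,
                                   radius = 0.5))
  raw_vascular_graph(nodes, edges, roots = c(tree$root, r2))
}

## independent leaf pressure-drop recomputation from a tree with radii:
## sum of 8 mu l / (pi r^4) * flow over every root-to-leaf path
oracle_leaf_pressures <- function(tree, mu_cP = 4) {
  ids <- tree$edges$id
  parent <- ids[match(tree$edges$from, tree$edges$to)]
  len <- edge_lengths(tree)
  nleaf <- setNames(rep(0, length(ids)), ids)
  is_leaf <- !(tree$edges$to %in% tree$edges$from)
  ## leaf counts by repeated propagation (naive)
  nleaf[is_leaf] <- 1
  repeat {
    new <- nleaf
    for (i in seq_along(ids)) if (!is_leaf[i]) {
      d <- which(tree$edges$from == tree$edges$to[i])
      new[i] <- sum(nleaf[d])
    }
    if (all(new == nleaf)) break
    nleaf <- new
  }
  Rsi <- ifelse(len == 0, 0,
                8 * (mu_cP * 1e-3) * (len * 1e-3) / (pi * (tree$edges$radius * 1e-3)^4))
  dp <- setNames(numeric(sum(is_leaf)), ids[is_leaf])
  for (l in ids[is_leaf]) {
    e <- l; tot <- 0
    while (!is.na(e)) {
      i <- match(e, ids)
      tot <- tot + nleaf[i] * Rsi[i]
      e <- parent[i]
    }
    dp[l] <- tot
  }
  dp
}

## exhaustive permutation KS p-value (oracle for the path-counting method)
oracle_exact_ks_p <- function(x, y) {
  n0 <- length(x); n1 <- length(y); n <- n0 + n1
  w <- sort(c(x, y))
  last <- which(c(w[-1L] != w[-n], TRUE))
  v <- sort(unique(c(x, y)))
  D <- max(abs(findInterval(v, sort(x)) / n0 - findInterval(v, sort(y)) / n1))
  cmb <- utils::combn(n, n0)
  Dn <- apply(cmb, 2L, function(ix) {
    z <- numeric(n); z[ix] <- 1; cz <- cumsum(z)
    max(abs(cz[last] / n0 - (last - cz[last]) / n1))
  })
  mean(Dn >= D - 1e-12)
}

## random rotation matrix (QR of a Gaussian matrix, det +1)
rand_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

transform_tree <- function(tree, R = diag(3), shift = c(0, 0, 0), scale = 1) {
  P <- as.matrix(tree$nodes[, c("x", "y", "z")])
  P <- scale * P %*% t(R) + matrix(shift, nrow(P), 3, byrow = TRUE)
  tree$nodes$x <- P[, 1L]; tree$nodes$y <- P[, 2L]; tree$nodes$z <- P[, 3L]
  tree
}
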