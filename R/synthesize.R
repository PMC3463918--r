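#' Perfect binary fixture tree
#'
#' A planar perfect binary tree of the given depth: `2^depth` leaves,
#' `2^(depth+1) - 1` edges, radii following the Murray halving of flow
#' (`gamma = 3`, factor `2^(-1/3)` per level).  Useful as an analytically
#' understood fixture: all leaf edges have Strahler* order `depth`.
#'
#' @param depth number of bifurcation levels (0 = single edge).
#' @param edge_length vertical drop per level, mm.
#' @param root_radius radius of the root edge, mm.
#' @return a [vascular_tree()].
#' @export
make_perfect_tree <- function(depth, edge_length = 10, root_radius = 1) {
  stopifnot(depth >= 0)
  nodes <- data.frame(id = "n0", x = 0, y = 0, z = 0,
                      stringsAsFactors = FALSE)
  edges <- data.frame(id = character(), from = character(), to = character(),
                      radius = numeric(), stringsAsFactors = FALSE)
  nid <- 1L
  add_node <- function(x, y, z) {
    id <- paste0("n", nid); nid <<- nid + 1L
    nodes <<- rbind(nodes, data.frame(id = id, x = x, y = y, z = z))
    id
  }
  ## root edge straight down
  tip <- add_node(0, -edge_length, 0)
  edges <- rbind(edges, data.frame(id = "e0", from = "n0", to = tip,
                                   radius = root_radius))
  frontier <- list(list(node = tip, x = 0, level = 1L,
                        radius = root_radius))
  eid <- 1L
  while (length(frontier) && frontier[[1L]]$level <= depth) {
    nxt <- list()
    for (f in frontier) {
      w <- edge_length * 2^(depth - f$level)      # horizontal spread
      r <- f$radius * 2^(-1 / 3)
      for (s in c(-1, 1)) {
        child <- add_node(f$x + s * w, -edge_length * (f$level + 1L), 0)
        edges <- rbind(edges, data.frame(id = paste0("e", eid),
                                         from = f$node, to = child,
                                         radius = r))
        eid <- eid + 1L
        nxt[[length(nxt) + 1L]] <- list(node = child, x = f$x + s * w,
                                        level = f$level + 1L, radius = r)
      }
    }
    frontier <- nxt
  }
  vascular_tree(nodes, edges, "n0")
}

#' Specification of a synthetic tree population
#'
#' Describes a population of random vascular trees emulating a cohort of
#' skeletonised hepatic trees: random strictly binary topologies with leaf
#' counts uniform in `leaf_range`, and per-edge geometry drawn from
#' Strahler*-order-dependent distributions.  Lengths and radii decay
#' geometrically with the order with log-normal noise; bifurcation angles
#' are drawn independently (truncated normal daughter angle `phi_a`,
#' half-normal parent inclination `phi_b` and projection angle `phi_c`)
#' and realised exactly in the constructed geometry.  Because every
#' feature at a given order is drawn i.i.d. across trees, two populations
#' with the same spec differ only by sampling noise.
#'
#' @param n_trees number of trees.
#' @param leaf_range integer range of leaf counts (default `c(150, 350)`,
#'   the range of the clinical trees the generator stands in for).
#' @param length_scale root-edge length scale, mm.
#' @param length_decay multiplicative length decay per Strahler* order.
#' @param length_sdlog log-normal length noise.
#' @param radius_scale root radius scale, mm.
#' @param radius_decay multiplicative radius decay per order.
#' @param radius_sdlog log-normal radius noise.
#' @param phi_a_mean,phi_a_sd daughter-angle distribution, degrees.
#' @param phi_b_scale,phi_c_scale half-normal scales, degrees.
#' @param seed integer seed.
#' @return a list of class `synthetic_population_spec`.
#' @export
synthetic_population_spec <- function(n_trees = 10, leaf_range = c(150, 350),
                                      length_scale = 30, length_decay = 0.55,
                                      length_sdlog = 0.4,
                                      radius_scale = 4, radius_decay = 0.6,
                                      radius_sdlog = 0.25,
                                      phi_a_mean = 100, phi_a_sd = 25,
                                      phi_b_scale = 20, phi_c_scale = 25,
                                      seed = 1L) {
  stopifnot(n_trees >= 1, leaf_range[1L] >= 1, leaf_range[2L] >= leaf_range[1L],
            length_scale > 0, radius_scale > 0,
            length_decay > 0, radius_decay > 0)
  structure(as.list(environment()), class = "synthetic_population_spec")
}

## random strictly binary topology by sequential leaf splitting;
## returns child1/child2 integer vectors (edge indices, 0 = none)
random_topology <- function(n_leaves) {
  child1 <- child2 <- integer(1L)
  leaves <- 1L
  while (length(leaves) < n_leaves) {
    pick <- leaves[sample.int(length(leaves), 1L)]
    i1 <- length(child1) + 1L; i2 <- i1 + 1L
    child1 <- c(child1, 0L, 0L); child2 <- c(child2, 0L, 0L)
    child1[pick] <- i1; child2[pick] <- i2
    leaves <- c(setdiff(leaves, pick), i1, i2)
  }
  list(child1 = child1, child2 = child2)
}

## Strahler orders on a child-array topology (iterative post-order)
topology_strahler <- function(topo) {
  n <- length(topo$child1)
  ord <- integer(n)
  stack <- 1L; state <- integer(n)
  while (length(stack)) {
    e <- stack[length(stack)]
    if (state[e] == 0L) {
      state[e] <- 1L
      if (topo$child1[e] > 0L) stack <- c(stack, topo$child1[e], topo$child2[e])
    } else {
      stack <- stack[-length(stack)]
      if (state[e] == 1L) {
        state[e] <- 2L
        if (topo$child1[e] == 0L) ord[e] <- 1L
        else {
          d <- c(ord[topo$child1[e]], ord[topo$child2[e]])
          ord[e] <- if (d[1L] == d[2L]) d[1L] + 1L else max(d)
        }
      }
    }
  }
  ord
}

rodrigues <- function(v, axis, theta) {
  v * cos(theta) +
    c(axis[2] * v[3] - axis[3] * v[2],
      axis[3] * v[1] - axis[1] * v[3],
      axis[1] * v[2] - axis[2] * v[1]) * sin(theta) +
    axis * sum(axis * v) * (1 - cos(theta))
}

## daughter directions realising (phi_a, phi_b, phi_c) exactly, given the
## unit parent direction (pointing into the bifurcation)
daughter_directions <- function(p, phi_a, phi_b, phi_c, psi, sgn) {
  u0 <- if (abs(p[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  t1 <- unitize(c(u0[2] * p[3] - u0[3] * p[2],
                  u0[3] * p[1] - u0[1] * p[3],
                  u0[1] * p[2] - u0[2] * p[1]))
  t2 <- c(p[2] * t1[3] - p[3] * t1[2],
          p[3] * t1[1] - p[1] * t1[3],
          p[1] * t1[2] - p[2] * t1[1])
  w <- cos(psi) * t1 + sin(psi) * t2
  nrm <- sin(phi_b) * p + cos(phi_b) * w      # unit normal of daughter plane
  proj <- unitize(p - sum(p * nrm) * nrm)
  bis <- rodrigues(proj, nrm, sgn * phi_c)
  list(d1 = rodrigues(bis, nrm, phi_a / 2),
       d2 = rodrigues(bis, nrm, -phi_a / 2))
}

#' Generate a synthetic population of vascular trees
#'
#' Realises a [synthetic_population_spec()]: deterministic given the seed.
#'
#' @param spec a `synthetic_population_spec`.
#' @return list of [vascular_tree()] objects.
#' @export
make_population <- function(spec) {
  stopifnot(inherits(spec, "synthetic_population_spec"))
  with_local_seed(spec$seed, {
    lapply(seq_len(spec$n_trees), function(i) make_synthetic_tree(spec))
  })
}

make_synthetic_tree <- function(spec) {
  n_leaves <- sample.int(spec$leaf_range[2L] - spec$leaf_range[1L] + 1L, 1L) +
    spec$leaf_range[1L] - 1L
  topo <- random_topology(n_leaves)
  n <- length(topo$child1)
  s_star <- topology_strahler(topo)[1L] - topology_strahler(topo)
  deg <- pi / 180
  len <- spec$length_scale * spec$length_decay^s_star *
    exp(rnorm(n, 0, spec$length_sdlog))
  rad <- spec$radius_scale * spec$radius_decay^s_star *
    exp(rnorm(n, 0, spec$radius_sdlog))
  ## pre-order walk assigning directions and positions
  dir <- matrix(NA_real_, n, 3L)
  start <- matrix(NA_real_, n, 3L)
  dir[1L, ] <- c(0, 0, -1); start[1L, ] <- c(0, 0, 0)
  stack <- 1L
  while (length(stack)) {
    e <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (topo$child1[e] == 0L) next
    endp <- start[e, ] + len[e] * dir[e, ]
    phi_a <- min(max(rnorm(1, spec$phi_a_mean, spec$phi_a_sd), 10), 170) * deg
    phi_b <- min(abs(rnorm(1, 0, spec$phi_b_scale)), 80) * deg
    phi_c <- min(abs(rnorm(1, 0, spec$phi_c_scale)), 80) * deg
    psi <- runif(1, 0, 2 * pi)
    sgn <- sample(c(-1, 1), 1L)
    dd <- daughter_directions(dir[e, ], phi_a, phi_b, phi_c, psi, sgn)
    for (cc in c("child1", "child2")) {
      d <- topo[[cc]][e]
      dir[d, ] <- if (cc == "child1") dd$d1 else dd$d2
      start[d, ] <- endp
      stack <- c(stack, d)
    }
  }
  ## assemble node/edge tables: node k = terminal of edge k, plus the root node
  to_id <- paste0("n", seq_len(n))
  endpos <- start + len * dir
  nodes <- data.frame(id = c("root", to_id),
                      x = c(0, endpos[, 1L]),
                      y = c(0, endpos[, 2L]),
                      z = c(0, endpos[, 3L]), stringsAsFactors = FALSE)
  parent <- integer(n)
  for (e in seq_len(n)) {
    for (cc in c("child1", "child2")) {
      d <- topo[[cc]][e]
      if (d > 0L) parent[d] <- e
    }
  }
  from_id <- ifelse(parent == 0L, "root", paste0("n", parent))
  edges <- data.frame(id = paste0("e", seq_len(n)), from = from_id,
                      to = to_id, radius = rad, stringsAsFactors = FALSE)
  vascular_tree(nodes, edges, "root")
}
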