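#' Configuration for Constrained Constructive Optimization
#'
#' Collects every tunable of the tree generator.  The cost of a tree is
#' \deqn{F(T) = \sum_e l(e)\, r(e)^\lambda + C \sum_n \mathrm{dist}^2(n, \mathrm{organ}),}
#' with `lambda = 2` the first term is proportional to intravascular volume.
#' Radii follow the bifurcation-exponent law with `gamma = 3` (Murray's
#' law) and Hagen-Poiseuille rebalancing towards equal leaf exit pressures.
#'
#' @param lambda radius exponent of the cost (default 2.0).
#' @param penalty_C out-of-organ penalty constant, mm^(lambda-1) when
#'   lengths are in mm (default 42).
#' @param gamma bifurcation exponent (default 3, fixed in the algorithm).
#' @param viscosity `"constant"` or `"radius_dependent"` (Fåhræus-Lindqvist
#'   effect via the apparent-viscosity formula, see [viscosity()]).
#' @param mu_inf asymptotic viscosity in cP (default 4.0).
#' @param delta viscosity length parameter in µm (default 4.29).
#' @param root_condition `"fixed_root_radius"` (default; scale taken from
#'   `root_radius` or, when generating from a measured seed tree, its root)
#'   or `"fixed_pressure_drop"` (root radius from `pressure_drop` [Pa] and
#'   `total_flow` [m^3/s]).
#' @param root_radius root radius in mm for the fixed-radius condition.
#' @param pressure_drop,total_flow root boundary condition for the
#'   fixed-pressure mode; defaults 533 Pa (about 4 mmHg) and 1.17e-5 m^3/s
#'   (about 700 mL/min, a resting portal flow).
#' @param n_candidates number of existing edges (nearest midpoints) tried as
#'   connection sites for a new leaf (default 40).
#' @param n_shortlist number of best candidate topologies re-optimized at
#'   the final tolerance (default 20).
#' @param final_tolerance gradient-descent stopping step norm in mm
#'   (default 1e-3); the rough pass stops at its square root.
#' @param armijo_beta,armijo_c1 Armijo backtracking factor and slope
#'   parameter.
#' @param gd_maxit maximal gradient-descent iterations per optimization.
#' @param rebalance_tol,rebalance_maxit fixed-point controls of the radius
#'   rebalancing under radius-dependent viscosity.
#' @param seed integer seed for target sampling done on behalf of the
#'   generator.
#' @return a list of class `cco_config`.
#' @export
cco_config <- function(lambda = 2.0, penalty_C = 42, gamma = 3,
                       viscosity = c("constant", "radius_dependent"),
                       mu_inf = 4.0, delta = 4.29,
                       root_condition = c("fixed_root_radius",
                                          "fixed_pressure_drop"),
                       root_radius = 1.0, pressure_drop = 533,
                       total_flow = 1.17e-5,
                       n_candidates = 40, n_shortlist = 20,
                       final_tolerance = 1e-3,
                       armijo_beta = 0.5, armijo_c1 = 1e-4, gd_maxit = 200,
                       rebalance_tol = 1e-10, rebalance_maxit = 200,
                       seed = 1L) {
  viscosity <- match.arg(viscosity)
  root_condition <- match.arg(root_condition)
  stopifnot(lambda > 0, penalty_C >= 0, n_shortlist <= n_candidates,
            final_tolerance > 0, gamma > 0)
  structure(list(lambda = lambda, penalty_C = penalty_C, gamma = gamma,
                 viscosity = viscosity, mu_inf = mu_inf, delta = delta,
                 root_condition = root_condition, root_radius = root_radius,
                 pressure_drop = pressure_drop, total_flow = total_flow,
                 n_candidates = n_candidates, n_shortlist = n_shortlist,
                 final_tolerance = final_tolerance,
                 armijo_beta = armijo_beta, armijo_c1 = armijo_c1,
                 gd_maxit = gd_maxit, rebalance_tol = rebalance_tol,
                 rebalance_maxit = rebalance_maxit, seed = seed),
            class = "cco_config")
}

## tree -> flat arrays for the C++ core
tree_arrays <- function(tree) {
  ni <- node_lookup(tree)
  list(nodes = node_positions(tree),
       from = as.integer(ni[tree$edges$from]),
       to = as.integer(ni[tree$edges$to]),
       radius = tree$edges$radius,
       root = as.integer(ni[tree$root]))
}

## flat arrays -> tree, reusing original ids and inventing fresh ones for
## appended nodes/edges
arrays_to_tree <- function(arr, tree) {
  n_old <- nrow(tree$nodes); ne_old <- nrow(tree$edges)
  n_new <- nrow(arr$nodes) - n_old
  node_ids <- c(tree$nodes$id,
                if (n_new > 0) fresh_ids(tree$nodes$id, "gn", n_new))
  ne_new <- length(arr$from) - ne_old
  edge_ids <- c(tree$edges$id,
                if (ne_new > 0) fresh_ids(tree$edges$id, "ge", ne_new))
  nodes <- data.frame(id = node_ids, x = arr$nodes[, 1L], y = arr$nodes[, 2L],
                      z = arr$nodes[, 3L], stringsAsFactors = FALSE)
  edges <- data.frame(id = edge_ids, from = node_ids[arr$from],
                      to = node_ids[arr$to], radius = arr$radius,
                      stringsAsFactors = FALSE)
  vascular_tree(nodes, edges, node_ids[arr$root_node])
}

domain_arg <- function(domain) {
  if (is.null(domain)) NULL else domain_cpp_spec(domain)
}

#' Apparent blood viscosity as a function of vessel radius
#'
#' Below about 150 µm the apparent viscosity of blood decreases with the
#' tube radius (Fåhræus-Lindqvist effect).  The model is
#' \eqn{\mu(r) = \mu_\infty (1 + \delta/r)^2} with \eqn{\mu_\infty = 4} cP
#' and \eqn{\delta = 4.29} µm for \eqn{r \le 140} µm (radii below 4 µm are
#' clamped to the 4 µm value), a linear transition to \eqn{\mu_\infty} on
#' [140, 160] µm, and \eqn{\mu_\infty} above.  Continuous everywhere.
#'
#' @param r_um radius in µm (positive).
#' @param config a [cco_config()] (supplies `mu_inf` and `delta`).
#' @return viscosity in cP.
#' @examples
#' viscosity(4.29)   # delta/r = 1, so 4 * mu_inf = 16 cP
#' viscosity(200)    # 4 cP
#' @export
viscosity <- function(r_um, config = cco_config()) {
  as.numeric(cpp_viscosity(as.numeric(r_um), unclass(config)))
}

#' Hagen-Poiseuille flow resistance of a cylindrical edge
#'
#' \eqn{R = 8 \mu l / (\pi r^4)} in SI units (Pa s / m^3); geometry is given
#' in mm, viscosity is evaluated by the configured model.  Zero-length
#' (trivial) edges have zero resistance.
#'
#' @param l length in mm.
#' @param r radius in mm.
#' @param config a [cco_config()].
#' @return resistance in Pa s m^-3.
#' @export
edge_resistance <- function(l, r, config = cco_config()) {
  stopifnot(length(l) == length(r) || length(l) == 1L || length(r) == 1L)
  out <- numeric(max(length(l), length(r)))
  l <- rep_len(l, length(out)); r <- rep_len(r, length(out))
  if (any(r <= 0 & l > 0)) stop("nonpositive radius on an edge of positive length")
  mu_cP <- ifelse(config$viscosity == "constant", config$mu_inf,
                  viscosity(pmax(r, 1e-12) * 1e3, config))
  ifelse(l == 0, 0, 8 * (mu_cP * 1e-3) * (l * 1e-3) / (pi * (r * 1e-3)^4))
}

#' Rebalance the radii of a vascular tree
#'
#' Assigns radii so that (a) at every bifurcation the daughter radius
#' fractions satisfy the bifurcation-exponent law
#' \eqn{\beta_1^\gamma + \beta_2^\gamma = 1}, (b) every leaf receives the
#' same flow, and (c) the pressure drop from the root to every leaf is
#' equal (Hagen-Poiseuille resistances).  With constant viscosity a single
#' leaf-to-root resistance accumulation followed by a root-to-leaf radius
#' propagation is exact; with radius-dependent viscosity the two sweeps are
#' iterated to a fixed point (relative radius change below
#' `rebalance_tol`).  The absolute scale comes from the root condition.
#'
#' @param tree a [vascular_tree()] with positive lengths on flow-carrying
#'   edges.
#' @param config a [cco_config()].
#' @return list of class `flow_state`: `tree` (radii updated), `flow`
#'   (per-edge flow in leaf units, or m^3/s in fixed-pressure mode),
#'   `resistance` (Pa s m^-3), `leafcount`, `leaf_pressure_drop` (named by
#'   leaf edge id), `iterations`.
#' @export
rebalance_radii <- function(tree, config = cco_config()) {
  arr <- tree_arrays(tree)
  res <- cpp_rebalance(arr$nodes, arr$from, arr$to, arr$radius, arr$root,
                       unclass(config))
  tree$edges$radius <- res$radius
  structure(list(tree = tree, flow = setNames(res$flow, tree$edges$id),
                 resistance = setNames(res$resistance, tree$edges$id),
                 leafcount = setNames(res$leafcount, tree$edges$id),
                 leaf_pressure_drop = setNames(res$leaf_pressure_drop,
                                               tree$edges$id[res$leaf_edge]),
                 iterations = res$iterations),
            class = "flow_state")
}

#' Generation cost of a tree
#'
#' \eqn{F(T) = \sum_e l(e) r(e)^\lambda + C \sum_n \mathrm{dist}^2(n,
#' \mathrm{organ})}.  Radii are used as stored; call [rebalance_radii()]
#' first if they are stale.
#'
#' @param tree a [vascular_tree()].
#' @param domain an [organ_domain] or `NULL` (no penalty term).
#' @param config a [cco_config()].
#' @return the cost (mm^(lambda+1) for the volume-like term).
#' @export
tree_cost <- function(tree, domain = NULL, config = cco_config()) {
  arr <- tree_arrays(tree)
  cpp_tree_cost(arr$nodes, arr$from, arr$to, arr$radius, arr$root,
                unclass(config), domain_arg(domain))
}

#' Candidate connection edges for a new leaf
#'
#' The `k` edges whose midpoints are closest to the new point, ties broken
#' by edge id; `k` is truncated to the number of edges.
#'
#' @param tree a [vascular_tree()].
#' @param new_point 3-vector, mm.
#' @param k number of candidates (default 40).
#' @return character vector of edge ids, nearest first.
#' @export
candidate_edges <- function(tree, new_point, k = 40) {
  ni <- node_lookup(tree); P <- node_positions(tree)
  mid <- (P[ni[tree$edges$from], , drop = FALSE] +
            P[ni[tree$edges$to], , drop = FALSE]) / 2
  d2 <- rowSums((mid - matrix(new_point, nrow(mid), 3L, byrow = TRUE))^2)
  ord <- order(d2, tree$edges$id)
  tree$edges$id[head(ord, min(k, length(ord)))]
}

#' Optimize the position of a new bifurcation
#'
#' Temporarily splits `target_edge` with a bifurcation connecting
#' `new_leaf`, then minimises the tree cost over the bifurcation position
#' by gradient descent (central-difference gradients) with Armijo
#' backtracking.  Radii are fully rebalanced at every cost evaluation;
#' skipping that mid-optimization produces considerably different results.
#'
#' @param tree a [vascular_tree()].
#' @param target_edge edge id to split.
#' @param new_leaf 3-vector: position of the new leaf, mm.
#' @param tolerance stopping step norm, mm (default the configured final
#'   tolerance).
#' @param config a [cco_config()].
#' @param domain optional [organ_domain] for the penalty term.
#' @param start optional starting position (default: edge midpoint).
#' @return list with `position` (3-vector) and `cost`.
#' @export
optimize_bifurcation <- function(tree, target_edge, new_leaf,
                                 tolerance = NULL, config = cco_config(),
                                 domain = NULL, start = NULL) {
  arr <- tree_arrays(tree)
  ei <- match(target_edge, tree$edges$id)
  if (is.na(ei)) stop("unknown edge id: ", target_edge)
  if (is.null(tolerance)) tolerance <- config$final_tolerance
  if (is.null(start))
    start <- (arr$nodes[arr$from[ei], ] + arr$nodes[arr$to[ei], ]) / 2
  res <- cpp_optimize_bifurcation(arr$nodes, arr$from, arr$to, arr$radius,
                                  arr$root, ei, as.numeric(new_leaf),
                                  as.numeric(start), tolerance,
                                  unclass(config), domain_arg(domain))
  list(position = as.numeric(res$position), cost = res$cost)
}

#' Cost of a tree with a tentative bifurcation at a given position
#'
#' Splits `target_edge` with a bifurcation at `position` connecting
#' `new_leaf`, rebalances all radii and returns the resulting tree cost
#' without any optimization.  Useful for inspecting the cost landscape the
#' optimizer works on (e.g. grid searches).
#'
#' @inheritParams optimize_bifurcation
#' @param position 3-vector: bifurcation position to evaluate, mm.
#' @return the tree cost at that position.
#' @export
bifurcation_cost <- function(tree, target_edge, new_leaf, position,
                             config = cco_config(), domain = NULL) {
  config$gd_maxit <- 0L
  optimize_bifurcation(tree, target_edge, new_leaf,
                       tolerance = config$final_tolerance, config = config,
                       domain = domain, start = position)$cost
}

#' Add one leaf to a tree by Constrained Constructive Optimization
#'
#' Tries the `n_candidates` nearest edges as connection sites, optimizes
#' each temporary bifurcation at the rough tolerance (square root of the
#' final tolerance), re-optimizes the `n_shortlist` best at the final
#' tolerance, and commits the cheapest connection.  The result has exactly
#' one more leaf and two more edges, radii rebalanced.
#'
#' @inheritParams optimize_bifurcation
#' @param new_point position of the new leaf, mm.
#' @return the extended [vascular_tree()], with an `audit` attribute
#'   recording the chosen edge, the committed cost and the shortlist costs.
#' @export
add_leaf <- function(tree, new_point, config = cco_config(), domain = NULL) {
  arr <- tree_arrays(tree)
  res <- cpp_add_leaf(arr$nodes, arr$from, arr$to, arr$radius, arr$root,
                      as.numeric(new_point), unclass(config),
                      domain_arg(domain))
  out <- arrays_to_tree(res$tree, tree)
  a <- res$audit
  a$edge <- tree$edges$id[a$edge]
  attr(out, "audit") <- a
  out
}

#' Generate or extend a vascular tree by CCO
#'
#' Adds the given leaf targets one at a time (in sampling order), each time
#' committing the locally optimal new bifurcation (see [add_leaf()]).
#' Deterministic given the targets and configuration.
#'
#' @param seed_tree a valid [vascular_tree()]; may be a single root edge
#'   (see [make_root_seed()]).
#' @param domain an [organ_domain] or `NULL`.
#' @param leaf_targets a [sample_leaf_targets()] result or an n x 3 matrix.
#' @param config a [cco_config()].
#' @return the generated [vascular_tree()] with an `audit` attribute: one
#'   record per insertion (chosen edge id, committed cost, shortlist
#'   costs).
#' @export
generate_tree <- function(seed_tree, domain = NULL, leaf_targets,
                          config = cco_config()) {
  pts <- if (inherits(leaf_targets, "leaf_target_set")) leaf_targets$points
         else as_points_matrix(leaf_targets)
  if (!nrow(pts)) return(seed_tree)
  arr <- tree_arrays(seed_tree)
  res <- cpp_generate(arr$nodes, arr$from, arr$to, arr$radius, arr$root,
                      pts, unclass(config), domain_arg(domain))
  out <- arrays_to_tree(res$tree, seed_tree)
  ## map chosen edge indices (at insertion time) to final edge ids
  audit <- lapply(seq_along(res$audit), function(i) {
    a <- res$audit[[i]]
    a$edge <- out$edges$id[a$edge]
    a
  })
  attr(out, "audit") <- audit
  out
}

#' Single-root-edge seed tree
#'
#' Convenience builder for generating a tree from scratch: one root edge
#' from `root_pos` to `tip_pos` with the given radius.
#'
#' @param root_pos,tip_pos 3-vectors, mm.
#' @param radius mm.
#' @return a [vascular_tree()] with one edge.
#' @export
make_root_seed <- function(root_pos, tip_pos, radius = 1) {
  vascular_tree(
    nodes = data.frame(id = c("root", "tip"),
                       x = c(root_pos[1], tip_pos[1]),
                       y = c(root_pos[2], tip_pos[2]),
                       z = c(root_pos[3], tip_pos[3])),
    edges = data.frame(id = "e0", from = "root", to = "tip", radius = radius),
    root = "root")
}
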