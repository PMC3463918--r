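#' Contract very short edges to length zero
#'
#' Edges shorter than `threshold` are contracted: the terminal node is
#' moved onto the initial (parent-side) node and the edge becomes a trivial
#' (zero-length) bookkeeping edge.  Contraction cascades until stable:
#' moving a node may shorten its daughter edges below the threshold.
#' Downstream features involving contracted edges become undefined and are
#' ignored by the analysis.
#'
#' @param tree a [vascular_tree()].
#' @param threshold length threshold in mm (default 0.1).
#' @return the tree with contracted edges flagged `trivial`.
#' @export
contract_short_edges <- function(tree, threshold = 0.1) {
  stopifnot(threshold >= 0)
  ni <- node_lookup(tree)
  pre <- rev(postorder_edges(tree))   # parents before daughters
  repeat {
    changed <- FALSE
    P <- node_positions(tree)
    for (e in pre) {
      i <- ni[tree$edges$from[e]]; j <- ni[tree$edges$to[e]]
      len <- sqrt(sum((P[i, ] - P[j, ])^2))
      if (tree$edges$trivial[e] || len < threshold) {
        if (len > 0) {
          P[j, ] <- P[i, ]
          changed <- TRUE
        }
        if (!tree$edges$trivial[e]) { tree$edges$trivial[e] <- TRUE; changed <- TRUE }
      }
    }
    tree$nodes$x <- P[, 1L]; tree$nodes$y <- P[, 2L]; tree$nodes$z <- P[, 3L]
    if (!changed) break
  }
  tree
}

#' Prune a tree to its coarse anatomy
#'
#' Keeps the root edge and, recursively, every daughter edge whose initial
#' node lies outside the organ (measured vascular trees enter the organ
#' from outside the segmented mask) or whose radius exceeds 0.25 times the
#' maximum radius of the tree.  The recursion stops at the first failing
#' edge; the pruned result is re-corrected (monofurcations introduced by
#' one-sided pruning are merged).
#'
#' @param tree a [vascular_tree()].
#' @param domain an [organ_domain].
#' @param radius_fraction threshold fraction of the maximum radius
#'   (default 0.25, strict `>`).
#' @return the pruned, re-corrected [vascular_tree()].
#' @export
prune_to_coarse <- function(tree, domain, radius_fraction = 0.25) {
  rmax <- max(tree$edges$radius)
  ch <- edge_children(tree)
  ni <- node_lookup(tree); P <- node_positions(tree)
  keep <- logical(nrow(tree$edges))
  re <- root_edge_index(tree)
  keep[re] <- TRUE
  frontier <- re
  while (length(frontier)) {
    nxt <- integer()
    for (e in frontier) for (d in ch[[e]]) {
      p0 <- P[ni[tree$edges$from[d]], ]
      ok <- !domain_inside(domain, p0) ||
        tree$edges$radius[d] > radius_fraction * rmax
      if (ok) { keep[d] <- TRUE; nxt <- c(nxt, d) }
    }
    frontier <- nxt
  }
  sub_edges <- tree$edges[keep, , drop = FALSE]
  sub_nodes <- tree$nodes[tree$nodes$id %in%
                            c(tree$root, sub_edges$from, sub_edges$to), ,
                          drop = FALSE]
  correct_graph(raw_vascular_graph(sub_nodes, sub_edges, tree$root))$tree
}

#' Remove one bifurcation level of leaf edges
#'
#' Prunes every leaf edge of the tree (the generated leaf nodes plus any
#' remaining leaves of the coarse seed tree), then re-corrects the
#' resulting monofurcations.  This emulates the limited resolution of
#' clinical CT data, which misses the finest bifurcation level.  Repeated
#' calls keep shrinking the tree by one level.
#'
#' @param tree a [vascular_tree()].
#' @return the pruned, re-corrected [vascular_tree()].
#' @export
prune_leaf_level <- function(tree) {
  lv <- leaf_edges(tree)
  if (length(lv) >= nrow(tree$edges))
    stop("pruning all leaf edges would leave an empty tree")
  sub_edges <- tree$edges[-lv, , drop = FALSE]
  sub_nodes <- tree$nodes[tree$nodes$id %in%
                            c(tree$root, sub_edges$from, sub_edges$to), ,
                          drop = FALSE]
  correct_graph(raw_vascular_graph(sub_nodes, sub_edges, tree$root))$tree
}

#' Shift bifurcation points along the daughter-angle bisector
#'
#' Moves every bifurcation point by `fraction` times the mean daughter
#' edge length along the unit bisector of the two daughter directions
#' (away from the parent, towards the daughters), which widens the angle
#' between the daughters.  Daughter endpoints and all radii are unchanged;
#' radii are deliberately not rebalanced afterwards.  All displacements are
#' computed from the input geometry and applied simultaneously.
#' Bifurcations with a zero-length daughter or antiparallel daughters
#' (undefined bisector) are skipped.
#'
#' @param tree a [vascular_tree()].
#' @param fraction shift fraction (default 0.09, calibrated so generated
#'   daughter angles match measured hepatic trees on average).
#' @return the shifted [vascular_tree()]; attribute `skipped` lists edge
#'   ids of skipped bifurcations.
#' @export
bisector_shift <- function(tree, fraction = 0.09) {
  ch <- edge_children(tree)
  ni <- node_lookup(tree); P <- node_positions(tree)
  newP <- P
  skipped <- character()
  for (e in seq_len(nrow(tree$edges))) {
    d <- ch[[e]]
    if (length(d) != 2L) next
    b <- ni[tree$edges$to[e]]          # the bifurcation point
    t1 <- ni[tree$edges$to[d[1L]]]; t2 <- ni[tree$edges$to[d[2L]]]
    v1 <- P[t1, ] - P[b, ]; v2 <- P[t2, ] - P[b, ]
    l1 <- vnorm(v1); l2 <- vnorm(v2)
    if (l1 == 0 || l2 == 0) { skipped <- c(skipped, tree$edges$id[e]); next }
    bis <- unitize(v1 / l1 + v2 / l2)
    if (is.null(bis)) { skipped <- c(skipped, tree$edges$id[e]); next }
    newP[b, ] <- P[b, ] + fraction * mean(c(l1, l2)) * bis
  }
  tree$nodes$x <- newP[, 1L]; tree$nodes$y <- newP[, 2L]; tree$nodes$z <- newP[, 3L]
  attr(tree, "skipped") <- skipped
  tree
}

#' Distance from a point to a (solid) triangle
#'
#' Closest-point computation on the filled triangle `(a, b, c)`.
#'
#' @param p,a,b,c 3-vectors.
#' @return list with `distance`, `closest` (3-vector) and `normal` (unit
#'   normal of the triangle plane, or `NULL` if degenerate).
#' @export
point_triangle_distance <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  n <- c(ab[2] * ac[3] - ab[3] * ac[2],
         ab[3] * ac[1] - ab[1] * ac[3],
         ab[1] * ac[2] - ab[2] * ac[1])
  nn <- unitize(n)
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(ptd_out(p, a, nn))
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(ptd_out(p, b, nn))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    v <- d1 / (d1 - d3)
    return(ptd_out(p, a + v * ab, nn))
  }
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(ptd_out(p, c, nn))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    w <- d2 / (d2 - d6)
    return(ptd_out(p, a + w * ac, nn))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(ptd_out(p, b + w * (c - b), nn))
  }
  denom <- va + vb + vc
  v <- vb / denom; w <- vc / denom
  ptd_out(p, a + v * ab + w * ac, nn)
}

ptd_out <- function(p, q, nn) {
  list(distance = vnorm(p - q), closest = q, normal = nn)
}

## triangle of a bifurcation: (initial node of the parent edge, terminal
## nodes of the daughters); returns NULL for non-bifurcations
bifurcation_triangle <- function(tree, e, ch, ni, P) {
  d <- ch[[e]]
  if (length(d) != 2L) return(NULL)
  list(a = P[ni[tree$edges$from[e]], ],
       b = P[ni[tree$edges$to[d[1L]]], ],
       c = P[ni[tree$edges$to[d[2L]]], ],
       bnode = ni[tree$edges$to[e]])
}

triangle_degenerate <- function(tr) {
  ab <- tr$b - tr$a; ac <- tr$c - tr$a
  n <- c(ab[2] * ac[3] - ab[3] * ac[2],
         ab[3] * ac[1] - ab[1] * ac[3],
         ab[1] * ac[2] - ab[2] * ac[1])
  L <- max(vnorm(tr$b - tr$a), vnorm(tr$c - tr$a), vnorm(tr$c - tr$b))
  L == 0 || vnorm(n) < 1e-12 * L^2
}

triangle_longest_side <- function(tr) {
  max(vnorm(tr$b - tr$a), vnorm(tr$c - tr$a), vnorm(tr$c - tr$b))
}

#' Nonflatness of the bifurcations of a tree
#'
#' For each bifurcation, the triangle spanned by the initial node of the
#' parent edge and the terminal nodes of the two daughter edges is
#' considered.  Nonflatness is the Euclidean distance of the bifurcation
#' point from this (solid) triangle, divided by the triangle's longest
#' side; it is 0 for flat bifurcations and undefined (`NA`) for degenerate
#' (collinear) triangles.
#'
#' @param tree a [vascular_tree()].
#' @return named numeric vector (by parent edge id), one entry per
#'   bifurcation; `NA` where degenerate.
#' @export
nonflatness <- function(tree) {
  ch <- edge_children(tree)
  ni <- node_lookup(tree); P <- node_positions(tree)
  idx <- which(lengths(ch) == 2L)
  out <- setNames(rep(NA_real_, length(idx)), tree$edges$id[idx])
  for (k in seq_along(idx)) {
    tr <- bifurcation_triangle(tree, idx[k], ch, ni, P)
    if (triangle_degenerate(tr)) next
    ptd <- point_triangle_distance(P[tr$bnode, ], tr$a, tr$b, tr$c)
    out[k] <- ptd$distance / triangle_longest_side(tr)
  }
  out
}

#' Empirical nonflatness distribution
#'
#' Wraps a sample of nonflatness ratios for use by
#' [nonflatness_adjust()].  Measured distributions can be loaded from a
#' one-column CSV; `synthetic_nonflatness_distribution()` provides a
#' clearly labelled synthetic default (half-normal), useful when no
#' measured distribution is available.
#'
#' @param values numeric vector of nonflatness ratios (all >= 0).
#' @param source label describing the provenance of the sample.
#' @return object of class `nonflatness_distribution`.
#' @export
nonflatness_distribution <- function(values, source = "user") {
  values <- as.numeric(values)
  if (!length(values) || any(!is.finite(values)) || any(values < 0))
    stop("nonflatness values must be finite and >= 0")
  structure(list(values = values, source = source),
            class = "nonflatness_distribution")
}

#' @rdname nonflatness_distribution
#' @param n sample size.
#' @param scale half-normal scale parameter.
#' @param seed integer seed.
#' @export
synthetic_nonflatness_distribution <- function(n = 1000, scale = 0.05,
                                               seed = 1L) {
  vals <- with_local_seed(seed, abs(rnorm(n, 0, scale)))
  nonflatness_distribution(vals, source = "synthetic half-normal")
}

#' @rdname nonflatness_distribution
#' @param path one-column CSV file of ratios.
#' @export
read_nonflatness_csv <- function(path) {
  v <- utils::read.csv(path)[[1L]]
  nonflatness_distribution(v, source = path)
}

#' Impose a nonflatness distribution on the bifurcations of a tree
#'
#' Draws one target ratio per bifurcation from the empirical distribution
#' (seeded inverse-CDF sampling) and moves each bifurcation point purely
#' along the normal of its triangle (random seeded sign) so that its
#' nonflatness equals the drawn target.  When the in-plane projection of a
#' bifurcation point falls inside its triangle (the typical geometry) the
#' purely normal move hits the target exactly and the in-plane position is
#' untouched — in particular, flat bifurcations stay flat under a zero
#' target.  Where the residual in-plane distance already exceeds the
#' target, the smallest move achieving it is used instead (along the line
#' towards the triangle's closest point).  Because the
#' triangle of one bifurcation involves neighbouring bifurcation points,
#' the assignment is iterated (Gauss-Seidel over the tree) until the
#' geometry settles.  Applied uniformly over the tree, not per Strahler*
#' order; radii are unchanged.  Degenerate triangles are skipped.
#'
#' @param tree a [vascular_tree()].
#' @param distribution a [nonflatness_distribution()].
#' @param seed integer seed for the draws.
#' @param tol convergence tolerance on the largest bifurcation displacement
#'   per sweep, mm (default 1e-12).
#' @param maxit maximal sweeps (default 1000; deep trees can need several
#'   hundred sweeps before the coupled moves settle).
#' @return the adjusted [vascular_tree()]; attributes `targets` (named by
#'   parent edge id), `skipped` (degenerate triangles) and `unreached`
#'   (targets that did not settle to 1e-9, normally empty).
#' @export
nonflatness_adjust <- function(tree, distribution, seed = 1L,
                               tol = 1e-12, maxit = 1000) {
  stopifnot(inherits(distribution, "nonflatness_distribution"))
  ch <- edge_children(tree)
  ni <- node_lookup(tree)
  idx <- which(lengths(ch) == 2L)
  vals <- sort(distribution$values)
  draws <- with_local_seed(seed, {
    u <- runif(length(idx))
    s <- sample(c(-1, 1), length(idx), replace = TRUE)
    list(target = vals[pmax(1L, ceiling(u * length(vals)))], sign = s)
  })
  P <- node_positions(tree)
  skipped <- character()
  first <- TRUE
  for (sweep in seq_len(maxit)) {
    delta <- 0
    for (k in seq_along(idx)) {
      e <- idx[k]
      tr <- bifurcation_triangle(tree, e, ch, ni, P)
      if (triangle_degenerate(tr)) {
        if (first) skipped <- c(skipped, tree$edges$id[e])
        next
      }
      L <- triangle_longest_side(tr)
      ptd <- point_triangle_distance(P[tr$bnode, ], tr$a, tr$b, tr$c)
      o0 <- sum((P[tr$bnode, ] - ptd$closest) * ptd$normal)
      d_ip2 <- max(ptd$distance^2 - o0^2, 0)
      tL <- draws$target[k] * L
      if (tL^2 >= d_ip2) {
        ## reachable by a purely normal move
        o_new <- draws$sign[k] * sqrt(tL^2 - d_ip2)
        target_pos <- P[tr$bnode, ] + (o_new - o0) * ptd$normal
      } else {
        ## smallest move achieving the target: along the ray from the
        ## closest triangle point through the current position
        u <- unitize(P[tr$bnode, ] - ptd$closest)
        target_pos <- ptd$closest + tL * u
      }
      delta <- max(delta, vnorm(target_pos - P[tr$bnode, ]))
      P[tr$bnode, ] <- target_pos
    }
    first <- FALSE
    if (delta < tol) break
  }
  tree$nodes$x <- P[, 1L]; tree$nodes$y <- P[, 2L]; tree$nodes$z <- P[, 3L]
  targets <- setNames(draws$target, tree$edges$id[idx])
  attr(tree, "targets") <- targets
  attr(tree, "skipped") <- skipped
  achieved <- nonflatness(tree)[names(targets)]
  miss <- abs(achieved - targets) > 1e-9 & !is.na(achieved)
  attr(tree, "unreached") <- setdiff(names(targets)[miss], skipped)
  tree
}

#' Intravascular volume of a tree
#'
#' \eqn{\sum_e \pi r(e)^2 l(e)} in mm^3.
#'
#' @param tree a [vascular_tree()].
#' @return volume in mm^3.
#' @export
tree_volume <- function(tree) {
  sum(pi * tree$edges$radius^2 * edge_lengths(tree))
}
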