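## vector helpers --------------------------------------------------------------

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-300) return(NULL)
  v / n
}

angle_between <- function(u, v) {
  ## numerically safe angle via atan2(|u x v|, u.v)
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  atan2(vnorm(cr), sum(u * v))
}

#' Bifurcation angles
#'
#' A bifurcation is fully described by three angles defined in the canonical
#' frame in which the two daughter edges lie in the xy-plane with their
#' angle bisector along the +x axis: `phi_a` is the angle between the two
#' daughter edges, `phi_b` the (unsigned) inclination of the parent edge to
#' the daughter plane, and `phi_c` the angle between the xy-projection of
#' the parent edge and the bisector.  The parent direction points along the
#' flow into the bifurcation, so a straight pass-through yields
#' `phi_c = 0`.  All results are independent of the daughter labelling and
#' of rigid motions.
#'
#' @param parent_dir 3-vector: direction of the parent edge, pointing into
#'   the bifurcation (terminal minus initial node of the parent edge).
#' @param d1_dir,d2_dir 3-vectors: daughter directions, pointing away from
#'   the bifurcation.
#' @param degrees report angles in degrees (default) or radians.
#' @return named numeric vector `c(phi_a, phi_b, phi_c)`; entries are `NA`
#'   where undefined (zero-length direction, or `phi_c` for antiparallel
#'   daughters / a parent perpendicular to the daughter plane).
#' @examples
#' bifurcation_angles(c(1, 0, 0), c(1, 1, 0), c(1, -1, 0))  # 90, 0, 0
#' @export
bifurcation_angles <- function(parent_dir, d1_dir, d2_dir, degrees = TRUE) {
  und <- c(phi_a = NA_real_, phi_b = NA_real_, phi_c = NA_real_)
  p <- unitize(parent_dir); u1 <- unitize(d1_dir); u2 <- unitize(d2_dir)
  if (is.null(p) || is.null(u1) || is.null(u2)) return(und)
  phi_a <- angle_between(u1, u2)
  out <- und
  out["phi_a"] <- phi_a
  ## plane of the daughters: normal u1 x u2; undefined if (anti)parallel
  n <- c(u1[2] * u2[3] - u1[3] * u2[2],
         u1[3] * u2[1] - u1[1] * u2[3],
         u1[1] * u2[2] - u1[2] * u2[1])
  nn <- unitize(n)
  bis <- unitize(u1 + u2)
  if (!is.null(nn)) {
    s <- sum(p * nn)                     # sine of the inclination
    out["phi_b"] <- asin(min(1, abs(s)))
    proj <- p - s * nn
    pp <- unitize(proj)
    if (!is.null(pp) && !is.null(bis) && vnorm(proj) > 1e-12)
      out["phi_c"] <- angle_between(pp, bis)
  }
  if (degrees) out <- out * 180 / pi
  out
}

#' Bifurcation exponent
#'
#' The bifurcation exponent \eqn{\gamma} of a bifurcation with parent radius
#' \eqn{r_p} and daughter radii \eqn{r_1, r_2} is the unique root of
#' \eqn{r_1^\gamma + r_2^\gamma = r_p^\gamma}.  Murray's law corresponds to
#' \eqn{\gamma = 3}, the optimal trade-off between pumping power and
#' metabolic vessel maintenance under laminar Poiseuille flow.  A positive
#' root exists only when the parent radius exceeds the larger daughter
#' radius; otherwise (and for nonpositive radii) the value is undefined and
#' excluded from downstream statistics.
#'
#' @param r_p,r_1,r_2 radii in consistent units (mm).
#' @param tol bisection tolerance on gamma (default 1e-10).
#' @return the exponent, or `NA` when undefined.  The root is sought in
#'   `[1e-3, 50]`; measured hepatic distributions lie well inside.
#' @examples
#' bifurcation_exponent(2^(1/3), 1, 1)  # Murray's law: 3
#' bifurcation_exponent(2, 1, 1)        # 1
#' @export
bifurcation_exponent <- function(r_p, r_1, r_2, tol = 1e-10) {
  if (any(!is.finite(c(r_p, r_1, r_2))) || r_p <= 0 || r_1 <= 0 || r_2 <= 0)
    return(NA_real_)
  if (r_p <= max(r_1, r_2)) return(NA_real_)
  a <- r_1 / r_p; b <- r_2 / r_p     # both in (0, 1)
  f <- function(g) a^g + b^g - 1     # strictly decreasing in g
  lo <- 1e-3; hi <- 50
  if (f(lo) < 0 || f(hi) > 0) return(NA_real_)
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

#' Per-edge geometric feature table
#'
#' Computes, for every edge of a corrected tree, its Strahler* order and the
#' ten geometric features used in the similarity analysis: radius `r` and
#' length `l`; the decrease ratios `eta_r` (parent radius / own radius) and
#' `eta_l`; the asymmetry ratios `sigma_r` and `sigma_l` (larger daughter
#' value / smaller daughter value, at nonterminal edges); the bifurcation
#' exponent `gamma`; and the bifurcation angles `phi_a`, `phi_b`, `phi_c`
#' (degrees).  Exponent and angles are attached to the parent edge of the
#' bifurcation.  A feature that cannot be computed at an edge (root edge for
#' `eta`, terminal edges for `sigma`/`gamma`/angles, zero lengths or radii,
#' no positive root for `gamma`) is `NA` and is excluded from any downstream
#' statistic, so the number of bifurcations actually contributing may differ
#' between features.
#'
#' @param tree a [vascular_tree()].
#' @return data frame of class `feature_table`, one row per edge, with
#'   columns `edge`, `s_star`, `trivial`, `r`, `l`, `eta_r`, `sigma_r`,
#'   `eta_l`, `sigma_l`, `gamma`, `phi_a`, `phi_b`, `phi_c`.
#' @export
feature_table <- function(tree) {
  stopifnot(inherits(tree, "vascular_tree"))
  ne <- nrow(tree$edges)
  ss <- strahler_star_orders(tree)
  len <- edge_lengths(tree)
  rad <- tree$edges$radius
  par <- edge_parents(tree)
  ch <- edge_children(tree)
  ni <- node_lookup(tree)
  P <- node_positions(tree)

  eta_r <- eta_l <- sigma_r <- sigma_l <- gam <- rep(NA_real_, ne)
  phi <- matrix(NA_real_, ne, 3L,
                dimnames = list(NULL, c("phi_a", "phi_b", "phi_c")))
  for (i in seq_len(ne)) {
    p <- par[i]
    if (!is.na(p)) {
      if (rad[i] > 0) eta_r[i] <- rad[p] / rad[i]
      if (len[i] > 0) eta_l[i] <- len[p] / len[i]
    }
    d <- ch[[i]]
    if (length(d) == 2L) {
      rd <- rad[d]; ld <- len[d]
      if (min(rd) > 0) sigma_r[i] <- max(rd) / min(rd)
      if (min(ld) > 0) sigma_l[i] <- max(ld) / min(ld)
      gam[i] <- bifurcation_exponent(rad[i], rd[1L], rd[2L])
      if (len[i] > 0 && all(ld > 0)) {
        pdir <- P[ni[tree$edges$to[i]], ] - P[ni[tree$edges$from[i]], ]
        d1 <- P[ni[tree$edges$to[d[1L]]], ] - P[ni[tree$edges$from[d[1L]]], ]
        d2 <- P[ni[tree$edges$to[d[2L]]], ] - P[ni[tree$edges$from[d[2L]]], ]
        phi[i, ] <- bifurcation_angles(pdir, d1, d2)
      }
    }
  }
  out <- data.frame(edge = tree$edges$id, s_star = as.integer(ss),
                    trivial = len == 0, r = rad, l = len,
                    eta_r = eta_r, sigma_r = sigma_r,
                    eta_l = eta_l, sigma_l = sigma_l, gamma = gam,
                    phi_a = phi[, 1L], phi_b = phi[, 2L], phi_c = phi[, 3L],
                    stringsAsFactors = FALSE)
  class(out) <- c("feature_table", "data.frame")
  out
}

## canonical feature names and groups used throughout the similarity analysis
vt_features <- function() c("r", "eta_r", "sigma_r", "gamma",
                            "l", "eta_l", "sigma_l",
                            "phi_a", "phi_b", "phi_c")

vt_feature_groups <- function() list(
  radius = c("r", "eta_r", "sigma_r", "gamma"),
  length = c("l", "eta_l", "sigma_l"),
  angle  = c("phi_a", "phi_b", "phi_c"))
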