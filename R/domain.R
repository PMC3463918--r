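#' Organ domains
#'
#' An organ domain supplies the inside test, the unsigned distance to the
#' organ (0 for interior points) that drives the out-of-organ penalty of the
#' generation cost, and a bounding box for pseudorandom leaf-target
#' sampling.  Analytic domains are compositions of spheres, ellipsoids and
#' axis-aligned boxes under union, intersection and difference; voxel
#' domains are binary masks with a precomputed Euclidean distance field.
#' All coordinates are world coordinates in mm.
#'
#' Distances to spheres and boxes are exact; the ellipsoid distance is exact
#' for exterior points (iterative closest-point solve) and a smooth
#' standard approximation inside; composite shapes use the usual
#' signed-distance-field estimates (`min` for union, `max` for
#' intersection, `max(a, -b)` for difference), which have the exact zero
#' set and interior test but may underestimate the exterior distance near
#' carved-out regions.
#'
#' @param center 3-vector, mm.
#' @param radius,radii sphere radius / ellipsoid semi-axes, mm.
#' @param lower,upper opposite corners of a box, mm.
#' @param a,b two `organ_domain` objects to combine.
#' @return an object of class `organ_domain`.
#' @name organ_domain
NULL

#' @rdname organ_domain
#' @export
domain_sphere <- function(center, radius) {
  stopifnot(length(center) == 3L, radius > 0)
  structure(list(kind = "analytic",
                 node = list(type = "sphere", center = as.numeric(center),
                             radius = as.numeric(radius))),
            class = "organ_domain")
}

#' @rdname organ_domain
#' @export
domain_ellipsoid <- function(center, radii) {
  stopifnot(length(center) == 3L, length(radii) == 3L, all(radii > 0))
  structure(list(kind = "analytic",
                 node = list(type = "ellipsoid", center = as.numeric(center),
                             radii = as.numeric(radii))),
            class = "organ_domain")
}

#' @rdname organ_domain
#' @export
domain_box <- function(lower, upper) {
  stopifnot(length(lower) == 3L, length(upper) == 3L, all(upper > lower))
  structure(list(kind = "analytic",
                 node = list(type = "box", lower = as.numeric(lower),
                             upper = as.numeric(upper))),
            class = "organ_domain")
}

domain_combine <- function(a, b, op) {
  stopifnot(inherits(a, "organ_domain"), inherits(b, "organ_domain"),
            a$kind == "analytic", b$kind == "analytic")
  structure(list(kind = "analytic",
                 node = list(type = op, a = a$node, b = b$node)),
            class = "organ_domain")
}

#' @rdname organ_domain
#' @export
domain_union <- function(a, b) domain_combine(a, b, "union")

#' @rdname organ_domain
#' @export
domain_intersection <- function(a, b) domain_combine(a, b, "intersection")

#' @rdname organ_domain
#' @export
domain_difference <- function(a, b) domain_combine(a, b, "difference")

#' Voxel-mask organ domain
#'
#' Builds an organ domain from a binary voxel mask.  The unsigned Euclidean
#' distance field to the mask is precomputed with an exact distance
#' transform (anisotropic voxel spacing supported) and evaluated by
#' trilinear interpolation; points beyond the grid add their distance to
#' the grid boundary, keeping the field continuous.
#'
#' @param mask 3-D array, nonzero = inside the organ.
#' @param spacing voxel spacing per axis, mm.
#' @param origin world position of the centre of voxel `[1,1,1]`, mm.
#' @return an `organ_domain` of kind `"voxel"`.
#' @export
domain_voxel <- function(mask, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(length(dim(mask)) == 3L, length(spacing) == 3L, all(spacing > 0))
  m <- array(as.integer(mask != 0), dim = dim(mask))
  if (!any(m == 1L)) stop("voxel mask is empty")
  field <- cpp_edt3d(as.integer(m), dim(m), as.numeric(spacing))
  structure(list(kind = "voxel", mask = m,
                 field = array(field, dim = dim(m)),
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "organ_domain")
}

#' Read a voxel organ domain from a NIfTI mask
#'
#' @param path path to a NIfTI file; nonzero voxels are inside the organ.
#' @return an `organ_domain` of kind `"voxel"`.
#' @export
read_domain_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("reading NIfTI masks requires the RNifti package")
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  domain_voxel(as.array(img), spacing = spacing, origin = c(0, 0, 0))
}

## postfix serialization consumed by the C++ evaluator
flatten_domain_node <- function(node, acc = list(ops = integer(), params = list())) {
  if (node$type %in% c("union", "intersection", "difference")) {
    acc <- flatten_domain_node(node$a, acc)
    acc <- flatten_domain_node(node$b, acc)
    code <- c(union = 10L, intersection = 11L, difference = 12L)[[node$type]]
    acc$ops <- c(acc$ops, code)
  } else if (node$type == "sphere") {
    acc$ops <- c(acc$ops, 1L)
    acc$params <- c(acc$params, list(c(node$center, node$radius)))
  } else if (node$type == "ellipsoid") {
    acc$ops <- c(acc$ops, 2L)
    acc$params <- c(acc$params, list(c(node$center, node$radii)))
  } else if (node$type == "box") {
    acc$ops <- c(acc$ops, 3L)
    acc$params <- c(acc$params, list(c(node$lower, node$upper)))
  } else stop("unknown domain node type: ", node$type)
  acc
}

domain_cpp_spec <- function(domain) {
  stopifnot(inherits(domain, "organ_domain"))
  if (domain$kind == "voxel") {
    list(kind = "voxel", field = as.numeric(domain$field),
         mask = as.integer(domain$mask), dim = dim(domain$mask),
         spacing = domain$spacing, origin = domain$origin)
  } else {
    flat <- flatten_domain_node(domain$node)
    list(kind = "analytic", ops = flat$ops, params = flat$params)
  }
}

#' Unsigned distance from points to an organ domain
#'
#' @param domain an `organ_domain`.
#' @param points numeric 3-vector or n x 3 matrix of world coordinates (mm).
#' @return numeric vector of distances in mm; 0 for interior points.
#' @export
domain_distance <- function(domain, points) {
  pts <- as_points_matrix(points)
  if (any(!is.finite(pts))) stop("non-finite point coordinate")
  as.numeric(cpp_domain_distance(domain_cpp_spec(domain), pts))
}

#' Inside test for an organ domain
#'
#' @inheritParams domain_distance
#' @return logical vector.
#' @export
domain_inside <- function(domain, points) {
  pts <- as_points_matrix(points)
  if (any(!is.finite(pts))) stop("non-finite point coordinate")
  as.logical(cpp_domain_inside(domain_cpp_spec(domain), pts))
}

as_points_matrix <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L, byrow = TRUE)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("points must be 3-vectors")
  points
}

#' Bounding box of an organ domain
#'
#' @param domain an `organ_domain`.
#' @return list with 3-vectors `lower` and `upper` (mm).
#' @export
domain_bbox <- function(domain) {
  if (domain$kind == "voxel") {
    ext <- (dim(domain$mask) - 1L) * domain$spacing
    return(list(lower = domain$origin, upper = domain$origin + ext))
  }
  node_bbox <- function(node) {
    switch(node$type,
      sphere = list(lower = node$center - node$radius,
                    upper = node$center + node$radius),
      ellipsoid = list(lower = node$center - node$radii,
                       upper = node$center + node$radii),
      box = list(lower = node$lower, upper = node$upper),
      union = {
        a <- node_bbox(node$a); b <- node_bbox(node$b)
        list(lower = pmin(a$lower, b$lower), upper = pmax(a$upper, b$upper))
      },
      intersection = {
        a <- node_bbox(node$a); b <- node_bbox(node$b)
        list(lower = pmax(a$lower, b$lower), upper = pmin(a$upper, b$upper))
      },
      difference = node_bbox(node$a))
  }
  node_bbox(domain$node)
}

#' Default nonconvex liver stand-in domain
#'
#' An ellipsoid with an off-centre spherical bite taken out of it: a simple
#' nonconvex organ shape that exercises the out-of-organ penalty without
#' requiring a clinical segmentation mask.  Default semi-axes are in the
#' range of a human liver (mm).
#'
#' @param radii ellipsoid semi-axes, mm.
#' @param bite_center,bite_radius centre and radius of the removed sphere.
#' @return an `organ_domain`.
#' @export
domain_liver_standin <- function(radii = c(80, 60, 50),
                                 bite_center = c(55, 40, 0),
                                 bite_radius = 45) {
  domain_difference(domain_ellipsoid(c(0, 0, 0), radii),
                    domain_sphere(bite_center, bite_radius))
}

#' Sample pseudorandom leaf-target positions inside an organ
#'
#' Rejection sampling of uniform points in the domain's bounding box,
#' keeping points that fall inside the organ and respect a minimal pairwise
#' distance.  Deterministic given `(domain, n, min_distance, seed)` (seeded
#' Mersenne-Twister draws).
#'
#' @param domain an `organ_domain`.
#' @param n number of points.
#' @param min_distance minimal pairwise distance, mm.
#' @param seed integer seed.
#' @param max_draws retry budget (default `1e4 * n`); exceeding it raises an
#'   infeasibility error.
#' @return object of class `leaf_target_set`: list with `points`
#'   (n x 3 matrix), `min_distance`, `seed`.
#' @export
sample_leaf_targets <- function(domain, n, min_distance = 0, seed = 1L,
                                max_draws = 1e4 * n) {
  stopifnot(n >= 1)
  bb <- domain_bbox(domain)
  pts <- matrix(NA_real_, n, 3L)
  got <- 0L
  with_local_seed(seed, {
    draws <- 0L
    while (got < n) {
      if (draws >= max_draws)
        stop("could not place ", n, " leaf targets with min_distance = ",
             min_distance, " within ", max_draws, " draws")
      draws <- draws + 1L
      p <- bb$lower + runif(3L) * (bb$upper - bb$lower)
      if (!domain_inside(domain, p)) next
      if (got > 0L && min_distance > 0) {
        d2 <- rowSums((pts[seq_len(got), , drop = FALSE] -
                         matrix(p, got, 3L, byrow = TRUE))^2)
        if (any(d2 < min_distance^2)) next
      }
      got <- got + 1L
      pts[got, ] <- p
    }
  })
  structure(list(points = pts, min_distance = min_distance, seed = seed),
            class = "leaf_target_set")
}

#' @export
print.leaf_target_set <- function(x, ...) {
  cat("Leaf target set:", nrow(x$points), "points, min distance",
      x$min_distance, "mm, seed", x$seed, "\n")
  invisible(x)
}
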