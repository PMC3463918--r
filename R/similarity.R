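#' Limiting Kolmogorov distribution
#'
#' Evaluates the CDF of the limiting Kolmogorov-Smirnov distribution,
#' \eqn{P_K(x) = 1 - 2\sum_{i\ge1} (-1)^{i-1} e^{-2 i^2 x^2}}.  For small
#' arguments (`x < 1`) the equivalent Jacobi-theta series
#' \eqn{(\sqrt{2\pi}/x) \sum_{i\ge1} e^{-(2i-1)^2\pi^2/(8x^2)}} is used for
#' numerical stability.  Series are truncated once a term drops below 1e-16.
#'
#' @param x nonnegative numeric vector.
#' @return \eqn{P_K(x)} for each element; 0 at `x = 0`.
#' @export
ks_limit_cdf <- function(x) {
  if (any(x < 0)) stop("ks_limit_cdf is defined for x >= 0 only")
  vapply(x, function(xx) {
    if (xx == 0) return(0)
    if (xx < 1) {
      s <- 0
      for (i in 1:100) {
        t <- exp(-(2 * i - 1)^2 * pi^2 / (8 * xx^2))
        s <- s + t
        if (t < 1e-16) break
      }
      sqrt(2 * pi) / xx * s
    } else {
      s <- 0
      for (i in 1:100) {
        t <- (-1)^(i - 1) * exp(-2 * i^2 * xx^2)
        s <- s + t
        if (abs(t) < 1e-16) break
      }
      min(1, max(0, 1 - 2 * s))
    }
  }, numeric(1L))
}

## sup-distance between the two empirical CDFs on the merged support
ks_statistic <- function(x, y) {
  v <- sort(unique(c(x, y)))
  Fx <- findInterval(v, sort(x)) / length(x)
  Fy <- findInterval(v, sort(y)) / length(y)
  max(abs(Fx - Fy))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes the sup-distance \eqn{D} between the empirical CDFs of two
#' samples and a p-value for the null hypothesis of a common underlying
#' distribution.  The asymptotic p-value evaluates the limiting Kolmogorov
#' distribution at the rescaled statistic
#' \eqn{D\sqrt{n_0 n_1/(n_0+n_1)}}; it is known to overestimate p for small
#' samples.  The `"exact_small"` method (default whenever
#' \eqn{n_0+n_1 \le} `exact_threshold`) instead uses the permutation null
#' distribution of \eqn{D}: exhaustive over all \eqn{\binom{n_0+n_1}{n_0}}
#' splits of the pooled sample when that count does not exceed
#' `exhaustive_limit`, otherwise `n_mc` seeded Monte-Carlo permutations.
#'
#' @param x,y nonempty numeric samples.
#' @param method `"auto"` (default), `"asymptotic"` or `"exact_small"`.
#' @param alpha significance level for the rejection decision (default 0.05).
#' @param exact_threshold switch to the exact small-sample method when
#'   `length(x) + length(y)` is at most this (default 25).
#' @return object of class `ks_result`: list with `D`, `n0`, `n1`, `scaled`,
#'   `p`, `reject`, `method`.
#' @examples
#' ks_two_sample(1:3, 4:6)$p   # exact permutation p = 2/20 = 0.1
#' @export
ks_two_sample <- function(x, y, method = c("auto", "asymptotic", "exact_small"),
                          alpha = 0.05, exact_threshold = 25) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  method <- match.arg(method)
  n0 <- length(x); n1 <- length(y)
  if (method == "auto")
    method <- if (n0 + n1 <= exact_threshold) "exact_small" else "asymptotic"
  D <- ks_statistic(x, y)
  scaled <- D * sqrt(n0 * n1 / (n0 + n1))
  p <- if (method == "asymptotic") 1 - ks_limit_cdf(scaled)
       else ks_exact_p(x, y, D)
  structure(list(D = D, n0 = n0, n1 = n1, scaled = scaled, p = p,
                 reject = p < alpha, method = method, alpha = alpha),
            class = "ks_result")
}

## Exact permutation p-value P(D_perm >= D_obs) over all C(n0+n1, n0) splits
## of the pooled sample, computed by tie-aware lattice-path counting: paths
## allocate the x-labels group by group (tie runs of the pooled sorted
## sample); a path state is killed once the CDF difference at a group
## boundary reaches D_obs.  Identical to exhaustive enumeration, in
## O(G * n0 * n1) instead of O(choose(n, n0)).
ks_exact_p <- function(x, y, D) {
  n0 <- length(x); n1 <- length(y)
  w <- sort(c(x, y)); n <- n0 + n1
  sizes <- rle(w)$lengths
  ## cnt[i + 1] = number of (weighted) surviving paths with i x-labels used
  cnt <- numeric(n0 + 1L); cnt[1L] <- 1
  used <- 0L
  thr <- D - 1e-12
  for (g in seq_along(sizes)) {
    cg <- sizes[g]
    newcnt <- numeric(n0 + 1L)
    ways <- choose(cg, 0:cg)
    for (i in which(cnt > 0) - 1L) {
      kmax <- min(cg, n0 - i)
      ks <- 0:kmax
      newcnt[i + ks + 1L] <- newcnt[i + ks + 1L] + cnt[i + 1L] * ways[ks + 1L]
    }
    used <- used + cg
    ii <- 0:n0
    bad <- abs(ii / n0 - (used - ii) / n1) >= thr
    newcnt[bad] <- 0
    cnt <- newcnt
  }
  1 - cnt[n0 + 1L] / choose(n, n0)
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("Two-sample KS test (%s): D = %.4g, n = (%d, %d), p = %.4g%s\n",
              x$method, x$D, x$n0, x$n1, x$p,
              if (x$reject) sprintf("  [reject at P = %g]", x$alpha) else ""))
  invisible(x)
}

#' Similarity analysis configuration
#'
#' @param alpha KS significance level P (default 0.05; conventional, any
#'   other level may be chosen).
#' @param exact_threshold small-sample KS control, see [ks_two_sample()].
#' @return a list of class `similarity_config`.
#' @export
similarity_config <- function(alpha = 0.05, exact_threshold = 25) {
  structure(list(alpha = alpha, exact_threshold = exact_threshold),
            class = "similarity_config")
}

ks_with_config <- function(x, y, config) {
  ks_two_sample(x, y, method = "auto", alpha = config$alpha,
                exact_threshold = config$exact_threshold)
}

#' Single-population similarity ratio
#'
#' Fraction of pairs of distinct trees of one population whose samples of a
#' given feature at a given Strahler* order are not rejected by the KS test.
#' Pairs in which either tree contributes no defined value are excluded from
#' numerator and denominator alike.  The test is symmetric, so unordered
#' pairs are counted.
#'
#' @param samples list of numeric vectors, one per tree (values of one
#'   feature at one Strahler* order, `NA`-free).
#' @param config a [similarity_config()].
#' @return ratio in `[0, 1]`, or `NA` if fewer than two trees contribute.
#' @export
similarity_ratio_single <- function(samples, config = similarity_config()) {
  keep <- which(vapply(samples, length, integer(1L)) > 0L)
  if (length(keep) < 2L) return(NA_real_)
  prs <- combn(keep, 2L)
  dec <- vapply(seq_len(ncol(prs)), function(k) {
    ks_with_config(samples[[prs[1L, k]]], samples[[prs[2L, k]]], config)$reject
  }, logical(1L))
  mean(!dec)
}

#' Two-population similarity ratio
#'
#' As [similarity_ratio_single()], over the full cross product of one
#' population against another.
#'
#' @param samples_m,samples_g lists of numeric vectors (one per tree of the
#'   measured and generated population, respectively).
#' @inheritParams similarity_ratio_single
#' @return ratio in `[0, 1]`, or `NA` if no valid pair exists.
#' @export
similarity_ratio_two <- function(samples_m, samples_g,
                                 config = similarity_config()) {
  km <- which(vapply(samples_m, length, integer(1L)) > 0L)
  kg <- which(vapply(samples_g, length, integer(1L)) > 0L)
  if (!length(km) || !length(kg)) return(NA_real_)
  dec <- logical(0)
  for (i in km) for (j in kg)
    dec <- c(dec, ks_with_config(samples_m[[i]], samples_g[[j]], config)$reject)
  mean(!dec)
}

## order cutoff: smallest s with n_s < n_trees / 2 (real division, strict)
order_cutoff <- function(n_s, n_trees) {
  ## n_s: numeric vector indexed by order 0, 1, ...
  s <- 0L
  while (s < length(n_s) && n_s[s + 1L] >= n_trees / 2) s <- s + 1L
  s
}

#' Average similarity ratios over Strahler* orders
#'
#' Averages per-order similarity ratios for one feature into a per-feature
#' value, restricted to the orders below the cutoff \eqn{\tilde s}: the
#' smallest order at which fewer than half of the trees still have edges.
#' Weights are the tree counts \eqn{n_s} in the single-population case and
#' the geometric means \eqn{\sqrt{n_s(\mathcal T_m) n_s(\mathcal T_g)}} in
#' the two-population case (with \eqn{\tilde s} the minimum of the two
#' cutoffs).  Orders with an undefined ratio are skipped together with their
#' weight.
#'
#' @param ratios numeric vector of per-order ratios for orders `0, 1, ...`
#'   (may contain `NA`).
#' @param n_s vector of per-order tree counts of the (first) population.
#' @param n_trees number of trees in the (first) population.
#' @param n_s_g,n_trees_g counts for the second population (two-population
#'   case); `NULL` for the single-population case.
#' @return list with `value` (the weighted mean, `NA` if the cutoff is 0 or
#'   no order contributes), `s_tilde`, and the `weights` used.
#' @export
average_over_orders <- function(ratios, n_s, n_trees,
                                n_s_g = NULL, n_trees_g = NULL) {
  if (is.null(n_s_g)) {
    s_tilde <- order_cutoff(n_s, n_trees)
    w <- n_s
  } else {
    s_tilde <- min(order_cutoff(n_s, n_trees),
                   order_cutoff(n_s_g, n_trees_g))
    len <- max(length(n_s), length(n_s_g))
    pad <- function(v) c(v, rep(0, len - length(v)))
    w <- sqrt(pad(n_s) * pad(n_s_g))
  }
  if (s_tilde == 0L) return(list(value = NA_real_, s_tilde = 0L, weights = w))
  idx <- seq_len(min(s_tilde, length(ratios), length(w)))
  r <- ratios[idx]; wi <- w[idx]
  ok <- !is.na(r)
  value <- if (any(ok) && sum(wi[ok]) > 0) sum(wi[ok] * r[ok]) / sum(wi[ok])
           else NA_real_
  list(value = value, s_tilde = s_tilde, weights = w)
}

#' Average per-feature similarities into group and total averages
#'
#' Feature groups are fixed: radius = \{r, eta_r, sigma_r, gamma\},
#' length = \{l, eta_l, sigma_l\}, angle = \{phi_a, phi_b, phi_c\}.  In the
#' single-population case the group value is the arithmetic mean of its
#' features.  In the two-population case the features are weighted by their
#' single-population similarities in the measured population, so that
#' features invariant among measured trees count more ("similarity where it
#' is expected").  Group weights are the summed measured per-feature
#' similarities divided by the group size, and the total is the weighted
#' mean of the group values.
#'
#' @param per_feature named numeric vector of per-feature averages (the
#'   quantity being aggregated; two-population values in the two-population
#'   case).  `NA` entries are excluded.
#' @param weights_single named numeric vector of single-population
#'   per-feature averages used as weights; in the single-population case
#'   pass `per_feature` itself (it then only enters the group weights).
#' @param mode `"single"` or `"two"`.
#' @return list with `groups` (named vector), `group_weights`, `total`.
#' @export
average_over_features <- function(per_feature, weights_single = per_feature,
                                  mode = c("single", "two")) {
  mode <- match.arg(mode)
  grps <- vt_feature_groups()
  gv <- gw <- setNames(rep(NA_real_, length(grps)), names(grps))
  for (g in names(grps)) {
    f <- grps[[g]]
    v <- per_feature[f]; ws <- weights_single[f]
    ok <- !is.na(v) & !is.na(ws)
    if (!any(ok)) next
    gv[g] <- if (mode == "single") mean(v[ok])
             else sum(ws[ok] * v[ok]) / sum(ws[ok])
    gw[g] <- sum(ws[ok]) / sum(ok)
  }
  ok <- !is.na(gv) & !is.na(gw)
  total <- if (any(ok)) sum(gw[ok] * gv[ok]) / sum(gw[ok]) else NA_real_
  list(groups = gv, group_weights = gw, total = total)
}
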