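test_that("limiting Kolmogorov distribution matches direct series evaluation", {
  expect_equal(ks_limit_cdf(0), 0)
  expect_equal(ks_limit_cdf(10), 1)
  expect_error(ks_limit_cdf(-0.1), "x >= 0")
  ## direct alternating-series oracle; below x ~ 0.5 its cancellation noise
  ## exceeds 1e-12 relative (the theta branch exists for exactly that reason)
  direct <- function(x) 1 - 2 * sum((-1)^(0:59) * exp(-2 * (1:60)^2 * x^2))
  for (x in c(0.5, 0.8284, 1.0, 1.2247, 1.5, 2.2))
    expect_equal(ks_limit_cdf(x), direct(x), tolerance = 1e-12)
  expect_lt(abs(ks_limit_cdf(0.3) - direct(0.3)), 1e-13)
  expect_equal(ks_limit_cdf(1.2247), 0.9004, tolerance = 1e-4)
  ## monotone nondecreasing
  xs <- seq(0.05, 3, by = 0.05)
  expect_true(all(diff(ks_limit_cdf(xs)) >= 0))
})

test_that("two-sample KS statistic agrees with stats::ks.test", {
  set.seed(10)
  for (i in 1:20) {
    x <- rnorm(sample(5:40, 1)); y <- rnorm(sample(5:40, 1), 0.3)
    k <- ks_two_sample(x, y, method = "asymptotic")
    ref <- suppressWarnings(stats::ks.test(x, y))
    expect_equal(k$D, unname(ref$statistic), tolerance = 1e-12)
    ## symmetry
    k2 <- ks_two_sample(y, x, method = "asymptotic")
    expect_equal(k$D, k2$D); expect_equal(k$p, k2$p)
  }
})

test_that("exact small-sample p equals the exhaustive permutation oracle", {
  k <- ks_two_sample(1:3, 4:6)
  expect_equal(k$method, "exact_small")
  expect_equal(k$D, 1)
  expect_equal(k$p, 2 / 20)
  expect_equal(ks_two_sample(1:3, 4:6, method = "asymptotic")$p, 0.0996,
               tolerance = 1e-3)

  set.seed(77)
  for (i in 1:12) {
    n0 <- sample(2:8, 1); n1 <- sample(2:8, 1)
    x <- round(rnorm(n0), 1); y <- round(rnorm(n1), 1)   # ties likely
    expect_equal(ks_two_sample(x, y, method = "exact_small")$p,
                 oracle_exact_ks_p(x, y), tolerance = 1e-12)
  }

  ## identical samples: no distance, no rejection
  k <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(k$D, 0); expect_equal(k$p, 1); expect_false(k$reject)
  expect_error(ks_two_sample(numeric(), 1:3), "nonempty")
})

test_that("null rejection rate matches the exact discrete size of the test", {
  ## with n0 = n1 = 20 the statistic lives on a 1/20 lattice; at P = 0.05 the
  ## asymptotic test rejects iff D >= 0.45, whose exact null probability the
  ## permutation machinery itself provides
  size <- vasctree:::ks_exact_p(seq_len(20), 20 + seq_len(20), 0.45)
  expect_equal(size, 0.03354, tolerance = 1e-3)
  set.seed(31)
  n_rep <- 400
  rej <- vapply(seq_len(n_rep), function(i) {
    ks_two_sample(runif(20), runif(20), method = "asymptotic")$reject
  }, logical(1))
  rate <- mean(rej)
  expect_true(abs(rate - size) <= 3 * sqrt(size * (1 - size) / n_rep))
})

test_that("similarity ratios: identical, disjoint and hand-enumerated cases", {
  cfg <- similarity_config()
  same <- replicate(4, rnorm(12, 0, 1), simplify = FALSE)
  expect_equal(similarity_ratio_single(rep(same[1], 4), cfg), 1)
  far <- list(as.numeric(1:50), as.numeric(101:150))
  expect_equal(similarity_ratio_single(far, cfg), 0)
  expect_equal(similarity_ratio_two(far[1], far[2], cfg), 0)
  expect_equal(similarity_ratio_two(same[1:2], same[1:2], cfg) >= 0.5, TRUE)

  ## mixed population of 4 trees: brute-force pairwise oracle
  set.seed(8)
  samples <- list(rnorm(15), rnorm(15), rnorm(15, 4), rnorm(20, 4))
  dec <- outer(1:4, 1:4, Vectorize(function(i, j)
    if (i < j) !ks_two_sample(samples[[i]], samples[[j]])$reject else NA))
  oracle <- mean(dec[upper.tri(dec)])
  expect_equal(similarity_ratio_single(samples, cfg), oracle)

  ## 3 x 2 cross product
  dec2 <- outer(1:2, 3:4, Vectorize(function(i, j)
    !ks_two_sample(samples[[i]], samples[[j]])$reject))
  expect_equal(similarity_ratio_two(samples[1:2], samples[3:4], cfg),
               mean(dec2))

  ## empty samples are excluded from numerator and denominator
  with_empty <- c(samples[1:2], list(numeric()), samples[3])
  expect_equal(similarity_ratio_single(with_empty, cfg),
               similarity_ratio_single(with_empty[-3], cfg))
  expect_true(is.na(similarity_ratio_single(list(rnorm(5)), cfg)))
})

test_that("order averaging implements the half-of-the-trees cutoff", {
  ## ratios all equal: weighted mean is that constant
  r <- average_over_orders(rep(0.7, 4), c(10, 9, 8, 6), 10)
  expect_equal(r$value, 0.7)
  ## at-least-half rule: n_s = (4, 4, 2) of 4 trees keeps order 2 (2 >= 4/2)
  r <- average_over_orders(c(1, 0.5, 0.9), c(4, 4, 2), 4)
  expect_equal(r$s_tilde, 3L)
  expect_equal(r$value, (4 * 1 + 4 * 0.5 + 2 * 0.9) / 10)
  ## the first order strictly below half stops the averaging
  r <- average_over_orders(c(1, 0.5, 0.9), c(4, 4, 1), 4)
  expect_equal(r$s_tilde, 2L)
  expect_equal(r$value, (4 * 1 + 4 * 0.5) / 8)
  ## two-population weights: geometric means, cutoff is the minimum
  r <- average_over_orders(c(0.8, 0.6), c(4, 1), 4, c(9, 9), 10)
  expect_equal(r$weights[1L], 6)          # sqrt(4 * 9)
  expect_equal(r$s_tilde, 1L)             # second pop: 1 < 2
  expect_equal(r$value, 0.8)
  ## NA ratios are skipped with their weight
  r <- average_over_orders(c(0.8, NA, 0.4), c(6, 6, 6), 6)
  expect_equal(r$value, (0.8 * 6 + 0.4 * 6) / 12)
  ## cutoff 0 is undefined
  expect_true(is.na(average_over_orders(c(0.5), c(1), 4)$value))
})

test_that("feature averaging follows the spreadsheet oracle", {
  feats <- c("r", "eta_r", "sigma_r", "gamma", "l", "eta_l",
             "sigma_l", "phi_a", "phi_b", "phi_c")
  single <- setNames(c(0.27, 0.689, 0.772, 0.895, 0.78, 0.969, 0.925,
                       0.923, 0.938, 0.872), feats)
  two <- setNames(c(0.174, 0.506, 0.449, 0.684, 0.384, 0.965, 0.937,
                    0.810, 0.908, 0.827), feats)

  res1 <- average_over_features(single, single, "single")
  ## explicit arithmetic, group by group
  expect_equal(unname(res1$groups["radius"]),
               mean(c(0.27, 0.689, 0.772, 0.895)))
  expect_equal(unname(res1$groups["length"]), mean(c(0.78, 0.969, 0.925)))
  expect_equal(unname(res1$groups["angle"]), mean(c(0.923, 0.938, 0.872)))
  wR <- sum(c(0.27, 0.689, 0.772, 0.895)) / 4
  wL <- sum(c(0.78, 0.969, 0.925)) / 3
  wA <- sum(c(0.923, 0.938, 0.872)) / 3
  expect_equal(unname(res1$group_weights), c(wR, wL, wA))
  expect_equal(res1$total,
               (wR * res1$groups[["radius"]] + wL * res1$groups[["length"]] +
                wA * res1$groups[["angle"]]) / (wR + wL + wA))

  res2 <- average_over_features(two, single, "two")
  num <- sum(single[1:4] * two[1:4]); den <- sum(single[1:4])
  expect_equal(unname(res2$groups["radius"]), num / den)
  ## uniform weights collapse the weighted form onto the arithmetic mean
  uni <- setNames(rep(0.5, 10), feats)
  res3 <- average_over_features(two, uni, "two")
  expect_equal(unname(res3$groups["length"]), mean(two[5:7]))

  ## all features equal c: every level equals c
  allc <- setNames(rep(0.61, 10), feats)
  res4 <- average_over_features(allc, allc, "single")
  expect_equal(unname(res4$groups), rep(0.61, 3))
  expect_equal(res4$total, 0.61)
})

test_that("similarity report: populations of identical trees score 1", {
  pop <- rep(list(rand_valid_tree(1, n_leaves = 12)), 3)
  rep1 <- similarity_report(pop)
  expect_equal(rep1$total, 1)
  rep2 <- similarity_report(pop, pop)
  expect_equal(rep2$total, 1)
  expect_true(all(rep2$per_feature[!is.na(rep2$per_feature)] == 1))
  expect_true(all(rep2$groups[!is.na(rep2$groups)] == 1))
})

test_that("similarity report is deterministic and audit-consistent", {
  pop_a <- make_population(synthetic_population_spec(n_trees = 4,
                                                     leaf_range = c(15, 25),
                                                     seed = 5))
  pop_b <- make_population(synthetic_population_spec(n_trees = 3,
                                                     leaf_range = c(15, 25),
                                                     seed = 6))
  r1 <- similarity_report(pop_a, pop_b)
  r2 <- similarity_report(pop_a, pop_b)
  expect_identical(r1, r2)

  ## per-cell ratios equal independent recomputation from the audit log
  aud <- r1$audit[r1$audit$mode == "two", ]
  for (f in unique(aud$feature)) for (s in unique(aud$order[aud$feature == f])) {
    rows <- aud[aud$feature == f & aud$order == s, ]
    expect_equal(r1$ratios[f, as.character(s)], mean(!rows$reject))
  }

  ## rigid motion applied to every tree leaves all numbers unchanged
  R <- rand_rotation(3)
  pop_a2 <- lapply(pop_a, transform_tree, R = R, shift = c(5, 5, 5))
  r3 <- similarity_report(pop_a2, pop_b)
  expect_equal(r3$per_feature, r1$per_feature, tolerance = 1e-9)

  ## tree relabeling within a population does not change the report
  r4 <- similarity_report(pop_a[c(3, 1, 2, 4)], pop_b)
  expect_equal(r4$total, r1$total)
})

test_that("report export writes the three artifacts", {
  pop <- lapply(1:3, function(s) rand_valid_tree(s, n_leaves = 8))
  rep1 <- similarity_report(pop)
  stem <- tempfile()
  write_similarity_csv(rep1, stem)
  expect_true(file.exists(paste0(stem, ".features.csv")))
  feat <- read.csv(paste0(stem, ".features.csv"))
  expect_equal(feat$similarity[feat$feature == "Total average"], rep1$total)
  expect_true(file.exists(paste0(stem, ".ratios.csv")))
  expect_true(file.exists(paste0(stem, ".audit.json")))
})
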