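test_that("viscosity model: values, continuity, monotonicity", {
  expect_equal(viscosity(4.29), 16)                 # delta/r = 1 -> 4 mu_inf
  expect_equal(viscosity(200), 4)
  expect_equal(viscosity(160), 4)
  expect_equal(viscosity(140), 4 * (1 + 4.29 / 140)^2, tolerance = 1e-12)
  expect_equal(viscosity(140), 4.249, tolerance = 1e-4)
  ## continuity at the transition endpoints
  expect_lt(abs(viscosity(140 - 1e-9) - viscosity(140 + 1e-9)), 1e-9)
  expect_lt(abs(viscosity(160 - 1e-9) - viscosity(160 + 1e-9)), 1e-9)
  ## clamped below 4 um
  expect_equal(viscosity(1), viscosity(4))
  ## monotone nonincreasing
  r <- seq(4, 250, by = 0.25)
  expect_true(all(diff(viscosity(r)) <= 1e-12))
  expect_error(viscosity(0), "r > 0")
})

test_that("edge resistance follows Hagen-Poiseuille", {
  expect_equal(edge_resistance(1, 1), 8 * 4e-3 * 1e-3 / (pi * (1e-3)^4))
  expect_equal(edge_resistance(1, 1), 1.0186e7, tolerance = 1e-4)
  expect_equal(edge_resistance(5, 1) / edge_resistance(5, 2), 16)
  expect_equal(edge_resistance(0, 1), 0)
  expect_error(edge_resistance(1, 0), "nonpositive radius")
})

test_that("radius rebalancing reproduces closed-form solutions", {
  ## symmetric bifurcation: beta = 2^(-1/3)
  fs <- rebalance_radii(make_perfect_tree(1), cco_config(root_radius = 1))
  expect_equal(sort(unique(round(fs$tree$edges$radius, 10))),
               round(c(2^(-1 / 3), 1), 10))
  ## daughter leaf lengths 16 and 1: l1/r1^4 = l2/r2^4 with beta^3 sum = 1
  ## => r1/r2 = 2, r2 = 9^(-1/3)
  tr <- vascular_tree(
    nodes = data.frame(id = c("r", "b", "l1", "l2"), x = 0,
                       y = c(10, 0, -16, -1), z = c(0, 0, 0, 1e-9)),
    edges = data.frame(id = c("e0", "e1", "e2"), from = c("r", "b", "b"),
                       to = c("b", "l1", "l2"), radius = 1),
    root = "r")
  fs <- rebalance_radii(tr, cco_config(root_radius = 1))
  r <- setNames(fs$tree$edges$radius, fs$tree$edges$id)
  expect_equal(unname(r["e1"] / r["e2"]), 2, tolerance = 1e-10)
  expect_equal(unname(r["e2"]), 9^(-1 / 3), tolerance = 1e-10)
  expect_equal(unname(r["e0"]), 1)
})

test_that("rebalancing equalises leaf pressure drops (independent oracle)", {
  for (s in 1:25) {
    tr <- rand_valid_tree(s, n_leaves = sample(3:16, 1))
    fs <- rebalance_radii(tr, cco_config(root_radius = 2))
    dp <- oracle_leaf_pressures(fs$tree)
    expect_lt(max(abs(dp - mean(dp))) / mean(dp), 1e-6)
    ## and the reported drops agree with the oracle
    expect_equal(sort(unname(fs$leaf_pressure_drop)), sort(unname(dp)),
                 tolerance = 1e-9)
    ## bifurcation-exponent law at every bifurcation
    ft <- feature_table(fs$tree)
    g <- ft$gamma[!is.na(ft$gamma)]
    expect_true(all(abs(g - 3) < 1e-7))
  }
})

test_that("radius-dependent viscosity rebalancing converges and stays consistent", {
  tr <- rand_valid_tree(99, n_leaves = 12)
  tr <- transform_tree(tr, scale = 0.05)   # push radii into the F-L regime
  cfg <- cco_config(root_radius = 0.15, viscosity = "radius_dependent")
  fs <- rebalance_radii(tr, cfg)
  expect_gt(fs$iterations, 1)
  ## equal pressure drops under the radius-dependent viscosities
  dp <- fs$leaf_pressure_drop
  expect_lt(max(abs(dp - mean(dp))) / mean(dp), 1e-6)
  ## resistances reported use mu(r) of the final radii
  mu <- viscosity(fs$tree$edges$radius * 1e3, cfg)
  len <- edge_lengths(fs$tree)
  Rexp <- ifelse(len == 0, 0,
                 8 * (mu * 1e-3) * (len * 1e-3) /
                   (pi * (fs$tree$edges$radius * 1e-3)^4))
  expect_equal(unname(fs$resistance), Rexp, tolerance = 1e-10)
})

test_that("fixed-pressure-drop root condition sets the absolute scale", {
  tr <- make_perfect_tree(2)
  cfg <- cco_config(root_condition = "fixed_pressure_drop",
                    pressure_drop = 400, total_flow = 2e-5)
  fs <- rebalance_radii(tr, cfg)
  ## total resistance times total flow equals the prescribed pressure drop
  dp <- fs$leaf_pressure_drop
  expect_equal(unname(dp), rep(400, 4), tolerance = 1e-6)
})

test_that("tree cost: volume term, penalty term, degenerate exponent", {
  s <- make_root_seed(c(0, 0, 10), c(0, 0, 0), 1)
  expect_equal(tree_cost(s, NULL, cco_config(lambda = 2)), 10)
  ## one endpoint 2 mm outside a sphere: penalty C * 2^2 at that node
  dom <- domain_sphere(c(0, 0, 4), 6)   # tip (0,0,0) inside, root 2 mm out
  expect_equal(tree_cost(s, dom, cco_config(lambda = 2, penalty_C = 42)),
               10 + 42 * 0, tolerance = 1e-12)
  dom2 <- domain_sphere(c(0, 0, -2), 6) # root (0,0,10) is 6 mm outside
  expect_equal(tree_cost(s, dom2, cco_config(lambda = 2, penalty_C = 42)),
               10 + 42 * 36, tolerance = 1e-9)
  ## lambda = 0: total length plus penalty
  tr <- make_perfect_tree(2)
  expect_equal(tree_cost(tr, NULL, cco_config(lambda = 1e-12)),
               sum(edge_lengths(tr)), tolerance = 1e-6)
  ## C = 0: penalty vanishes exactly
  expect_equal(tree_cost(s, dom2, cco_config(lambda = 2, penalty_C = 0)), 10)
})

test_that("candidate edges are the nearest midpoints with id tie-breaks", {
  s <- make_root_seed(c(0, 0, 10), c(0, 0, 0), 1)
  expect_equal(candidate_edges(s, c(5, 5, 5)), "e0")

  tr <- rand_valid_tree(17, n_leaves = 101)   # 201 edges
  p <- c(1, -5, 2)
  got <- candidate_edges(tr, p, 40)
  ## oracle: exhaustive sort
  ni <- setNames(seq_len(nrow(tr$nodes)), tr$nodes$id)
  P <- as.matrix(tr$nodes[, c("x", "y", "z")])
  mid <- (P[ni[tr$edges$from], ] + P[ni[tr$edges$to], ]) / 2
  d2 <- rowSums((mid - matrix(p, nrow(mid), 3, byrow = TRUE))^2)
  oracle <- tr$edges$id[order(d2, tr$edges$id)][1:40]
  expect_equal(got, oracle)
  expect_equal(length(candidate_edges(tr, p, 10000)), nrow(tr$edges))
})

test_that("bifurcation optimization descends and respects symmetry", {
  ## 3-edge toy tree
  tr <- vascular_tree(
    nodes = data.frame(id = c("r", "b", "l1", "l2"),
                       x = c(0, 0, -6, 6), y = c(12, 4, -4, -4), z = 0),
    edges = data.frame(id = c("e0", "e1", "e2"), from = c("r", "b", "b"),
                       to = c("b", "l1", "l2"), radius = 1),
    root = "r")
  cfg <- cco_config(root_radius = 1, final_tolerance = 1e-4)
  leaf <- c(3, -2, 1)
  c_mid <- bifurcation_cost(tr, "e2", leaf,
                            position = c(3, 0, 0), config = cfg)
  opt <- optimize_bifurcation(tr, "e2", leaf, config = cfg)
  expect_lte(opt$cost, c_mid + 1e-12)

  ## mirror-symmetric configuration: new leaf on the symmetry plane of e0
  leaf_sym <- c(0, -6, 0)
  opt_sym <- optimize_bifurcation(tr, "e0", leaf_sym, config = cfg)
  expect_lt(abs(opt_sym$position[1]), 0.05)
  expect_equal(opt_sym$position[3], 0, tolerance = 1e-6)
})

test_that("add_leaf grows the tree by one leaf and two edges", {
  tr <- make_perfect_tree(2)
  n_leaf <- length(vasctree:::leaf_edges(tr))
  out <- add_leaf(tr, c(4, -25, 3), config = cco_config(root_radius = 1))
  expect_true(validate_vascular_tree(out))
  expect_equal(nrow(out$edges), nrow(tr$edges) + 2L)
  expect_equal(length(vasctree:::leaf_edges(out)), n_leaf + 1L)
  aud <- attr(out, "audit")
  expect_equal(aud$cost, min(aud$shortlist_costs))
  expect_true(aud$edge %in% tr$edges$id)
})

test_that("generation is deterministic and respects a convex domain", {
  dom <- domain_sphere(c(0, 0, 0), 20)
  tg <- sample_leaf_targets(dom, 12, min_distance = 2, seed = 5)
  ## seed tree fully inside the (convex) domain: every attachment point is
  ## interior, so optimal bifurcations are interior and the penalty inactive
  seedt <- make_root_seed(c(0, 0, 19.5), c(0, 0, 14), 1.5)
  cfg <- cco_config(root_radius = 1.5)
  g1 <- generate_tree(seedt, dom, tg, cfg)
  g2 <- generate_tree(seedt, dom, tg, cfg)
  expect_identical(g1, g2)
  expect_equal(generate_tree(seedt, dom, matrix(numeric(), 0, 3), cfg), seedt)
  d <- domain_distance(dom, as.matrix(g1$nodes[, c("x", "y", "z")]))
  expect_true(all(d == 0))
})
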