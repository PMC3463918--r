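test_that("parallel parent edges merge with cross-section preservation", {
  nodes <- data.frame(id = c("a", "b", "c", "d"), x = c(0, 0, 1, -1),
                      y = c(0, -1, -2, -2), z = 0)
  edges <- data.frame(id = c("p1", "p2", "d1", "d2"), from = c("a", "a", "b", "b"),
                      to = c("b", "b", "c", "d"), radius = c(3, 4, 1, 1))
  res <- correct_graph(raw_vascular_graph(nodes, edges, "a"))
  expect_equal(res$tree$edges$radius[res$tree$edges$id == "p1"], 5)  # sqrt(9+16)
  expect_true(validate_vascular_tree(res$tree))
})

test_that("monofurcation chains merge with arithmetic-mean radii", {
  nodes <- data.frame(id = c("a", "b", "c"), x = 0, y = c(0, -1, -2), z = 0)
  edges <- data.frame(id = c("e1", "e2"), from = c("a", "b"), to = c("b", "c"),
                      radius = c(2, 4))
  res <- correct_graph(raw_vascular_graph(nodes, edges, "a"))
  expect_equal(nrow(res$tree$edges), 1L)
  expect_equal(res$tree$edges$radius, 3)
  expect_equal(res$tree$edges$to, "c")
})

test_that("a trifurcation splits into bifurcations joined by a trivial edge", {
  nodes <- data.frame(id = c("r", "v", "l1", "l2", "l3"),
                      x = c(0, 0, -1, 0, 1), y = c(1, 0, -1, -1, -1), z = 0)
  edges <- data.frame(id = c("e0", "d1", "d2", "d3"), from = c("r", "v", "v", "v"),
                      to = c("v", "l1", "l2", "l3"), radius = c(2, 1, 1, 1))
  res <- correct_graph(raw_vascular_graph(nodes, edges, "r"))
  tr <- res$tree
  expect_true(validate_vascular_tree(tr))
  expect_equal(nrow(tr$edges), 5L)
  len <- edge_lengths(tr)
  expect_equal(sum(len == 0), 1L)                       # one trivial edge
  expect_equal(tr$edges$radius[len == 0], 2)            # parent's radius
  ## geometry of the original edges unchanged: same midpoints
  mids <- function(t) {
    ni <- setNames(seq_len(nrow(t$nodes)), t$nodes$id)
    P <- as.matrix(t$nodes[, c("x", "y", "z")])
    m <- (P[ni[t$edges$from], , drop = FALSE] + P[ni[t$edges$to], , drop = FALSE]) / 2
    m[edge_lengths(t) > 0, , drop = FALSE]
  }
  expect_setequal(apply(round(mids(tr), 10), 1, paste, collapse = ","),
                  apply(round(mids(vascular_tree(nodes, edges, "r",
                                                 validate = FALSE)), 10),
                        1, paste, collapse = ","))
})

test_that("corrupted graphs are repaired to valid trees (property)", {
  for (s in 1:40) {
    tr <- rand_valid_tree(s, n_leaves = sample(3:12, 1))
    g <- corrupt_tree(tr, seed = 1000 + s)
    res <- correct_graph(g)
    expect_true(validate_vascular_tree(res$tree))
    ## area conservation at every parallel-parent merge, from the log
    for (e in res$log) if (e$kind == "merge_parallel")
      expect_equal(e$radius_after^2, sum(e$radius_before^2),
                   tolerance = 1e-12)
    ## idempotence: correcting the corrected tree changes nothing
    res2 <- correct_graph(raw_vascular_graph(res$tree$nodes, res$tree$edges,
                                             res$tree$root))
    expect_equal(res2$tree$edges[order(res2$tree$edges$id), ],
                 res$tree$edges[order(res$tree$edges$id), ],
                 ignore_attr = TRUE)
    expect_equal(res2$tree$root, res$tree$root)
  }
})

test_that("replaying the correction log reproduces the corrected tree", {
  for (s in c(2, 7, 19)) {
    tr <- rand_valid_tree(s, n_leaves = 8)
    g <- corrupt_tree(tr, seed = 500 + s)
    res <- correct_graph(g)
    rp <- replay_corrections(g, res$log)
    expect_equal(rp$edges[order(rp$edges$id), ],
                 res$tree$edges[order(res$tree$edges$id), ],
                 ignore_attr = TRUE)
    expect_equal(rp$root, res$tree$root)
    expect_equal(rp$nodes[order(rp$nodes$id), ],
                 res$tree$nodes[order(res$tree$nodes$id), ],
                 ignore_attr = TRUE)
  }
})

test_that("proper loops and empty graphs are rejected", {
  nodes <- data.frame(id = c("a", "b"), x = 0, y = c(0, -1), z = 0)
  edges <- data.frame(id = c("e1", "e2"), from = c("a", "b"), to = c("b", "a"),
                      radius = 1)
  expect_error(correct_graph(raw_vascular_graph(nodes, edges, "a")),
               "proper loop")
  g0 <- raw_vascular_graph(data.frame(id = "a", x = 0, y = 0, z = 0),
                           data.frame(id = character(), from = character(),
                                      to = character(), radius = numeric()))
  expect_error(correct_graph(g0), "empty")
})

test_that("the primary root is the one supplying the largest subtree", {
  tr1 <- rand_valid_tree(11, n_leaves = 8)   # large component
  nodes <- rbind(tr1$nodes,
                 data.frame(id = c("q", "qt"), x = c(100, 100), y = c(0, -1), z = 0))
  edges <- rbind(tr1$edges[, c("id", "from", "to", "radius")],
                 data.frame(id = "qe", from = "q", to = "qt", radius = 1))
  res <- correct_graph(raw_vascular_graph(nodes, edges, roots = c("q", tr1$root)))
  expect_equal(res$tree$root, tr1$root)
})

test_that("the shipped example skeleton graph corrects cleanly", {
  f <- system.file("extdata", "example_raw_graph.json", package = "vasctree")
  g <- read_graph(f)
  res <- correct_graph(g)
  expect_true(validate_vascular_tree(res$tree))
  kinds <- vapply(res$log, function(e) e$kind, character(1))
  expect_true(all(c("merge_parallel", "merge_monofurcation",
                    "split_multifurcation", "remove_isolated") %in% kinds))
  merged <- res$log[[which(kinds == "merge_parallel")[1]]]
  expect_equal(merged$radius_after, sqrt(1.2^2 + 0.9^2))
})
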