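test_that("dominance requires weak ordering everywhere and strict somewhere", {
  expect_true(check_dominance(c(1, 1), c(0.5, 0.5), eps = 0))
  expect_false(check_dominance(c(0.5, 0.5), c(0.5, 0.5), eps = 0))
  expect_false(check_dominance(c(0.6, 0.2), c(0.2, 0.5), eps = 0))
  # eps slack admits small inversions
  expect_true(check_dominance(c(1, 0.95), c(0.5, 1.0), eps = 0.1))
  expect_error(check_dominance(c(1, 1), c(1, 1, 1)),
               class = "clonephylo_input_error")
})

test_that("the sum rule bounds sibling CCFs by their parent in every sample", {
  expect_true(check_sum_rule(c(1, 1), list(c(0.6, 0.2), c(0.3, 0.5)), eps = 0))
  expect_false(check_sum_rule(c(1, 1), list(c(0.7, 0.4), c(0.5, 0.3)), eps = 0))
  expect_true(check_sum_rule(c(1, 1), list(c(0.8, 0.9)), eps = 0))
  expect_error(check_sum_rule(c(1, 1), list()),
               class = "clonephylo_input_error")
})

test_that("the crossing rule classifies pairwise CCF orderings symmetrically", {
  expect_equal(check_crossing_rule(c(0.6, 0.2), c(0.2, 0.5), eps = 0),
               "branching-required")
  expect_equal(check_crossing_rule(c(0.6, 0.5), c(0.2, 0.1), eps = 0),
               "order-permitted")
  expect_equal(check_crossing_rule(c(0.4, 0.4), c(0.4, 0.4), eps = 0),
               "symmetric")
  # swapping arguments preserves the branching and symmetric classes
  set.seed(3)
  for (i in 1:50) {
    a <- runif(3)
    b <- runif(3)
    ra <- check_crossing_rule(a, b, eps = 0.05)
    rb <- check_crossing_rule(b, a, eps = 0.05)
    if (ra %in% c("branching-required", "symmetric")) expect_equal(rb, ra)
  }
})

test_that("mutually exclusive clonal clusters force a unique first bifurcation", {
  loc <- matrix(c(1, 1, 1, 1,
                  1, 1, 0, 0,
                  0, 0, 1, 1), nrow = 3, byrow = TRUE,
                dimnames = list(c("t", "b", "d"), paste0("S", 1:4)))
  cl <- make_clusters(loc, sizes = c(1000L, 100L, 100L), truncal_id = "t")
  sol <- build_trees(cl, eps = 0.1)
  expect_equal(length(sol$trees), 1)
  expect_equal(tree_signature(sol$trees[[1]]), "b<-t;d<-t")
  expect_equal(count_bifurcations(sol$trees[[1]]), 1)
})

test_that("a lone truncal cluster gives a single-node tree", {
  loc <- matrix(1, 1, 2, dimnames = list("t", c("S1", "S2")))
  cl <- make_clusters(loc, sizes = 500L, truncal_id = "t")
  sol <- build_trees(cl)
  expect_equal(length(sol$trees), 1)
  tr <- sol$trees[[1]]
  expect_equal(nrow(tr$nodes), 1)
  expect_equal(count_bifurcations(tr), 0)
})

test_that("build_trees equals brute-force enumeration on random instances", {
  set.seed(42)
  n_checked <- 0
  for (rep in 1:60) {
    k <- sample(2:5, 1)            # non-root clusters; <= 6 total
    S <- sample(2:3, 1)
    loc <- rbind(t = rep(1, S),
                 matrix(round(runif(k * S), 2), k, S,
                        dimnames = list(letters[seq_len(k)], NULL)))
    colnames(loc) <- paste0("S", seq_len(S))
    eps <- sample(c(0, 0.05, 0.1), 1)
    expected <- sort(brute_force_trees(loc, "t", eps))
    cl <- make_clusters(loc, sizes = rep(50L, k + 1), truncal_id = "t")
    sol <- suppressWarnings(build_trees(cl, eps = eps))
    if (length(expected) > 0) {
      got <- sort(vapply(sol$trees, tree_signature, character(1)))
      expect_equal(got, expected)
      expect_equal(nrow(sol$removed), 0)
      n_checked <- n_checked + 1
    } else {
      # no tree over the full set: clusters must have been removed
      expect_gt(nrow(sol$removed), 0)
    }
  }
  expect_gt(n_checked, 15)  # the comparison must actually exercise trees
})

test_that("returned trees are ranked by consumed slack and audit clean", {
  # two valid placements for 'x': under t (slack 0.05, from the sum rule at
  # the root) or under b (slack 0.10: edge inversion in S2 plus the sum rule
  # at b); the root placement must rank first
  loc <- matrix(c(1, 1,
                  0.6, 0.5,
                  0.4, 0.55), nrow = 3, byrow = TRUE,
                dimnames = list(c("t", "b", "x"), c("S1", "S2")))
  cl <- make_clusters(loc, sizes = c(500L, 100L, 50L), truncal_id = "t")
  sol <- build_trees(cl, eps = 0.1)
  expect_equal(length(sol$trees), 2)
  expect_true(all(diff(sol$slack) >= 0))
  expect_equal(tree_signature(sol$trees[[1]]), "b<-t;x<-t")
  for (tr in sol$trees) {
    nd <- tr$nodes[!is.na(tr$nodes$parent_id), ]
    for (i in seq_len(nrow(nd))) {
      expect_true(check_dominance(loc[nd$parent_id[i], ],
                                  loc[nd$cluster_id[i], ], eps = 0.1))
    }
    for (p in unique(nd$parent_id)) {
      kids <- nd$cluster_id[nd$parent_id == p]
      expect_true(check_sum_rule(loc[p, ],
                                 lapply(kids, function(k) loc[k, ]),
                                 eps = 0.1))
    }
  }
})

test_that("an artefact cluster the root cannot dominate is removed", {
  loc <- matrix(c(1, 1,
                  0.6, 0.3,
                  0.9, 1.4), nrow = 3, byrow = TRUE,
                dimnames = list(c("t", "b", "bad"), c("S1", "S2")))
  # 'bad' exceeds the trunk in S2; with eps = 0.1 nothing can parent it
  cl <- make_clusters(loc, sizes = c(500L, 100L, 20L), truncal_id = "t")
  sol <- build_trees(cl, eps = 0.1)
  expect_equal(sol$removed$cluster_id, "bad")
  expect_gt(length(sol$trees), 0)
  expect_false("bad" %in% sol$trees[[1]]$nodes$cluster_id)
})

test_that("the enumeration bound fails loudly", {
  n <- 13
  loc <- rbind(t = c(1, 1),
               matrix(runif(2 * (n - 1), 0.1, 0.6), n - 1, 2,
                      dimnames = list(paste0("c", 1:(n - 1)), NULL)))
  colnames(loc) <- c("S1", "S2")
  cl <- make_clusters(loc, sizes = rep(50L, n), truncal_id = "t")
  expect_error(build_trees(cl), class = "clonephylo_input_error")
})

test_that("sample subtrees keep only the clones present in the sample", {
  loc <- matrix(c(1, 1, 1, 1,
                  1, 1, 0, 0,
                  0.7, 0, 0, 0,
                  0, 0, 1, 1), nrow = 4, byrow = TRUE,
                dimnames = list(c("t", "b", "d", "e"), paste0("S", 1:4)))
  cl <- make_clusters(loc, sizes = c(1000L, 100L, 80L, 100L), truncal_id = "t")
  sol <- build_trees(cl, eps = 0.05)
  tr <- sol$trees[[1]]

  s1 <- sample_subtree(tr, "S1")
  expect_setequal(s1$nodes$cluster_id, c("t", "b", "d"))
  s3 <- sample_subtree(tr, "S3")
  expect_setequal(s3$nodes$cluster_id, c("t", "e"))
  # the truncal root survives in every sample subtree
  for (s in paste0("S", 1:4)) {
    expect_true("t" %in% sample_subtree(tr, s)$nodes$cluster_id)
  }
  # an excluded intermediate re-attaches its child to a retained ancestor
  s1_no_b <- sample_subtree(tr, "S1", presence_tol = 0.99)
  expect_true(all(is.na(s1_no_b$nodes$parent_id) |
                    s1_no_b$nodes$parent_id %in% s1_no_b$nodes$cluster_id))
  expect_error(sample_subtree(tr, "S9"), class = "clonephylo_input_error")
})

test_that("drivers are annotated on their carrying branch", {
  loc <- matrix(c(1, 1,
                  0.6, 0.2), nrow = 2, byrow = TRUE,
                dimnames = list(c("t", "b"), c("S1", "S2")))
  cl <- make_clusters(loc, sizes = c(200L, 50L), truncal_id = "t")
  cl$assignments <- tibble::tibble(
    snv_id = c("v1", "v2", "v3"),
    cluster_id = c("t", "b", NA),
    prob = 1
  )
  sol <- build_trees(cl, eps = 0)
  tr <- sol$trees[[1]]
  drv <- tibble::tibble(snv_id = c("v1", "v2", "v4"),
                        gene = c("BRAF", "TP53", "PTEN"))
  out <- assign_drivers(tr, cl, drv)
  expect_equal(out$drivers$cluster_id, c("t", "b"))
  expect_equal(out$drivers$truncal, c(TRUE, FALSE))
  expect_equal(attr(out$drivers, "unplaced"), "v4")
  # empty driver list leaves the tree untouched
  expect_equal(assign_drivers(tr, cl, drv[0, ])$drivers, tr$drivers)
})

test_that("bifurcation counting distinguishes chains from branch points", {
  loc <- matrix(c(1, 1, 0.8, 0.6, 0.5, 0.3), nrow = 3, byrow = TRUE,
                dimnames = list(c("t", "a", "b"), c("S1", "S2")))
  cl <- make_clusters(loc, sizes = c(100L, 50L, 25L), truncal_id = "t")
  sol <- build_trees(cl, eps = 0)
  chains <- Filter(function(tr) {
    all(table(tr$nodes$parent_id[!is.na(tr$nodes$parent_id)]) == 1)
  }, sol$trees)
  expect_gt(length(chains), 0)
  expect_equal(count_bifurcations(chains[[1]]), 0)
})
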