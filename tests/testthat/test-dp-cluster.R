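# fast sampler settings for small fixtures
fast_cfg <- function(seed = 1) {
  cluster_config(n_iter = 600, burn_in = 300, thin = 5, seed = seed)
}

# two-sample fixture: n_shared clonal SNVs in both samples plus n_private
# SNVs at `ccf_private` in sample A only
two_cluster_ccf <- function(n_shared = 50, n_private = 50, ccf_private = 0.7,
                            seed = 1) {
  cl <- tibble::tibble(
    cluster_id = c("T", "P"), parent_id = c(NA, "T"),
    n_snvs = c(n_shared, n_private),
    A = c(1, ccf_private), B = c(1, 0)
  )
  spec <- simulation_spec(cl, c(A = 0.85, B = 0.85), seed = seed)
  sim <- simulate_reads(spec)
  list(sim = sim,
       ccf = compute_ccf(sim$reads, sim_segments(sim), sim_purities(sim)))
}

test_that("a single truncal population yields one occupied cluster", {
  cl <- tibble::tibble(cluster_id = "T", parent_id = NA_character_,
                       n_snvs = 300L, A = 1, B = 1)
  spec <- simulation_spec(cl, c(A = 0.9, B = 0.8), seed = 2)
  sim <- simulate_reads(spec)
  ccf <- compute_ccf(sim$reads, sim_segments(sim), sim_purities(sim))
  out <- dp_cluster(ccf, fast_cfg(3))
  expect_equal(nrow(out$clusters), 1)
  expect_true(out$clusters$truncal)
  expect_true(all(abs(out$locations$ccf - 1) <= 0.05))
})

test_that("50 private subclonal SNVs separate from 50 shared clonal SNVs", {
  fx <- two_cluster_ccf(seed = 4)
  out <- dp_cluster(fx$ccf, fast_cfg(4))
  expect_equal(nrow(out$clusters), 2)
  locs <- tidy(out) |>
    tidyr::pivot_wider(id_cols = cluster_id, names_from = sample_id,
                       values_from = ccf)
  trunk <- locs[locs$cluster_id == out$clusters$cluster_id[out$clusters$truncal], ]
  priv <- locs[locs$cluster_id != trunk$cluster_id, ]
  expect_equal(unlist(trunk[c("A", "B")], use.names = FALSE), c(1, 1),
               tolerance = 0.05)
  expect_equal(priv$A, 0.7, tolerance = 0.05)
  expect_lt(priv$B, 0.05)
})

test_that("the sampler is deterministic given a seed and label-stable across seeds", {
  fx <- two_cluster_ccf(seed = 6)
  a <- dp_cluster(fx$ccf, fast_cfg(7))
  b <- dp_cluster(fx$ccf, fast_cfg(7))
  expect_identical(tidy(a), tidy(b))
  expect_identical(a$assignments, b$assignments)

  # a different sampler seed relabels but keeps locations within 0.05
  c_ <- dp_cluster(fx$ccf, fast_cfg(8))
  loc_mat <- function(x) {
    w <- tidyr::pivot_wider(x$locations, id_cols = cluster_id,
                            names_from = sample_id, values_from = ccf)
    m <- as.matrix(w[-1])
    m[order(m[, 1], m[, 2]), , drop = FALSE]
  }
  expect_equal(dim(loc_mat(a)), dim(loc_mat(c_)))
  expect_true(all(abs(loc_mat(a) - loc_mat(c_)) <= 0.05))
})

test_that("assignments partition the clustered SNVs", {
  fx <- two_cluster_ccf(seed = 9)
  out <- dp_cluster(fx$ccf, fast_cfg(9))
  expect_equal(sort(unique(fx$ccf$snv_id)),
               sort(c(out$assignments$snv_id, out$excluded)))
  expect_equal(anyDuplicated(out$assignments$snv_id), 0)
  expect_true(all(out$assignments$prob >= 0 & out$assignments$prob <= 1))
  sizes <- out$assignments |> dplyr::count(cluster_id)
  expect_equal(sizes$n[match(out$clusters$cluster_id, sizes$cluster_id)],
               out$clusters$n_snvs)
})

test_that("small clusters are dropped inclusively at the threshold", {
  loc <- matrix(c(1, 1, 0.5, 0.2, 0.4, 0.1), nrow = 3, byrow = TRUE,
                dimnames = list(c("a", "b", "c"), c("S1", "S2")))
  out <- make_clusters(loc, sizes = c(985L, 10L, 5L), truncal_id = "a")
  out$assignments <- tibble::tibble(
    snv_id = sprintf("v%04d", 1:1000),
    cluster_id = rep(c("a", "b", "c"), c(985, 10, 5)),
    prob = 1
  )
  # exactly 1.0% is retained ("at least 1%"); 0.5% is dropped
  kept <- filter_small_clusters(out, min_fraction = 0.01)
  expect_equal(kept$clusters$cluster_id, c("a", "b"))
  expect_equal(sum(is.na(kept$assignments$cluster_id)), 5)
  expect_false("c" %in% kept$locations$cluster_id)
  # no-op when everything is large enough
  expect_equal(filter_small_clusters(out, 0.001)$clusters, out$clusters)
  expect_error(filter_small_clusters(out, 1),
               class = "clonephylo_input_error")
})

test_that("clonality labels follow the CCF locations per sample", {
  loc <- matrix(c(1, 1, 1, 1,
                  1, 1, 0, 0,
                  0.3, 0.3, 0.3, 0.3), nrow = 3, byrow = TRUE,
                dimnames = list(c("t", "b", "s"), paste0("S", 1:4)))
  cl <- make_clusters(loc, sizes = c(100L, 50L, 40L), truncal_id = "t")
  cl$clusters$truncal <- NULL
  out <- annotate_clonality(cl)
  lab <- function(id) out$locations$clonality[out$locations$cluster_id == id]
  expect_equal(lab("t"), rep("clonal", 4))
  expect_equal(lab("b"), c("clonal", "clonal", "absent", "absent"))
  expect_equal(lab("s"), rep("subclonal", 4))
  expect_equal(out$clusters$truncal, c(TRUE, FALSE, FALSE))
})

test_that("degenerate inputs fail loudly", {
  fx <- two_cluster_ccf(n_shared = 1, n_private = 0, seed = 1)
  expect_error(run_gibbs(fx$ccf, fast_cfg()),
               class = "clonephylo_input_error")
  expect_error(cluster_config(n_iter = 100, burn_in = 100),
               class = "clonephylo_input_error")
})
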