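test_that("mutation copy number inverts the expected-VAF relation", {
  expect_equal(mutation_copy_number(0.5, 1.0, 2, 2), 1.0)
  expect_equal(mutation_copy_number(0.25, 0.5, 2, 2), 1.0)
  expect_equal(mutation_copy_number(0.4, 0.8, 3, 2), 1.4)
  expect_error(mutation_copy_number(0.5, 0, 2, 2),
               class = "clonephylo_input_error")

  # algebraic round trip: n_mut(expected_vaf(c, m, rho)) = c * m exactly
  set.seed(4)
  for (i in 1:200) {
    ccf <- runif(1)
    m <- sample(1:3, 1)
    cnt <- sample(m:5, 1)
    rho <- runif(1, 0.1, 1)
    v <- expected_vaf(ccf, m, rho, cnt, 2)
    expect_equal(mutation_copy_number(v, rho, cnt, 2), ccf * m,
                 tolerance = 1e-12)
  }
})

test_that("with purity 1 at diploid het loci, CCF equals twice the VAF", {
  alt <- c(0L, 5L, 10L, 17L, 20L)
  depth <- rep(40L, 5)
  est <- assign_multiplicity(alt, depth, 1.0, 2, 1)
  expect_equal(est$ccf, 2 * alt / depth)
  expect_true(all(est$multiplicity == 1))
})

test_that("multiplicity is chosen by binomial maximum likelihood, with capping", {
  one <- assign_multiplicity(30, 60, 1.0, 2, 1)
  expect_equal(one$multiplicity, 1L)
  expect_equal(one$ccf, 1.0)

  # vaf 0.7 at CN 3: Binom favours m = 2 (p = 2/3) over m = 1 (p = 1/3);
  # raw ccf 2.1 / 2 = 1.05 is capped to 1
  two <- assign_multiplicity(28, 40, 1.0, 3, 2)
  expect_equal(two$multiplicity, 2L)
  expect_equal(two$ccf, 1.0)
  expect_true(two$capped)

  low <- assign_multiplicity(5, 50, 1.0, 2, 1)
  expect_equal(low$ccf, 0.2)
  expect_false(low$capped)

  expect_error(assign_multiplicity(5, 0, 1, 2, 1),
               class = "clonephylo_input_error")
  expect_error(assign_multiplicity(5, 4, 1, 2, 1),
               class = "clonephylo_input_error")
})

test_that("multiplicity matches an exhaustive-likelihood oracle on random cases", {
  set.seed(11)
  n <- 1000
  purity <- runif(n, 0.3, 1)
  cn_major <- sample(1:4, n, replace = TRUE)
  cn_minor <- vapply(cn_major, function(m) sample(0:m, 1), 0L)
  cn_tumour <- cn_major + cn_minor
  depth <- sample(10:120, n, replace = TRUE)
  true_m <- vapply(cn_major, function(m) sample(1:m, 1), 0L)
  p <- expected_vaf(runif(n), true_m, purity, cn_tumour, 2)
  alt <- rbinom(n, depth, p)
  est <- assign_multiplicity(alt, depth, purity, cn_tumour, cn_major)
  oracle <- vapply(seq_len(n), function(i) {
    ms <- seq_len(cn_major[i])
    ll <- vapply(ms, function(m) {
      pm <- min(max(expected_vaf(1, m, purity[i], cn_tumour[i], 2), 1e-9),
                1 - 1e-9)
      dbinom(alt[i], depth[i], pm, log = TRUE)
    }, 0)
    ms[which.max(ll)]
  }, 0L)
  expect_equal(est$multiplicity, oracle)
})

test_that("compute_ccf fills cells via segment lookup and flags the gaps", {
  reads <- tibble::tibble(
    snv_id = c("s1", "s1", "s2", "s2"),
    chrom = "1", pos = c(500L, 500L, 9000L, 9000L),
    ref = "A", alt = "T",
    sample_id = c("P1", "P2", "P1", "P2"),
    alt_count = c(17L, 10L, 8L, 0L), depth = c(34L, 40L, 20L, 0L)
  )
  segments <- tibble::tibble(
    sample_id = c("P1", "P2"), chrom = "1",
    start = 0L, end = c(1000L, 1000L), major_cn = 1L, minor_cn = 1L
  )
  purities <- tibble::tibble(sample_id = c("P1", "P2"), purity = c(1.0, 0.8))
  ccf <- compute_ccf(reads, segments, purities)
  expect_s3_class(ccf, "ccf_matrix")

  cell <- function(s, p) ccf[ccf$snv_id == s & ccf$sample_id == p, ]
  expect_equal(cell("s1", "P1")$ccf, 1.0)
  expect_equal(cell("s1", "P1")$multiplicity, 1L)
  # s2 lies outside every segment: flagged, no estimate
  expect_true(all(cell("s2", "P1")$missing_cn))
  expect_true(is.na(cell("s2", "P1")$ccf))
  expect_true(cell("s2", "P2")$zero_depth)
  expect_error(compute_ccf(reads, segments, purities[1, ]),
               class = "clonephylo_input_error")
})

test_that("cluster-level CCF estimates recover the generating CCFs", {
  sim <- simulate_reads(simulation_design(2, trunk_scale = 0.01, seed = 31))
  ccf <- compute_ccf(sim$reads, sim_segments(sim), sim_purities(sim))
  # uncapped per-cluster mean (mutation_cn / m is unbiased; capping is not)
  err <- ccf |>
    dplyr::inner_join(sim$truth, by = c("snv_id", "sample_id")) |>
    dplyr::filter(!is.na(mutation_cn)) |>
    dplyr::group_by(cluster_id, sample_id) |>
    dplyr::summarise(n = dplyr::n(),
                     abs_err = abs(mean(mutation_cn / multiplicity.x) -
                                     true_ccf[1]),
                     .groups = "drop") |>
    dplyr::filter(n >= 50)
  # mean absolute error across cluster x sample cells; a single 50-SNV cell
  # has standard error ~0.026, so the per-cell bound is left to 3 SE
  # (per-SNV CCF sd is at most ~0.25 at these depths and purities)
  expect_lt(mean(err$abs_err), 0.05)
  expect_true(all(err$abs_err < 3 * 0.25 / sqrt(err$n)))
})

test_that("purity is recovered from the highest-VAF density peak", {
  set.seed(8)
  uni <- pmin(pmax(rnorm(300, 0.35, 0.02), 0), 1)
  expect_equal(estimate_purity_from_vaf_peak(uni), 0.70, tolerance = 0.02)

  bi <- c(pmin(pmax(rnorm(250, 0.15, 0.02), 0), 1),
          pmin(pmax(rnorm(150, 0.35, 0.02), 0), 1))
  expect_equal(estimate_purity_from_vaf_peak(bi), 0.70, tolerance = 0.02)

  # peak near 0.5 caps at purity 1
  half <- pmin(pmax(rnorm(200, 0.52, 0.02), 0), 1)
  expect_equal(estimate_purity_from_vaf_peak(half), 1.0)

  expect_error(estimate_purity_from_vaf_peak(rep(0.3, 5)),
               class = "clonephylo_input_error")
  expect_error(estimate_purity_from_vaf_peak(rep(0, 50)),
               class = "clonephylo_input_error")
})

test_that("diploid-assumption CCFs follow 2 vaf / purity", {
  reads <- tibble::tibble(
    snv_id = c("a", "b", "c"), chrom = "1", pos = c(1L, 2L, 3L),
    ref = "A", alt = "T", sample_id = "P",
    alt_count = c(14L, 0L, 19L), depth = c(40L, 40L, 40L)
  )
  ccf <- ccf_assuming_diploid(reads, 0.7)
  expect_equal(ccf$ccf[1], 1.0)          # 0.35 * 2 / 0.7
  expect_equal(ccf$ccf[2], 0.0)
  expect_true(all(ccf$multiplicity == 1))
  expect_true(all(ccf$cn_tumour == 2))
  # analytic inversion: vaf = rho/2 * 0.27 recovers CCF 0.27
  reads27 <- tibble::tibble(snv_id = "d", chrom = "1", pos = 4L, ref = "A",
                            alt = "T", sample_id = "P",
                            alt_count = round(0.7 / 2 * 0.27 * 10000),
                            depth = 10000L)
  expect_equal(ccf_assuming_diploid(reads27, 0.7)$ccf, 0.27, tolerance = 1e-3)
})

test_that("CCF is monotone in VAF, all else equal", {
  alt <- 0:40
  est <- assign_multiplicity(alt, rep(40L, 41), 0.75, 2, 1)
  expect_true(all(diff(est$mutation_cn) > 0))
  expect_true(all(diff(est$ccf[!is.na(est$ccf)]) >= 0))
})
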