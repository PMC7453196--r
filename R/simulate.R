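#' Simulate multi-sample SNV read counts from a clone tree
#'
#' Generates per-SNV, per-sample read counts under the spec's clonal structure.
#' For every SNV and sample, sequencing depth is drawn from a Poisson with the
#' spec's mean coverage, and the mutant read count from a binomial whose
#' success rate is [expected_vaf()] of the cluster's true CCF, adjusted for the
#' sample's purity and the locus ploidy. All loci are diploid with mutation
#' multiplicity 1 unless the spec says otherwise. Depth-0 cells are retained
#' with zero alt reads. The draw is deterministic given the spec (its `seed`
#' field is used through a private RNG stream).
#'
#' @param spec A [simulation_spec()] or [simulation_design()] object.
#' @return A list of class `clone_sim`:
#' \describe{
#'   \item{reads}{Long tibble with one row per SNV x sample: `snv_id`,
#'     `chrom`, `pos` (1-based), `ref`, `alt`, `sample_id`, `alt_count`,
#'     `depth`.}
#'   \item{truth}{Ground truth, one row per SNV x sample: `snv_id`,
#'     `cluster_id`, `sample_id`, `multiplicity`, `cn_tumour`, `true_ccf`.}
#'   \item{spec}{The input spec.}
#' }
#' @examples
#' sim <- simulate_reads(simulation_design(2, trunk_scale = 0.001))
#' dplyr::count(sim$truth, cluster_id)
#' @export
simulate_reads <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  samples <- spec$samples
  n_total <- sum(spec$clusters$n_snvs)
  if (n_total == 0) {
    empty_reads <- tibble(snv_id = character(), chrom = character(),
                          pos = integer(), ref = character(), alt = character(),
                          sample_id = character(), alt_count = integer(),
                          depth = integer())
    empty_truth <- tibble(snv_id = character(), cluster_id = character(),
                          sample_id = character(), multiplicity = integer(),
                          cn_tumour = integer(), true_ccf = double())
    return(structure(list(reads = empty_reads, truth = empty_truth, spec = spec),
                     class = "clone_sim"))
  }
  withr_seed(spec$seed, {
    cluster_of <- rep(spec$clusters$cluster_id, spec$clusters$n_snvs)
    snv_id <- sprintf("snv%06d", seq_len(n_total))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_total, replace = TRUE)
    alt <- purrr::map_chr(ref, ~ sample(setdiff(bases, .x), 1))
    loci <- tibble(
      snv_id = snv_id, cluster_id = cluster_of,
      chrom = "1", pos = seq_len(n_total) * 100L, ref = ref, alt = alt,
      multiplicity = 1L, cn_tumour = spec$ploidy_tumour_locus
    )
    ccf_long <- spec$clusters %>%
      select(all_of(c("cluster_id", samples))) %>%
      tidyr::pivot_longer(all_of(samples), names_to = "sample_id",
                          values_to = "true_ccf")
    truth <- loci %>%
      tidyr::crossing(sample_id = samples) %>%
      left_join(ccf_long, by = c("cluster_id", "sample_id")) %>%
      arrange(.data$snv_id, match(.data$sample_id, samples))
    p <- expected_vaf(truth$true_ccf, truth$multiplicity,
                      spec$purity[truth$sample_id],
                      truth$cn_tumour, spec$ploidy_normal)
    depth <- rpois(nrow(truth), spec$coverage_lambda)
    alt_count <- rbinom(nrow(truth), depth, p)
    reads <- truth %>%
      select(all_of(c("snv_id", "chrom", "pos", "ref", "alt", "sample_id"))) %>%
      mutate(alt_count = alt_count, depth = depth)
    truth <- truth %>%
      select(all_of(c("snv_id", "cluster_id", "sample_id", "multiplicity",
                      "cn_tumour", "true_ccf")))
    structure(list(reads = reads, truth = truth, spec = spec),
              class = "clone_sim")
  })
}

#' @export
print.clone_sim <- function(x, ...) {
  cat(sprintf("<clone_sim> %d SNVs x %d samples (coverage ~ Poisson(%g))\n",
              n_distinct(x$reads$snv_id), length(x$spec$samples),
              x$spec$coverage_lambda))
  invisible(x)
}

#' Tables derived from a simulation, in pipeline input form
#'
#' Convenience accessors turning a `clone_sim` into the inputs the analysis
#' stages expect: diploid copy-number segments covering every simulated locus
#' for each sample, and the per-sample purity table.
#'
#' @param sim A `clone_sim` from [simulate_reads()].
#' @return `sim_segments()`: a segment tibble (`sample_id`, `chrom`, `start`,
#'   `end`, `major_cn`, `minor_cn`; 0-based half-open). `sim_purities()`: a
#'   tibble (`sample_id`, `purity`).
#' @export
sim_segments <- function(sim) {
  stopifnot(inherits(sim, "clone_sim"))
  spec <- sim$spec
  major <- as.integer(ceiling(spec$ploidy_tumour_locus / 2))
  minor <- spec$ploidy_tumour_locus - major
  span <- sim$reads %>% distinct(.data$chrom, .data$pos)
  tidyr::crossing(sample_id = spec$samples,
                  span %>% group_by(.data$chrom) %>%
                    summarise(start = 0L, end = max(.data$pos) + 1L,
                              .groups = "drop")) %>%
    mutate(major_cn = major, minor_cn = minor)
}

#' @rdname sim_segments
#' @export
sim_purities <- function(sim) {
  stopifnot(inherits(sim, "clone_sim"))
  tibble(sample_id = sim$spec$samples, purity = unname(sim$spec$purity))
}
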