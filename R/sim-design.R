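#' Expected variant allele frequency of a mutation
#'
#' Forward model linking the cancer cell fraction (CCF) of a mutation to the
#' fraction of sequencing reads expected to carry it. A mutation present in a
#' fraction `ccf` of tumour cells, on `multiplicity` of the `cn_tumour` copies
#' at its locus, in a sample of purity `purity`, is expected at
#' \deqn{VAF = \frac{m \cdot CCF \cdot \rho}{\rho \, CN_t + (1-\rho) \, CN_n}.}
#'
#' This is the success rate used by [simulate_reads()] when drawing mutant
#' reads, and its inverse underlies [mutation_copy_number()].
#'
#' @param ccf Cancer cell fraction in \[0, 1\] (vectorised).
#' @param multiplicity Number of mutated copies at the locus (<= `cn_tumour`).
#' @param purity Tumour purity \eqn{\rho} in (0, 1].
#' @param cn_tumour Total tumour copy number at the locus.
#' @param cn_normal Copy number in contaminating normal cells (2 on autosomes).
#' @return Expected VAF in \[0, 1\].
#' @examples
#' expected_vaf(1, 1, 1, 2, 2)      # clonal heterozygous, pure diploid: 0.5
#' expected_vaf(0.7, 1, 0.8, 2, 2)  # 0.28
#' @export
expected_vaf <- function(ccf, multiplicity, purity, cn_tumour = 2, cn_normal = 2) {
  if (any(ccf < 0 | ccf > 1, na.rm = TRUE)) {
    abort_input("`ccf` must lie in [0, 1]")
  }
  if (any(purity < 0 | purity > 1, na.rm = TRUE)) {
    abort_input("`purity` must lie in [0, 1]")
  }
  if (any(multiplicity > cn_tumour, na.rm = TRUE)) {
    abort_input("`multiplicity` cannot exceed `cn_tumour`")
  }
  denom <- purity * cn_tumour + (1 - purity) * cn_normal
  if (any(denom <= 0, na.rm = TRUE)) {
    abort_input("zero copies of DNA at locus (purity %s with normal CN %s)",
                purity[1], cn_normal[1])
  }
  multiplicity * ccf * purity / denom
}

#' Build a simulation specification from explicit clusters
#'
#' Defines the ground-truth clonal structure that [simulate_reads()] turns into
#' read counts: a set of mutation clusters (one truncal, i.e. carried by the
#' most recent common ancestor of all samples) with per-sample CCFs, per-sample
#' purities, and a Poisson coverage model.
#'
#' @param clusters Data frame with one row per cluster: `cluster_id`,
#'   `parent_id` (`NA` for the truncal cluster), `n_snvs`, and one numeric
#'   column per sample named in `names(purity)` giving the cluster's CCF in
#'   that sample.
#' @param purity Named numeric vector of per-sample purities in (0, 1]; the
#'   names define the sample ids.
#' @param coverage_lambda Mean sequencing depth; per-locus depth is drawn from
#'   a Poisson with this mean.
#' @param ploidy_normal,ploidy_tumour_locus Copy number in normal cells and at
#'   each simulated locus (both default 2: diploid loci).
#' @param seed Integer seed; [simulate_reads()] is deterministic given the spec.
#' @return A `sim_spec` object.
#' @seealso [simulation_design()] for the standard validation designs.
#' @export
simulation_spec <- function(clusters, purity, coverage_lambda = 34,
                            ploidy_normal = 2, ploidy_tumour_locus = 2,
                            seed = 1L) {
  samples <- names(purity)
  if (is.null(samples) || any(samples == "")) {
    abort_input("`purity` must be a named vector; names are the sample ids")
  }
  if (any(purity <= 0 | purity > 1)) {
    abort_input("purities must lie in (0, 1]")
  }
  if (coverage_lambda <= 0) abort_input("`coverage_lambda` must be positive")
  clusters <- as_tibble(clusters)
  required <- c("cluster_id", "parent_id", "n_snvs", samples)
  missing_cols <- setdiff(required, names(clusters))
  if (length(missing_cols) > 0) {
    abort_input("`clusters` is missing columns: %s",
                paste(missing_cols, collapse = ", "))
  }
  if (any(clusters$n_snvs < 0)) abort_input("cluster sizes must be >= 0")
  ccf <- as.matrix(clusters[samples])
  if (any(ccf < 0 | ccf > 1)) abort_input("cluster CCFs must lie in [0, 1]")
  root <- is.na(clusters$parent_id)
  if (sum(root) != 1) {
    abort_input("exactly one cluster must be truncal (parent_id = NA); found %d",
                sum(root))
  }
  if (any(ccf[root, ] != 1)) {
    abort_input("the truncal cluster must have CCF 1 in every sample")
  }
  # infinite-sites dominance: a child cannot exceed its parent in any sample
  idx <- setNames(seq_len(nrow(clusters)), clusters$cluster_id)
  for (i in which(!root)) {
    p <- idx[[clusters$parent_id[i]]]
    if (is.null(p)) abort_input("unknown parent '%s'", clusters$parent_id[i])
    if (any(ccf[i, ] > ccf[p, ] + 1e-12)) {
      abort_input("cluster '%s' exceeds its parent's CCF in some sample",
                  clusters$cluster_id[i])
    }
  }
  structure(
    list(
      clusters = clusters,
      samples = samples,
      purity = purity,
      coverage_lambda = coverage_lambda,
      ploidy_normal = as.integer(ploidy_normal),
      ploidy_tumour_locus = as.integer(ploidy_tumour_locus),
      seed = as.integer(seed)
    ),
    class = "sim_spec"
  )
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf(
    "<sim_spec> %d clusters, %d samples, %s SNVs, coverage ~ Poisson(%g), seed %d\n",
    nrow(x$clusters), length(x$samples),
    format(sum(x$clusters$n_snvs), big.mark = ","),
    x$coverage_lambda, x$seed
  ))
  print(x$clusters, ...)
  invisible(x)
}

#' Standard multi-metastasis validation designs
#'
#' Six fixed designs used to validate cluster and tree recovery on data with a
#' known clonal structure: four samples, Poisson(34) coverage, per-sample
#' purities drawn uniformly in \[0.7, 0.95\]. Design 1 is truncal-only
#' (a trunk of 100,000 SNVs, no branches). Designs 2-6 add six non-truncal
#' clusters arranged as three bifurcations: a first bifurcation of two
#' mutually exclusive clonal clusters (CCF 1 in samples 1-2 and 0 in 3-4, and
#' vice versa), then under each a pair of second-step subclones, one at mean
#' CCF 0.7 and one at 0.3, each unique to a single sample. Every branch carries
#' the same burden: 50, 100, 150, 200 or 500 SNVs for designs 2-6, so totals
#' range from 100,300 to 103,000 SNVs.
#'
#' @param design Integer 1-6 selecting the design.
#' @param trunk_scale Scale factor applied to the trunk only (branch burdens
#'   are untouched), so the proportional structure can be tightened for small
#'   runs; e.g. `trunk_scale = 0.05` gives a 5,000-SNV trunk.
#' @param purity Optional named per-sample purity vector overriding the drawn
#'   values.
#' @param seed Seed stored in the spec; also used to draw the purities.
#' @return A [simulation_spec()] object.
#' @examples
#' simulation_design(2)$clusters    # trunk + six branch clusters
#' sum(simulation_design(6)$clusters$n_snvs)  # 103000
#' @export
simulation_design <- function(design, trunk_scale = 1, purity = NULL, seed = 1L) {
  if (length(design) != 1 || !design %in% 1:6) {
    abort_input("`design` must be a single integer in 1..6")
  }
  n_trunk <- as.integer(round(100000 * trunk_scale))
  samples <- paste0("S", 1:4)
  if (is.null(purity)) {
    purity <- withr_seed(seed, setNames(runif(4, 0.7, 0.95), samples))
  }
  trunk <- tibble(cluster_id = "T", parent_id = NA_character_, n_snvs = n_trunk,
                  S1 = 1, S2 = 1, S3 = 1, S4 = 1)
  if (design == 1) {
    cl <- trunk
  } else {
    burden <- c(50L, 100L, 150L, 200L, 500L)[design - 1]
    cl <- bind_rows(
      trunk,
      tibble(cluster_id = "B", parent_id = "T", n_snvs = burden,
             S1 = 1, S2 = 1, S3 = 0, S4 = 0),
      tibble(cluster_id = "C", parent_id = "T", n_snvs = burden,
             S1 = 0, S2 = 0, S3 = 1, S4 = 1),
      tibble(cluster_id = "D", parent_id = "B", n_snvs = burden,
             S1 = 0.7, S2 = 0, S3 = 0, S4 = 0),
      tibble(cluster_id = "E", parent_id = "B", n_snvs = burden,
             S1 = 0, S2 = 0.3, S3 = 0, S4 = 0),
      tibble(cluster_id = "F", parent_id = "C", n_snvs = burden,
             S1 = 0, S2 = 0, S3 = 0.7, S4 = 0),
      tibble(cluster_id = "G", parent_id = "C", n_snvs = burden,
             S1 = 0, S2 = 0, S3 = 0, S4 = 0.3)
    )
  }
  simulation_spec(cl, purity = purity, coverage_lambda = 34, seed = seed)
}

# evaluate `expr` under a temporary seed without disturbing the global RNG
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Serialise / restore a simulation specification
#'
#' Writes the spec as a YAML document (documented keys: `samples`, `purity`,
#' `coverage_lambda`, `ploidy_normal`, `ploidy_tumour_locus`, `seed`,
#' `clusters` with per-sample `ccf` maps) and reads it back.
#'
#' @param spec A `sim_spec` object.
#' @param path File path.
#' @return `read_sim_spec()` returns the restored `sim_spec`;
#'   `write_sim_spec()` returns `path` invisibly.
#' @export
write_sim_spec <- function(spec, path) {
  stopifnot(inherits(spec, "sim_spec"))
  cl <- purrr::pmap(spec$clusters, function(cluster_id, parent_id, n_snvs, ...) {
    list(cluster_id = cluster_id,
         parent_id = if (is.na(parent_id)) NULL else parent_id,
         n_snvs = n_snvs,
         ccf = list(...))
  })
  yaml::write_yaml(list(
    samples = as.list(spec$samples),
    purity = as.list(spec$purity),
    coverage_lambda = spec$coverage_lambda,
    ploidy_normal = spec$ploidy_normal,
    ploidy_tumour_locus = spec$ploidy_tumour_locus,
    seed = spec$seed,
    clusters = cl
  ), path, precision = 12)
  invisible(path)
}

#' @rdname write_sim_spec
#' @export
read_sim_spec <- function(path) {
  y <- yaml::read_yaml(path)
  samples <- unlist(y$samples)
  clusters <- purrr::map_dfr(y$clusters, function(cl) {
    ccf <- unlist(cl$ccf)[samples]
    tibble(cluster_id = cl$cluster_id,
           parent_id = cl$parent_id %||% NA_character_,
           n_snvs = as.integer(cl$n_snvs),
           !!!as.list(ccf))
  })
  simulation_spec(clusters,
                  purity = unlist(y$purity)[samples],
                  coverage_lambda = y$coverage_lambda,
                  ploidy_normal = y$ploidy_normal %||% 2L,
                  ploidy_tumour_locus = y$ploidy_tumour_locus %||% 2L,
                  seed = y$seed %||% 1L)
}
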