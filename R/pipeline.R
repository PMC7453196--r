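#' Configure an end-to-end clonality analysis
#'
#' Collects input locations and stage parameters for [run_pipeline()]. Either
#' give file paths (`reads`, `segments`, `purities` as written by the package
#' readers/writers) or pass the corresponding tibbles directly.
#'
#' @param reads Path to an SNV table (TSV or VCF) or a long reads tibble.
#' @param segments Path to a segment TSV or a segment tibble.
#' @param purities Path to a purity TSV or a purity tibble.
#' @param drivers Optional driver table (`snv_id`, `gene`) or path.
#' @param cluster A [cluster_config()].
#' @param tree_eps CCF tolerance for the tree rules (default 0.1).
#' @param min_fraction Small-cluster threshold (default 0.01).
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing files.
#' @param seed Seed recorded in outputs and used for clustering (overrides
#'   `cluster$seed`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(reads, segments, purities, drivers = NULL,
                            cluster = cluster_config(), tree_eps = 0.1,
                            min_fraction = 0.01, out_dir = NULL, seed = 1L) {
  structure(list(reads = reads, segments = segments, purities = purities,
                 drivers = drivers, cluster = cluster, tree_eps = tree_eps,
                 min_fraction = min_fraction, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the [pipeline_config()] arguments; `cluster` is a map of
#' [cluster_config()] arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cl <- do.call(cluster_config, y$cluster %||% list())
  pipeline_config(reads = y$reads, segments = y$segments,
                  purities = y$purities, drivers = y$drivers,
                  cluster = cl, tree_eps = y$tree_eps %||% 0.1,
                  min_fraction = y$min_fraction %||% 0.01,
                  out_dir = y$out_dir, seed = y$seed %||% 1L)
}

#' Run the full clonality pipeline
#'
#' Executes the three analysis steps in order — (1) CCF estimation for every
#' SNV from read counts, copy number and purity; (2) pseudo-heterogeneity
#' filtering and Dirichlet-process clustering of SNVs across samples;
#' (3) clone-tree reconstruction under the sum and crossing rules — followed
#' by per-sample subtrees and driver placement. Any stage failure aborts with
#' the stage name and cause. When `out_dir` is set, writes the cluster
#' assignment TSV, filter report TSV, tree Newick + JSON sidecar, and a run
#' log recording the seed and resolved parameters so the run can be
#' reproduced from the log alone.
#'
#' @param cfg A [pipeline_config()].
#' @return List of class `clone_pipeline`: `ccf`, `filter_report`,
#'   `clusters` (after small-cluster filtering and clonality annotation),
#'   `solutions` (all valid trees, ranked), `tree` (the top-ranked tree with
#'   drivers placed), and `log` (character vector).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  log <- c(sprintf("clonephylo %s", as.character(utils::packageVersion("clonephylo"))),
           sprintf("seed: %d", cfg$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)),
                   class = "clonephylo_pipeline_error")
    })
  }
  reads <- stage("read-inputs", load_table(cfg$reads, read_snv_table))
  segments <- stage("read-inputs", load_table(cfg$segments, read_copy_number_segments))
  purities <- stage("read-inputs", load_table(cfg$purities, read_sample_purity))
  drivers <- if (is.null(cfg$drivers)) NULL else {
    stage("read-inputs", load_table(cfg$drivers, function(p) {
      readr::read_tsv(p, comment = "#", show_col_types = FALSE)
    }))
  }

  ccf <- stage("ccf", compute_ccf(reads, segments, purities))
  cna_mask <- stage("filter", cna_consistent_loci(reads, segments))
  ccf_cons <- ccf %>% semi_join(cna_mask %>% filter(.data$keep), by = "snv_id")
  class(ccf_cons) <- class(ccf)
  flt <- stage("filter", filter_pseudo_heterogeneity(ccf_cons))
  report <- bind_rows(
    cna_mask %>% filter(!.data$keep),
    flt$report
  ) %>%
    group_by(.data$snv_id) %>% slice(1) %>% ungroup()
  log <- c(log, sprintf("filter: %d of %d SNVs removed",
                        sum(!report$keep), n_distinct(ccf$snv_id)))

  cl_cfg <- cfg$cluster
  cl_cfg$seed <- cfg$seed
  clusters <- stage("cluster", dp_cluster(flt$ccf, cl_cfg)) %>%
    filter_small_clusters(cfg$min_fraction) %>%
    annotate_clonality(cl_cfg$clonal_tol, cl_cfg$absence_tol)
  log <- c(log, sprintf("cluster: %d clusters (iter %d, burn %d, thin %d, K %d)",
                        nrow(clusters$clusters), cl_cfg$n_iter, cl_cfg$burn_in,
                        cl_cfg$thin, cl_cfg$max_clusters))

  solutions <- stage("tree", build_trees(clusters, eps = cfg$tree_eps))
  if (length(solutions$trees) == 0) {
    rlang::abort("pipeline stage 'tree' failed: no valid tree",
                 class = "clonephylo_pipeline_error")
  }
  tree <- solutions$trees[[1]]
  if (!is.null(drivers)) {
    tree <- stage("drivers", assign_drivers(tree, clusters, drivers))
  }
  log <- c(log, sprintf("tree: %d solution(s); top tree has %d bifurcation(s); eps %g",
                        length(solutions$trees), count_bifurcations(tree),
                        cfg$tree_eps))

  out <- structure(list(ccf = ccf, filter_report = report, clusters = clusters,
                        solutions = solutions, tree = tree, log = log),
                   class = "clone_pipeline")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cluster_assignments(clusters, file.path(cfg$out_dir, "clusters.tsv"))
    writeLines("# pseudo-heterogeneity / CNA-consistency filter report",
               file.path(cfg$out_dir, "filter_report.tsv"))
    readr::write_tsv(report, file.path(cfg$out_dir, "filter_report.tsv"),
                     append = TRUE, col_names = TRUE)
    write_tree_bundle(tree, file.path(cfg$out_dir, "tree"))
    writeLines(log, file.path(cfg$out_dir, "run_log.txt"))
  }
  out
}

load_table <- function(x, reader) {
  if (is.character(x) && length(x) == 1) reader(x) else as_tibble(x)
}

#' @export
print.clone_pipeline <- function(x, ...) {
  cat("<clone_pipeline>\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}
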