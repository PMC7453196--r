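#' Configuration for Dirichlet-process CCF clustering
#'
#' Settings for the truncated stick-breaking Gibbs sampler and the cluster
#' post-processing. Defaults are sized for whole-genome style inputs (a few
#' thousand SNVs, a handful of samples).
#'
#' @param n_iter Total Gibbs sweeps (default 2000).
#' @param burn_in Sweeps discarded before recording (default 1000).
#' @param thin Keep every `thin`-th sweep after burn-in (default 10).
#' @param max_clusters Truncation level of the stick-breaking representation
#'   (default 30; must be at least the number of clusters expected).
#' @param alpha_prior Shape and rate of the Gamma prior on the DP
#'   concentration, resampled every sweep (default `c(1, 1)`).
#' @param theta_max Upper end of the component-CCF support; slightly above 1
#'   so clonal mass is not squeezed against the boundary before the summary
#'   caps locations at 1 (default 1.2).
#' @param grid_step Resolution of the griddy-Gibbs grid over
#'   `[0, theta_max]` used to sample component CCFs (default 0.02).
#' @param merge_tol Components whose posterior locations differ by at most
#'   this much in every sample are merged into one cluster (default 0.05).
#' @param min_snvs Minimum number of modally assigned SNVs for a component
#'   group to be called a cluster (default 5); smaller groups are outlier
#'   traps rather than posterior-density peaks, and their SNVs are
#'   reassigned to the best remaining cluster.
#' @param min_fraction Minimum fraction of clustered SNVs a cluster must hold
#'   to survive [filter_small_clusters()] (default 0.01).
#' @param clonal_tol,absence_tol Clonality calling tolerances used by
#'   [annotate_clonality()]: clonal when `|CCF - 1| <= clonal_tol` (0.1),
#'   absent when `CCF <= absence_tol` (0.05).
#' @param seed RNG seed for the sampler and its k-means initialisation.
#' @return A `cluster_config` list.
#' @export
cluster_config <- function(n_iter = 2000, burn_in = 1000, thin = 10,
                           max_clusters = 30, alpha_prior = c(1, 1),
                           theta_max = 1.2, grid_step = 0.02,
                           merge_tol = 0.05, min_snvs = 5L,
                           min_fraction = 0.01, clonal_tol = 0.1,
                           absence_tol = 0.05, seed = 1L) {
  if (burn_in >= n_iter) abort_input("`burn_in` must be smaller than `n_iter`")
  if (max_clusters < 2) abort_input("`max_clusters` must be >= 2")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), max_clusters = as.integer(max_clusters),
                 alpha_prior = alpha_prior, theta_max = theta_max,
                 grid_step = grid_step, merge_tol = merge_tol,
                 min_snvs = as.integer(min_snvs),
                 min_fraction = min_fraction, clonal_tol = clonal_tol,
                 absence_tol = absence_tol, seed = as.integer(seed)),
            class = "cluster_config")
}

#' Sample the multidimensional Dirichlet-process mixture posterior
#'
#' Clusters SNVs by their CCFs jointly across all samples of a patient with a
#' Dirichlet-process binomial mixture, sampled by Gibbs under a truncated
#' stick-breaking representation. The likelihood is evaluated on the raw read
#' counts: an SNV assigned to component \eqn{k} contributes, in each sample
#' \eqn{s}, \eqn{alt \sim Binom(depth, \theta_{ks} \cdot c)} where
#' \eqn{\theta_{ks}} is the component CCF and \eqn{c} the purity/copy-number
#' factor of [expected_vaf()] — so deep sites weigh more than shallow ones,
#' and CCF point estimates are used only to initialise (k-means) and report.
#' Component CCFs carry independent Uniform(0, `theta_max`) priors; the DP
#' concentration is resampled each sweep under a Gamma prior.
#'
#' Cells flagged `missing_cn` or `zero_depth` are excluded from the
#' likelihood; SNVs flagged `implausible` in any sample (CCF > 1.5) are
#' excluded from clustering altogether.
#'
#' @param ccf A `ccf_matrix` from [compute_ccf()] or [ccf_assuming_diploid()].
#' @param config A [cluster_config()].
#' @return A `dp_trace` object holding the thinned posterior draws of
#'   component locations and assignments.
#' @seealso [call_clusters()] to summarise the trace into clusters;
#'   [dp_cluster()] for the one-call wrapper.
#' @export
run_gibbs <- function(ccf, config = cluster_config()) {
  stopifnot(inherits(ccf, "ccf_matrix"))
  samples <- unique(ccf$sample_id)
  bad <- ccf %>% filter(.data$implausible) %>% distinct(.data$snv_id)
  x <- ccf %>%
    anti_join(bad, by = "snv_id") %>%
    mutate(
      usable = !.data$missing_cn & !.data$zero_depth,
      cfac = ifelse(.data$usable,
                    expected_vaf(1, .data$multiplicity, .data$purity,
                                 .data$cn_tumour, 2),
                    NA_real_)
    )
  usable_snvs <- x %>%
    group_by(.data$snv_id) %>%
    summarise(any_usable = any(.data$usable), .groups = "drop") %>%
    filter(.data$any_usable)
  x <- x %>% semi_join(usable_snvs, by = "snv_id")
  snv_ids <- unique(x$snv_id)
  n <- length(snv_ids)
  if (n < 2) abort_input("need at least 2 SNVs with usable cells to cluster")

  wide <- function(col, fill) {
    m <- x %>%
      select(all_of(c("snv_id", "sample_id", col))) %>%
      tidyr::pivot_wider(names_from = "sample_id", values_from = all_of(col)) %>%
      arrange(match(.data$snv_id, snv_ids))
    mm <- as.matrix(m[samples])
    mm[is.na(mm)] <- fill
    mm
  }
  alt_m <- wide("alt_count", 0L)
  dep_m <- wide("depth", 0L)
  cfac_m <- wide("cfac", NA_real_)
  # unique conversion factors index the precomputed likelihood tables
  ufac <- sort(unique(cfac_m[!is.na(cfac_m)]))
  cidx <- matrix(-1L, n, length(samples))
  ok <- !is.na(cfac_m)
  cidx[ok] <- match(cfac_m[ok], ufac) - 1L
  storage.mode(alt_m) <- "integer"
  storage.mode(dep_m) <- "integer"
  storage.mode(cidx) <- "integer"

  K <- config$max_clusters
  grid <- seq(0, config$theta_max, by = config$grid_step)
  withr_seed(config$seed, {
    ccf_pts <- wide("ccf", 0)
    ccf_pts <- pmin(ccf_pts, config$theta_max)
    k0 <- min(K, max(1L, nrow(unique(round(ccf_pts, 3)))))
    z0 <- if (k0 > 1) {
      kmeans(ccf_pts, centers = k0, nstart = 1, iter.max = 30)$cluster - 1L
    } else {
      rep(0L, n)
    }
    raw <- gibbs_dp_binom(alt_m, dep_m, cidx, ufac, K,
                          config$n_iter, config$burn_in, config$thin,
                          config$alpha_prior[1], config$alpha_prior[2],
                          grid, as.integer(z0))
    structure(list(theta = raw$theta, z = raw$z, alpha = raw$alpha,
                   snv_ids = snv_ids, samples = samples,
                   excluded = bad$snv_id, config = config),
              class = "dp_trace")
  })
}

#' @export
print.dp_trace <- function(x, ...) {
  cat(sprintf("<dp_trace> %d SNVs x %d samples, %d retained sweeps (K = %d)\n",
              length(x$snv_ids), length(x$samples), nrow(x$z),
              x$config$max_clusters))
  invisible(x)
}

#' Call mutation clusters from a posterior trace
#'
#' Summarises the Gibbs trace into discrete clusters: each occupied component
#' is located at its posterior median CCF per sample (over the sweeps in
#' which it held at least one SNV), components whose locations agree within
#' `merge_tol` in every sample are merged, each SNV is assigned to its
#' maximum-posterior cluster, and locations are capped into \[0, 1\].
#' Component groups modally holding fewer than `min_snvs` SNVs are not
#' called (an outlier trap is not a density peak); their SNVs are
#' reassigned. Clusters are labelled `cl1`, `cl2`, ... in decreasing size
#' order.
#'
#' @param trace A `dp_trace` from [run_gibbs()].
#' @param config A [cluster_config()]; only `merge_tol` and `min_snvs` are
#'   used here.
#' @return A `clone_clusters` object: list with `clusters` (tibble
#'   `cluster_id`, `n_snvs`), `locations` (tibble `cluster_id`, `sample_id`,
#'   `ccf`), and `assignments` (tibble `snv_id`, `cluster_id`, `prob`).
#' @export
call_clusters <- function(trace, config = trace$config) {
  stopifnot(inherits(trace, "dp_trace"))
  n_keep <- nrow(trace$z)
  if (n_keep < 1) abort_input("empty trace: no retained sweeps")
  n <- length(trace$snv_ids)
  S <- length(trace$samples)
  K <- dim(trace$theta)[2]

  # posterior assignment probabilities per SNV x component
  prob <- matrix(0, n, K)
  for (t in seq_len(n_keep)) {
    zt <- trace$z[t, ]
    prob[cbind(seq_len(n), zt)] <- prob[cbind(seq_len(n), zt)] + 1
  }
  prob <- prob / n_keep

  # occupancy-conditional posterior median location per component
  loc <- matrix(NA_real_, K, S)
  for (k in seq_len(K)) {
    occ <- vapply(seq_len(n_keep), function(t) any(trace$z[t, ] == k), logical(1))
    if (!any(occ)) next
    th <- trace$theta[, k, occ, drop = FALSE]  # S x 1 x T_occ
    loc[k, ] <- apply(th, 1, median)
  }
  hard <- max.col(prob, ties.method = "first")
  occupied <- sort(unique(hard))

  # merge components indistinguishable in every sample
  groups <- as.list(occupied)
  repeat {
    merged <- FALSE
    for (a in seq_along(groups)) {
      for (b in seq_along(groups)) {
        if (b <= a) next
        la <- group_location(groups[[a]], loc, prob, hard)
        lb <- group_location(groups[[b]], loc, prob, hard)
        if (all(abs(la - lb) <= config$merge_tol)) {
          groups[[a]] <- c(groups[[a]], groups[[b]])
          groups[[b]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }

  # group-level posterior membership and modal assignment
  gp <- vapply(groups, function(g) rowSums(prob[, g, drop = FALSE]),
               numeric(n))
  gp <- matrix(gp, nrow = n)
  hard_g <- max.col(gp, ties.method = "first")
  sizes <- tabulate(hard_g, nbins = length(groups))

  # a posterior-density peak needs minimal support: components holding fewer
  # than min_snvs SNVs at the mode are outlier traps, not clusters; their
  # SNVs go to the best-supported remaining cluster
  keep <- sizes >= config$min_snvs
  if (!any(keep)) keep[which.max(sizes)] <- TRUE
  groups <- groups[keep]
  gp <- gp[, keep, drop = FALSE]
  hard_g <- max.col(gp, ties.method = "first")
  sizes <- tabulate(hard_g, nbins = length(groups))

  ord <- order(sizes, decreasing = TRUE)
  groups <- groups[ord]
  gp <- gp[, ord, drop = FALSE]
  hard_g <- match(hard_g, ord)
  sizes <- sizes[ord]
  ids <- paste0("cl", seq_along(groups))

  locations <- purrr::map2_dfr(groups, ids, function(g, id) {
    tibble(cluster_id = id, sample_id = trace$samples,
           ccf = pmin(1, pmax(0, group_location(g, loc, prob, hard))))
  })
  assignments <- tibble(
    snv_id = trace$snv_ids,
    cluster_id = ids[hard_g],
    prob = gp[cbind(seq_len(n), hard_g)]
  )
  structure(list(clusters = tibble(cluster_id = ids, n_snvs = sizes),
                 locations = locations, assignments = assignments,
                 samples = trace$samples, excluded = trace$excluded),
            class = "clone_clusters")
}

# size-weighted mean location of a merge group of components
group_location <- function(comps, loc, prob, hard) {
  w <- vapply(comps, function(k) max(1L, sum(hard == k)), integer(1))
  if (length(comps) == 1) return(loc[comps[[1]], ])
  colSums(loc[unlist(comps), , drop = FALSE] * w) / sum(w)
}

#' Drop clusters below a minimum share of clustered SNVs
#'
#' Downstream tree reconstruction uses clusters representing at least a fixed
#' fraction (default 1%) of the clustered SNVs; smaller clusters are dropped
#' and their SNVs marked unassigned (`cluster_id = NA`). The threshold is
#' inclusive: a cluster holding exactly the minimum fraction is retained.
#'
#' @param clusters A `clone_clusters` object.
#' @param min_fraction Minimum fraction in \[0, 1) (default 0.01).
#' @return The filtered `clone_clusters`.
#' @export
filter_small_clusters <- function(clusters, min_fraction = 0.01) {
  stopifnot(inherits(clusters, "clone_clusters"))
  if (min_fraction < 0 || min_fraction >= 1) {
    abort_input("`min_fraction` must lie in [0, 1)")
  }
  total <- sum(clusters$clusters$n_snvs)
  keep <- clusters$clusters %>% filter(.data$n_snvs / total >= min_fraction)
  dropped <- setdiff(clusters$clusters$cluster_id, keep$cluster_id)
  clusters$clusters <- keep
  clusters$locations <- clusters$locations %>%
    filter(.data$cluster_id %in% keep$cluster_id)
  clusters$assignments <- clusters$assignments %>%
    mutate(cluster_id = ifelse(.data$cluster_id %in% dropped,
                               NA_character_, .data$cluster_id))
  clusters
}

#' Label clusters clonal, subclonal or absent per sample
#'
#' Within each sample a cluster is clonal if its CCF is within `clonal_tol`
#' of 1, absent if at or below `absence_tol`, and subclonal otherwise. A
#' cluster clonal in every sample is truncal: it sits on the trunk, carried
#' by the most recent common ancestor of all sampled tumour cells.
#'
#' @param clusters A `clone_clusters` object.
#' @param clonal_tol,absence_tol Tolerances (defaults 0.1 and 0.05).
#' @return The `clone_clusters` with a `clonality` column added to
#'   `$locations` and a `truncal` flag added to `$clusters`.
#' @export
annotate_clonality <- function(clusters, clonal_tol = 0.1, absence_tol = 0.05) {
  stopifnot(inherits(clusters, "clone_clusters"))
  clusters$locations <- clusters$locations %>%
    mutate(clonality = case_when(
      abs(.data$ccf - 1) <= clonal_tol ~ "clonal",
      .data$ccf <= absence_tol ~ "absent",
      TRUE ~ "subclonal"
    ))
  truncal <- clusters$locations %>%
    group_by(.data$cluster_id) %>%
    summarise(truncal = all(.data$clonality == "clonal"), .groups = "drop")
  clusters$clusters <- clusters$clusters %>%
    select(-any_of("truncal")) %>%
    left_join(truncal, by = "cluster_id")
  clusters
}

#' One-call subclonal deconvolution
#'
#' Runs [run_gibbs()], [call_clusters()] and [annotate_clonality()] in
#' sequence.
#'
#' @inheritParams run_gibbs
#' @return An annotated `clone_clusters` object.
#' @export
dp_cluster <- function(ccf, config = cluster_config()) {
  trace <- run_gibbs(ccf, config)
  call_clusters(trace, config) %>%
    annotate_clonality(config$clonal_tol, config$absence_tol)
}

#' @export
print.clone_clusters <- function(x, ...) {
  cat(sprintf("<clone_clusters> %d clusters over %d samples, %d SNVs assigned\n",
              nrow(x$clusters), length(x$samples),
              sum(!is.na(x$assignments$cluster_id))))
  print(tidy(x), ...)
  invisible(x)
}

#' @describeIn dp_cluster Tidy a `clone_clusters`: one row per cluster x
#'   sample with size, CCF location and (if annotated) clonality.
#' @param x A `clone_clusters` object.
#' @param ... Unused.
#' @method tidy clone_clusters
#' @export
tidy.clone_clusters <- function(x, ...) {
  x$locations %>% left_join(x$clusters, by = "cluster_id")
}

#' @describeIn dp_cluster One-row summary: number of clusters, clustered and
#'   unassigned SNVs, truncal cluster id if annotated.
#' @method glance clone_clusters
#' @export
glance.clone_clusters <- function(x, ...) {
  truncal_id <- if ("truncal" %in% names(x$clusters)) {
    id <- x$clusters$cluster_id[which(x$clusters$truncal)]
    if (length(id) == 1) id else NA_character_
  } else NA_character_
  tibble(
    n_clusters = nrow(x$clusters),
    n_snvs = sum(!is.na(x$assignments$cluster_id)),
    n_unassigned = sum(is.na(x$assignments$cluster_id)),
    n_excluded = length(x$excluded),
    truncal_cluster = truncal_id
  )
}
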