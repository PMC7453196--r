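# Shared fixtures. Heavy simulation-recovery runs are cached per (design,
# seed) so several test files can interrogate the same posterior without
# re-running the sampler.

.run_cache <- new.env(parent = emptyenv())

# simulate a design at desk scale (trunk 5,000), estimate CCFs, cluster
recovery_run <- function(design, seed = 100 + design, trunk_scale = 0.05) {
  key <- sprintf("d%d_s%d_t%s", design, seed, trunk_scale)
  if (!is.null(.run_cache[[key]])) {
    return(.run_cache[[key]])
  }
  sim <- simulate_reads(simulation_design(design, trunk_scale = trunk_scale,
                                          seed = seed))
  ccf <- compute_ccf(sim$reads, sim_segments(sim), sim_purities(sim))
  clusters <- dp_cluster(ccf, cluster_config(seed = seed))
  res <- list(sim = sim, ccf = ccf, clusters = clusters)
  .run_cache[[key]] <- res
  res
}

# truth CCF per cluster x sample for a sim
truth_locations <- function(sim) {
  sim$spec$clusters |>
    tidyr::pivot_longer(dplyr::all_of(sim$spec$samples),
                        names_to = "sample_id", values_to = "true_ccf") |>
    dplyr::select(cluster_id, parent_id, sample_id, true_ccf)
}

# match each called cluster to the nearest truth cluster (euclidean on the
# per-sample location vectors); returns tibble(cluster_id, true_id, dist)
match_clusters_to_truth <- function(clusters, sim) {
  tl <- truth_locations(sim) |>
    tidyr::pivot_wider(id_cols = cluster_id, names_from = sample_id,
                       values_from = true_ccf)
  tm <- as.matrix(tl[sim$spec$samples])
  cl <- clusters$locations |>
    tidyr::pivot_wider(id_cols = cluster_id, names_from = sample_id,
                       values_from = ccf)
  cm <- as.matrix(cl[sim$spec$samples])
  idx <- apply(cm, 1, function(v) which.min(colSums((t(tm) - v)^2)))
  tibble::tibble(
    cluster_id = cl$cluster_id,
    true_id = tl$cluster_id[idx],
    dist = sqrt(vapply(seq_along(idx),
                       function(i) sum((cm[i, ] - tm[idx[i], ])^2), 0))
  )
}

# hand-build a clone_clusters object from a location matrix (rows = clusters)
make_clusters <- function(ccf_mat, sizes, truncal_id) {
  samples <- colnames(ccf_mat)
  ids <- rownames(ccf_mat)
  locations <- tibble::tibble(
    cluster_id = rep(ids, each = length(samples)),
    sample_id = rep(samples, length(ids)),
    ccf = as.vector(t(ccf_mat))
  )
  structure(list(
    clusters = tibble::tibble(cluster_id = ids, n_snvs = sizes,
                              truncal = ids == truncal_id),
    locations = locations,
    assignments = tibble::tibble(snv_id = character(),
                                 cluster_id = character(), prob = double()),
    samples = samples, excluded = character(0)
  ), class = "clone_clusters")
}

# parent vector (child -> parent) of a clone_tree, canonical string form
tree_signature <- function(tree) {
  nd <- tree$nodes[!is.na(tree$nodes$parent_id), ]
  nd <- nd[order(nd$cluster_id), ]
  paste(nd$cluster_id, nd$parent_id, sep = "<-", collapse = ";")
}

# Independent brute-force clone-tree enumeration: try every parent
# assignment, test acyclicity and the three CCF rules with direct
# arithmetic (no shared code with build_trees' pruned search).
brute_force_trees <- function(ccf_mat, root_id, eps) {
  ids <- rownames(ccf_mat)
  children <- setdiff(ids, root_id)
  n <- length(children)
  if (n == 0) {
    return("")
  }
  combos <- expand.grid(rep(list(ids), n), stringsAsFactors = FALSE)
  sigs <- character(0)
  for (r in seq_len(nrow(combos))) {
    parent <- stats::setNames(as.character(combos[r, ]), children)
    if (any(parent == children)) next
    # acyclicity: every child must reach the root
    ok <- TRUE
    for (ch in children) {
      node <- ch
      steps <- 0
      while (node != root_id) {
        node <- parent[[node]]
        steps <- steps + 1
        if (steps > n + 1) {
          ok <- FALSE
          break
        }
      }
      if (!ok) break
    }
    if (!ok) next
    # edge dominance
    for (ch in children) {
      p <- parent[[ch]]
      if (!(all(ccf_mat[p, ] >= ccf_mat[ch, ] - eps) &&
              any(ccf_mat[p, ] > ccf_mat[ch, ] + eps))) {
        ok <- FALSE
        break
      }
    }
    if (!ok) next
    # sum rule at every parent
    for (p in unique(parent)) {
      sibs <- names(parent)[parent == p]
      if (any(colSums(ccf_mat[sibs, , drop = FALSE]) > ccf_mat[p, ] + eps)) {
        ok <- FALSE
        break
      }
    }
    if (!ok) next
    # crossing rule: CCF-crossing pairs may not be ancestrally related
    anc <- function(x) {
      out <- character(0)
      while (x != root_id) {
        x <- parent[[x]]
        out <- c(out, x)
      }
      out
    }
    for (a in ids) {
      for (b in ids) {
        if (a >= b) next
        crossing <- any(ccf_mat[a, ] > ccf_mat[b, ] + eps) &&
          any(ccf_mat[b, ] > ccf_mat[a, ] + eps)
        if (crossing &&
            (a %in% c(if (b != root_id) anc(b)) ||
               b %in% c(if (a != root_id) anc(a)))) {
          ok <- FALSE
          break
        }
      }
      if (!ok) break
    }
    if (!ok) next
    prt <- parent[order(names(parent))]
    sigs <- c(sigs, paste(names(prt), prt, sep = "<-", collapse = ";"))
  }
  sigs
}
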