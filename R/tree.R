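#' Pairwise CCF ordering rules for clone-tree reconstruction
#'
#' Under the infinite sites assumption (each mutation arises once and never
#' reverts), CCFs across samples constrain ancestry:
#'
#' * **Dominance** (`check_dominance()`): an ancestor's CCF must be greater
#'   than or equal to its descendant's in every sample and strictly greater
#'   in at least one.
#' * **Sum rule** (`check_sum_rule()`): sibling clusters' CCFs may not add up
#'   to more than their shared parent's CCF in any sample; if they do, they
#'   must be collinear rather than siblings.
#' * **Crossing rule** (`check_crossing_rule()`): if cluster B exceeds
#'   cluster C in one sample and C exceeds B in another, the two clusters
#'   must lie on separate branches (`"branching-required"`). If one weakly
#'   dominates the other the relation is `"order-permitted"`; vectors equal
#'   within tolerance are `"symmetric"`.
#'
#' All three take an `eps` slack because estimated CCFs are noisy; the rules
#' are exact only for true CCFs.
#'
#' @param ancestor_ccf,descendant_ccf,parent_ccf,ccf_b,ccf_c Per-sample CCF
#'   vectors (equal length).
#' @param children_ccfs List of per-sample CCF vectors (the siblings).
#' @param eps CCF noise tolerance (default 0.1).
#' @return `check_dominance()` and `check_sum_rule()` return a logical;
#'   `check_crossing_rule()` returns one of `"branching-required"`,
#'   `"order-permitted"`, `"symmetric"`.
#' @examples
#' check_dominance(c(1, 1), c(0.5, 0.5), eps = 0)        # TRUE
#' check_sum_rule(c(1, 1), list(c(0.6, 0.2), c(0.3, 0.5)), eps = 0)  # TRUE
#' check_crossing_rule(c(0.6, 0.2), c(0.2, 0.5), eps = 0)  # branching-required
#' @export
check_dominance <- function(ancestor_ccf, descendant_ccf, eps = 0.1) {
  if (length(ancestor_ccf) != length(descendant_ccf)) {
    abort_input("CCF vectors have different lengths")
  }
  all(ancestor_ccf >= descendant_ccf - eps) &&
    any(ancestor_ccf > descendant_ccf + eps)
}

#' @rdname check_dominance
#' @export
check_sum_rule <- function(parent_ccf, children_ccfs, eps = 0.1) {
  if (length(children_ccfs) == 0) abort_input("need at least one child")
  lens <- vapply(children_ccfs, length, integer(1))
  if (any(lens != length(parent_ccf))) {
    abort_input("CCF vectors have different lengths")
  }
  child_sum <- Reduce(`+`, children_ccfs)
  all(child_sum <= parent_ccf + eps)
}

#' @rdname check_dominance
#' @export
check_crossing_rule <- function(ccf_b, ccf_c, eps = 0.1) {
  if (length(ccf_b) != length(ccf_c)) {
    abort_input("CCF vectors have different lengths")
  }
  b_gt <- any(ccf_b > ccf_c + eps)
  c_gt <- any(ccf_c > ccf_b + eps)
  if (b_gt && c_gt) "branching-required"
  else if (b_gt || c_gt) "order-permitted"
  else "symmetric"
}

#' Reconstruct clone trees from called clusters
#'
#' Enumerates rooted trees over the clusters — the truncal cluster is the
#' root (the most recent common ancestor of all sampled tumour cells) — and
#' keeps those satisfying dominance along every edge, the sum rule at every
#' node, and the crossing rule (pairs whose CCF ordering flips between
#' samples may not be ancestrally related). If no tree is valid, the cluster
#' involved in the most pairwise violations (ties broken towards fewer SNVs)
#' is removed as a putative artefact and enumeration is retried. Valid trees
#' are ranked by the total slack the rules consumed (the summed amount by
#' which edge dominance and node sum constraints were only met thanks to
#' `eps`), most parsimonious first.
#'
#' @param clusters An annotated `clone_clusters` (needs the `truncal` flag
#'   from [annotate_clonality()]).
#' @param eps CCF noise tolerance applied to all three rules (default 0.1).
#' @param max_clusters Enumeration bound; more clusters than this fails
#'   loudly with advice to prune (default 12).
#' @return A `tree_solutions` object: list with `trees` (list of
#'   `clone_tree` objects, ranked), `removed` (tibble of removed clusters and
#'   reasons), and `eps`.
#' @export
build_trees <- function(clusters, eps = 0.1, max_clusters = 12) {
  stopifnot(inherits(clusters, "clone_clusters"))
  if (!"truncal" %in% names(clusters$clusters)) {
    abort_input("clusters lack clonality annotation; run annotate_clonality() first")
  }
  root_id <- clusters$clusters$cluster_id[which(clusters$clusters$truncal)]
  if (length(root_id) != 1) {
    abort_input("need exactly one truncal cluster; found %d", length(root_id))
  }
  samples <- clusters$samples
  loc <- clusters$locations %>%
    tidyr::pivot_wider(id_cols = "cluster_id", names_from = "sample_id",
                       values_from = "ccf")
  ccf_mat <- as.matrix(loc[samples])
  rownames(ccf_mat) <- loc$cluster_id
  sizes <- setNames(clusters$clusters$n_snvs, clusters$clusters$cluster_id)

  active <- loc$cluster_id
  removed <- tibble(cluster_id = character(), reason = character())
  repeat {
    if (length(active) > max_clusters) {
      abort_input(paste0("%d clusters exceed the enumeration bound of %d; ",
                         "prune clusters (e.g. filter_small_clusters()) first"),
                  length(active), max_clusters)
    }
    sol <- enumerate_trees(ccf_mat[active, , drop = FALSE], root_id, eps)
    if (length(sol) > 0 || length(active) <= 1) break
    worst <- most_violating_cluster(ccf_mat[active, , drop = FALSE], root_id,
                                    sizes[active], eps)
    removed <- bind_rows(removed,
                         tibble(cluster_id = worst, reason = "rule-violations"))
    active <- setdiff(active, worst)
  }

  trees <- purrr::map(sol, function(parent) {
    new_clone_tree(parent, clusters, ccf_mat, root_id)
  })
  slack <- vapply(sol, function(parent) {
    tree_slack(parent, ccf_mat)
  }, double(1))
  ord <- order(slack)
  structure(list(trees = trees[ord], slack = slack[ord], removed = removed,
                 eps = eps), class = "tree_solutions")
}

# Enumerate parent assignments for non-root clusters, depth-first with
# dominance pruning; returns a list of named parent vectors (child -> parent).
enumerate_trees <- function(ccf_mat, root_id, eps) {
  ids <- rownames(ccf_mat)
  children <- setdiff(ids, root_id)
  if (length(children) == 0) {
    return(list(setNames(character(0), character(0))))
  }
  # candidate parents by dominance
  cand <- purrr::map(children, function(ch) {
    ids[vapply(ids, function(p) {
      p != ch && check_dominance(ccf_mat[p, ], ccf_mat[ch, ], eps)
    }, logical(1))]
  })
  names(cand) <- children
  # pairwise crossing constraints: branching-required pairs cannot be related
  must_branch <- matrix(FALSE, length(ids), length(ids),
                        dimnames = list(ids, ids))
  for (a in ids) {
    for (b in ids) {
      if (a < b &&
          check_crossing_rule(ccf_mat[a, ], ccf_mat[b, ], eps) ==
            "branching-required") {
        must_branch[a, b] <- must_branch[b, a] <- TRUE
      }
    }
  }
  out <- list()
  assign_next <- function(i, parent) {
    if (i > length(children)) {
      if (tree_is_valid(parent, ccf_mat, root_id, must_branch, eps)) {
        out[[length(out) + 1]] <<- parent
      }
      return(invisible(NULL))
    }
    ch <- children[i]
    for (p in cand[[ch]]) {
      parent[ch] <- p
      # prune: no cycles through already-assigned parents
      if (!creates_cycle(parent, ch, root_id)) assign_next(i + 1, parent)
    }
  }
  assign_next(1, setNames(character(0), character(0)))
  out
}

creates_cycle <- function(parent, start, root_id) {
  seen <- character(0)
  node <- start
  while (!is.na(p <- parent[node] %||% NA_character_) && node != root_id) {
    if (node %in% seen) return(TRUE)
    seen <- c(seen, node)
    node <- unname(p)
    if (is.na(node)) break
  }
  FALSE
}

# full validity audit of a parent assignment
tree_is_valid <- function(parent, ccf_mat, root_id, must_branch, eps) {
  ids <- rownames(ccf_mat)
  children <- names(parent)
  # dominance along each edge
  for (ch in children) {
    if (!check_dominance(ccf_mat[parent[ch], ], ccf_mat[ch, ], eps)) return(FALSE)
  }
  # sum rule at every node with children
  for (p in unique(parent)) {
    sibs <- children[parent == p]
    if (!check_sum_rule(ccf_mat[p, ], lapply(sibs, function(s) ccf_mat[s, ]),
                        eps)) {
      return(FALSE)
    }
  }
  # crossing rule: branching-required pairs must not be ancestor/descendant
  anc <- function(node) {
    path <- character(0)
    while (!is.na(p <- parent[node] %||% NA_character_)) {
      path <- c(path, unname(p))
      node <- unname(p)
    }
    c(path, root_id[!(root_id %in% path)])
  }
  for (a in ids) {
    for (b in ids) {
      if (a < b && must_branch[a, b]) {
        if (a %in% anc(b) || b %in% anc(a)) return(FALSE)
      }
    }
  }
  TRUE
}

# total tolerance consumed: CCF excess of children over parents (edge-wise)
# plus sibling-sum excess over parents, over all samples
tree_slack <- function(parent, ccf_mat) {
  s <- 0
  for (ch in names(parent)) {
    s <- s + sum(pmax(0, ccf_mat[ch, ] - ccf_mat[parent[ch], ]))
  }
  for (p in unique(parent)) {
    sibs <- names(parent)[parent == p]
    child_sum <- colSums(ccf_mat[sibs, , drop = FALSE])
    s <- s + sum(pmax(0, child_sum - ccf_mat[p, ]))
  }
  s
}

# greedy artefact choice: cluster in most violated pairwise/triple constraints
most_violating_cluster <- function(ccf_mat, root_id, sizes, eps) {
  ids <- rownames(ccf_mat)
  score <- setNames(rep(0, length(ids)), ids)
  for (a in ids) {
    for (b in ids) {
      if (a >= b) next
      rel <- check_crossing_rule(ccf_mat[a, ], ccf_mat[b, ], eps)
      dom_ab <- check_dominance(ccf_mat[a, ], ccf_mat[b, ], eps)
      dom_ba <- check_dominance(ccf_mat[b, ], ccf_mat[a, ], eps)
      if (rel != "branching-required" && !dom_ab && !dom_ba) {
        # unplaceable pair: neither order nor branching cleanly supported
        score[a] <- score[a] + 1
        score[b] <- score[b] + 1
      }
    }
  }
  # clusters the root fails to dominate are prime artefact candidates
  for (a in setdiff(ids, root_id)) {
    if (!check_dominance(ccf_mat[root_id, ], ccf_mat[a, ], eps)) {
      score[a] <- score[a] + 2
    }
  }
  score[root_id] <- -Inf  # never remove the trunk
  top <- names(score)[score == max(score)]
  top[order(sizes[top])][1]
}

# assemble a clone_tree object from a parent vector
new_clone_tree <- function(parent, clusters, ccf_mat, root_id) {
  ids <- c(root_id, names(parent))
  nodes <- tibble(
    cluster_id = ids,
    parent_id = c(NA_character_, unname(parent)),
    n_snvs = unname(clusters$clusters$n_snvs[
      match(ids, clusters$clusters$cluster_id)]),
    mean_ccf = rowMeans(ccf_mat[ids, , drop = FALSE])
  )
  structure(list(nodes = nodes,
                 locations = clusters$locations %>%
                   filter(.data$cluster_id %in% ids),
                 samples = clusters$samples,
                 drivers = tibble(snv_id = character(), gene = character(),
                                  cluster_id = character(), truncal = logical())),
            class = "clone_tree")
}

#' @export
print.tree_solutions <- function(x, ...) {
  cat(sprintf("<tree_solutions> %d valid tree(s), %d cluster(s) removed (eps = %g)\n",
              length(x$trees), nrow(x$removed), x$eps))
  if (length(x$trees) > 0) print(x$trees[[1]])
  invisible(x)
}

#' @export
print.clone_tree <- function(x, ...) {
  cat(sprintf("<clone_tree> %d clones, %d bifurcation(s)\n",
              nrow(x$nodes), count_bifurcations(x)))
  print(x$nodes, ...)
  invisible(x)
}

#' @describeIn build_trees Tidy a `clone_tree`: the node table (cluster,
#'   parent, SNV count as branch length, mean CCF as branch width).
#' @param x A `clone_tree`.
#' @param ... Unused.
#' @method tidy clone_tree
#' @export
tidy.clone_tree <- function(x, ...) x$nodes

#' @describeIn build_trees One-row tree summary.
#' @method glance clone_tree
#' @export
glance.clone_tree <- function(x, ...) {
  tibble(n_clones = nrow(x$nodes),
         n_snvs = sum(x$nodes$n_snvs),
         n_bifurcations = count_bifurcations(x),
         n_drivers = nrow(x$drivers))
}

#' Number of bifurcations in a clone tree
#'
#' Counts internal nodes with at least two children.
#'
#' @param tree A `clone_tree`.
#' @return Integer count.
#' @export
count_bifurcations <- function(tree) {
  stopifnot(inherits(tree, "clone_tree"))
  kids <- table(tree$nodes$parent_id[!is.na(tree$nodes$parent_id)])
  sum(kids >= 2)
}

#' Induced subtree of the clones present in one sample
#'
#' A sample's tree is the subtree of the patient-level clone tree containing
#' just the clones observed in that sample (CCF above `presence_tol`). The
#' truncal root is always retained; children of excluded nodes are re-attached
#' to their nearest retained ancestor.
#'
#' @param tree A `clone_tree`.
#' @param sample_id Sample to restrict to.
#' @param presence_tol Minimum CCF for presence (default 0.05).
#' @return A `clone_tree` for the sample.
#' @export
sample_subtree <- function(tree, sample_id, presence_tol = 0.05) {
  stopifnot(inherits(tree, "clone_tree"))
  if (!sample_id %in% tree$samples) {
    abort_input("unknown sample '%s'", sample_id)
  }
  ccf_s <- tree$locations %>%
    filter(.data$sample_id == !!sample_id) %>%
    select(all_of(c("cluster_id", "ccf")))
  root <- tree$nodes$cluster_id[is.na(tree$nodes$parent_id)]
  present <- union(root, ccf_s$cluster_id[ccf_s$ccf > presence_tol])
  parent <- setNames(tree$nodes$parent_id, tree$nodes$cluster_id)
  lift <- function(node) {
    p <- parent[[node]]
    while (!is.na(p) && !(p %in% present)) p <- parent[[p]]
    p
  }
  nodes <- tree$nodes %>%
    filter(.data$cluster_id %in% present) %>%
    mutate(parent_id = vapply(.data$cluster_id, function(id) {
      if (id == root) NA_character_ else lift(id)
    }, character(1)))
  out <- tree
  out$nodes <- nodes
  out$locations <- tree$locations %>% filter(.data$cluster_id %in% present)
  out$drivers <- tree$drivers %>% filter(.data$cluster_id %in% present)
  out
}

#' Place driver mutations on the clone tree
#'
#' Drivers assigned to the truncal cluster are annotated on the trunk (and
#' flagged truncal); drivers in a non-MRCA cluster are annotated on that
#' branch. Driver SNVs without a cluster assignment are reported in the
#' `unplaced` attribute rather than failing. Display order of drivers is the
#' input order.
#'
#' @param tree A `clone_tree`.
#' @param clusters The `clone_clusters` whose assignments place the SNVs.
#' @param driver_snvs Tibble (`snv_id`, `gene`) of driver mutations.
#' @return The tree with `$drivers` filled (`snv_id`, `gene`, `cluster_id`,
#'   `truncal`).
#' @export
assign_drivers <- function(tree, clusters, driver_snvs) {
  stopifnot(inherits(tree, "clone_tree"))
  driver_snvs <- as_tibble(driver_snvs)
  if (nrow(driver_snvs) == 0) return(tree)
  root <- tree$nodes$cluster_id[is.na(tree$nodes$parent_id)]
  placed <- driver_snvs %>%
    left_join(clusters$assignments %>%
                select(all_of(c("snv_id", "cluster_id"))),
              by = "snv_id") %>%
    mutate(truncal = !is.na(.data$cluster_id) & .data$cluster_id == root)
  tree$drivers <- placed %>%
    filter(!is.na(.data$cluster_id), .data$cluster_id %in% tree$nodes$cluster_id)
  attr(tree$drivers, "unplaced") <- placed %>%
    filter(is.na(.data$cluster_id) |
             !(.data$cluster_id %in% tree$nodes$cluster_id)) %>%
    pull("snv_id")
  tree
}
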