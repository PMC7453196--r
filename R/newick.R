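#' Serialise a clone tree as Newick
#'
#' Node labels are cluster ids and branch lengths are the number of SNVs
#' assigned to the cluster (the branch-length convention used when drawing
#' clone trees). The string round-trips through standard Newick parsers such
#' as `ape::read.tree()`.
#'
#' @param tree A `clone_tree`.
#' @return A single Newick string, semicolon-terminated.
#' @examples
#' \dontrun{write_tree_newick(tree)  # "(B:50,C:50)T:5000;"}
#' @export
write_tree_newick <- function(tree) {
  stopifnot(inherits(tree, "clone_tree"))
  nodes <- tree$nodes
  root <- nodes$cluster_id[is.na(nodes$parent_id)]
  kids <- split(nodes$cluster_id[!is.na(nodes$parent_id)],
                nodes$parent_id[!is.na(nodes$parent_id)])
  len <- setNames(nodes$n_snvs, nodes$cluster_id)
  rec <- function(id) {
    ch <- kids[[id]]
    lab <- sprintf("%s:%d", id, len[[id]])
    if (is.null(ch)) lab
    else sprintf("(%s)%s", paste(vapply(ch, rec, character(1)), collapse = ","),
                 lab)
  }
  paste0(rec(root), ";")
}

#' Write the full tree bundle (Newick + JSON sidecar)
#'
#' The Newick file carries topology and SNV branch lengths; the JSON sidecar
#' carries everything Newick cannot: per-sample CCF locations (branch widths),
#' driver annotations and per-sample subtrees.
#'
#' @param tree A `clone_tree`.
#' @param path Output path without extension; writes `<path>.nwk` and
#'   `<path>.json`.
#' @param presence_tol Presence threshold forwarded to [sample_subtree()].
#' @return Invisibly, the two paths written.
#' @export
write_tree_bundle <- function(tree, path, presence_tol = 0.05) {
  stopifnot(inherits(tree, "clone_tree"))
  nwk <- paste0(path, ".nwk")
  writeLines(write_tree_newick(tree), nwk)
  subtrees <- lapply(setNames(tree$samples, tree$samples), function(s) {
    write_tree_newick(sample_subtree(tree, s, presence_tol))
  })
  side <- list(
    nodes = tree$nodes,
    locations = tree$locations,
    drivers = tree$drivers,
    sample_subtrees = subtrees
  )
  jsn <- paste0(path, ".json")
  jsonlite::write_json(side, jsn, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(nwk, jsn))
}
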