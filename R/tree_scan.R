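#' Read and write phylogenies in Newick format
#'
#' Thin wrappers around `ape` tree I/O with the contract checks the rest of
#' the pipeline relies on: unique leaf labels, quoted labels and polytomies
#' accepted.
#'
#' @param path Path to a Newick file.
#' @return For `read_newick()`, an `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) {
    stop_input("tree file not found: ", path)
  }
  tree <- tryCatch(ape::read.tree(path), error = function(e) NULL,
                   warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop_input("could not parse Newick in ", path)
  }
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    stop_input("duplicate leaf label(s) in ", path, ": ",
               paste(dup, collapse = ", "))
  }
  tree
}

#' @rdname read_newick
#' @param tree An `ape::phylo` tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Prune a tree to a subset of samples
#'
#' Keeps only the requested leaves; degree-2 internal nodes left behind are
#' suppressed with branch lengths summed through them.
#'
#' @param tree An `ape::phylo` tree.
#' @param sample_ids Leaf labels to keep (non-empty subset of the leaves).
#' @return The pruned tree.
#' @export
prune_to <- function(tree, sample_ids) {
  if (length(sample_ids) == 0L) {
    stop_input("cannot prune to an empty sample set")
  }
  unknown <- setdiff(sample_ids, tree$tip.label)
  if (length(unknown)) {
    stop_input("sample id(s) not in the tree: ",
               paste(unknown, collapse = ", "))
  }
  ape::keep.tip(tree, sample_ids)
}

#' Re-root a tree on an outgroup
#'
#' Places the root on the edge separating the outgroup from the remaining
#' samples. The outgroup must form a clade in the unrooted sense.
#'
#' @param tree An `ape::phylo` tree with at least 3 leaves.
#' @param outgroup Leaf labels of the outgroup (proper, non-empty subset).
#' @return The re-rooted tree (same leaf set).
#' @export
reroot_on <- function(tree, outgroup) {
  if (length(outgroup) == 0L) {
    stop_input("outgroup must be non-empty")
  }
  unknown <- setdiff(outgroup, tree$tip.label)
  if (length(unknown)) {
    stop_input("outgroup sample id(s) not in the tree: ",
               paste(unknown, collapse = ", "))
  }
  rest <- setdiff(tree$tip.label, outgroup)
  if (length(rest) == 0L) {
    stop_input("outgroup cannot contain every leaf")
  }
  if (ape::Ntip(tree) < 3L) {
    stop_input("re-rooting requires at least 3 leaves")
  }
  if (length(outgroup) > 1L &&
      !(ape::is.monophyletic(tree, outgroup) ||
        ape::is.monophyletic(tree, rest))) {
    stop_input("outgroup is not monophyletic (unrooted sense)")
  }
  out <- ape::root(ape::unroot(tree), outgroup = outgroup,
                   resolve.root = TRUE)
  out
}

# Precomputed indices for one rooted tree: children lists, node depths,
# preorder ranks and the tip set under each node.
tree_index <- function(tree) {
  nt <- ape::Ntip(tree)
  nn <- tree$Nnode
  root <- nt + 1L
  edge <- ape::reorder.phylo(tree, "cladewise")$edge
  n_nodes <- nt + nn
  children <- vector("list", n_nodes)
  for (i in seq_len(nrow(edge))) {
    children[[edge[i, 1L]]] <- c(children[[edge[i, 1L]]], edge[i, 2L])
  }
  pre <- c(root, edge[, 2L])  # preorder node sequence
  pre_rank <- integer(n_nodes)
  pre_rank[pre] <- seq_along(pre)
  depth <- integer(n_nodes)
  for (i in seq_len(nrow(edge))) {
    depth[edge[i, 2L]] <- depth[edge[i, 1L]] + 1L
  }
  tips <- vector("list", n_nodes)
  for (v in seq_len(nt)) tips[[v]] <- tree$tip.label[v]
  for (i in rev(seq_len(nrow(edge)))) {
    p <- edge[i, 1L]
    tips[[p]] <- c(tips[[edge[i, 2L]]], tips[[p]])
  }
  list(n_tip = nt, root = root, children = children, depth = depth,
       pre_rank = pre_rank, tips = tips)
}

new_cluster_partition <- function(nodes, idx, expanded = NA_integer_) {
  nodes <- nodes[order(idx$pre_rank[nodes])]
  structure(
    list(members = lapply(nodes, function(v) idx$tips[[v]]),
         nodes = nodes,
         expanded = expanded),
    class = "cluster_partition"
  )
}

#' @export
print.cluster_partition <- function(x, ...) {
  sizes <- lengths(x$members)
  cat(sprintf("cluster_partition: %d clusters over %d samples (sizes %s)\n",
              length(sizes), sum(sizes), paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Tabulate a cluster partition
#'
#' @param partition A `cluster_partition`.
#' @return Tibble with `cluster_id`, `node_id`, `n_samples`, `sample_ids`
#'   (comma-joined), clusters in tree preorder.
#' @export
partition_tibble <- function(partition) {
  tibble::tibble(
    cluster_id = paste0("c", seq_along(partition$nodes)),
    node_id = partition$nodes,
    n_samples = lengths(partition$members),
    sample_ids = vapply(partition$members, paste, "", collapse = ",")
  )
}

#' Successive cut levels of a rooted tree
#'
#' The first partition is given by the subtrees of the root (two clusters,
#' or more for a root polytomy). Each subsequent partition refines the
#' previous one by expanding exactly one internal node into its children,
#' nodes taken in breadth-first (shallowest-first) order with ties at equal
#' depth broken by preorder index; the final partition is the singleton
#' leaves.
#'
#' @param tree A rooted `ape::phylo` tree with >= 2 leaves.
#' @return List of `cluster_partition` objects; each carries the node whose
#'   expansion produced it (`expanded`; the root for the first).
#' @export
cut_levels <- function(tree) {
  if (ape::Ntip(tree) < 2L) {
    stop_param("cut_levels requires a tree with at least 2 leaves")
  }
  idx <- tree_index(tree)
  internal <- which(seq_len(length(idx$tips)) > idx$n_tip)
  to_expand <- setdiff(internal, idx$root)
  to_expand <- to_expand[order(idx$depth[to_expand], idx$pre_rank[to_expand])]
  nodes <- idx$children[[idx$root]]
  partitions <- vector("list", 1L + length(to_expand))
  partitions[[1L]] <- new_cluster_partition(nodes, idx, expanded = idx$root)
  for (i in seq_along(to_expand)) {
    v <- to_expand[i]
    nodes <- c(setdiff(nodes, v), idx$children[[v]])
    partitions[[i + 1L]] <- new_cluster_partition(nodes, idx, expanded = v)
  }
  partitions
}

# log10 Fisher p per HMM for one partition of the matrix samples.
partition_log10p <- function(partition, matrix, tie_tol, max_tables) {
  sizes <- lengths(partition$members)
  if (length(sizes) == 1L) {
    return(setNames(rep(0, ncol(matrix)), colnames(matrix)))
  }
  f <- integer(nrow(matrix))
  for (ci in seq_along(partition$members)) {
    f[match(partition$members[[ci]], rownames(matrix))] <- ci
  }
  pos <- rowsum(unclass(matrix), f)
  vapply(seq_len(ncol(matrix)), function(j) {
    fisher_exact_2xk(sizes, as.integer(pos[, j]), tie_tol = tie_tol,
                     max_tables = max_tables)$log10_p
  }, 0) |> setNames(colnames(matrix))
}

check_tree_matrix <- function(tree, matrix) {
  extra <- setdiff(rownames(matrix), tree$tip.label)
  miss <- setdiff(tree$tip.label, rownames(matrix))
  if (length(extra) || length(miss)) {
    stop_input(
      "presence matrix samples and tree leaves differ",
      if (length(miss)) paste0("; leaves without calls: ",
                               paste(miss, collapse = ", ")) else "",
      if (length(extra)) paste0("; samples not in tree: ",
                                paste(extra, collapse = ", ")) else ""
    )
  }
}

#' Scan tree cut levels for skewed HMM distributions
#'
#' For every cut level of the tree (see [cut_levels()]) and every HMM,
#' computes the exact two-sided Fisher p-value for non-random distribution
#' of hits across the clusters of that partition. The minimal-p level per
#' HMM is flagged (`best`; ties broken by earliest cut level), and levels
#' with `p < alpha` are flagged significant. Branch lengths play no role;
#' only the topology is used.
#'
#' @param tree Rooted tree whose leaves are exactly the matrix samples.
#' @param matrix A `presence_matrix`.
#' @param alpha Significance level (default 0.001).
#' @inheritParams fisher_exact_2xk
#' @return Object of class `branch_scan`: list with `results` (tibble
#'   `hmm_id`, `level`, `node_id`, `p_value`, `log10_p`, `best`,
#'   `significant`), `partitions` (the cut levels), and `alpha`.
#' @export
branch_scan <- function(tree, matrix, alpha = 0.001, tie_tol = 1e-7,
                        max_tables = 1e7) {
  check_tree_matrix(tree, matrix)
  partitions <- cut_levels(tree)
  rows <- lapply(seq_along(partitions), function(l) {
    lp <- partition_log10p(partitions[[l]], matrix, tie_tol, max_tables)
    tibble::tibble(hmm_id = colnames(matrix), level = l,
                   node_id = partitions[[l]]$expanded,
                   p_value = unname(10^lp), log10_p = unname(lp))
  })
  results <- dplyr::bind_rows(rows)
  results <- results[order(results$hmm_id, results$level), ]
  results <- dplyr::mutate(
    dplyr::group_by(results, .data$hmm_id),
    best = seq_along(.data$log10_p) ==
      which.min(.data$log10_p),  # earliest level wins ties
    significant = .data$p_value < alpha
  )
  results <- dplyr::ungroup(results)
  structure(list(results = results, partitions = partitions, alpha = alpha),
            class = "branch_scan")
}

#' @export
print.branch_scan <- function(x, ...) {
  nb <- sum(x$results$best & x$results$significant)
  cat(sprintf(
    "branch_scan: %d HMMs x %d cut levels; %d significant best splits (alpha = %g)\n",
    length(unique(x$results$hmm_id)), length(x$partitions), nb, x$alpha))
  invisible(x)
}

#' Collapse uninformative nodes into terminal clusters
#'
#' Descends the tree's cut levels from the root. Expanding a node is kept
#' only if, for at least one HMM, the refined partition's p-value is both
#' below `alpha` and smaller than the unrefined partition's p-value by at
#' least a factor of `improvement_factor` ("substantial improvement",
#' operationalised; both knobs are exposed). Samples below a rejected
#' expansion stay merged in the parent's retained cluster. Candidate nodes
#' are taken shallowest-first, ties by preorder index; the procedure stops
#' when no kept expansions remain.
#'
#' @inheritParams branch_scan
#' @param improvement_factor Required fold improvement in p (default 10).
#' @return A `cluster_partition` of terminal clusters.
#' @export
simplify_tree <- function(tree, matrix, alpha = 0.001,
                          improvement_factor = 10, tie_tol = 1e-7,
                          max_tables = 1e7) {
  check_tree_matrix(tree, matrix)
  if (!is.numeric(improvement_factor) || improvement_factor < 1) {
    stop_param("improvement_factor must be >= 1")
  }
  idx <- tree_index(tree)
  cur_nodes <- idx$root
  cur_lp <- setNames(rep(0, ncol(matrix)), colnames(matrix))
  pending <- idx$root
  log_alpha <- log10(alpha)
  log_impr <- log10(improvement_factor)
  while (length(pending)) {
    ord <- order(idx$depth[pending], idx$pre_rank[pending])
    v <- pending[ord[1L]]
    pending <- pending[-ord[1L]]
    cand_nodes <- c(setdiff(cur_nodes, v), idx$children[[v]])
    cand <- new_cluster_partition(cand_nodes, idx)
    cand_lp <- partition_log10p(cand, matrix, tie_tol, max_tables)
    keep <- any(cand_lp < log_alpha & cand_lp < cur_lp - log_impr)
    if (keep) {
      cur_nodes <- cand_nodes
      cur_lp <- cand_lp
      kids <- idx$children[[v]]
      pending <- c(pending, kids[kids > idx$n_tip])
    }
  }
  new_cluster_partition(cur_nodes, idx)
}
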