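# Fixtures are built in code; no binary files.

# Presence matrix + clade map realising given per-clade positive counts.
matrix_from_counts <- function(positives, sizes,
                               clades = paste0("clade", seq_along(sizes)),
                               hmm = "h1") {
  stopifnot(length(positives) == length(sizes), all(positives <= sizes))
  sample_ids <- unlist(lapply(seq_along(sizes), function(i) {
    sprintf("%s_s%03d", clades[i], seq_len(sizes[i]))
  }))
  calls <- unlist(lapply(seq_along(sizes), function(i) {
    c(rep(1L, positives[i]), rep(0L, sizes[i] - positives[i]))
  }))
  m <- matrix(calls, ncol = 1, dimnames = list(sample_ids, hmm))
  clade_map <- tibble::tibble(
    sample_id = sample_ids,
    clade = rep(clades, times = sizes)
  )
  list(matrix = m, clades = clade_map)
}

# Write a hit tibble to a temp TSV and return the path.
write_hits_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(df, path)
  path
}

# Independent Fisher oracle 1: enumerate all 2xK tables with the observed
# margins directly in R, probabilities from choose() arithmetic.
enumerate_k_vectors <- function(sizes, total) {
  if (length(sizes) == 1L) {
    if (total >= 0 && total <= sizes) return(matrix(total, 1, 1))
    return(matrix(numeric(0), 0, 1))
  }
  rest_max <- sum(sizes[-1L])
  out <- list()
  for (k in max(0, total - rest_max):min(sizes[1L], total)) {
    sub <- enumerate_k_vectors(sizes[-1L], total - k)
    if (nrow(sub)) out[[length(out) + 1L]] <- cbind(k, sub)
  }
  if (!length(out)) matrix(numeric(0), 0, length(sizes)) else
    do.call(rbind, out)
}

oracle_fisher_tables <- function(sizes, positives, tol = 1e-7) {
  tabs <- enumerate_k_vectors(sizes, sum(positives))
  num <- apply(tabs, 1, function(k) prod(choose(sizes, k)))
  obs <- prod(choose(sizes, positives))
  sum(num[num <= obs * (1 + tol)]) / choose(sum(sizes), sum(positives))
}

# Independent Fisher oracle 2: enumerate every assignment of individual
# samples to the positive label (N <= 14), no table-level shortcuts.
oracle_fisher_assignments <- function(sizes, positives, tol = 1e-7) {
  N <- sum(sizes)
  T <- sum(positives)
  group <- rep(seq_along(sizes), times = sizes)
  obs <- prod(choose(sizes, positives))
  if (T == 0 || T == N) return(1)
  subsets <- utils::combn(N, T)
  hits <- apply(subsets, 2, function(idx) {
    k <- tabulate(group[idx], nbins = length(sizes))
    prod(choose(sizes, k)) <= obs * (1 + tol)
  })
  sum(hits) / choose(N, T)
}

# 32-tip tree whose root separates a balanced 8-clade (L01..L08) from a
# random 24-tip subtree (R01..R24); the planted-loss fixture.
planted_loss_tree <- function(seed = 1) {
  t8 <- ape::stree(8, "balanced")
  t8$tip.label <- sprintf("L%02d", 1:8)
  t24 <- withr::with_seed(seed,
    ape::rtree(24, tip.label = sprintf("R%02d", 1:24), br = NULL))
  ape::read.tree(text = paste0(
    "(", sub(";", "", ape::write.tree(t8)), ",",
    sub(";", "", ape::write.tree(t24)), ");"))
}

one_hmm_matrix <- function(states, hmm = "g1") {
  matrix(as.integer(states), ncol = 1,
         dimnames = list(names(states), hmm))
}

expect_valid_partition <- function(partition, leaves) {
  all_members <- unlist(partition$members)
  expect_false(any(duplicated(all_members)))
  expect_setequal(all_members, leaves)
  expect_true(all(lengths(partition$members) >= 1))
}
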