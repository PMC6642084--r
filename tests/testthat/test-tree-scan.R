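newick_tree <- function(text) {
  path <- tempfile(fileext = ".nwk")
  writeLines(text, path)
  read_newick(path)
}

tree_children_of_root <- function(tree) {
  root <- ape::Ntip(tree) + 1L
  tree$edge[tree$edge[, 1] == root, 2]
}

test_that("read_newick parses, rejects duplicates, round-trips", {
  tr <- newick_tree("((A,B),(C,D));")
  expect_equal(ape::Ntip(tr), 4L)
  expect_equal(tr$Nnode, 3L)

  poly <- newick_tree("(A,B,C);")
  expect_equal(ape::Ntip(poly), 3L)
  expect_length(tree_children_of_root(poly), 3L)

  expect_error(newick_tree("((A,B),(A,C));"), "duplicate",
               class = "cladescan_input_error")
  expect_error(read_newick(tempfile()), "not found",
               class = "cladescan_input_error")

  out <- tempfile(fileext = ".nwk")
  write_newick(tr, out)
  back <- read_newick(out)
  expect_setequal(back$tip.label, tr$tip.label)
  expect_equal(suppressWarnings(ape::dist.topo(back, tr))[1], 0)
})

test_that("prune_to keeps the requested leaves and suppresses knees", {
  tr <- newick_tree("((A:1,B:1):1,(C:1,D:1):1);")
  pr <- prune_to(tr, c("A", "C", "D"))
  expect_setequal(pr$tip.label, c("A", "C", "D"))
  expect_true(ape::is.monophyletic(pr, c("C", "D")))
  # branch lengths summed through the suppressed node above A
  expect_equal(pr$edge.length[pr$edge[, 2] == which(pr$tip.label == "A")], 2)

  same <- prune_to(tr, tr$tip.label)
  expect_equal(suppressWarnings(ape::dist.topo(same, tr))[1], 0)

  expect_error(prune_to(tr, character(0)), class = "cladescan_input_error")
  expect_error(prune_to(tr, c("A", "ZZ")), "ZZ",
               class = "cladescan_input_error")
})

test_that("reroot_on places the root between outgroup and the rest", {
  tr <- newick_tree("((A,B),(C,D));")
  rt <- reroot_on(tr, c("C", "D"))
  expect_setequal(rt$tip.label, tr$tip.label)
  expect_true(ape::is.monophyletic(rt, c("C", "D")))
  expect_true(ape::is.monophyletic(rt, c("A", "B")))

  single <- reroot_on(tr, "A")
  expect_true(ape::is.monophyletic(single, c("B", "C", "D")))

  expect_error(reroot_on(tr, tr$tip.label), class = "cladescan_input_error")
  expect_error(reroot_on(tr, c("A", "C")), "monophyletic",
               class = "cladescan_input_error")
})

test_that("cut_levels refines one node at a time, shallowest first", {
  bal <- newick_tree("((A,B),(C,D));")
  parts <- cut_levels(bal)
  expect_equal(vapply(parts, function(p) length(p$members), 0L), c(2L, 3L, 4L))

  cat4 <- newick_tree("(((A,B),C),D);")
  parts <- cut_levels(cat4)
  shapes <- lapply(parts, function(p)
    sort(vapply(p$members, paste, "", collapse = "+")))
  expect_equal(shapes[[1]], sort(c("A+B+C", "D")))
  expect_equal(shapes[[2]], sort(c("A+B", "C", "D")))
  expect_equal(shapes[[3]], sort(c("A", "B", "C", "D")))

  two <- newick_tree("(A,B);")
  parts <- cut_levels(two)
  expect_length(parts, 1L)
  expect_equal(sort(unlist(parts[[1]]$members)), c("A", "B"))
})

test_that("cut_levels partitions are true, strictly refining partitions", {
  withr::with_seed(21, {
    for (i in 1:10) {
      n <- sample(4:20, 1)
      tr <- ape::rtree(n, tip.label = sprintf("t%02d", 1:n))
      parts <- cut_levels(tr)
      prev_n <- 1L
      for (p in parts) {
        expect_valid_partition(p, tr$tip.label)
        expect_gt(length(p$members), prev_n - 1L)
        prev_n <- length(p$members)
      }
      expect_equal(length(parts[[length(parts)]]$members), n)
    }
  })
})

test_that("branch_scan finds the planted clade loss with the closed-form p", {
  tree <- planted_loss_tree(seed = 1)
  states <- setNames(as.integer(!grepl("^L", tree$tip.label)),
                     tree$tip.label)
  m <- one_hmm_matrix(states)
  bs <- branch_scan(tree, m)
  best <- bs$results[bs$results$best, ]
  expect_equal(best$level, 1L)
  expect_equal(best$p_value, 1 / choose(32, 8), tolerance = 1e-12)
  expect_true(best$significant)
  part <- bs$partitions[[best$level]]
  expect_true(any(vapply(part$members, setequal, TRUE,
                         y = sprintf("L%02d", 1:8))))

  # uniformly present HMM: every p = 1, nothing significant
  bu <- branch_scan(tree, one_hmm_matrix(setNames(rep(1L, 32),
                                                  tree$tip.label)))
  expect_true(all(bu$results$p_value == 1))
  expect_false(any(bu$results$significant))

  # leaf/sample mismatch is an error listing the offender
  m_bad <- m
  rownames(m_bad)[1] <- "intruder"
  expect_error(branch_scan(tree, m_bad), "intruder",
               class = "cladescan_input_error")
})

test_that("branch_scan p-values are invariant to leaf order and rerooting", {
  tree <- planted_loss_tree(seed = 2)
  states <- setNames(as.integer(!grepl("^L", tree$tip.label)),
                     tree$tip.label)
  m <- one_hmm_matrix(states)
  p_ref <- sort(branch_scan(tree, m)$results$log10_p)

  shuf <- m[sample(nrow(m)), , drop = FALSE]
  expect_equal(sort(branch_scan(tree, shuf)$results$log10_p), p_ref,
               tolerance = 1e-12)

  # re-rooting on the same outgroup (the 8-clade) preserves the partitions'
  # p-values (levels may reorder)
  rt <- reroot_on(tree, sprintf("L%02d", 1:8))
  p_rt <- branch_scan(rt, m)$results$log10_p
  expect_equal(min(p_rt), min(p_ref), tolerance = 1e-12)
})

test_that("simplify_tree collapses uninformative nodes", {
  tree <- planted_loss_tree(seed = 3)
  states <- setNames(as.integer(!grepl("^L", tree$tip.label)),
                     tree$tip.label)
  part <- simplify_tree(tree, one_hmm_matrix(states))
  expect_length(part$members, 2L)
  expect_true(any(vapply(part$members, setequal, TRUE,
                         y = sprintf("L%02d", 1:8))))
  expect_valid_partition(part, tree$tip.label)

  # all HMMs present everywhere: a single cluster of all leaves
  uni <- matrix(1L, 32, 3, dimnames = list(tree$tip.label,
                                           c("a", "b", "c")))
  expect_length(simplify_tree(tree, uni)$members, 1L)
})

test_that("simplify_tree always returns a valid partition", {
  withr::with_seed(77, {
    for (i in 1:20) {
      n <- sample(6:24, 1)
      tr <- ape::rtree(n, tip.label = sprintf("t%02d", 1:n))
      m <- matrix(rbinom(3 * n, 1, runif(1, 0.2, 0.8)), n, 3,
                  dimnames = list(tr$tip.label, c("h1", "h2", "h3")))
      part <- simplify_tree(tr, m)
      expect_valid_partition(part, tr$tip.label)
    }
  })
})

test_that("the true branch wins the scan in most dropout replicates", {
  tree <- planted_loss_tree(seed = 1)
  truth <- setNames(as.integer(!grepl("^L", tree$tip.label)),
                    tree$tip.label)
  lost_clade <- sprintf("L%02d", 1:8)
  withr::with_seed(1001, {
    hit <- vapply(1:100, function(i) {
      observed <- truth & (runif(32) < 0.9)   # detection dropout
      bs <- branch_scan(tree, one_hmm_matrix(as.integer(observed) |>
                                               setNames(tree$tip.label)))
      best <- bs$results[bs$results$best, ]
      part <- bs$partitions[[best$level]]
      any(vapply(part$members, setequal, TRUE, y = lost_clade))
    }, TRUE)
  })
  expect_gt(mean(hit), 0.5)
})


test_that("significant best splits are rare when nothing was lost", {
  tree <- planted_loss_tree(seed = 1)
  withr::with_seed(1002, {
    sig <- vapply(1:100, function(i) {
      observed <- runif(32) < 0.9   # uniform presence, dropout only
      bs <- branch_scan(tree, one_hmm_matrix(as.integer(observed) |>
                                               setNames(tree$tip.label)))
      any(bs$results$best & bs$results$significant)
    }, TRUE)
  })
  expect_lte(mean(sig), 0.01)
})
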