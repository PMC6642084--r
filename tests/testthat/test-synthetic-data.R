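test_that("simulate_tree produces labeled, reproducible trees", {
  bal <- simulate_tree(4, "balanced")
  expect_equal(sort(bal$tip.label), sprintf("t%03d", 1:4))
  expect_true(all(bal$edge.length == 1))
  expect_error(simulate_tree(6, "balanced"), class = "cladescan_param_error")

  y1 <- simulate_tree(50, "yule", seed = 7)
  y2 <- simulate_tree(50, "yule", seed = 7)
  expect_identical(ape::write.tree(y1), ape::write.tree(y2))
  expect_equal(ape::Ntip(y1), 50L)
  expect_equal(y1$Nnode, 49L)   # binary
  expect_true(all(y1$edge.length > 0))
  expect_error(simulate_tree(1), class = "cladescan_param_error")
})

test_that("simulate_trait respects degenerate rate settings", {
  tr <- simulate_tree(8, "balanced")
  still <- simulate_trait(tr, gain_rate = 0, loss_rate = 0, root_state = 1,
                          seed = 1)
  expect_true(all(still$tip_states == 1L))
  expect_equal(nrow(still$events), 0L)

  dead <- simulate_trait(tr, gain_rate = 0, loss_rate = 5, root_state = 0,
                         seed = 2)
  expect_true(all(dead$tip_states == 0L))
  expect_equal(nrow(dead$events), 0L)
})

test_that("loss frequency matches the closed-form pure-death solution", {
  # two tips at distance t from the root with loss_rate * t = ln 2:
  # P(absent at a tip) = 1 - exp(-loss_rate * t) = 1/2
  tr <- ape::read.tree(text = "(A:1,B:1);")
  n <- 10000
  withr::with_seed(99, {
    absent <- vapply(seq_len(n), function(i) {
      simulate_trait(tr, gain_rate = 0, loss_rate = log(2),
                     root_state = 1)$tip_states[["A"]] == 0L
    }, TRUE)
  })
  se3 <- 3 * sqrt(0.25 / n)
  expect_lt(abs(mean(absent) - 0.5), se3)
})

test_that("tip states replay the recorded event list", {
  tr <- simulate_tree(16, "yule", seed = 3)
  idx <- cladescan:::tree_index(tr)
  for (s in 1:10) {
    tra <- simulate_trait(tr, gain_rate = 0.3, loss_rate = 0.5,
                          root_state = 1, seed = 100 + s)
    # replay: per tip, state = root_state flipped once per event on its path
    for (tip in seq_len(ape::Ntip(tr))) {
      path_nodes <- tip
      v <- tip
      while (v != idx$root) {
        v <- tr$edge[match(v, tr$edge[, 2]), 1]
        path_nodes <- c(path_nodes, v)
      }
      n_flips <- sum(tra$events$child %in% path_nodes)
      expected <- (tra$root_state + n_flips) %% 2L
      expect_equal(unname(tra$tip_states[tr$tip.label[tip]]), expected)
    }
  }
})

test_that("dropout observation recovers truth when noise-free", {
  tr <- simulate_tree(8, "balanced")
  genes <- list(g1 = simulate_trait(tr, 0.02, 0.3, 1, seed = 5),
                g2 = simulate_trait(tr, 0.02, 0.3, 1, seed = 6))
  truth <- sim_truth(tr, genes)
  obs <- apply_dropout(truth, detection_prob = 1,
                       bitscore_model = list(spurious_rate = 0), seed = 7)
  m <- presence_call(obs$hits, samples = tr$tip.label,
                     hmms = c("g1", "g2"))
  states <- cbind(g1 = genes$g1$tip_states[tr$tip.label],
                  g2 = genes$g2$tip_states[tr$tip.label])
  expect_equal(unclass(m), states, ignore_attr = TRUE)

  # detection_prob = 0: no hits above the calling threshold
  obs0 <- apply_dropout(truth, 0, list(spurious_rate = 0.5), seed = 8)
  expect_true(all(obs0$hits$bitscore < 10))
})

test_that("dropout is binomial and conserves the truly-present pairs", {
  tr <- simulate_tree(32, "yule", seed = 5)
  genes <- lapply(1:40, function(i) simulate_trait(tr, 0, 0, 1))
  names(genes) <- sprintf("g%03d", 1:40)
  truth <- sim_truth(tr, genes)
  obs <- apply_dropout(truth, 0.7, list(spurious_rate = 0), seed = 6)
  n_present <- 32 * 40
  detected <- obs$detected[!is.na(obs$detected)]
  expect_length(detected, n_present)         # conservation
  expect_equal(sum(detected) + sum(detected == 0L), n_present)
  se3 <- 3 * sqrt(0.7 * 0.3 / n_present)
  expect_lt(abs(mean(detected) - 0.7), se3)
})

test_that("generate_dataset writes a consistent, byte-reproducible bundle", {
  cfg <- sim_config(n_taxa = 16, n_genes = 4, seed = 42, lipids = TRUE,
                    spurious_rate = 0.2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- generate_dataset(cfg, d1)
  p2 <- generate_dataset(cfg, d2)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
  hits <- load_hits(p1$hits)
  clades <- load_clades(p1$clades)
  tree <- read_newick(p1$tree)
  expect_setequal(clades$sample_id, tree$tip.label)
  expect_true(all(hits$sample_id %in% tree$tip.label))
  truth_json <- jsonlite::read_json(p1$truth)
  expect_equal(truth_json$schema_version, 1L)
  expect_length(truth_json$genes, 4L)

  # no genes: valid tree, header-only hit table
  cfg0 <- sim_config(n_taxa = 8, n_genes = 0, seed = 1)
  p0 <- generate_dataset(cfg0, withr::local_tempdir())
  expect_equal(nrow(load_hits(p0$hits)), 0L)
  expect_equal(ape::Ntip(read_newick(p0$tree)), 8L)
})

test_that("a pinned clade loss appears verbatim in the truth", {
  tips <- c("t001", "t002", "t003", "t004")
  cfg <- sim_config(n_taxa = 8, tree_model = "balanced", n_genes = 2,
                    seed = 9, detection_prob = 1, spurious_rate = 0,
                    forced_losses = list(list(gene = 1, tips = tips)))
  paths <- generate_dataset(cfg, withr::local_tempdir())
  truth <- attr(paths, "truth")
  ev <- truth$genes$g001$events
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "loss")
  idx <- cladescan:::tree_index(truth$tree)
  expect_setequal(idx$tips[[ev$child]], tips)
  expect_equal(unname(truth$genes$g001$tip_states[tips]), rep(0L, 4))
  expect_true(all(truth$genes$g001$tip_states[setdiff(truth$tree$tip.label,
                                                      tips)] == 1L))
})

test_that("evaluate_detection scores a perfect detector at power 1", {
  tips <- sprintf("L%02d", 1:8)
  tree <- planted_loss_tree(seed = 4)
  genes <- lapply(1:5, function(i) {
    states <- setNames(as.integer(!(tree$tip.label %in% tips)),
                       tree$tip.label)
    idx <- cladescan:::tree_index(tree)
    node <- ape::getMRCA(tree, tips)
    structure(list(
      tip_states = states,
      events = tibble::tibble(parent = idx$root, child = node,
                              type = "loss", position = 0.5),
      root_state = 1L, node_states = NULL), class = "sim_trait")
  })
  names(genes) <- sprintf("g%03d", 1:5)
  truth <- sim_truth(tree, genes)
  obs <- apply_dropout(truth, 1, list(spurious_rate = 0), seed = 1)
  m <- presence_call(obs$hits, samples = tree$tip.label,
                     hmms = names(genes))
  scan <- branch_scan(tree, m)
  ev <- evaluate_detection(scan, truth)
  expect_equal(ev$power, 1)
  expect_true(is.na(ev$false_discovery_rate))   # no null genes here

  # mismatched gene sets are rejected
  truth_bad <- sim_truth(tree, genes[1:3])
  expect_error(evaluate_detection(scan, truth_bad),
               class = "cladescan_input_error")
})
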