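#' Configuration for a synthetic phylotranscriptomic dataset
#'
#' Bundles the parameters of the generative model: a tree, binary gene
#' presence evolving on it by gain/loss events, incomplete per-sample
#' detection (transcriptome dropout), and bitscore noise around the calling
#' threshold. Defaults reflect the study conditions the package is designed
#' around: losses common and regains rare (loss 0.1 vs gain 0.01 events per
#' unit branch length), detection probability 0.9 per truly present gene,
#' and true-hit bitscores one bit above the 10-bit threshold plus an
#' exponential tail of scale 20 bits, with spurious sub-threshold noise
#' hits at rate 0.1 per sample-gene.
#'
#' @param n_taxa Number of leaves (>= 2).
#' @param tree_model `"yule"` (pure-birth) or `"balanced"` (requires
#'   `n_taxa` a power of two; unit branch lengths).
#' @param gain_rate,loss_rate Gain/loss rates per unit branch length (>= 0).
#' @param root_state 0, 1 or `"stationary"` (draws from
#'   `gain_rate / (gain_rate + loss_rate)`).
#' @param detection_prob Probability a truly present gene is detected in a
#'   sample's transcriptome, i.i.d. per (sample, gene).
#' @param n_genes Number of genes to simulate.
#' @param threshold Calling threshold in bits.
#' @param bitscore_offset,bitscore_scale True-hit bitscores are
#'   `threshold + bitscore_offset + Exp(scale = bitscore_scale)`.
#' @param spurious_rate Expected sub-threshold noise hits per sample-gene,
#'   bitscores uniform on (0, threshold).
#' @param n_clades Number of clade labels to derive from the shallowest
#'   tree cut with at least that many clusters.
#' @param forced_losses Optional list of `list(gene = i, tips = c(...))`
#'   entries pinning a single loss event to the branch above the smallest
#'   clade containing `tips`; such genes evolve deterministically (present
#'   everywhere else).
#' @param lipids If `TRUE`, also generate a lipid table in which samples
#'   truly carrying `marker_gene` are DGTS-dominant.
#' @param marker_gene Gene index used as the DGTS marker (default 1).
#' @param seed Integer seed; every random draw is keyed to it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 32, tree_model = c("yule", "balanced"),
                       gain_rate = 0.01, loss_rate = 0.1, root_state = 1,
                       detection_prob = 0.9, n_genes = 20, threshold = 10,
                       bitscore_offset = 1, bitscore_scale = 20,
                       spurious_rate = 0.1, n_clades = 2,
                       forced_losses = list(), lipids = FALSE,
                       marker_gene = 1, seed = 1) {
  tree_model <- match.arg(tree_model)
  if (!is.numeric(n_taxa) || n_taxa < 2) stop_param("n_taxa must be >= 2")
  if (gain_rate < 0 || loss_rate < 0) stop_param("rates must be >= 0")
  if (!identical(root_state, "stationary") &&
      !(is.numeric(root_state) && root_state %in% c(0, 1))) {
    stop_param("root_state must be 0, 1 or \"stationary\"")
  }
  if (detection_prob < 0 || detection_prob > 1) {
    stop_param("detection_prob must lie in [0, 1]")
  }
  if (n_genes < 0) stop_param("n_genes must be >= 0")
  if (spurious_rate < 0) stop_param("spurious_rate must be >= 0")
  structure(
    list(n_taxa = as.integer(n_taxa), tree_model = tree_model,
         gain_rate = gain_rate, loss_rate = loss_rate,
         root_state = root_state, detection_prob = detection_prob,
         n_genes = as.integer(n_genes), threshold = threshold,
         bitscore_offset = bitscore_offset, bitscore_scale = bitscore_scale,
         spurious_rate = spurious_rate, n_clades = as.integer(n_clades),
         forced_losses = forced_losses, lipids = isTRUE(lipids),
         marker_gene = as.integer(marker_gene), seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a species tree
#'
#' @param n_taxa Number of leaves.
#' @param tree_model `"yule"` or `"balanced"` (see [sim_config()]).
#' @param seed Integer seed (ignored by the deterministic balanced model).
#' @return A rooted `ape::phylo` with leaves `t001`, `t002`, ... and
#'   positive branch lengths.
#' @export
simulate_tree <- function(n_taxa, tree_model = c("yule", "balanced"),
                          seed = 1) {
  tree_model <- match.arg(tree_model)
  if (n_taxa < 2) stop_param("n_taxa must be >= 2")
  if (tree_model == "balanced") {
    if (abs(log2(n_taxa) - round(log2(n_taxa))) > 1e-9) {
      stop_param("balanced trees require n_taxa to be a power of two")
    }
    tree <- ape::stree(n_taxa, type = "balanced")
    tree$edge.length <- rep(1, nrow(tree$edge))
  } else {
    tree <- withr::with_seed(seed, ape::rphylo(n_taxa, birth = 1, death = 0))
  }
  tree$tip.label <- sprintf("t%03d", seq_len(n_taxa))
  tree
}

#' Simulate one gene's gain/loss history on a tree
#'
#' A two-state continuous-time Markov chain per branch: while the gene is
#' present, loss events arrive at `loss_rate` per unit length; while
#' absent, gains arrive at `gain_rate`. Tip states are the replay of the
#' recorded events from the root state.
#'
#' @param tree A rooted `ape::phylo` with branch lengths.
#' @param gain_rate,loss_rate Event rates (>= 0).
#' @param root_state 0, 1 or `"stationary"`.
#' @param seed Optional integer seed (if `NULL`, uses the current RNG
#'   stream).
#' @return List of class `sim_trait`: `tip_states` (named 0/1 over
#'   leaves), `events` (tibble `parent`, `child`, `type`, `position`),
#'   `root_state`, `node_states`.
#' @export
simulate_trait <- function(tree, gain_rate, loss_rate, root_state = 1,
                           seed = NULL) {
  if (gain_rate < 0 || loss_rate < 0) stop_param("rates must be >= 0")
  run <- function() {
    if (identical(root_state, "stationary")) {
      if (gain_rate + loss_rate <= 0) {
        stop_param("stationary root state needs gain_rate + loss_rate > 0")
      }
      rs <- rbinom(1L, 1L, gain_rate / (gain_rate + loss_rate))
    } else {
      rs <- as.integer(root_state)
    }
    tre <- ape::reorder.phylo(tree, "cladewise")
    edge <- tre$edge
    len <- tre$edge.length
    if (is.null(len)) len <- rep(1, nrow(edge))
    nt <- length(tree$tip.label)
    state <- integer(nt + tree$Nnode)
    state[nt + 1L] <- rs
    ev_parent <- integer(0)
    ev_child <- integer(0)
    ev_type <- character(0)
    ev_pos <- double(0)
    for (i in seq_len(nrow(edge))) {
      s <- state[edge[i, 1L]]
      pos <- 0
      repeat {
        rate <- if (s == 1L) loss_rate else gain_rate
        if (rate <= 0) break
        pos <- pos + rexp(1L, rate)
        if (pos >= len[i]) break
        ev_parent <- c(ev_parent, edge[i, 1L])
        ev_child <- c(ev_child, edge[i, 2L])
        ev_type <- c(ev_type, if (s == 1L) "loss" else "gain")
        ev_pos <- c(ev_pos, pos)
        s <- 1L - s
      }
      state[edge[i, 2L]] <- s
    }
    events <- tibble::tibble(parent = ev_parent, child = ev_child,
                             type = ev_type, position = ev_pos)
    structure(
      list(tip_states = setNames(state[seq_len(nt)], tree$tip.label),
           events = events, root_state = rs,
           node_states = state),
      class = "sim_trait"
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Loss pinned to the branch above the smallest clade containing `tips`:
# present everywhere except below that branch.
forced_loss_trait <- function(tree, tips) {
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown)) {
    stop_param("forced loss tips not in the tree: ",
               paste(unknown, collapse = ", "))
  }
  idx <- tree_index(tree)
  node <- if (length(tips) == 1L) {
    match(tips, tree$tip.label)
  } else {
    ape::getMRCA(tree, tips)
  }
  if (node == idx$root) {
    stop_param("forced loss tips span the root; pick tips forming a proper clade")
  }
  below <- idx$tips[[node]]
  parent <- tree$edge[match(node, tree$edge[, 2L]), 1L]
  elen <- if (is.null(tree$edge.length)) 1 else
    tree$edge.length[match(node, tree$edge[, 2L])]
  states <- setNames(as.integer(!(tree$tip.label %in% below)),
                     tree$tip.label)
  structure(
    list(tip_states = states,
         events = tibble::tibble(parent = parent, child = node,
                                 type = "loss", position = elen / 2),
         root_state = 1L, node_states = NULL),
    class = "sim_trait"
  )
}

#' Bundle per-gene trait histories into one truth object
#'
#' @param tree The tree the traits evolved on.
#' @param genes Named list of `sim_trait` objects (names = gene/HMM ids).
#' @return Object of class `sim_truth`.
#' @export
sim_truth <- function(tree, genes) {
  stopifnot(is.list(genes), !is.null(names(genes)))
  structure(list(tree = tree, genes = genes), class = "sim_truth")
}

truth_state_matrix <- function(truth) {
  m <- vapply(truth$genes,
              function(g) g$tip_states[truth$tree$tip.label],
              integer(ape::Ntip(truth$tree)))
  rownames(m) <- truth$tree$tip.label
  m
}

#' Observe simulated genes through transcriptome dropout
#'
#' Each truly present (sample, gene) pair is detected with probability
#' `detection_prob`; detected pairs emit one transcript hit with a
#' bitscore above the calling threshold (`threshold + offset +
#' Exp(scale)`). Spurious sub-threshold hits (bitscore uniform on
#' (0, threshold)) are added with Poisson(`spurious_rate`) counts per
#' (sample, gene). Truly absent genes never emit supra-threshold hits.
#'
#' @param truth A `sim_truth` (or single `sim_trait` plus `tree`).
#' @param detection_prob Detection probability in `[0, 1]`.
#' @param bitscore_model List with `threshold`, `offset`, `scale`,
#'   `spurious_rate` (defaults as in [sim_config()]).
#' @param seed Optional integer seed.
#' @return List of class `sim_observation`: `hits` (tibble of hit
#'   records), `detected` (0/1 matrix over truly present pairs, NA where
#'   absent).
#' @export
apply_dropout <- function(truth, detection_prob,
                          bitscore_model = list(threshold = 10, offset = 1,
                                                scale = 20,
                                                spurious_rate = 0.1),
                          seed = NULL) {
  if (detection_prob < 0 || detection_prob > 1) {
    stop_param("detection_prob must lie in [0, 1]")
  }
  bm <- utils::modifyList(
    list(threshold = 10, offset = 1, scale = 20, spurious_rate = 0.1),
    bitscore_model)
  run <- function() {
    states <- truth_state_matrix(truth)
    samples <- rownames(states)
    genes <- colnames(states)
    detected <- matrix(NA_integer_, nrow(states), ncol(states),
                       dimnames = dimnames(states))
    rows <- list()
    for (j in seq_along(genes)) {
      for (i in seq_along(samples)) {
        if (states[i, j] == 1L) {
          d <- rbinom(1L, 1L, detection_prob)
          detected[i, j] <- d
          if (d == 1L) {
            score <- bm$threshold + bm$offset + rexp(1L, 1 / bm$scale)
            rows[[length(rows) + 1L]] <- tibble::tibble(
              sample_id = samples[i], hmm_id = genes[j],
              transcript_id = paste0(samples[i], "_", genes[j], "_t1"),
              bitscore = round(score, 3))
          }
        }
        nsp <- if (bm$spurious_rate > 0) rpois(1L, bm$spurious_rate) else 0L
        if (nsp > 0L) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            sample_id = samples[i], hmm_id = genes[j],
            transcript_id = paste0(samples[i], "_", genes[j], "_n",
                                   seq_len(nsp)),
            bitscore = round(runif(nsp, 0, bm$threshold), 3))
        }
      }
    }
    hits <- if (length(rows)) dplyr::bind_rows(rows) else {
      tibble::tibble(sample_id = character(), hmm_id = character(),
                     transcript_id = character(), bitscore = double())
    }
    structure(list(hits = hits, detected = detected),
              class = "sim_observation")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a complete synthetic dataset on disk
#'
#' Writes mutually consistent files exactly in the formats the analysis
#' consumes: `hits.tsv`, `tree.nwk`, `clades.tsv`, `truth.json`
#' (versioned schema, sufficient to score any detector) and, optionally,
#' `lipids.tsv`. Byte-identical across runs with the same config.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, with the `sim_truth` object attached
#'   as attribute `truth`.
#' @export
generate_dataset <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(hits = file.path(dir, "hits.tsv"),
                tree = file.path(dir, "tree.nwk"),
                clades = file.path(dir, "clades.tsv"),
                truth = file.path(dir, "truth.json"))
  tree <- simulate_tree(config$n_taxa, config$tree_model, config$seed)
  truth_obj <- withr::with_seed(config$seed + 1L, {
    forced <- setNames(
      lapply(config$forced_losses, function(fl) fl$tips),
      vapply(config$forced_losses,
             function(fl) sprintf("g%03d", fl$gene), "")
    )
    genes <- lapply(seq_len(config$n_genes), function(g) {
      id <- sprintf("g%03d", g)
      if (id %in% names(forced)) {
        forced_loss_trait(tree, forced[[id]])
      } else {
        simulate_trait(tree, config$gain_rate, config$loss_rate,
                       config$root_state)
      }
    })
    names(genes) <- sprintf("g%03d", seq_len(config$n_genes))
    sim_truth(tree, genes)
  })
  obs <- apply_dropout(
    truth_obj, config$detection_prob,
    bitscore_model = list(threshold = config$threshold,
                          offset = config$bitscore_offset,
                          scale = config$bitscore_scale,
                          spurious_rate = config$spurious_rate),
    seed = config$seed + 2L)

  hdr <- list(seed = config$seed, schema = 1L)
  write_tsv_with_header(obs$hits, paths$hits, hdr)
  write_newick(tree, paths$tree)

  clade_map <- derive_clades(tree, config$n_clades)
  write_tsv_with_header(clade_map, paths$clades, hdr)

  truth_json <- list(
    schema_version = 1L,
    seed = config$seed,
    samples = tree$tip.label,
    genes = lapply(truth_obj$genes, function(g) {
      list(root_state = g$root_state,
           tip_states = as.list(g$tip_states),
           events = g$events)
    })
  )
  jsonlite::write_json(truth_json, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  if (config$lipids && config$n_genes >= config$marker_gene) {
    paths$lipids <- file.path(dir, "lipids.tsv")
    marker <- truth_obj$genes[[config$marker_gene]]$tip_states
    lip <- withr::with_seed(config$seed + 3L, {
      dplyr::bind_rows(lapply(names(marker), function(s) {
        pc <- round(runif(2, 50, 200), 2)
        dgts <- if (marker[s] == 1L) round(runif(2, 300, 900), 2) else c(0, 0)
        tibble::tibble(
          sample_id = s,
          lipid_class = c("PC", "PC", "DGTS", "DGTS"),
          species_id = c("PC_34_1", "PC_36_2", "DGTS_34_1", "DGTS_36_2"),
          abundance = c(pc, dgts))
      }))
    })
    lip <- lip[lip$abundance > 0 | lip$lipid_class == "PC", ]
    write_tsv_with_header(lip, paths$lipids, hdr)
  }
  structure(paths, truth = truth_obj)
}

# Clade labels from the shallowest cut with >= n_clades clusters.
derive_clades <- function(tree, n_clades) {
  parts <- cut_levels(tree)
  sizes <- vapply(parts, function(p) length(p$members), 0L)
  pick <- which(sizes >= n_clades)[1L]
  if (is.na(pick)) pick <- length(parts)
  part <- parts[[pick]]
  dplyr::bind_rows(lapply(seq_along(part$members), function(ci) {
    tibble::tibble(sample_id = part$members[[ci]],
                   clade = sprintf("clade%d", ci))
  }))
}

#' Score a branch scan against simulation ground truth
#'
#' Power is the fraction of genes with at least one true gain/loss event
#' whose best split is significant at `alpha` and isolates a cluster equal
#' to the tip set below a true event's branch. The false discovery rate is
#' the fraction of significant best splits among genes with no events.
#' Best-branch accuracy (match regardless of significance) is reported per
#' gene.
#'
#' @param scan A `branch_scan` over the simulated genes.
#' @param truth The matching `sim_truth`.
#' @param alpha Significance level (default: the scan's own).
#' @return List with `power`, `false_discovery_rate` and a per-gene
#'   tibble `genes` (`hmm_id`, `has_event`, `significant`, `matched`).
#' @export
evaluate_detection <- function(scan, truth, alpha = NULL) {
  stopifnot(inherits(scan, "branch_scan"), inherits(truth, "sim_truth"))
  if (nrow(scan$results) == 0L) {
    stop_param("empty scan results")
  }
  alpha <- alpha %||% scan$alpha
  scanned <- unique(scan$results$hmm_id)
  if (!setequal(scanned, names(truth$genes))) {
    stop_input("scan and truth cover different gene sets")
  }
  idx <- tree_index(truth$tree)
  best <- scan$results[scan$results$best, ]
  per_gene <- lapply(best$hmm_id, function(g) {
    row <- best[best$hmm_id == g, ]
    ev <- truth$genes[[g]]$events
    has_event <- nrow(ev) > 0L
    part <- scan$partitions[[row$level]]
    matched <- FALSE
    if (has_event) {
      for (child in unique(ev$child)) {
        clade <- idx$tips[[child]]
        if (any(vapply(part$members, setequal, TRUE, y = clade))) {
          matched <- TRUE
          break
        }
      }
    }
    tibble::tibble(hmm_id = g, has_event = has_event,
                   significant = row$p_value < alpha, matched = matched)
  })
  genes <- dplyr::bind_rows(per_gene)
  with_ev <- genes[genes$has_event, ]
  null_g <- genes[!genes$has_event, ]
  list(
    power = if (nrow(with_ev)) mean(with_ev$significant & with_ev$matched)
            else NA_real_,
    false_discovery_rate = if (nrow(null_g)) mean(null_g$significant)
                           else NA_real_,
    genes = genes
  )
}
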