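#' Simulate a Yule (pure-birth) tree
#'
#' While `k` lineages exist, the waiting time to the next speciation is
#' exponential with rate `k * birth_rate`; the lineage that splits is
#' chosen uniformly.  The clock starts at the root split (two lineages),
#' so the root height is the sum over k = 2..n of Exp(k * birth_rate)
#' waiting times, with expectation `(1/birth_rate) * sum_{k=2}^{n} 1/k`.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param birth_rate Speciation rate (> 0).
#' @return A rooted ultrametric `ape::phylo` with tips `t1..tn`.
#' @export
simulate_yule_tree <- function(n_taxa, birth_rate) {
  stopifnot(n_taxa >= 2, birth_rate > 0)
  waits <- stats::rexp(n_taxa - 1, rate = (2:n_taxa) * birth_rate)
  height <- sum(waits)
  root <- n_taxa + 1L
  next_internal <- root + 1L
  # active lineages: parent node id and start time
  act_parent <- c(root, root)
  act_start <- c(0, 0)
  ep <- ec <- integer(0); el <- numeric(0)
  if (n_taxa > 2) {
    times <- cumsum(waits)[1:(n_taxa - 2)]  # internal split times
    for (j in seq_along(times)) {
      i <- sample.int(length(act_parent), 1)
      node <- next_internal; next_internal <- next_internal + 1L
      ep <- c(ep, act_parent[i]); ec <- c(ec, node)
      el <- c(el, times[j] - act_start[i])
      act_parent <- c(act_parent[-i], node, node)
      act_start <- c(act_start[-i], times[j], times[j])
    }
  }
  ep <- c(ep, act_parent); ec <- c(ec, seq_len(n_taxa))
  el <- c(el, height - act_start)
  tree <- list(edge = cbind(ep, ec), edge.length = el,
               tip.label = paste0("t", seq_len(n_taxa)),
               Nnode = n_taxa - 1L)
  dimnames(tree$edge) <- NULL
  class(tree) <- "phylo"
  ape::reorder.phylo(tree, "cladewise")
}

#' Simulate a nucleotide alignment under a site-model state
#'
#' Per site a rate category is drawn from the state's
#' [category_mixture()].  A zero-rate (invariable) site copies a root
#' base drawn from the stationary frequencies to every taxon; otherwise
#' the root base is drawn from the frequencies and evolved along each
#' branch with the transition probabilities of the normalized rate
#' matrix at `category rate * branch length`.
#'
#' @param tree Rooted `ape::phylo` with branch lengths in expected
#'   substitutions per site.
#' @param state A [site_model_state()].
#' @param n_sites Number of sites.
#' @return A taxa x sites character matrix of bases (A, C, G, T), with
#'   the per-site category rates in attribute `"site_rates"`.
#' @export
simulate_alignment <- function(tree, state, n_sites) {
  stopifnot(n_sites > 0)
  bases <- c("A", "C", "G", "T")
  mix <- category_mixture(state)
  rates6 <- expand_rates(state$model, state$group_rates)
  Q <- rate_matrix(rates6, state$freqs, normalize = TRUE)
  dec <- decompose_q(Q, state$freqs)
  cat_of_site <- sample.int(length(mix$rates), n_sites, replace = TRUE,
                            prob = mix$weights)
  tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  ntip <- length(tr$tip.label)
  root <- tr$edge[1, 1]
  nodes_state <- matrix(0L, max(tr$edge), n_sites)
  nodes_state[root, ] <- sample.int(4, n_sites, replace = TRUE,
                                    prob = state$freqs)
  for (cat in unique(cat_of_site)) {
    idx <- which(cat_of_site == cat)
    rate <- mix$rates[cat]
    if (rate == 0) {
      # invariable: copy the root base everywhere
      for (e in seq_len(nrow(tr$edge)))
        nodes_state[tr$edge[e, 2], idx] <- nodes_state[tr$edge[e, 1], idx]
    } else {
      for (e in seq_len(nrow(tr$edge))) {
        P <- prob_matrix(dec, rate * tr$edge.length[e])
        P <- pmax(P, 0)
        par <- nodes_state[tr$edge[e, 1], idx]
        child <- integer(length(idx))
        for (b in 1:4) {
          sel <- par == b
          if (any(sel))
            child[sel] <- sample.int(4, sum(sel), replace = TRUE,
                                     prob = P[b, ])
        }
        nodes_state[tr$edge[e, 2], idx] <- child
      }
    }
  }
  aln <- matrix(bases[nodes_state[seq_len(ntip), , drop = FALSE]],
                nrow = ntip, dimnames = list(tr$tip.label, NULL))
  attr(aln, "site_rates") <- mix$rates[cat_of_site]
  aln
}

#' Simulation design for the calibration study
#'
#' @param tree_source `"fixed"` (use `newick`) or `"yule"` (a fresh
#'   Yule tree per replicate with the birth rate drawn from a log-normal
#'   with real-space mean `yule_mean` and log-scale sd `yule_sdlog`).
#' @param newick Newick string for the fixed tree; the default is the
#'   three-taxon calibration tree.
#' @param n_taxa Tips for Yule trees.
#' @param n_sites Alignment length per replicate.
#' @param replicates Number of replicates.
#' @param force Named list clamping indicator draws (see
#'   [sample_prior_state()]), defining one design cell, e.g.
#'   `list(has_gamma = 1, has_inv = 0, has_est_freqs = 0)`.
#' @param yule_mean,yule_sdlog Birth-rate prior (real-space mean and
#'   log-scale standard deviation).
#' @return A list of class `simulation_design`.
#' @export
simulation_design <- function(tree_source = c("fixed", "yule"),
                              newick = "(A:0.2,(B:0.15,C:0.15):0.05);",
                              n_taxa = 5, n_sites = 10000, replicates = 20,
                              force = list(),
                              yule_mean = 5.5, yule_sdlog = 0.048) {
  tree_source <- match.arg(tree_source)
  stopifnot(n_sites > 0, replicates > 0)
  structure(list(tree_source = tree_source, newick = newick,
                 n_taxa = n_taxa, n_sites = n_sites,
                 replicates = replicates, force = force,
                 yule_mean = yule_mean, yule_sdlog = yule_sdlog),
            class = "simulation_design")
}

#' Run the simulation-based calibration study
#'
#' For each replicate: draw a true site-model state from the prior
#' (with any clamped indicators), simulate an alignment, run the
#' reversible-jump chain on it, and keep the truth plus the trace.
#'
#' @param design A [simulation_design()].
#' @param chain_cfg A [chain_config()]; its seed seeds replicate `i`
#'   as `seed + i`.
#' @param prior_cfg A [prior_config()] used both for the truth draws
#'   and for the analysis.
#' @param set_kind Model set for truth draws and analysis.
#' @param truth_prior Optional separate [prior_config()] for the truth
#'   draws (defaults to `prior_cfg`).
#' @return A list with `truths` (list of states), `traces` (list of
#'   trace data frames) and `design`.
#' @export
run_validation_study <- function(design, chain_cfg, prior_cfg,
                                 set_kind = "tstv", truth_prior = prior_cfg) {
  models <- enumerate_models(set_kind)
  fixed_tree <- if (design$tree_source == "fixed")
    ape::read.tree(text = design$newick) else NULL
  truths <- traces <- vector("list", design$replicates)
  for (i in seq_len(design$replicates)) {
    rep_seed <- chain_cfg$seed + i
    set.seed(rep_seed)
    truth <- sample_prior_state(truth_prior, models, force = design$force)
    tree <- if (design$tree_source == "fixed") fixed_tree
            else simulate_yule_tree(design$n_taxa,
                                    stats::rlnorm(1,
                                      log(design$yule_mean) - design$yule_sdlog^2 / 2,
                                      design$yule_sdlog))
    aln <- simulate_alignment(tree, truth, design$n_sites)
    cfg_i <- chain_cfg
    cfg_i$seed <- rep_seed
    traces[[i]] <- run_chain(cfg_i, prior_cfg, set_kind,
                             alignment = aln, tree = tree)
    truths[[i]] <- truth
  }
  list(truths = truths, traces = traces, design = design)
}
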