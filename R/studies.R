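#' Rate-recovery study on the fixed three-taxon tree
#'
#' Reproduces the rate-accuracy calibration: site models are drawn from
#' the prior (transition rates log-normal with real-space mean 1,
#' transversion rates exponential mean 1; uniform model prior on the
#' transition/transversion split set), alignments of `n_sites` sites
#' are simulated on the tree `(A:0.2,(B:0.15,C:0.15):0.05)` -- half the
#' replicates with gamma rate heterogeneity, half without -- and each is
#' analysed with the reversible-jump chain.  Posterior-mean expanded
#' rates are then regressed on the true rates per rate position.
#'
#' @param replicates Number of replicates (half with, half without
#'   gamma rate heterogeneity; truths never include the explicit
#'   invariable-site category, though invariant columns arise freely).
#' @param n_sites Alignment length.
#' @param seed Base seed.
#' @param chain_length,log_every Chain settings per replicate.
#' @param set_kind Model set.
#' @param burnin Burn-in fraction discarded before posterior means.
#' @return A list with `r_squared` (named, per rate position), `truth`
#'   and `estimate` matrices (replicates x 6), and the per-replicate
#'   true states.
#' @export
rate_recovery_study <- function(replicates = 100, n_sites = 10000,
                                seed = 1, chain_length = 10000,
                                log_every = 10, set_kind = "tstv",
                                burnin = 0.2) {
  pc <- prior_config(rate_prior = "tstv", model_prior = "uniform")
  half <- ceiling(replicates / 2)
  truth_mat <- est_mat <- matrix(NA_real_, replicates, 6)
  colnames(truth_mat) <- colnames(est_mat) <-
    c("rateAC", "rateAG", "rateAT", "rateCG", "rateCT", "rateGT")
  truths <- vector("list", replicates)
  for (i in seq_len(replicates)) {
    # truths are plain or +G with equal base frequencies; invariant
    # columns arise stochastically from the gamma categories rather
    # than from an explicit +I truth (the analysis still averages over
    # all indicators)
    force <- list(has_gamma = as.integer(i > half), has_inv = 0,
                  has_est_freqs = 0)
    design <- simulation_design(tree_source = "fixed", n_sites = n_sites,
                                replicates = 1, force = force)
    cfg <- chain_config(chain_length = chain_length,
                        log_every = log_every, seed = seed * 1000 + i)
    res <- run_validation_study(design, cfg, pc, set_kind = set_kind)
    truths[[i]] <- res$truths[[1]]
    truth_mat[i, ] <- expand_rates(res$truths[[1]]$model,
                                   res$truths[[1]]$group_rates)
    tr <- discard_burnin(res$traces[[1]], burnin)
    est_mat[i, ] <- colMeans(as.matrix(tr[, colnames(est_mat)]))
  }
  r2 <- vapply(seq_len(6), function(p)
    stats::cor(truth_mat[, p], est_mat[, p])^2, 1)
  names(r2) <- colnames(truth_mat)
  list(r_squared = r2, truth = truth_mat, estimate = est_mat,
       truths = truths)
}

#' Coverage study over site-model variant cells
#'
#' Runs [run_validation_study()] for each requested cell of the
#' calibration grid (a combination of clamped gamma / invariable-site /
#' frequency indicators, everything else drawn from the prior) and
#' pools the replicates into one [coverage_report()].
#'
#' @param cells A list of named lists, each a `force` argument for
#'   [simulation_design()]; defaults to plain and +G under equal and
#'   estimated frequencies.
#' @param replicates Replicates per cell.
#' @param n_sites Alignment length.
#' @param seed Base seed.
#' @param chain_length,log_every Chain settings per replicate.
#' @param set_kind Model set.
#' @param level Credibility level.
#' @param burnin Burn-in fraction.
#' @return A list with `report` (pooled [coverage_report()]), and the
#'   pooled `truths` and `traces`.
#' @export
coverage_study <- function(cells = NULL, replicates = 15, n_sites = 10000,
                           seed = 1, chain_length = 30000, log_every = 6,
                           set_kind = "tstv", level = 0.95, burnin = 0.2) {
  if (is.null(cells))
    cells <- list(
      list(has_gamma = 0, has_inv = 0, has_est_freqs = 0),
      list(has_gamma = 1, has_inv = 0, has_est_freqs = 0),
      list(has_gamma = 0, has_inv = 0, has_est_freqs = 1),
      list(has_gamma = 1, has_inv = 0, has_est_freqs = 1))
  pc <- prior_config(rate_prior = "tstv", model_prior = "uniform")
  # operator schedule weighted toward the continuous parameters: HPD
  # intervals are interval *estimates*, and their accuracy is limited by
  # the effective sample size of each marginal, so the calibration study
  # spends proportionally more moves on rates, frequencies and shape
  w <- c(split = 1, merge = 1, rate_exchange = 3, gamma_flip = 0.7,
         inv_flip = 0.7, freq_flip = 0.7, variant_swap = 0.5,
         alpha_scale = 1.5, pinv_walk = 1, freq_walk = 2.5)
  truths <- traces <- list()
  for (ci in seq_along(cells)) {
    design <- simulation_design(tree_source = "fixed", n_sites = n_sites,
                                replicates = replicates,
                                force = cells[[ci]])
    cfg <- chain_config(chain_length = chain_length,
                        log_every = log_every, weights = w,
                        seed = seed * 10000 + ci * 100)
    res <- run_validation_study(design, cfg, pc, set_kind = set_kind)
    truths <- c(truths, res$truths)
    traces <- c(traces, res$traces)
  }
  list(report = coverage_report(truths, traces, level = level,
                                burnin = burnin),
       truths = truths, traces = traces)
}

#' Monte-Carlo tail probability of the base-frequency prior
#'
#' Probability, under the Dirichlet(4,4,4,4) base-frequency prior, that
#' the smallest of the four frequencies falls below a threshold.
#'
#' @param n Number of draws.
#' @param threshold Frequency threshold.
#' @param conc Dirichlet concentration vector.
#' @return Estimated probability (as a fraction, not percent).
#' @export
min_freq_tail_prob <- function(n = 1e6, threshold = 0.05,
                               conc = c(4, 4, 4, 4)) {
  # blockwise to bound memory
  hits <- 0
  left <- n
  while (left > 0) {
    b <- min(left, 2e5)
    g <- matrix(stats::rgamma(4 * b, rep(conc, each = b)), ncol = 4)
    hits <- hits + sum(g[cbind(seq_len(b), max.col(-g))] / rowSums(g) <
                         threshold)
    left <- left - b
  }
  hits / n
}

#' Mean Yule root height under the calibration birth-rate prior
#'
#' @param n Number of simulated trees.
#' @param n_taxa Tips per tree.
#' @param mean_rate Real-space mean of the log-normal birth-rate prior.
#' @param sdlog Log-scale standard deviation of the prior.
#' @return Mean root height across the simulated trees.
#' @export
mean_yule_height <- function(n = 10000, n_taxa = 5, mean_rate = 5.5,
                             sdlog = 0.048) {
  meanlog <- log(mean_rate) - sdlog^2 / 2
  heights <- vapply(seq_len(n), function(i) {
    lambda <- stats::rlnorm(1, meanlog, sdlog)
    tree <- simulate_yule_tree(n_taxa, lambda)
    max(ape::node.depth.edgelength(tree))
  }, 1)
  mean(heights)
}
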