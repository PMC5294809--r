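#' Chain configuration
#'
#' @param chain_length Total number of MCMC iterations.
#' @param log_every Thinning interval for the trace.
#' @param seed Integer seed; the chain is fully reproducible.
#' @param weights Named numeric operator weights.  Operators:
#'   `split`, `merge`, `rate_exchange`, `gamma_flip`, `inv_flip`,
#'   `freq_flip`, `variant_swap`, `alpha_scale`, `pinv_walk`,
#'   `freq_walk`.
#' @param delta Initial window of the rate-exchange proposal.
#' @param scale_log_window Initial log-window of the multiplicative
#'   scale proposal for `alpha`.
#' @param pinv_sigma Initial standard deviation of the logit-space
#'   random walk on `p_inv`.
#' @param freq_conc Concentration of the Dirichlet frequency walk.
#' @param target_acceptance Tuning target for the adapted proposals.
#' @param burnin_frac Fraction of the chain treated as burn-in; tuning
#'   parameters adapt (Robbins-Monro) only during burn-in and are frozen
#'   afterwards so detailed balance holds for the retained sample.
#' @return A list of class `chain_config`.
#' @export
chain_config <- function(chain_length = 10000L, log_every = 10L, seed = 1L,
                         weights = c(split = 1, merge = 1, rate_exchange = 2,
                                     gamma_flip = 1, inv_flip = 1,
                                     freq_flip = 1, variant_swap = 0.5,
                                     alpha_scale = 1,
                                     pinv_walk = 1, freq_walk = 1),
                         delta = 1, scale_log_window = 1.4,
                         pinv_sigma = 1, freq_conc = 150,
                         target_acceptance = 0.234, burnin_frac = 0.1) {
  stopifnot(chain_length > 0, log_every > 0, all(weights >= 0),
            any(weights > 0), delta > 0, burnin_frac >= 0, burnin_frac < 1)
  structure(list(chain_length = as.integer(chain_length),
                 log_every = as.integer(log_every), seed = as.integer(seed),
                 weights = weights, delta = delta,
                 scale_log_window = scale_log_window,
                 pinv_sigma = pinv_sigma, freq_conc = freq_conc,
                 target_acceptance = target_acceptance,
                 burnin_frac = burnin_frac),
            class = "chain_config")
}

proposal_outcome <- function(state, log_hastings = 0, valid = TRUE,
                             noop = FALSE) {
  list(state = state, log_hastings = log_hastings, valid = valid,
       noop = noop)
}

# Locate which group of `parent_model` the groups of `child_model` come
# from; returns integer vector over child groups.  Memoized: there are
# at most a few hundred (child, parent) pairs.
group_parent_map <- function(child_model, parent_model) {
  model_memo(paste0("m", child_model, parent_model), function() {
    gc <- model_groups(child_model)
    gp <- model_groups(parent_model)
    vapply(gc, function(g)
      which(vapply(gp, function(h) all(g %in% h), TRUE))[1], 1L)
  })
}

#' Split proposal (trans-dimensional)
#'
#' Refines the current substitution model along a split edge of the
#' model graph: a child model is chosen uniformly among the split
#' candidates, the rate `r` of the split group is divided between the
#' two new groups (sizes `n_i`, `n_j`) as `r_i = r + u/n_i`,
#' `r_j = r - u/n_j` with `u` uniform on `(-n_i r, n_j r)`, which keeps
#' the expanded rates summing to 6.  At GTR (no candidates) the current
#' state is proposed, which is what makes uniform model sampling exact.
#' The returned `log_hastings` holds the proposal-ratio and Jacobian
#' contributions under the standard Metropolis-Hastings-Green
#' convention; the per-model volume factor of the constrained rate space
#' lives in [log_prior()].
#'
#' @param state A [site_model_state()].
#' @param graph A [model_graph()].
#' @return A proposal outcome: list with `state`, `log_hastings`,
#'   `valid`, `noop`.
#' @export
propose_split <- function(state, graph) {
  S <- split_candidates(state$model, graph)
  if (length(S) == 0) return(proposal_outcome(state, noop = TRUE))
  child <- sample(rep(S, 2), 1)
  map <- group_parent_map(child, state$model)
  s <- map[duplicated(map) | duplicated(map, fromLast = TRUE)][1]
  ij <- which(map == s)
  sizes_child <- lengths(model_groups(child))
  ni <- sizes_child[ij[1]]; nj <- sizes_child[ij[2]]
  r <- state$group_rates[s]
  u <- stats::runif(1, -ni * r, nj * r)
  ri <- r + u / ni; rj <- r - u / nj
  if (ri <= 0 || rj <= 0) return(proposal_outcome(state, valid = FALSE))
  new_rates <- numeric(length(sizes_child))
  for (g in seq_along(sizes_child))
    new_rates[g] <- if (g == ij[1]) ri else if (g == ij[2]) rj
                    else state$group_rates[map[g]]
  ns <- state
  ns$model <- child
  ns$group_rates <- new_rates
  P <- merge_candidates(child, graph)
  lh <- log(length(S)) - log(length(P)) +
    log(r * (ni + nj)) + log((ni + nj) / (ni * nj))
  proposal_outcome(ns, lh)
}

#' Merge proposal (trans-dimensional)
#'
#' Coarsens the current model along a merge edge: a parent model is
#' chosen uniformly among the merge candidates and the two merged groups
#' are replaced by one of rate `(n_i r_i + n_j r_j) / (n_i + n_j)`.
#' At model 111111 (no candidates) the current state is proposed.
#'
#' @inheritParams propose_split
#' @return A proposal outcome.
#' @export
propose_merge <- function(state, graph) {
  P <- merge_candidates(state$model, graph)
  if (length(P) == 0) return(proposal_outcome(state, noop = TRUE))
  parent <- sample(rep(P, 2), 1)
  map <- group_parent_map(state$model, parent)
  s <- map[duplicated(map) | duplicated(map, fromLast = TRUE)][1]
  ij <- which(map == s)
  sizes <- lengths(model_groups(state$model))
  ni <- sizes[ij[1]]; nj <- sizes[ij[2]]
  ri <- state$group_rates[ij[1]]; rj <- state$group_rates[ij[2]]
  r <- (ni * ri + nj * rj) / (ni + nj)
  nparent <- length(model_groups(parent))
  new_rates <- numeric(nparent)
  for (g in seq_len(nparent))
    new_rates[g] <- if (g == s) r else state$group_rates[which(map == g)[1]]
  ns <- state
  ns$model <- parent
  ns$group_rates <- new_rates
  S <- split_candidates(parent, graph)
  lh <- log(length(P)) - log(length(S)) -
    log(r * (ni + nj)) - log((ni + nj) / (ni * nj))
  proposal_outcome(ns, lh)
}

#' Rate-exchange proposal
#'
#' Moves rate between two randomly chosen groups:
#' `r_i' = r_i - u`, `r_j' = r_j + u n_i / n_j` with
#' `u ~ Uniform(0, delta)`, preserving the sum-to-6 constraint.  Fails
#' (automatic reject) when `r_i'` would be negative.  The reverse move
#' decrements `r_j` by `u n_i / n_j`, so the proposal is only symmetric
#' when the two group sizes are equal: in general the Hastings factor is
#' `n_i / n_j`, and the move must also be rejected when the reverse
#' draw `u n_i / n_j` falls outside the window `(0, delta)` (otherwise
#' the reverse density is zero).  Both corrections are required for the
#' chain to sample models without bias, which the prior-sampling tests
#' verify.
#'
#' @param state A [site_model_state()].
#' @param delta Window width (> 0).
#' @return A proposal outcome.
#' @export
propose_rate_exchange <- function(state, delta) {
  sizes <- lengths(model_groups(state$model))
  if (length(sizes) < 2) return(proposal_outcome(state, noop = TRUE))
  ij <- sample(length(sizes), 2)
  ni <- sizes[ij[1]]; nj <- sizes[ij[2]]
  u <- stats::runif(1, 0, delta)
  ri <- state$group_rates[ij[1]] - u
  if (ri <= 0 || u * ni / nj > delta)
    return(proposal_outcome(state, valid = FALSE))
  ns <- state
  ns$group_rates[ij[1]] <- ri
  ns$group_rates[ij[2]] <- state$group_rates[ij[2]] + u * ni / nj
  proposal_outcome(ns, log(ni / nj))
}

#' Indicator birth/death proposals
#'
#' Toggle one of the binary indicators.  A birth draws the associated
#' parameter fresh from its prior density `d` (gamma shape, proportion
#' invariable, or base frequencies), so the Hastings term is
#' `-log d(new)` for a birth and `+log d(current)` for a death; the
#' Jacobian is 1.  With the prior itself as `d`, prior and proposal
#' densities cancel in the acceptance ratio and only the indicator prior
#' and the likelihood remain.
#'
#' @param state A [site_model_state()].
#' @param cfg A [prior_config()].
#' @param which One of `"gamma"`, `"inv"`, `"freqs"`.
#' @return A proposal outcome.
#' @export
propose_indicator_flip <- function(state, cfg, which = c("gamma", "inv", "freqs")) {
  which <- match.arg(which)
  ns <- state
  if (which == "gamma") {
    if (!state$has_gamma) {
      ns$has_gamma <- 1L
      ns$alpha <- stats::rexp(1, cfg$alpha_rate)
      lh <- -stats::dexp(ns$alpha, cfg$alpha_rate, log = TRUE)
    } else {
      ns$has_gamma <- 0L
      lh <- stats::dexp(state$alpha, cfg$alpha_rate, log = TRUE)
    }
  } else if (which == "inv") {
    if (!state$has_inv) {
      ns$has_inv <- 1L
      ns$p_inv <- stats::rbeta(1, cfg$pinv_shape1, cfg$pinv_shape2)
      lh <- -stats::dbeta(ns$p_inv, cfg$pinv_shape1, cfg$pinv_shape2,
                          log = TRUE)
    } else {
      ns$has_inv <- 0L
      lh <- stats::dbeta(state$p_inv, cfg$pinv_shape1, cfg$pinv_shape2,
                         log = TRUE)
    }
  } else {
    if (!state$has_est_freqs) {
      ns$has_est_freqs <- 1L
      ns$freqs <- rdirichlet1(cfg$freq_conc)
      lh <- -log_ddirichlet(ns$freqs, cfg$freq_conc)
    } else {
      ns$has_est_freqs <- 0L
      lh <- log_ddirichlet(state$freqs, cfg$freq_conc)
      ns$freqs <- rep(0.25, 4)
    }
  }
  proposal_outcome(ns, lh)
}

#' Variant-swap proposal
#'
#' Exchanges the two single-component rate-heterogeneity variants in
#' one move: from +G (gamma only) it proposes +I with a fresh `p_inv`
#' from its prior, and from +I it proposes +G with a fresh `alpha`.
#' The two variants often fit similar signals (many slow sites), but
#' the stepwise route between them via +G+I requires the retained
#' parameter to stay fixed while the other is born, which can leave a
#' chain trapped in one variant for thousands of iterations; the direct
#' swap bridges the two modes.  Hastings term: log of the abandoned
#' parameter's density minus log of the new parameter's density;
#' Jacobian 1.  A no-op from plain or +G+I states.
#'
#' @param state A [site_model_state()].
#' @param cfg A [prior_config()].
#' @return A proposal outcome.
#' @export
propose_variant_swap <- function(state, cfg) {
  ns <- state
  if (state$has_gamma == 1L && state$has_inv == 0L) {
    ns$has_gamma <- 0L; ns$has_inv <- 1L
    ns$p_inv <- stats::rbeta(1, cfg$pinv_shape1, cfg$pinv_shape2)
    lh <- stats::dexp(state$alpha, cfg$alpha_rate, log = TRUE) -
      stats::dbeta(ns$p_inv, cfg$pinv_shape1, cfg$pinv_shape2, log = TRUE)
  } else if (state$has_gamma == 0L && state$has_inv == 1L) {
    ns$has_gamma <- 1L; ns$has_inv <- 0L
    ns$alpha <- stats::rexp(1, cfg$alpha_rate)
    lh <- stats::dbeta(state$p_inv, cfg$pinv_shape1, cfg$pinv_shape2,
                       log = TRUE) -
      stats::dexp(ns$alpha, cfg$alpha_rate, log = TRUE)
  } else {
    return(proposal_outcome(state, noop = TRUE))
  }
  proposal_outcome(ns, lh)
}

#' Multiplicative scale proposal
#'
#' Scales a positive value by `exp(lambda * (U - 1/2))` with `U` uniform,
#' i.e. a random walk on the log scale; the Hastings term is `+log s`.
#'
#' @param value Positive value to scale.
#' @param log_window Width `lambda` of the log-scale window.
#' @return List with `value` (scaled) and `log_hastings`.
#' @export
propose_scale <- function(value, log_window) {
  s <- exp(log_window * (stats::runif(1) - 0.5))
  list(value = value * s, log_hastings = log(s))
}

#' Logit random-walk proposal for a proportion
#'
#' @param p Current value in (0, 1).
#' @param sigma Walk standard deviation on the logit scale.
#' @return List with `value` and `log_hastings`.
#' @export
propose_logit_walk <- function(p, sigma) {
  y <- log(p / (1 - p)) + stats::rnorm(1, 0, sigma)
  pn <- 1 / (1 + exp(-y))
  list(value = pn,
       log_hastings = log(pn * (1 - pn)) - log(p * (1 - p)))
}

#' Dirichlet frequency-walk proposal
#'
#' Proposes `f' ~ Dirichlet(conc * f)`; only applicable when base
#' frequencies are being estimated.
#'
#' @param state A [site_model_state()] with `has_est_freqs = 1`.
#' @param conc Concentration of the proposal kernel.
#' @return A proposal outcome.
#' @export
propose_freq_walk <- function(state, conc) {
  if (!state$has_est_freqs) return(proposal_outcome(state, noop = TRUE))
  f <- state$freqs
  fn <- rdirichlet1(conc * f)
  if (any(fn <= 1e-12)) return(proposal_outcome(state, valid = FALSE))
  ns <- state
  ns$freqs <- fn
  lh <- log_ddirichlet(f, conc * fn) - log_ddirichlet(fn, conc * f)
  proposal_outcome(ns, lh)
}

TRACE_NUM_COLS <- c("Sample", "posterior", "likelihood", "prior",
                    "rateAC", "rateAG", "rateAT", "rateCG", "rateCT",
                    "rateGT", "hasGammaRates", "gammaShape",
                    "hasInvariableSites", "proportionInvariable",
                    "hasEqualFreqs", "freqA", "freqC", "freqG", "freqT")

#' Run the reversible-jump site-model chain
#'
#' A Metropolis-Hastings(-Green) sampler over substitution models, rate
#' parameters, gamma/invariable-site indicators and base frequencies.
#' Operators are selected by weight each iteration; acceptance is
#' `min(1, exp(log posterior ratio + log Hastings))`.  The rate-exchange
#' window, the `alpha` scale window and the `p_inv` walk are tuned
#' toward the target acceptance during burn-in and frozen afterwards.
#'
#' @param chain_cfg A [chain_config()].
#' @param prior_cfg A [prior_config()].
#' @param set_kind Model set (`"all"`, `"tstv"`, `"named"`) or a
#'   character vector of models.
#' @param alignment,tree Data for the likelihood: any input accepted by
#'   [compress_patterns()] and a rooted `ape::phylo`.  If both are
#'   `NULL` the likelihood is constant 0 and the chain samples the
#'   prior.
#' @param likelihood Optional likelihood function of one state argument
#'   (e.g. from [likelihood_evaluator()]); overrides `alignment`/`tree`.
#' @param init Optional initial [site_model_state()]; defaults to the
#'   Jukes-Cantor state with all indicators off.
#' @param k Number of gamma categories.
#' @return A `data.frame` trace (one row per retained sample) with the
#'   sampled model, the six expanded rates, indicators, `gammaShape`,
#'   `proportionInvariable`, frequencies, and log posterior /
#'   likelihood / prior.  Attributes: `graph`, `accept_rates`.
#' @export
run_chain <- function(chain_cfg, prior_cfg, set_kind = "tstv",
                      alignment = NULL, tree = NULL, likelihood = NULL,
                      init = NULL, k = 4L) {
  models <- if (length(set_kind) == 1 && set_kind %in% c("all", "tstv", "named"))
    enumerate_models(set_kind) else sort(unique(set_kind))
  graph <- model_graph(models)
  const_lik <- FALSE
  if (is.null(likelihood)) {
    if (is.null(alignment)) {
      const_lik <- TRUE
      likelihood <- function(state) 0
    } else {
      pt <- if (inherits(alignment, "pattern_table")) alignment
            else compress_patterns(alignment)
      likelihood <- likelihood_evaluator(tree, pt)
    }
  }
  set.seed(chain_cfg$seed)
  state <- if (is.null(init)) site_model_state("111111", k = k) else init
  info <- graph$info
  # model prior and rate-space volume folded into one per-model constant
  base_lp <- new.env(parent = emptyenv())
  for (mm in models)
    assign(mm, model_log_prior(mm, models, prior_cfg$model_prior) -
               log_rate_volume(mm), envir = base_lp)
  tstv <- prior_cfg$rate_prior == "tstv"
  pind <- prior_cfg$indicator_prob
  ar <- prior_cfg$alpha_rate
  b1 <- prior_cfg$pinv_shape1; b2 <- prior_cfg$pinv_shape2
  fc <- prior_cfg$freq_conc
  lp_of <- function(m, rates, hg, alpha, hi, pinv, hf, freqs) {
    lp <- base_lp[[m]]
    if (tstv)
      lp <- lp + log_tstv_density(rates[info[[m]]$code], prior_cfg)
    nset <- hg + hi + hf
    lp <- lp + nset * log(pind) + (3 - nset) * log(1 - pind)
    if (hg) lp <- lp + stats::dexp(alpha, ar, log = TRUE)
    if (hi) lp <- lp + stats::dbeta(pinv, b1, b2, log = TRUE)
    if (hf) lp <- lp + log_ddirichlet(freqs, fc)
    lp
  }
  mk_state <- function(m, rates, hg, alpha, hi, pinv, hf, freqs) {
    structure(list(model = m, group_rates = rates, has_gamma = hg,
                   alpha = alpha, has_inv = hi, p_inv = pinv,
                   has_est_freqs = hf, freqs = freqs, k = k),
              class = "site_model_state")
  }
  # unpack the state into locals for the hot loop
  m <- state$model; rates <- state$group_rates
  hg <- state$has_gamma; alpha <- state$alpha
  hi <- state$has_inv; pinv <- state$p_inv
  hf <- state$has_est_freqs; freqs <- state$freqs
  k <- state$k
  ll <- likelihood(state)
  lp <- lp_of(m, rates, hg, alpha, hi, pinv, hf, freqs)
  if (!is.finite(ll + lp))
    stop("initial state has non-finite posterior (likelihood = ", ll,
         ", prior = ", lp, ")")
  w <- chain_cfg$weights[chain_cfg$weights > 0]
  ops <- names(w)
  wcum <- cumsum(w / sum(w))
  nops <- length(ops)
  burnin <- floor(chain_cfg$burnin_frac * chain_cfg$chain_length)
  delta <- chain_cfg$delta
  scale_w <- chain_cfg$scale_log_window
  sigma <- chain_cfg$pinv_sigma
  freq_conc <- chain_cfg$freq_conc
  target <- chain_cfg$target_acceptance
  n_prop <- n_acc <- stats::setNames(numeric(nops), ops)
  nret <- floor(chain_cfg$chain_length / chain_cfg$log_every)
  num <- matrix(NA_real_, nret, length(TRACE_NUM_COLS),
                dimnames = list(NULL, TRACE_NUM_COLS))
  mods <- character(nret)
  nrow_out <- 0L
  for (it in seq_len(chain_cfg$chain_length)) {
    oi <- findInterval(stats::runif(1), wcum) + 1L
    if (oi > nops) oi <- nops
    op <- ops[oi]
    # proposal: new candidate components + log Hastings, or noop/invalid
    noop <- FALSE; valid <- TRUE; lh <- 0
    m2 <- m; rates2 <- rates; hg2 <- hg; alpha2 <- alpha
    hi2 <- hi; pinv2 <- pinv; hf2 <- hf; freqs2 <- freqs
    ei <- info[[m]]
    if (op == "split") {
      sp <- ei$splits
      if (length(sp) == 0L) noop <- TRUE
      else {
        ch <- sp[[sample.int(length(sp), 1L)]]
        r <- rates[ch$s]
        u <- stats::runif(1, -ch$ni * r, ch$nj * r)
        ri <- r + u / ch$ni; rj <- r - u / ch$nj
        if (ri <= 0 || rj <= 0) valid <- FALSE
        else {
          m2 <- ch$child
          rates2 <- rates[ch$map]
          rates2[ch$i1] <- ri; rates2[ch$i2] <- rj
          nn <- ch$ni + ch$nj
          lh <- log(length(sp)) - log(length(info[[m2]]$merges)) +
            log(r * nn) + log(nn / (ch$ni * ch$nj))
        }
      }
    } else if (op == "merge") {
      me <- ei$merges
      if (length(me) == 0L) noop <- TRUE
      else {
        pa <- me[[sample.int(length(me), 1L)]]
        nn <- pa$ni + pa$nj
        r <- (pa$ni * rates[pa$i1] + pa$nj * rates[pa$i2]) / nn
        m2 <- pa$parent
        rates2 <- numeric(pa$nparent)
        rates2[pa$map] <- rates
        rates2[pa$s] <- r
        lh <- log(length(me)) - log(length(info[[m2]]$splits)) -
          log(r * nn) - log(nn / (pa$ni * pa$nj))
      }
    } else if (op == "rate_exchange") {
      G <- ei$ngroups
      if (G < 2L) noop <- TRUE
      else {
        i <- sample.int(G, 1L)
        j <- sample.int(G - 1L, 1L); if (j >= i) j <- j + 1L
        sz <- ei$sizes
        u <- stats::runif(1, 0, delta)
        back <- u * sz[i] / sz[j]
        ri <- rates[i] - u
        if (ri <= 0 || back > delta) valid <- FALSE
        else {
          rates2[i] <- ri
          rates2[j] <- rates[j] + back
          lh <- log(sz[i] / sz[j])
        }
      }
    } else if (op == "gamma_flip") {
      if (!hg) {
        hg2 <- 1L
        alpha2 <- stats::rexp(1, ar)
        lh <- -stats::dexp(alpha2, ar, log = TRUE)
      } else {
        hg2 <- 0L
        lh <- stats::dexp(alpha, ar, log = TRUE)
      }
    } else if (op == "inv_flip") {
      if (!hi) {
        hi2 <- 1L
        pinv2 <- stats::rbeta(1, b1, b2)
        lh <- -stats::dbeta(pinv2, b1, b2, log = TRUE)
      } else {
        hi2 <- 0L
        lh <- stats::dbeta(pinv, b1, b2, log = TRUE)
      }
    } else if (op == "freq_flip") {
      if (!hf) {
        hf2 <- 1L
        freqs2 <- rdirichlet1(fc)
        lh <- -log_ddirichlet(freqs2, fc)
      } else {
        hf2 <- 0L
        lh <- log_ddirichlet(freqs, fc)
        freqs2 <- rep(0.25, 4)
      }
    } else if (op == "variant_swap") {
      if (hg == 1L && hi == 0L) {
        hg2 <- 0L; hi2 <- 1L
        pinv2 <- stats::rbeta(1, b1, b2)
        lh <- stats::dexp(alpha, ar, log = TRUE) -
          stats::dbeta(pinv2, b1, b2, log = TRUE)
      } else if (hg == 0L && hi == 1L) {
        hg2 <- 1L; hi2 <- 0L
        alpha2 <- stats::rexp(1, ar)
        lh <- stats::dbeta(pinv, b1, b2, log = TRUE) -
          stats::dexp(alpha2, ar, log = TRUE)
      } else noop <- TRUE
    } else if (op == "alpha_scale") {
      if (!hg) noop <- TRUE
      else {
        s <- exp(scale_w * (stats::runif(1) - 0.5))
        alpha2 <- alpha * s
        lh <- log(s)
      }
    } else if (op == "pinv_walk") {
      if (!hi) noop <- TRUE
      else {
        y <- log(pinv / (1 - pinv)) + stats::rnorm(1, 0, sigma)
        pinv2 <- 1 / (1 + exp(-y))
        if (pinv2 <= 0 || pinv2 >= 1) valid <- FALSE
        else lh <- log(pinv2 * (1 - pinv2)) - log(pinv * (1 - pinv))
      }
    } else if (op == "freq_walk") {
      if (!hf) noop <- TRUE
      else {
        freqs2 <- rdirichlet1(freq_conc * freqs)
        if (any(freqs2 <= 1e-12)) valid <- FALSE
        else lh <- log_ddirichlet(freqs, freq_conc * freqs2) -
               log_ddirichlet(freqs2, freq_conc * freqs)
      }
    }
    accepted <- FALSE
    if (noop) {
      accepted <- TRUE  # self-proposal (e.g. split at GTR): always accepted
    } else if (valid) {
      lp2 <- lp_of(m2, rates2, hg2, alpha2, hi2, pinv2, hf2, freqs2)
      if (is.finite(lp2)) {
        ll2 <- if (const_lik) 0 else
          likelihood(mk_state(m2, rates2, hg2, alpha2, hi2, pinv2, hf2,
                              freqs2))
        ratio <- (ll2 + lp2) - (ll + lp) + lh
        if (is.finite(ratio) && log(stats::runif(1)) < ratio) {
          m <- m2; rates <- rates2; hg <- hg2; alpha <- alpha2
          hi <- hi2; pinv <- pinv2; hf <- hf2; freqs <- freqs2
          ll <- ll2; lp <- lp2
          accepted <- TRUE
        }
      }
    }
    if (!noop) {
      n_prop[oi] <- n_prop[oi] + 1
      n_acc[oi] <- n_acc[oi] + accepted
      if (it <= burnin &&
          (op == "rate_exchange" || op == "alpha_scale" ||
           op == "pinv_walk" || op == "freq_walk")) {
        step <- exp(((if (accepted) 1 else 0) - target) /
                      sqrt(10 + n_prop[oi]))
        if (op == "rate_exchange") delta <- delta * step
        else if (op == "alpha_scale") scale_w <- scale_w * step
        else if (op == "pinv_walk") sigma <- sigma * step
        # concentration is an inverse step size: low acceptance means
        # the walk is too diffuse, so raise the concentration
        else freq_conc <- freq_conc / step
      }
    }
    if (it %% chain_cfg$log_every == 0L) {
      nrow_out <- nrow_out + 1L
      num[nrow_out, ] <- c(it, ll + lp, ll, lp, rates[info[[m]]$code],
                           hg, alpha, hi, pinv, 1 - hf, freqs)
      mods[nrow_out] <- m
    }
  }
  trace <- as.data.frame(num[seq_len(nrow_out), , drop = FALSE])
  trace$model <- mods[seq_len(nrow_out)]
  trace <- trace[, c("Sample", "posterior", "likelihood", "prior", "model",
                     "rateAC", "rateAG", "rateAT", "rateCG", "rateCT",
                     "rateGT", "hasGammaRates", "gammaShape",
                     "hasInvariableSites", "proportionInvariable",
                     "hasEqualFreqs", "freqA", "freqC", "freqG", "freqT")]
  attr(trace, "graph") <- graph
  attr(trace, "accept_rates") <- ifelse(n_prop > 0, n_acc / n_prop, NA)
  attr(trace, "tuning") <- list(delta = delta, scale = scale_w,
                                sigma = sigma, freq_conc = freq_conc)
  trace
}
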