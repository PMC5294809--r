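graph_tstv <- model_graph(enumerate_models("tstv"))

test_that("split and merge preserve the rate-sum constraint and invert", {
  set.seed(61)
  for (i in 1:100) {
    m <- sample(enumerate_models("tstv"), 1)
    st <- random_state(m)
    out <- propose_split(st, graph_tstv)
    sizes <- lengths(model_groups(out$state$model))
    expect_equal(sum(sizes * out$state$group_rates), 6, tolerance = 1e-9)
    if (!out$noop && out$valid) {
      expect_equal(model_dof(out$state$model), model_dof(m) + 1L)
      back <- propose_merge(out$state, graph_tstv)
      # merging is the exact inverse when it lands on the original model
      if (back$state$model == m) {
        expect_equal(back$state$group_rates, st$group_rates,
                     tolerance = 1e-9)
        # and the Hastings terms cancel for the matched pair
        expect_equal(out$log_hastings + back$log_hastings, 0,
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("merge rate is the size-weighted mean", {
  # HKY: transversion group (4 positions) at rate 0.5, transition group
  # (2 positions) at rate 2; merging to JC gives (4*0.5 + 2*2)/6 = 1
  st <- site_model_state("121121", c(0.5, 2))
  g <- model_graph(c("111111", "121121"))
  out <- propose_merge(st, g)
  expect_equal(out$state$model, "111111")
  expect_equal(out$state$group_rates, 1)
})

test_that("boundary models self-propose on split/merge", {
  gtr <- random_state("123456")
  out <- propose_split(gtr, graph_tstv)
  expect_true(out$noop)
  expect_equal(out$state$model, "123456")
  expect_equal(out$log_hastings, 0)
  jc <- site_model_state("111111")
  out2 <- propose_merge(jc, graph_tstv)
  expect_true(out2$noop)
  expect_equal(out2$state$model, "111111")
})

test_that("split candidates are proposed uniformly", {
  st <- site_model_state("111111")
  S <- split_candidates("111111", graph_tstv)
  set.seed(71)
  picks <- replicate(3000, propose_split(st, graph_tstv)$state$model)
  f <- table(factor(picks, levels = S)) / length(picks)
  expect_lt(max(abs(f - 1 / length(S))),
            4 * sqrt((1 / length(S)) / 3000))
})

test_that("split Jacobian matches the finite-difference determinant", {
  # map (r, u) -> (r_i, r_j) = (r + u/n_i, r - u/n_j)
  for (ns in list(c(1, 1), c(2, 1), c(3, 2), c(4, 2))) {
    ni <- ns[1]; nj <- ns[2]
    f <- function(x) c(x[1] + x[2] / ni, x[1] - x[2] / nj)
    h <- 1e-6
    x0 <- c(1.3, 0.2)
    J <- matrix(0, 2, 2)
    for (c in 1:2) {
      e <- c(0, 0); e[c] <- h
      J[, c] <- (f(x0 + e) - f(x0 - e)) / (2 * h)
    }
    expect_equal(abs(det(J)), (ni + nj) / (ni * nj), tolerance = 1e-6)
  }
})

test_that("rate exchange respects its support and Hastings factor", {
  st <- site_model_state("121121", c(0.1, 2.8))
  # forcing u > r_i must invalidate the move
  set.seed(81)
  outs <- replicate(200, propose_rate_exchange(st, delta = 2),
                    simplify = FALSE)
  moved <- Filter(function(o) o$valid && !o$noop, outs)
  for (o in moved) {
    sizes <- lengths(model_groups(o$state$model))
    expect_equal(sum(sizes * o$state$group_rates), 6, tolerance = 1e-9)
    expect_true(all(o$state$group_rates > 0))
    # Hastings factor is log(n_i/n_j) with sizes 4 and 2 here
    expect_true(any(abs(o$log_hastings - c(log(2), log(0.5))) < 1e-12))
  }
  expect_true(any(!vapply(outs, `[[`, TRUE, "valid")))
  # single-group model: operator is a no-op
  expect_true(propose_rate_exchange(site_model_state("111111"), 1)$noop)
})

test_that("indicator births draw from the prior and deaths reverse them", {
  cfg <- prior_config()
  st <- site_model_state("111111")
  set.seed(91)
  born <- propose_indicator_flip(st, cfg, "gamma")
  expect_equal(born$state$has_gamma, 1L)
  expect_equal(born$log_hastings,
               -dexp(born$state$alpha, 1, log = TRUE))
  dead <- propose_indicator_flip(born$state, cfg, "gamma")
  expect_equal(dead$state$has_gamma, 0L)
  # birth then death restores the original log target contribution
  expect_equal(born$log_hastings + dead$log_hastings, 0, tolerance = 1e-12)
  fr <- propose_indicator_flip(st, cfg, "freqs")
  expect_equal(fr$state$has_est_freqs, 1L)
  expect_equal(sum(fr$state$freqs), 1, tolerance = 1e-12)
  back <- propose_indicator_flip(fr$state, cfg, "freqs")
  expect_equal(back$state$freqs, rep(0.25, 4))
})

test_that("scale and walk proposals stay in their supports", {
  set.seed(95)
  for (i in 1:50) {
    sc <- propose_scale(0.8, 1.4)
    expect_gt(sc$value, 0)
    wk <- propose_logit_walk(0.3, 1)
    expect_gt(wk$value, 0); expect_lt(wk$value, 1)
  }
  st <- site_model_state("111111", has_est_freqs = 1,
                         freqs = c(0.3, 0.3, 0.2, 0.2))
  for (i in 1:20) {
    o <- propose_freq_walk(st, 200)
    if (o$valid) {
      expect_equal(sum(o$state$freqs), 1, tolerance = 1e-12)
      expect_true(all(o$state$freqs > 0))
    }
  }
  # freq walk is a no-op in equal-frequency mode
  expect_true(propose_freq_walk(site_model_state("111111"), 200)$noop)
})

test_that("chains are reproducible and respect state invariants", {
  cfg <- chain_config(chain_length = 4000, log_every = 10, seed = 11)
  pc <- prior_config()
  tr1 <- run_chain(cfg, pc, "named")
  tr2 <- run_chain(cfg, pc, "named")
  expect_identical(tr1, tr2)
  expect_equal(rowSums(tr1[, c("rateAC", "rateAG", "rateAT", "rateCG",
                               "rateCT", "rateGT")]),
               rep(6, nrow(tr1)), tolerance = 1e-9,
               ignore_attr = TRUE)
  fr <- as.matrix(tr1[, c("freqA", "freqC", "freqG", "freqT")])
  expect_equal(unname(rowSums(fr)), rep(1, nrow(tr1)), tolerance = 1e-9)
  expect_true(all(tr1$model %in% enumerate_models("named")))
  # different seed gives a different path
  cfg3 <- chain_config(chain_length = 4000, log_every = 10, seed = 12)
  expect_false(identical(run_chain(cfg3, pc, "named"), tr1))
})

test_that("a prior-only chain matches the prior marginals", {
  w <- c(split = 3, merge = 3, rate_exchange = 2, gamma_flip = 0.5,
         inv_flip = 0.5, freq_flip = 0.5, variant_swap = 0.5,
         alpha_scale = 0.5, pinv_walk = 0.5, freq_walk = 0.5)
  cfg <- chain_config(chain_length = 1.2e5, log_every = 30, seed = 13,
                      weights = w)
  pc <- prior_config()
  tr <- run_chain(cfg, pc, "tstv")
  f <- table(factor(tr$model, levels = enumerate_models("tstv")))
  expect_gt(chisq.test(f)$p.value, 0.001)
  expect_lt(abs(mean(tr$hasGammaRates) - 0.5), 0.05)
  expect_lt(abs(mean(tr$hasInvariableSites) - 0.5), 0.05)
  expect_lt(abs(mean(1 - tr$hasEqualFreqs) - 0.5), 0.05)
  # alpha given the indicator: Exponential(1) moments
  a <- tr$gammaShape[tr$hasGammaRates == 1]
  expect_lt(abs(mean(a) - 1), 0.1)
  p <- tr$proportionInvariable[tr$hasInvariableSites == 1]
  expect_lt(abs(mean(p) - 0.2), 0.03)
  fA <- tr$freqA[tr$hasEqualFreqs == 0]
  expect_lt(abs(mean(fA) - 0.25), 0.02)
  expect_lt(abs(sd(fA) - sqrt(4 * 12 / (16^2 * 17))), 0.02)
})

test_that("the chain recovers an enumerated two-model posterior", {
  # JC vs HKY on simulated data: the exact model posterior follows from
  # 1-D quadrature of the marginal likelihood over HKY's free rate
  models <- c("111111", "121121")
  tree <- fixed_tree()
  set.seed(17)
  truth <- site_model_state("121121", c(0.8, 1.4))
  aln <- simulate_alignment(tree, truth, 150)
  pt <- compress_patterns(aln)
  st_of <- function(u) site_model_state("121121", c(u, 3 - 2 * u))
  ll_jc <- pruning_log_likelihood(tree, pt, site_model_state("111111"))
  scale <- ll_jc
  marg_hky <- stats::integrate(function(us)
    vapply(us, function(u)
      exp(pruning_log_likelihood(tree, pt, st_of(u)) - scale), 1) / 1.5,
    1e-6, 1.5 - 1e-6, rel.tol = 1e-9)$value
  post_hky <- marg_hky / (marg_hky + exp(ll_jc - scale))
  w <- c(split = 2, merge = 2, rate_exchange = 2)
  cfg <- chain_config(chain_length = 4e4, log_every = 10, seed = 19,
                      weights = w)
  tr <- run_chain(cfg, prior_config(), models, alignment = pt, tree = tree)
  p_hat <- mean(tr$model == "121121")
  expect_lt(abs(p_hat - post_hky), 0.04)
})
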