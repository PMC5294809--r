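test_that("pattern compression is exact and tracks invariant compatibility", {
  aln <- matrix("A", nrow = 3, ncol = 4,
                dimnames = list(c("A", "B", "C"), NULL))
  pt <- compress_patterns(aln)
  expect_equal(length(pt$counts), 1)
  expect_equal(pt$counts, 4)
  expect_equal(unname(pt$inv_compat[, 1]), c(1, 0, 0, 0))

  aln2 <- matrix(c("A", "N", "A"), nrow = 3, ncol = 1,
                 dimnames = list(c("A", "B", "C"), NULL))
  expect_equal(unname(compress_patterns(aln2)$inv_compat[, 1]),
               c(1, 0, 0, 0))

  set.seed(3)
  aln3 <- matrix(sample(c("A", "C", "G", "T"), 3 * 500, replace = TRUE),
                 nrow = 3, dimnames = list(c("A", "B", "C"), NULL))
  pt3 <- compress_patterns(aln3)
  expect_lte(length(pt3$counts), 64)
  expect_equal(sum(pt3$counts), 500)

  expect_error(compress_patterns(matrix("J", 2, 2,
    dimnames = list(c("a", "b"), NULL))), "unknown nucleotide")
  expect_error(compress_patterns(matrix("A", 2, 0,
    dimnames = list(c("a", "b"), NULL))), "empty")
})

test_that("two-taxon likelihood matches the JC closed form", {
  for (d in c(0.05, 0.3, 1)) {
    tree <- read_tree(text = sprintf("(A:%g,B:%g);", d / 2, d / 2))
    aln <- matrix(c("A", "A", "G", "C"), nrow = 2,
                  dimnames = list(c("A", "B"), NULL))
    pt <- compress_patterns(aln)
    ll <- pruning_log_likelihood(tree, pt, site_model_state("111111"))
    match_lik <- 0.25 * (0.25 + 0.75 * exp(-4 * d / 3))
    mismatch_lik <- 0.25 * 0.25 * (1 - exp(-4 * d / 3))
    expect_equal(ll, log(match_lik) + log(mismatch_lik), tolerance = 1e-10)
  }
})

test_that("pruning equals brute-force summation over internal states", {
  tree <- fixed_tree()
  patterns <- list(c("A", "A", "A"), c("A", "C", "G"), c("T", "T", "C"),
                   c("A", "N", "A"), c("-", "C", "C"), c("R", "A", "G"))
  set.seed(11)
  states <- list(
    site_model_state("111111"),
    random_state("123456", has_est_freqs = 1,
                 freqs = c(0.15, 0.35, 0.3, 0.2)),
    random_state("121121", has_gamma = 1, alpha = 0.4),
    random_state("123425", has_inv = 1, p_inv = 0.35),
    random_state("121131", has_gamma = 1, alpha = 2, has_inv = 1,
                 p_inv = 0.2, has_est_freqs = 1,
                 freqs = c(0.4, 0.1, 0.2, 0.3)))
  for (st in states) {
    aln <- do.call(cbind, patterns)
    rownames(aln) <- c("A", "B", "C")
    pt <- compress_patterns(aln)
    ll <- pruning_log_likelihood(tree, pt, st)
    brute <- sum(vapply(patterns, function(p)
      log(brute_force_site_lik(st, p)), 1))
    expect_equal(ll, brute, tolerance = 1e-10)
  }
})

test_that("invariant-site shortcut equals explicit zero-rate evaluation", {
  # a zero-rate category has P(t) = I, so its explicit pruning value for
  # a pattern is the stationary mass of bases compatible with all taxa
  tree <- fixed_tree()
  st <- random_state("123341", seed = 5, has_inv = 1, p_inv = 0.3,
                     has_est_freqs = 1, freqs = c(0.2, 0.3, 0.1, 0.4))
  patterns <- list(c("A", "A", "A"), c("A", "C", "G"), c("N", "A", "R"))
  for (p in patterns) {
    compat <- rjsitemodel:::IUPAC[, p[1]] * rjsitemodel:::IUPAC[, p[2]] *
      rjsitemodel:::IUPAC[, p[3]]
    explicit <- sum(st$freqs * compat)
    aln <- matrix(p, 3, 1, dimnames = list(c("A", "B", "C"), NULL))
    pt <- compress_patterns(aln)
    expect_equal(unname(colSums(st$freqs * pt$inv_compat)), explicit)
  }
})

test_that("likelihood is invariant to compression and taxon order", {
  tree <- fixed_tree()
  set.seed(21)
  aln <- simulate_alignment(tree, random_state("121131"), 300)
  st <- random_state("123456", has_gamma = 1, alpha = 0.7)
  ll <- pruning_log_likelihood(tree, compress_patterns(aln), st)
  # uncompressed: feed each site separately and add
  ll_uncomp <- sum(vapply(seq_len(ncol(aln)), function(j)
    pruning_log_likelihood(tree, compress_patterns(aln[, j, drop = FALSE]),
                           st), 1))
  expect_equal(ll, ll_uncomp, tolerance = 1e-9)
  perm <- aln[c(2, 3, 1), ]
  expect_equal(pruning_log_likelihood(tree, compress_patterns(perm), st),
               ll, tolerance = 1e-9)
})

test_that("likelihood agrees with an independent phylogenetic library", {
  skip_if_not_installed("phangorn")
  tree <- fixed_tree()
  set.seed(31)
  aln <- simulate_alignment(tree, random_state("123456"), 400)
  st <- site_model_state("123456", c(0.5, 1.5, 0.8, 1.2, 1.6, 0.4),
                         has_gamma = 1, alpha = 0.5, has_est_freqs = 1,
                         freqs = c(0.1, 0.2, 0.3, 0.4))
  ll <- pruning_log_likelihood(tree, compress_patterns(aln), st)
  fit <- phangorn::pml(ape::unroot(tree), phangorn::phyDat(aln),
                       bf = st$freqs, Q = c(0.5, 1.5, 0.8, 1.2, 1.6, 0.4),
                       k = 4, shape = 0.5)
  expect_equal(ll, fit$logLik, tolerance = 1e-6)
})

test_that("p_inv -> 0 recovers the no-invariant-category likelihood", {
  tree <- fixed_tree()
  set.seed(41)
  aln <- simulate_alignment(tree, random_state("121121"), 200)
  pt <- compress_patterns(aln)
  base <- random_state("121121", has_gamma = 1, alpha = 1.2)
  ll0 <- pruning_log_likelihood(tree, pt, base)
  withinv <- base
  withinv$has_inv <- 1L
  withinv$p_inv <- 1e-9
  expect_equal(pruning_log_likelihood(tree, pt, withinv), ll0,
               tolerance = 1e-5)
})

test_that("the cached evaluator is coherent across gamma toggles", {
  tree <- fixed_tree()
  set.seed(51)
  aln <- simulate_alignment(tree, random_state("123321"), 300)
  pt <- compress_patterns(aln)
  ev <- likelihood_evaluator(tree, pt)
  st <- random_state("123321", has_gamma = 1, alpha = 0.9)
  st0 <- st; st0$has_gamma <- 0L
  v1 <- ev(st); v0 <- ev(st0)
  # toggling back must reproduce bit-identical values
  expect_identical(ev(st), v1)
  expect_identical(ev(st0), v0)
  expect_identical(ev(st), pruning_log_likelihood(tree, pt, st))
  # random proposal sweep: cached and fresh evaluation agree
  set.seed(52)
  for (i in 1:100) {
    sti <- random_state(sample(c("123321", "121121"), 1),
                        has_gamma = rbinom(1, 1, 0.5),
                        alpha = rexp(1) + 0.05,
                        has_inv = rbinom(1, 1, 0.5),
                        p_inv = runif(1, 0.05, 0.9))
    expect_equal(ev(sti), pruning_log_likelihood(tree, pt, sti),
                 tolerance = 1e-12)
  }
  expect_identical(likelihood_evaluator(tree, pt, constant = TRUE)(st), 0)
})

test_that("multiple zero-rate categories keep per-pattern alignment", {
  # at tiny alpha the lower gamma bins underflow to rate exactly 0 on
  # top of the explicit invariant category; each zero-rate category
  # must contribute the same per-pattern compatibility mass (a
  # recycling mistake here once scrambled patterns across categories)
  st <- site_model_state("111111", 1, has_gamma = 1, alpha = 3e-4,
                         has_inv = 1, p_inv = 0.6, has_est_freqs = 1,
                         freqs = c(0.4, 0.3, 0.2, 0.1))
  expect_equal(gamma_category_rates(3e-4, 4)[1:3], rep(0, 3))
  tree <- read_tree(text = "(A:0,B:0);")
  aln <- matrix(c("A", "A", "C", "C", "G", "G"), nrow = 2,
                dimnames = list(c("A", "B"), NULL))
  pt <- compress_patterns(aln)
  mix <- category_mixture(st)
  w0 <- sum(mix$weights[mix$rates == 0])
  # zero-length branches: every category reduces to the stationary mass
  expected <- sum(log(st$freqs[1:3]))
  expect_equal(pruning_log_likelihood(tree, pt, st), expected,
               tolerance = 1e-9)
  expect_equal(w0 + sum(mix$weights[mix$rates > 0]), 1, tolerance = 1e-12)
})

test_that("degenerate branch lengths give the stationary-mass likelihood", {
  tree <- read_tree(text = "(A:0,(B:0,C:0):0);")
  aln <- matrix(c("A", "A", "A"), 3, 1,
                dimnames = list(c("A", "B", "C"), NULL))
  st <- random_state("123456", seed = 6, has_est_freqs = 1,
                     freqs = c(0.4, 0.3, 0.2, 0.1))
  ll <- pruning_log_likelihood(tree, compress_patterns(aln), st)
  expect_equal(ll, log(st$freqs[1]), tolerance = 1e-10)
})
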