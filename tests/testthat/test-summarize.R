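test_that("credible model sets apply the smallest-set rule", {
  tr <- data.frame(model = rep("121121", 10))
  cs <- credible_model_set(tr, 0.95)
  expect_equal(cs$model, "121121")
  expect_equal(cs$prob, 1)

  models <- rep(c("a", "b", "c", "d"), times = c(50, 30, 15, 5))
  cs2 <- credible_model_set(models, 0.95)
  expect_equal(cs2$model, c("a", "b", "c"))
  expect_gte(attr(cs2, "mass"), 0.95)
  # dropping the least probable member falls below the level
  expect_lt(sum(cs2$prob[-3]), 0.95)

  # uniform over 31 models: need 30 to reach 95%
  u <- rep(enumerate_models("tstv"), each = 10)
  expect_equal(nrow(credible_model_set(u, 0.95)), 30)
  expect_error(credible_model_set(character(0)), "empty")
})

test_that("HPD intervals are the shortest order-statistic windows", {
  x <- 1:100
  h <- hpd_interval(x, 0.95)
  expect_equal(unname(h[2] - h[1]), 94)

  set.seed(301)
  e <- rexp(1e5)
  h2 <- hpd_interval(e, 0.95)
  # analytic shortest interval for Exp(1): (0, qexp(0.95)) = (0, ~3.0)
  expect_lt(h2[1], 0.01)
  expect_lt(abs(h2[2] - qexp(0.95)), 0.1)

  expect_equal(unname(hpd_interval(rep(2, 10), 0.95)), c(2, 2),
               ignore_attr = TRUE)
  expect_error(hpd_interval(1), "two samples")

  # equals brute-force minimization over all windows
  set.seed(302)
  for (i in 1:20) {
    y <- sort(rlnorm(60))
    m <- ceiling(0.9 * 60)
    widths <- y[m:60] - y[1:(60 - m + 1)]
    i0 <- which.min(widths)
    expect_equal(unname(hpd_interval(y, 0.9)),
                 c(y[i0], y[i0 + m - 1]), ignore_attr = TRUE)
  }
})

test_that("indicator posteriors and conditional summaries subset correctly", {
  tr <- data.frame(hasGammaRates = c(1, 1, 0, 1),
                   hasInvariableSites = c(0, 0, 0, 0),
                   hasEqualFreqs = c(1, 0, 1, 0),
                   gammaShape = c(0.5, 0.7, 99, 0.6))
  expect_equal(indicator_posterior(tr, "hasGammaRates"), 0.75)
  expect_equal(indicator_posterior(tr, "hasEstimatedFreqs"), 0.5)
  cs <- conditional_summary(tr, "gammaShape", "hasGammaRates")
  expect_equal(cs$mean, 0.6)  # the 99 at indicator 0 is ignored
  expect_equal(cs$n, 3)
  empty <- conditional_summary(
    data.frame(gammaShape = 1, hasGammaRates = 0),
    "gammaShape", "hasGammaRates")
  expect_true(is.na(empty$mean))
  expect_equal(empty$n, 0)
})

test_that("coverage is 100% for degenerate point posteriors at the truth", {
  truth <- site_model_state("121121", c(0.5, 2), has_gamma = 1,
                            alpha = 0.7, has_inv = 1, p_inv = 0.2,
                            has_est_freqs = 1,
                            freqs = c(0.25, 0.25, 0.25, 0.25))
  r6 <- unname(expand_rates("121121", c(0.5, 2)))
  tr <- data.frame(model = rep("121121", 50),
                   rateAC = r6[1], rateAG = r6[2], rateAT = r6[3],
                   rateCG = r6[4], rateCT = r6[5], rateGT = r6[6],
                   hasGammaRates = 1, gammaShape = 0.7,
                   hasInvariableSites = 1, proportionInvariable = 0.2,
                   hasEqualFreqs = 0, freqA = 0.25, freqC = 0.25,
                   freqG = 0.25, freqT = 0.25)
  rep_ <- coverage_report(list(truth, truth), list(tr, tr), burnin = 0)
  for (cell in rep_$rates) expect_equal(cell$coverage, 100)
  expect_equal(rep_$model$coverage, 100)
  expect_equal(rep_$site_model$coverage, 100)
  expect_equal(rep_$alpha$coverage, 100)
  expect_equal(rep_$p_inv$coverage, 100)
  expect_error(coverage_report(list(truth), list(tr, tr)), "mismatch")
})

test_that("coverage on calibrated Gaussian toys is near the nominal level", {
  # truth and samples drawn from the same distribution: expect ~95%
  set.seed(311)
  n <- 400
  hits <- vapply(seq_len(n), function(i) {
    truth <- rnorm(1)
    h <- hpd_interval(rnorm(400), 0.95)
    truth >= h[1] && truth <= h[2]
  }, TRUE)
  cov <- 100 * mean(hits)
  expect_gt(cov, 91); expect_lt(cov, 99)
})

test_that("effective size detects autocorrelation", {
  set.seed(321)
  x <- rnorm(2000)
  expect_gt(effective_size(x), 1000)
  y <- as.numeric(stats::filter(rnorm(2000), 0.9, "recursive"))
  expect_lt(effective_size(y), 500)
})
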