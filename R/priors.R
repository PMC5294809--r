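#' Prior configuration
#'
#' Defaults follow the package's standard analysis setup: a flat
#' Dirichlet prior on the constrained exchangeability rates (or,
#' alternatively, a log-normal prior with real-space mean 1 and log-scale
#' standard deviation 1.25 on transition rates together with an
#' exponential mean-1 prior on transversion rates), a Dirichlet(4,4,4,4)
#' prior on base frequencies, Beta(1,4) on the proportion of invariable
#' sites (mean 0.2), Exponential(mean 1) on the gamma shape, and
#' independent Bernoulli(1/2) priors on the three binary indicators so
#' the four site-model variants (plain, +G, +I, +G+I) are equiprobable
#' a priori.
#'
#' @param rate_prior `"flat"` (flat Dirichlet on the rate simplex) or
#'   `"tstv"` (log-normal transitions, exponential transversions).
#' @param ts_meanlog,ts_sdlog Log-normal parameters for transition rates;
#'   the default `ts_meanlog` makes the real-space mean 1.
#' @param tv_rate Exponential rate for transversion rates (mean `1/tv_rate`).
#' @param freq_conc Dirichlet concentration (length 4) for frequencies.
#' @param pinv_shape1,pinv_shape2 Beta parameters for `p_inv`.
#' @param alpha_rate Exponential rate for the gamma shape `alpha`.
#' @param model_prior `"uniform"` over models or `"dof"` (uniform over
#'   the number of free rate parameters).
#' @param indicator_prob Prior inclusion probability of each indicator.
#' @return A list of class `prior_config`.
#' @export
prior_config <- function(rate_prior = c("flat", "tstv"),
                         ts_sdlog = 1.25,
                         ts_meanlog = -ts_sdlog^2 / 2,
                         tv_rate = 1,
                         freq_conc = c(4, 4, 4, 4),
                         pinv_shape1 = 1, pinv_shape2 = 4,
                         alpha_rate = 1,
                         model_prior = c("uniform", "dof"),
                         indicator_prob = 0.5) {
  rate_prior <- match.arg(rate_prior)
  model_prior <- match.arg(model_prior)
  stopifnot(ts_sdlog > 0, tv_rate > 0, all(freq_conc > 0),
            pinv_shape1 > 0, pinv_shape2 > 0, alpha_rate > 0,
            indicator_prob > 0, indicator_prob < 1)
  structure(list(rate_prior = rate_prior, ts_meanlog = ts_meanlog,
                 ts_sdlog = ts_sdlog, tv_rate = tv_rate,
                 freq_conc = freq_conc, pinv_shape1 = pinv_shape1,
                 pinv_shape2 = pinv_shape2, alpha_rate = alpha_rate,
                 model_prior = model_prior, indicator_prob = indicator_prob),
            class = "prior_config")
}

log_ddirichlet <- function(x, conc) {
  if (any(x <= 0) || abs(sum(x) - 1) > 1e-8) return(-Inf)
  sum((conc - 1) * log(x)) + lgamma(sum(conc)) - sum(lgamma(conc))
}

rdirichlet1 <- function(conc) {
  g <- stats::rgamma(length(conc), shape = conc, rate = 1)
  g / sum(g)
}

# Log volume of the constrained rate space of a model: the set
# {r_g > 0 : sum(n_g r_g) = 6} has volume 6^(G-1) / ((G-1)! prod n_g)
# with respect to the coordinates used by the split/merge moves.  The
# flat Dirichlet prior on rates is 1/volume on this set; including the
# term makes trans-dimensional acceptance ratios exact for the flat
# prior (and serves as the reference-measure correction under the
# transition/transversion rate prior, whose exact surface normalizer is
# intractable; within-model ratios are unaffected).
log_rate_volume <- function(model) {
  model_memo(paste0("v", model), function() {
    n <- lengths(model_groups(model))
    G <- length(n)
    (G - 1) * log(RATE_SUM) - lgamma(G) - sum(log(n))
  })
}

# Per-position log density of the ts/tv rate prior on expanded rates.
log_tstv_density <- function(rates6, cfg) {
  ts <- stats::dlnorm(rates6[TRANSITIONS], cfg$ts_meanlog, cfg$ts_sdlog,
                      log = TRUE)
  tv <- stats::dexp(rates6[-TRANSITIONS], rate = cfg$tv_rate, log = TRUE)
  sum(ts) + sum(tv)
}

#' Log prior density of a site-model state
#'
#' Sums the model prior, the rate prior on the constrained rate space,
#' the indicator priors, and -- only when the corresponding indicator is
#' set -- the priors on base frequencies, the gamma shape and the
#' proportion of invariable sites.
#'
#' @param state A [site_model_state()].
#' @param cfg A [prior_config()].
#' @param models Character vector: the model set in use.
#' @return Log prior density; `-Inf` outside the support.
#' @export
log_prior <- function(state, cfg, models) {
  lp <- model_log_prior(state$model, models, cfg$model_prior)
  # rate prior on the constrained space (see log_rate_volume)
  lp <- lp - log_rate_volume(state$model)
  if (any(state$group_rates <= 0)) return(-Inf)
  if (cfg$rate_prior == "tstv") {
    rates6 <- expand_rates(state$model, state$group_rates)
    lp <- lp + log_tstv_density(rates6, cfg)
  }
  p <- cfg$indicator_prob
  lp <- lp + sum(stats::dbinom(c(state$has_gamma, state$has_inv,
                                 state$has_est_freqs), 1, p, log = TRUE))
  if (state$has_gamma)
    lp <- lp + stats::dexp(state$alpha, cfg$alpha_rate, log = TRUE)
  if (state$has_inv)
    lp <- lp + stats::dbeta(state$p_inv, cfg$pinv_shape1, cfg$pinv_shape2,
                            log = TRUE)
  if (state$has_est_freqs)
    lp <- lp + log_ddirichlet(state$freqs, cfg$freq_conc)
  lp
}

# Draw group rates for `model` from the rate prior, honoring the
# sum-to-6 constraint.  Flat prior: exact (scaled flat Dirichlet in the
# size-weighted coordinates).  ts/tv prior: six position rates are drawn
# independently, averaged within groups and rescaled to the constraint
# surface (an approximation to the conditional; used for simulation
# truth draws).
sample_group_rates <- function(model, cfg) {
  sizes <- lengths(model_groups(model))
  if (cfg$rate_prior == "flat") {
    z <- rdirichlet1(rep(1, length(sizes)))
    return(RATE_SUM * z / sizes)
  }
  pos <- numeric(6)
  pos[TRANSITIONS] <- stats::rlnorm(2, cfg$ts_meanlog, cfg$ts_sdlog)
  pos[-TRANSITIONS] <- stats::rexp(4, cfg$tv_rate)
  code <- parse_model_code(model)
  grp <- vapply(split(pos, code), mean, 1)
  grp * RATE_SUM / sum(sizes * grp)
}

sample_model <- function(models, cfg) {
  if (cfg$model_prior == "uniform") return(sample(models, 1))
  dofs <- vapply(models, model_dof, 1L)
  d <- sample(sort(unique(dofs)), 1)
  sample(rep(models[dofs == d], 2), 1)  # rep() guards length-1 sample()
}

#' Draw a site-model state from the prior
#'
#' @param cfg A [prior_config()].
#' @param models Character vector: the model set.
#' @param force Optional named list clamping components during the draw,
#'   with any of `has_gamma`, `has_inv`, `has_est_freqs` (0 or 1); used
#'   by the calibration study to pin the site-model variant.
#' @param k Number of gamma categories for the drawn state.
#' @return A [site_model_state()].
#' @export
sample_prior_state <- function(cfg, models, force = list(), k = 4L) {
  model <- sample_model(models, cfg)
  draw_ind <- function(name) {
    if (!is.null(force[[name]])) as.integer(force[[name]])
    else stats::rbinom(1, 1, cfg$indicator_prob)
  }
  has_gamma <- draw_ind("has_gamma")
  has_inv <- draw_ind("has_inv")
  has_est_freqs <- draw_ind("has_est_freqs")
  freqs <- if (has_est_freqs) rdirichlet1(cfg$freq_conc) else rep(0.25, 4)
  site_model_state(
    model = model,
    group_rates = sample_group_rates(model, cfg),
    has_gamma = has_gamma,
    alpha = stats::rexp(1, cfg$alpha_rate),
    has_inv = has_inv,
    p_inv = stats::rbeta(1, cfg$pinv_shape1, cfg$pinv_shape2),
    has_est_freqs = has_est_freqs,
    freqs = freqs, k = k)
}
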