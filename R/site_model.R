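RATE_SUM <- 6  # the six expanded exchangeability rates always sum to 6

#' Construct a site-model state
#'
#' The full state sampled by the reversible-jump chain: a substitution
#' model (a grouping of the six exchangeability rates), one rate per
#' group constrained so that the six expanded rates sum to 6, a binary
#' indicator plus shape parameter for discrete-gamma rate heterogeneity,
#' a binary indicator plus proportion for an invariable-site category,
#' and a binary indicator for estimated (versus equal) base frequencies.
#' `alpha` and `p_inv` always carry values but only enter the likelihood
#' and the prior when their indicator is 1.
#'
#' @param model Canonical model string.
#' @param group_rates Numeric vector, one positive rate per rate group
#'   (ordered by group label); must satisfy `sum(sizes * rates) == 6`.
#' @param has_gamma,has_inv,has_est_freqs Binary indicators (0/1).
#' @param alpha Gamma shape (> 0).
#' @param p_inv Proportion of invariable sites, in (0, 1).
#' @param freqs Base frequencies (A, C, G, T), positive, summing to 1.
#'   Forced to (1/4, 1/4, 1/4, 1/4) when `has_est_freqs = 0`.
#' @param k Number of discrete gamma categories (>= 2).
#' @return An object of class `site_model_state`.
#' @export
site_model_state <- function(model, group_rates = NULL, has_gamma = 0L,
                             alpha = 1, has_inv = 0L, p_inv = 0.1,
                             has_est_freqs = 0L, freqs = rep(0.25, 4),
                             k = 4L) {
  model <- canonicalize_model(model)
  sizes <- lengths(model_groups(model))
  if (is.null(group_rates)) group_rates <- rep(1, length(sizes))
  stopifnot(length(group_rates) == length(sizes), all(group_rates > 0),
            alpha > 0, p_inv > 0, p_inv < 1, k >= 2)
  if (abs(sum(sizes * group_rates) - RATE_SUM) > 1e-8)
    stop("group rates weighted by group sizes must sum to ", RATE_SUM)
  if (!has_est_freqs) freqs <- rep(0.25, 4)
  if (abs(sum(freqs) - 1) > 1e-8 || any(freqs <= 0))
    stop("freqs must be positive and sum to 1")
  structure(list(model = model, group_rates = as.numeric(group_rates),
                 has_gamma = as.integer(has_gamma), alpha = alpha,
                 has_inv = as.integer(has_inv), p_inv = p_inv,
                 has_est_freqs = as.integer(has_est_freqs),
                 freqs = as.numeric(freqs) / sum(freqs), k = as.integer(k)),
            class = "site_model_state")
}

#' @export
print.site_model_state <- function(x, ...) {
  cat("site_model_state:", x$model,
      sprintf("rates=(%s)", paste(signif(expand_rates(x$model, x$group_rates), 4),
                                  collapse = ", ")),
      if (x$has_gamma) sprintf("+G(alpha=%.3g)", x$alpha) else "",
      if (x$has_inv) sprintf("+I(p=%.3g)", x$p_inv) else "",
      if (x$has_est_freqs) "estimated freqs" else "equal freqs", "\n")
  invisible(x)
}

#' Expand group rates to the six exchangeability rates
#'
#' @param model Canonical model string.
#' @param group_rates One positive rate per group, ordered by group label.
#' @return Named numeric vector (ac, ag, at, cg, ct, gt) summing to 6.
#' @examples
#' expand_rates("121121", c(0.5, 2))  # 0.5 2 0.5 0.5 2 0.5
#' @export
expand_rates <- function(model, group_rates) {
  code <- if (is.character(model) && length(model) == 1L)
    model_memo(paste0("c", model), function() parse_model_code(model))
  else parse_model_code(model)
  if (length(group_rates) != max(code))
    stop("need one rate per group")
  out <- group_rates[code]
  if (abs(sum(out) - RATE_SUM) > 1e-8)
    stop("expanded rates must sum to ", RATE_SUM)
  stats::setNames(out, RATE_NAMES)
}

#' Build a time-reversible rate matrix
#'
#' Q\[i, j\] = pi_j * r_ij for i != j in nucleotide order (A, C, G, T),
#' diagonal set so rows sum to zero; optionally normalized so the
#' expected substitution rate at stationarity, -sum(pi_i Q\[i, i\]), is 1.
#'
#' @param rates Six exchangeability rates (ac, ag, at, cg, ct, gt).
#' @param freqs Stationary base frequencies (A, C, G, T).
#' @param normalize Rescale to unit expected rate (default TRUE).
#' @return A 4x4 matrix with attribute `"scale"`, the normalizer applied.
#' @export
rate_matrix <- function(rates, freqs, normalize = TRUE) {
  stopifnot(length(rates) == 6, length(freqs) == 4,
            all(rates >= 0), all(freqs > 0))
  if (all(rates == 0)) stop("all-zero rates")
  freqs <- freqs / sum(freqs)
  Q <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  # pairs in rate order: ac ag at cg ct gt
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (p in 1:6) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    Q[i, j] <- freqs[j] * rates[p]
    Q[j, i] <- freqs[i] * rates[p]
  }
  diag(Q) <- -rowSums(Q)
  scale <- 1
  if (normalize) {
    scale <- -sum(freqs * diag(Q))
    Q <- Q / scale
  }
  attr(Q, "scale") <- scale
  Q
}

#' Discrete-gamma category rates
#'
#' Mean-of-quantile-bin discretization: the gamma(alpha, alpha)
#' distribution (mean 1) is cut into `k` equal-probability bins and each
#' category rate is the exact conditional mean of its bin, so the
#' category rates always average to 1.
#'
#' @param alpha Gamma shape (> 0).
#' @param k Number of categories (>= 2).
#' @return Numeric vector of `k` category rates with mean 1.
#' @export
gamma_category_rates <- function(alpha, k) {
  stopifnot(alpha > 0, k >= 2)
  # bin edges at quantiles i/k of Gamma(alpha, rate = alpha)
  edges <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha,
                         rate = alpha)
  # E[X | a < X < b] for X ~ Gamma(alpha, alpha):
  # = [F_{alpha+1}(b) - F_{alpha+1}(a)] / [F_alpha(b) - F_alpha(a)] * (alpha/alpha)
  upper <- stats::pgamma(edges[-1], shape = alpha + 1, rate = alpha)
  lower <- stats::pgamma(edges[-(k + 1)], shape = alpha + 1, rate = alpha)
  rates <- (upper - lower) * k
  rates / mean(rates)  # exact unit mean against quantile round-off
}

#' Rate-category mixture of a site-model state
#'
#' Returns the list of (weight, rate) categories the likelihood averages
#' over.  With the invariable-site indicator set, a zero-rate category of
#' weight `p_inv` is added and the non-zero category rates are rescaled
#' by 1/(1 - p_inv) so the overall expected rate stays 1 and branch
#' lengths keep their substitutions-per-site meaning.
#'
#' @param state A [site_model_state()].
#' @return A list with numeric vectors `weights` and `rates`
#'   (class `category_mixture`); weights sum to 1, weighted mean rate is 1.
#' @export
category_mixture <- function(state) {
  if (state$has_inv && state$p_inv >= 1) stop("p_inv must be < 1")
  rates <- if (state$has_gamma) gamma_category_rates(state$alpha, state$k) else 1
  weights <- rep(1 / length(rates), length(rates))
  if (state$has_inv) {
    weights <- c(state$p_inv, (1 - state$p_inv) * weights)
    rates <- c(0, rates / (1 - state$p_inv))
  }
  structure(list(weights = weights, rates = rates), class = "category_mixture")
}
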