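#' Discard burn-in from a trace
#'
#' @param trace A trace data frame from [run_chain()].
#' @param burnin Fraction of rows to drop from the front (default 0.1).
#' @return The trimmed trace.
#' @export
discard_burnin <- function(trace, burnin = 0.1) {
  stopifnot(burnin >= 0, burnin < 1)
  n <- nrow(trace)
  if (n == 0) stop("empty trace")
  trace[(floor(burnin * n) + 1):n, , drop = FALSE]
}

#' Credible set of substitution models
#'
#' The smallest set of models whose posterior sample frequencies sum to
#' at least `level`: models are sorted by decreasing posterior
#' probability (ties broken by model string) and truncated at the first
#' cumulative mass >= `level`.
#'
#' @param trace A trace data frame (after burn-in removal), or a factor/
#'   character vector of sampled model strings.
#' @param level Credibility level (default 0.95).
#' @return A data frame with columns `model` and `prob`, ordered by
#'   decreasing probability; attribute `"mass"` holds the total.
#' @export
credible_model_set <- function(trace, level = 0.95) {
  models <- if (is.data.frame(trace)) trace$model else as.character(trace)
  if (length(models) == 0) stop("empty trace")
  p <- sort(table(models) / length(models), decreasing = TRUE)
  # stable tie-break on the model string
  ord <- order(-as.numeric(p), names(p))
  p <- p[ord]
  k <- which(cumsum(p) >= level)[1]
  if (is.na(k)) k <- length(p)
  out <- data.frame(model = names(p)[1:k], prob = as.numeric(p)[1:k],
                    stringsAsFactors = FALSE)
  attr(out, "mass") <- sum(out$prob)
  out
}

#' Highest posterior density interval
#'
#' The shortest contiguous window of `ceiling(level * n)` consecutive
#' order statistics of the sample.
#'
#' @param samples Numeric vector (>= 2 values).
#' @param level Credibility level.
#' @return Numeric vector `c(lower, upper)` with attribute `"level"`.
#' @export
hpd_interval <- function(samples, level = 0.95) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 2) stop("need at least two samples")
  x <- sort(samples)
  m <- ceiling(level * n)
  m <- min(m, n)
  widths <- x[m:n] - x[1:(n - m + 1)]
  i <- which.min(widths)
  structure(c(lower = x[i], upper = x[i + m - 1]), level = level)
}

#' Posterior probability of an indicator
#'
#' @param trace A trace data frame.
#' @param which Column name (`"hasGammaRates"`, `"hasInvariableSites"`)
#'   or `"hasEstimatedFreqs"` (complement of the logged
#'   `hasEqualFreqs`).
#' @return Fraction of samples with the flag set.
#' @export
indicator_posterior <- function(trace, which) {
  if (which == "hasEstimatedFreqs") return(mean(1 - trace$hasEqualFreqs))
  if (!which %in% names(trace)) stop("no column ", which, " in trace")
  mean(trace[[which]])
}

#' Conditional posterior summary of a parameter
#'
#' Mean and HPD interval of a parameter over the portion of the
#' posterior sample where an indicator is set (e.g. the gamma shape
#' conditioned on the heterogeneity indicator being 1).
#'
#' @param trace A trace data frame.
#' @param parameter Column name, e.g. `"gammaShape"`.
#' @param indicator Indicator column name, e.g. `"hasGammaRates"`;
#'   `NULL` for an unconditional summary.
#' @param level HPD level.
#' @return List with `mean`, `hpd`, `n`; all `NA` (with `n = 0`) when
#'   the conditioning subsample is empty or too small.
#' @export
conditional_summary <- function(trace, parameter, indicator = NULL,
                                level = 0.95) {
  x <- trace[[parameter]]
  if (is.null(x)) stop("no column ", parameter, " in trace")
  if (!is.null(indicator)) x <- x[trace[[indicator]] == 1]
  if (length(x) < 2)
    return(list(mean = NA_real_, hpd = c(lower = NA_real_, upper = NA_real_),
                n = length(x)))
  list(mean = mean(x), hpd = hpd_interval(x, level), n = length(x))
}

site_variant <- function(has_gamma, has_inv) {
  c("plain", "+G", "+I", "+G+I")[1 + has_gamma + 2 * has_inv]
}

#' Coverage report for a calibration study
#'
#' For paired truths and traces (see [run_validation_study()]) computes,
#' at the given level: per-position HPD coverage of the six expanded
#' exchangeability rates; HPD coverage of the four base frequencies
#' (only over replicates whose truth had estimated frequencies, and
#' conditioned on sampling estimated frequencies); credible-set coverage
#' of the true substitution model; credible-set coverage of the true
#' site-model variant (plain/+G/+I/+G+I, using the joint indicator
#' sample frequencies); and HPD coverage of `alpha` and `p_inv`
#' conditioned on sampling the true site-model variant (only over
#' replicates where the truth used them).
#'
#' @param truths List of true [site_model_state()]s.
#' @param traces List of trace data frames (burn-in already removed or
#'   use `burnin`).
#' @param level Credibility level.
#' @param burnin Burn-in fraction applied to each trace.
#' @return A list with elements `rates` (named coverage per rate
#'   position), `freqs`, `model`, `site_model`, `alpha`, `p_inv`; each
#'   entry is a list with `coverage` (percent), `hits`, `n`.
#' @export
coverage_report <- function(truths, traces, level = 0.95, burnin = 0.1) {
  if (length(truths) != length(traces)) stop("mismatched truth/trace lists")
  n <- length(truths)
  rate_cols <- c("rateAC", "rateAG", "rateAT", "rateCG", "rateCT", "rateGT")
  freq_cols <- c("freqA", "freqC", "freqG", "freqT")
  rate_hits <- matrix(NA, n, 6, dimnames = list(NULL, rate_cols))
  freq_hits <- matrix(NA, n, 4, dimnames = list(NULL, freq_cols))
  model_hits <- site_hits <- logical(n)
  alpha_hits <- pinv_hits <- rep(NA, n)
  for (i in seq_len(n)) {
    truth <- truths[[i]]
    tr <- discard_burnin(traces[[i]], burnin)
    true_rates <- expand_rates(truth$model, truth$group_rates)
    for (p in 1:6) {
      h <- hpd_interval(tr[[rate_cols[p]]], level)
      rate_hits[i, p] <- true_rates[p] >= h[1] && true_rates[p] <= h[2]
    }
    if (truth$has_est_freqs) {
      sub <- tr[tr$hasEqualFreqs == 0, , drop = FALSE]
      if (nrow(sub) >= 2) {
        for (p in 1:4) {
          h <- hpd_interval(sub[[freq_cols[p]]], level)
          freq_hits[i, p] <- truth$freqs[p] >= h[1] && truth$freqs[p] <= h[2]
        }
      }
    }
    cs <- credible_model_set(tr, level)
    model_hits[i] <- truth$model %in% cs$model
    variants <- site_variant(tr$hasGammaRates, tr$hasInvariableSites)
    vs <- credible_model_set(variants, level)
    site_hits[i] <- site_variant(truth$has_gamma, truth$has_inv) %in% vs$model
    cond <- variants == site_variant(truth$has_gamma, truth$has_inv)
    if (truth$has_gamma && sum(cond) >= 2) {
      h <- hpd_interval(tr$gammaShape[cond], level)
      alpha_hits[i] <- truth$alpha >= h[1] && truth$alpha <= h[2]
    }
    if (truth$has_inv && sum(cond) >= 2) {
      h <- hpd_interval(tr$proportionInvariable[cond], level)
      pinv_hits[i] <- truth$p_inv >= h[1] && truth$p_inv <= h[2]
    }
  }
  cell <- function(hits) {
    hits <- hits[!is.na(hits)]
    list(coverage = if (length(hits)) 100 * mean(hits) else NA_real_,
         hits = sum(hits), n = length(hits))
  }
  list(rates = apply(rate_hits, 2, cell),
       freqs = apply(freq_hits, 2, cell),
       model = cell(model_hits),
       site_model = cell(site_hits),
       alpha = cell(alpha_hits),
       p_inv = cell(pinv_hits))
}

#' Effective sample size of a trace column
#'
#' Standard initial-positive-sequence autocorrelation estimate.
#'
#' @param x Numeric vector.
#' @return Estimated effective sample size.
#' @export
effective_size <- function(x) {
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 1000), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq_along(ac)) {
    if (ac[k] < 0) break
    s <- s + ac[k]
  }
  n / (1 + 2 * s)
}
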