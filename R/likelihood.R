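# IUPAC nucleotide ambiguity codes as 4-row indicator columns (A, C, G, T).
iupac_table <- function() {
  codes <- list(
    A = "A", C = "C", G = "G", T = "T", U = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T"),
    "-" = c("A", "C", "G", "T"), "?" = c("A", "C", "G", "T"))
  bases <- c("A", "C", "G", "T")
  tab <- sapply(codes, function(x) as.numeric(bases %in% x))
  rownames(tab) <- bases
  tab
}
IUPAC <- iupac_table()

as_char_alignment <- function(alignment) {
  if (inherits(alignment, "DNAbin"))
    alignment <- toupper(as.character(alignment))
  if (is.list(alignment))
    alignment <- do.call(rbind, lapply(alignment, function(s) {
      if (length(s) == 1L && nchar(s) > 1L) strsplit(s, "")[[1]] else s
    }))
  if (!is.matrix(alignment)) stop("alignment must be a taxa x sites matrix")
  alignment <- toupper(alignment)
  if (ncol(alignment) == 0L || nrow(alignment) == 0L)
    stop("empty alignment")
  bad <- setdiff(unique(as.vector(alignment)), colnames(IUPAC))
  if (length(bad))
    stop("unknown nucleotide symbol(s): ", paste(bad, collapse = ", "))
  alignment
}

#' Compress an alignment into site patterns
#'
#' Identical columns of the alignment are collapsed into unique patterns
#' with counts.  For each pattern the set of bases compatible with the
#' pattern being constant (resolving IUPAC ambiguities; gaps and N match
#' everything) is recorded, which is what the constant-time
#' invariable-site likelihood term needs.
#'
#' @param alignment A taxa x sites character matrix (IUPAC symbols), a
#'   named list of sequence strings, or an `ape::DNAbin`.
#' @return An object of class `pattern_table`: list with `taxa`,
#'   `patterns` (taxa x npat character matrix), `counts`,
#'   `partials` (list of 4 x npat leaf indicator matrices, one per
#'   taxon), and `inv_compat` (4 x npat 0/1 matrix of bases compatible
#'   with a constant column).
#' @export
compress_patterns <- function(alignment) {
  alignment <- as_char_alignment(alignment)
  key <- apply(alignment, 2, paste, collapse = "\r")
  counts <- table(key)[unique(key)]
  keep <- match(names(counts), key)
  patterns <- alignment[, keep, drop = FALSE]
  partials <- lapply(seq_len(nrow(patterns)), function(i)
    IUPAC[, patterns[i, ], drop = FALSE])
  names(partials) <- rownames(alignment)
  inv_compat <- Reduce("*", partials)
  structure(list(taxa = rownames(alignment), patterns = patterns,
                 counts = as.numeric(counts), partials = partials,
                 inv_compat = inv_compat),
            class = "pattern_table")
}

#' @export
print.pattern_table <- function(x, ...) {
  cat("pattern_table:", length(x$taxa), "taxa,", length(x$counts),
      "patterns,", sum(x$counts), "sites\n")
  invisible(x)
}

# Eigendecomposition of a reversible Q for fast P(t) at many rates.
# Q reversible wrt freqs: diag(sqrt(pi)) Q diag(1/sqrt(pi)) is symmetric.
decompose_q <- function(Q, freqs) {
  sq <- sqrt(freqs)
  S <- outer(sq, 1 / sq) * Q
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  list(values = e$values,
       right = (1 / sq) * e$vectors,        # diag(1/sq) %*% V
       left = t(e$vectors * sq))            # t(V) %*% diag(sq)
}

prob_matrix <- function(dec, t) {
  P <- dec$right %*% (exp(dec$values * t) * dec$left)
  P[P < 0] <- 0
  P
}

# Postorder edge traversal of a rooted ape::phylo, checked against taxa.
tree_plan <- function(tree, taxa) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (!setequal(tree$tip.label, taxa))
    stop("tree tip labels must match alignment taxa")
  tree <- ape::reorder.phylo(tree, "postorder")
  list(edge = tree$edge, lengths = tree$edge.length,
       ntip = length(tree$tip.label), root = tree$edge[nrow(tree$edge), 1],
       tips = tree$tip.label)
}

# Pruning over all patterns for all non-zero category rates at once.
# Partial likelihood matrices are stacked vertically by category
# ((4k) x npat) and every edge applies a block-diagonal transition
# matrix in a single multiply, which is substantially faster than
# looping over categories.  Underflow rescaling (shared per pattern
# across categories) only pays off on larger trees.  Returns the k x
# npat matrix of per-category log site likelihoods.
prune_categories <- function(plan, dec, rates, pt, freqs) {
  k <- length(rates)
  npat <- length(pt$counts)
  do_scale <- plan$ntip > 8L
  rows <- 4L * k
  idx <- lapply(seq_len(k), function(c) (c - 1L) * 4L + 1:4)
  partial <- vector("list", max(plan$edge))
  logscale <- numeric(npat)
  for (i in seq_len(plan$ntip)) {
    L <- pt$partials[[plan$tips[i]]]
    partial[[i]] <- L[rep(seq_len(4L), k), , drop = FALSE]
  }
  Pbig <- matrix(0, rows, rows)
  for (e in seq_len(nrow(plan$edge))) {
    parent <- plan$edge[e, 1]; child <- plan$edge[e, 2]
    for (c in seq_len(k)) {
      P <- prob_matrix(dec, rates[c] * plan$lengths[e])
      Pbig[idx[[c]], idx[[c]]] <- P
    }
    contrib <- Pbig %*% partial[[child]]
    if (is.null(partial[[parent]])) {
      partial[[parent]] <- contrib
    } else {
      combined <- partial[[parent]] * contrib
      if (do_scale) {
        mx <- combined[1, ]
        for (r in 2:rows) mx <- pmax(mx, combined[r, ])
        if (min(mx) < 1e-150) {
          ok <- mx > 0 & is.finite(mx)
          mx[!ok] <- 1
          logscale <- logscale + log(mx)
          combined <- combined * rep(1 / mx, each = rows)
        }
      }
      partial[[parent]] <- combined
    }
  }
  root <- partial[[plan$root]]
  out <- matrix(0, k, npat)
  for (c in seq_len(k))
    out[c, ] <- log(colSums(freqs * root[idx[[c]], , drop = FALSE])) +
      logscale
  out
}

#' Alignment log-likelihood by Felsenstein pruning
#'
#' Per pattern, the likelihood is the mixture over non-zero rate
#' categories of the pruning likelihood with branch lengths multiplied by
#' the category rate, plus -- when the invariable-site indicator is set --
#' `p_inv` times the total stationary frequency of the bases compatible
#' with a constant column.  The zero-rate category is never evaluated by
#' pruning: for rate 0 the transition matrix is the identity, so a
#' pattern contributes its compatible-base frequency mass exactly.
#'
#' @param tree Rooted `ape::phylo` with branch lengths in expected
#'   substitutions per site; tip labels must match the alignment taxa.
#' @param pt A [compress_patterns()] table.
#' @param state A [site_model_state()].
#' @return Total log-likelihood (numeric scalar).
#' @export
pruning_log_likelihood <- function(tree, pt, state) {
  plan <- tree_plan(tree, pt$taxa)
  log_lik <- pattern_likelihoods(plan, pt, state)
  if (any(!is.finite(log_lik)))
    stop("non-finite pattern likelihood (model: ", state$model, ")")
  sum(pt$counts * log_lik)
}

pattern_likelihoods <- function(plan, pt, state, dec_cache = NULL) {
  rates6 <- expand_rates(state$model, state$group_rates)
  dec <- NULL
  if (!is.null(dec_cache)) {
    hit <- dec_cache$get()
    if (!is.null(hit) && identical(hit$rates6, rates6) &&
        identical(hit$freqs, state$freqs))
      dec <- hit$dec
  }
  if (is.null(dec)) {
    Q <- rate_matrix(rates6, state$freqs, normalize = TRUE)
    dec <- decompose_q(Q, state$freqs)
    if (!is.null(dec_cache))
      dec_cache$set(list(rates6 = rates6, freqs = state$freqs, dec = dec))
  }
  mix <- category_mixture(state)
  npat <- length(pt$counts)
  loglik <- matrix(-Inf, length(mix$rates), npat)
  nz <- which(mix$rates > 0)
  loglik[nz, ] <- prune_categories(plan, dec, mix$rates[nz], pt,
                                   state$freqs)
  zr <- which(mix$rates == 0)
  if (length(zr)) {
    # a zero-rate category (explicit invariant category, or a gamma bin
    # whose rate underflowed at tiny alpha) contributes the stationary
    # mass of bases compatible with a constant column, per pattern
    inv_ll <- log(colSums(state$freqs * pt$inv_compat))
    loglik[zr, ] <- matrix(inv_ll, length(zr), npat, byrow = TRUE)
  }
  # weighted mixture per pattern in log space; returns log likelihoods
  lw <- loglik + log(mix$weights)
  if (nrow(lw) == 1L) return(lw[1, ])
  mx <- lw[1, ]
  for (r in 2:nrow(lw)) mx <- pmax(mx, lw[r, ])
  acc <- exp(lw[1, ] - mx)
  for (r in 2:nrow(lw)) acc <- acc + exp(lw[r, ] - mx)
  mx + log(acc)
}

#' Cached likelihood evaluator
#'
#' Returns a function `f(state)` computing [pruning_log_likelihood()]
#' with memoization.  Two independent cache slots are kept, one for the
#' single-category configuration (`has_gamma = 0`) and one for the
#' k-category configuration (`has_gamma = 1`), so toggling the gamma
#' indicator back and forth does not invalidate the other configuration's
#' cached value.  With `constant = TRUE` the evaluator always returns 0,
#' which turns the posterior into the prior (used for sampling-from-the-
#' prior correctness checks).
#'
#' @param tree Rooted `ape::phylo`.
#' @param pt A [compress_patterns()] table.
#' @param constant If TRUE, always return 0 (prior-only runs).
#' @return A function of one argument (a `site_model_state`).
#' @export
likelihood_evaluator <- function(tree, pt, constant = FALSE) {
  if (constant) return(function(state) 0)
  plan <- tree_plan(tree, pt$taxa)
  cache <- list(`0` = NULL, `1` = NULL)  # per gamma configuration
  dec_store <- NULL
  dec_cache <- list(get = function() dec_store,
                    set = function(v) dec_store <<- v)
  function(state) {
    key <- list(state$model, state$group_rates, state$alpha, state$has_inv,
                state$p_inv, state$freqs, state$k, state$has_gamma)
    slot <- as.character(state$has_gamma)
    hit <- cache[[slot]]
    if (!is.null(hit) && identical(hit$key, key)) return(hit$value)
    log_lik <- pattern_likelihoods(plan, pt, state, dec_cache)
    if (any(!is.finite(log_lik)))
      stop("non-finite pattern likelihood (model: ", state$model, ")")
    value <- sum(pt$counts * log_lik)
    cache[[slot]] <<- list(key = key, value = value)
    value
  }
}
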