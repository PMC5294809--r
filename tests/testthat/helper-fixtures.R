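# shared fixtures and independent oracles

fixed_tree <- function() read_tree(text = "(A:0.2,(B:0.15,C:0.15):0.05);")

# Brute-force enumeration of canonical models: canonicalize every code in
# {1..6}^6 and take the unique set.  Independent of rg_strings().
brute_force_models <- function() {
  grid <- as.matrix(expand.grid(rep(list(1:6), 6)))
  sort(unique(apply(grid, 1, canonicalize_model)))
}

# Brute-force site likelihood for a 3-taxon rooted tree
# (A:da,(B:db,C:dc):dint) by explicit summation over the states of the
# root and the inner node, mixing over the state's rate categories.
brute_force_site_lik <- function(state, pattern, da = 0.2, db = 0.15,
                                 dc = 0.15, dint = 0.05) {
  rates6 <- expand_rates(state$model, state$group_rates)
  Q <- rate_matrix(rates6, state$freqs, normalize = TRUE)
  mix <- category_mixture(state)
  iup <- rjsitemodel:::IUPAC
  pa <- iup[, pattern[1]]; pb <- iup[, pattern[2]]; pc_ <- iup[, pattern[3]]
  total <- 0
  for (ci in seq_along(mix$rates)) {
    r <- mix$rates[ci]
    if (r == 0) {
      lik <- sum(state$freqs * pa * pb * pc_)
    } else {
      Pa <- expm_pade(Q * r * da); Pb <- expm_pade(Q * r * db)
      Pc <- expm_pade(Q * r * dc); Pi <- expm_pade(Q * r * dint)
      lik <- 0
      for (root in 1:4) for (inner in 1:4)
        lik <- lik + state$freqs[root] *
          sum(Pa[root, ] * pa) * Pi[root, inner] *
          sum(Pb[inner, ] * pb) * sum(Pc[inner, ] * pc_)
    }
    total <- total + mix$weights[ci] * lik
  }
  total
}

# Independent matrix exponential: scaling-and-squaring Taylor series
# (avoids the package's eigendecomposition path).
expm_pade <- function(M, order = 24) {
  s <- max(0, ceiling(log2(max(1e-16, norm(M, "1")))))
  A <- M / 2^s
  P <- diag(4); term <- diag(4)
  for (k in 1:order) {
    term <- term %*% A / k
    P <- P + term
  }
  for (i in seq_len(s)) P <- P %*% P
  P
}

random_state <- function(model = "123456", seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- lengths(model_groups(model))
  z <- rgamma(length(sizes), 1)
  gr <- 6 * (z / sum(z)) / sizes
  site_model_state(model, gr, ...)
}
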