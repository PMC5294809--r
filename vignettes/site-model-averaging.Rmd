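---
title: "Bayesian site-model averaging by reversible-jump MCMC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian site-model averaging by reversible-jump MCMC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A Bayesian phylogenetic analysis of nucleotide sequences needs a *site
model*: a time-reversible substitution model on {A, C, G, T} together
with a description of rate variation across sites (discrete-gamma
categories, a proportion of invariable sites) and a choice between
equal and estimated base frequencies.  The common practice of picking
one site model with a likelihood-based selection tool and conditioning
the Bayesian analysis on it discards model uncertainty and introduces a
circularity, because the selection step itself needs a tree.
`rjsitemodel` instead samples the site model *inside* the MCMC: the
chain moves through a space of substitution models and switches the
rate-heterogeneity components on and off, so every downstream estimate
is automatically averaged over site models in proportion to their
posterior support.

## The model space

A time-reversible substitution model is determined by six
exchangeability rates in the fixed order (ac, ag, at, cg, ct, gt) and
the stationary frequencies.  Constraining subsets of rates to be equal
partitions the six positions into groups; each partition is one model,
written as a six-symbol restricted-growth code ("121121" is HKY,
"123456" is GTR).  There are 203 such partitions.  Because transitions
(ag, ct) are empirically faster than transversions, the package also
offers the 31-model subset whose groups never mix a transition with a
transversion rate (plus the all-equal model 111111), and a 9-model set
of named models (JC, HKY, TN93, K81, TIM, TVM, GTR) completed by two
intermediates, 123345 and 123324, that make the graph connected by
single splits.

Models are the nodes of a directed graph whose edges split one rate
group into two (and, reversed, merge two groups into one).  The
reversible-jump chain walks this graph.

The six expanded rates always sum to 6.  This is an identifiability
constraint only — the rate matrix is separately normalized to one
expected substitution per site — but it shapes the geometry of the rate
space: a model with G groups of sizes $n_1,\dots,n_G$ has group rates
living on the simplex slice $\{r_g > 0 : \sum_g n_g r_g = 6\}$, whose
volume is $V_M = 6^{G-1} / ((G-1)!\,\prod_g n_g)$.

## Priors

* **Rates**: flat on the constrained rate space (the default), or
  log-normal with real-space mean 1 and log-standard-deviation 1.25 on
  transition rates together with exponential mean-1 on transversion
  rates.  The flat prior's normalized density given a model is exactly
  $1/V_M$; including this term in the joint density is what makes the
  trans-dimensional acceptance ratios exact (see below).  For the
  transition/transversion prior the surface normalizer is intractable;
  the package uses the product of per-rate densities relative to the
  same reference measure, which leaves within-model ratios exact and
  across-model ratios approximate.
* **Models**: uniform over the set, or uniform over the number of free
  rate parameters (degrees of freedom 0–5 each get total mass 1/6, so
  JC and GTR get exactly 1/6).
* **Frequencies**: Dirichlet(4,4,4,4) — evenly spread, with about a
  2.2% chance that some frequency falls below 0.05.
* **Gamma shape** α: exponential with mean 1.  **Proportion
  invariable** p_inv: Beta(1,4), mean 0.2.  These densities enter the
  posterior only while their binary indicator is 1.
* **Indicators**: independent Bernoulli(1/2), making the four variants
  plain / +G / +I / +G+I equiprobable a priori.  (This choice is a
  package default; any inclusion probability can be configured.)

## The likelihood

The alignment is compressed to unique site patterns with counts.  For
each non-zero rate category (1 category, or k = 4 equal-weight
discrete-gamma categories whose rates are the exact conditional means
of the quantile bins of Gamma(α, α)), Felsenstein pruning is run with
branch lengths multiplied by the category rate, using the
eigendecomposition of the normalized rate matrix.  When the
invariable-site indicator is on, a zero-rate category of weight p_inv
is added and the non-zero rates are rescaled by 1/(1 − p_inv) so the
expected rate stays 1 and branch lengths keep their
substitutions-per-site meaning.  The zero-rate category never runs
pruning: its transition matrix is the identity, so a pattern
contributes exactly the stationary mass of the bases compatible with a
constant column (ambiguity codes and gaps resolved), at constant cost.
Two cache slots — one per gamma configuration — let the chain toggle
the heterogeneity indicator without invalidating the other
configuration's last likelihood.

## Proposals and their Hastings factors

Acceptance follows the standard Metropolis–Hastings–Green rule
$\min\{1,\ \text{posterior ratio} \times q(S\mid S')/q(S'\mid S)
\times |J|\}$.

* **Split**: choose a child model uniformly among the graph children;
  the split group's rate r is divided as $r_i = r + u/n_i$,
  $r_j = r - u/n_j$ with $u \sim U(-n_i r,\ n_j r)$, preserving the
  rate sum.  The forward density is $1/(|S(M)|\,(n_i+n_j)\,r)$, the
  reverse $1/|P(M')|$, and the Jacobian of $(r,u) \mapsto (r_i,r_j)$ is
  $(n_i+n_j)/(n_i n_j)$.  At GTR the proposal returns the current
  state, which is required for uniform model sampling.  **Merge** is
  the mirror image, with merged rate $(n_i r_i + n_j r_j)/(n_i+n_j)$
  and JC self-proposing.  Together with the $1/V_M$ prior term these
  factors make a likelihood-free chain sample models exactly uniformly
  — the package's decisive correctness test, run over the full 31-model
  set in the test suite.  During development this test was also what
  arbitrated the bookkeeping: omitting the volume term, or treating the
  rate exchange below as symmetric, produces clearly non-uniform model
  frequencies on a small partition lattice.
* **Rate exchange**: two groups are chosen at random and
  $r_i' = r_i - u$, $r_j' = r_j + u\,n_i/n_j$ with
  $u \sim U(0, \delta)$.  This kernel is *not* symmetric when the group
  sizes differ: the reverse move draws $u' = u\,n_i/n_j$, so the
  correct Hastings factor is $n_i/n_j$ and the move must be rejected
  outright when $u\,n_i/n_j > \delta$ (the reverse draw would fall
  outside its window).  The proposal also fails when $r_i' < 0$.
* **Indicator birth/death** (gamma, invariable sites, estimated
  frequencies): flip the flag; a birth draws the parameter fresh from
  its prior density d, contributing $-\log d(\text{new})$ to the log
  Hastings term (a death contributes $+\log d(\text{old}))$; the
  Jacobian is 1.  With d equal to the prior, everything cancels except
  the indicator prior and the likelihood.  Parameters keep their old
  values while switched off, but those values are inert — they enter
  neither likelihood nor prior — and are overwritten at the next birth.
* **Variant swap**: a direct jump between the +I and +G variants
  (abandoning one parameter, drawing the other fresh from its prior).
  The two variants fit similar signals, and reaching one from the other
  through +G+I requires the retained parameter to stay fixed while the
  second is born — a path with very low acceptance that can trap a
  chain in the wrong variant for thousands of iterations.  The direct
  swap removes that trap; its Hastings term is the abandoned density
  over the fresh density, and with prior-draw proposals it leaves a
  likelihood-free chain exactly on the prior.
* **Scale / walk moves**: α is scaled multiplicatively on the log
  scale (Hastings $+\log s$), p_inv moves by a logit-space Gaussian
  walk, frequencies by a Dirichlet kernel centred on the current value;
  each operator only fires while its indicator is on.

The rate-exchange window, the α scale window, the p_inv walk scale and
the frequency-walk concentration are tuned by Robbins–Monro updates
toward an acceptance rate of 0.234 during burn-in only and frozen
afterwards, so the retained sample obeys detailed balance.  Tuning the
frequency walk matters more than it looks: with thousands of sites the
frequency posterior is far tighter than any fixed kernel width, and an
untuned walk mixes so slowly that its HPD intervals undercover.

## The simulator and the calibration studies

`simulate_alignment()` draws a category per site from the state's
mixture; a zero-rate site copies one root base (drawn from the
stationary frequencies) to every taxon, other sites evolve along the
tree with the transition probabilities at the category rate.
`simulate_yule_tree()` grows a pure-birth tree conditioned on the tip
count, waiting Exp(kλ) while k lineages exist; the expected root height
is $(1/\lambda)\sum_{k=2}^{n} 1/k$, about 0.233 for five taxa at
λ = 5.5 (and about the same once λ is drawn from the narrow log-normal
prior with real-space mean 5.5 and log-sd 0.048 used in the
calibration study).

Two studies, both on the fixed three-taxon tree
`(A:0.2,(B:0.15,C:0.15):0.05)` with 10,000-site alignments and truths
drawn from the prior (transition/transversion rate priors, uniform
model prior on the 31-model set):

* **Rate recovery** (`rate_recovery_study()`): posterior-mean expanded
  rates regressed on true rates, per rate position; a correctly
  implemented sampler reaches R² > 0.99 on every position.  The
  package's default scale is 100 replicates (half simulated with gamma
  heterogeneity, all with equal base frequencies and none with an
  explicit invariable-site truth category — invariant columns arise
  freely from the low-rate gamma categories) with 10,000-iteration
  chains.  Replicate counts much below this make the per-rate R² an
  unstable summary: a single weakly informative replicate (a tiny
  gamma shape puts most sites in near-zero rate categories) moves it
  by ±0.01.
* **Coverage** (`coverage_study()`): per-parameter 95% HPD coverage and
  credible-set coverage of the true substitution model and site-model
  variant.  For a well-calibrated Bayesian procedure each coverage is
  binomial around 95%; the test suite checks consistency with 0.95 by
  exact binomial tests at α = 0.01 (the same yardstick as the classic
  observation that 89/100 or fewer successes has probability ≈1.1%
  under p = 0.95).  The packaged scale is four cells — plain and +G
  under equal and estimated frequencies — with 15 replicates each and
  30,000-iteration chains retained densely (every 6th state).  Chain
  length and retention matter here for an easily missed reason: the
  empirical shortest-window HPD is biased narrow both when the
  effective sample size is small and, more surprisingly, through the
  minimum-width selection itself (in a Gaussian toy it covers ~93.7%
  rather than 95% even from a thousand independent draws), so
  undersized traces show spurious undercoverage that has nothing to do
  with the sampler.  Cells with the invariable-site indicator
  clamped on are omitted from the default grid because the +I/+G
  interaction needs many more replicates to distinguish genuine
  miscalibration from noise; the machinery accepts any cell list.

What the simulator deliberately shares with the analysis model — and
therefore what these studies do *not* probe — is the site-model family
itself: real data contain partition structure, alignment error,
selection and non-reversible processes that no member of the family
captures.  Passing calibration shows the sampler targets the posterior
it claims to target, not that the family is adequate for any particular
data set.

## Numerical choices and edge cases

* Restricted-growth canonicalization makes the model code unique; all
  user input is canonicalized on entry.
* The discrete-gamma bin means are computed from the incomplete-gamma
  identity (no quadrature) and renormalized to mean 1 against
  quantile round-off.
* Likelihood underflow is handled by per-pattern rescaling of partial
  likelihoods, activated on trees with more than 8 tips where it could
  matter; mixtures over categories are combined in log space.
* Degenerate inputs: zero-length branches are exact (transition matrix
  is the identity); `p_inv` at its bounds, negative rates and non-simplex
  frequencies are rejected with errors rather than silently clamped.
* Chains with a non-finite initial posterior abort with a diagnostic
  rather than starting.
* Posterior summaries use a default 10% burn-in (20% in the calibration
  studies, whose chains are short); HPD intervals are shortest
  order-statistic windows; credible model sets break probability ties
  by model string so results are deterministic.

## Known limitations

* The tree is fixed (topology and branch lengths): the package
  averages site models *given* a tree, it does not co-estimate the
  phylogeny.
* One partition per alignment; no codon or amino-acid model spaces.
* The transition/transversion rate prior is evaluated up to an
  intractable surface normalizer (see above); with that prior the
  model-indicator marginal under a constant likelihood is approximate,
  while the default flat prior is exact.
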