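---
title: "Exploratory phylogenetic path analysis with phylodag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exploratory phylogenetic path analysis with phylodag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylodag)
```

## The problem

Comparative datasets — species traits, or the traits of human societies
keyed to a language phylogeny — confound two things: which variables cause
which, and the non-independence of taxa that share ancestry. Confirmatory
phylogenetic path analysis addresses both at once, but only for a handful
of hand-specified causal structures. `phylodag` removes the
hand-specification step: it enumerates *every* directed acyclic graph
(DAG) over the chosen variables that a set of declared causal constraints
permits, scores each by phylogenetic d-separation, and condenses the
best-supported models into one averaged causal diagram.

## The model and its scoring

A candidate causal structure is a labelled DAG over the trait variables.
Each DAG entails a *basis set* of conditional-independence claims: for
every non-adjacent pair $\{x, y\}$, the claim
$x \perp y \mid \mathrm{pa}(x) \cup \mathrm{pa}(y)$. Each claim is tested
with a phylogenetic generalised least squares (PGLS) regression of one
pair member on the other plus the conditioning set; the claim's p-value is
the Wald p-value of the claimed-independent predictor. Claim p-values are
combined with Fisher's C,

$$C = -2 \sum_{k=1}^{K} \ln p_k,$$

which is $\chi^2_{2K}$ distributed when the model's claims all hold
(Shipley's test). Models are compared on the small-sample C-statistic
information criterion,

$$\mathrm{CICc} = C + 2q\,\frac{n}{n - 1 - q},$$

where $n$ is the number of taxa and $q$ the parameter count. By default
$q = |E| + |V|$ (one coefficient per edge plus one residual variance per
node, the `phylopath` convention); `q_def = "edges"` is available and the
choice is recorded in every report. Models within 2 CICc of the best are
retained and given Akaike weights $w_i \propto \exp(-\Delta_i/2)$.

**Conditional averaging.** A path's averaged coefficient is the weighted
mean over only the retained models containing that path (weights
renormalised within that subset); full averaging, where absent models
contribute zero, is available via `averaging = "full"`. The averaged
standard error includes the between-model spread,
$\mathrm{SE} = \sum_i w_i \sqrt{\mathrm{se}_i^2 + (\beta_i -
\bar\beta)^2}$, and confidence intervals are
$\bar\beta \pm 1.96\,\mathrm{SE}$ (a normal approximation; the multiplier
is configurable). Paths whose CI spans zero are flagged and omitted from
the rendered diagram. Because different retained models may orient the
same adjacency differently, the averaged model can legitimately contain
both directions of a pair; such pairs are flagged bidirectional rather
than treated as errors.

Path coefficients are fitted on standardised variables (mean 0, SD 1;
binary variables standardised for the coefficient fits but reported 0/1 in
data) so that magnitudes are comparable across paths and arrow widths in
the DOT rendering are meaningful.

## The constrained model space

Constraints come in two forms, declared with `constraint_spec()`:
*mutually exogenous groups* (members may be predicted only by members of
the same group — e.g. two environmental variables that no socio-cultural
variable can cause) and *forbidden parents* per variable. Enumeration
works on the digraph of permitted edges: every directed cycle lies inside
one strongly connected component of that digraph, so the space factorises
into the Cartesian product of the acyclic edge subsets of each component
with free inclusion of all between-component edges. This keeps the
six-variable study-pattern space (153,600 DAGs) enumerable in milliseconds
and, more importantly, makes the count itself checkable by hand:
$3 \times 25 \times 2^{11}$ for two mutually exogenous environmental
variables, a three-variable socio-cultural tournament, and eleven free
cross edges.

The space deliberately includes disconnected DAGs ("all possible models");
`connected_only = TRUE` filters them. A guard refuses more than 7 nodes or
`max_models` DAGs unless raised explicitly, since the unconstrained space
grows super-exponentially.

Scoring the whole space is vectorised: per-model parent sets, adjacency,
and transitive closures are computed as bit-parallel operations across the
entire membership matrix, and each *canonical claim* (response, predictor,
conditioning set) is fitted once process-wide through a content-addressed
cache. Correctness of the cache is enforced by a test comparing cache-on
and cache-off scores to 1e-12.

## Phylogenetic regression

`pgls_fit()` estimates $\beta = (X^\top \Sigma^{-1} X)^{-1} X^\top
\Sigma^{-1} y$ with $\Sigma$ derived from the tree and a correlation
parameter fitted by profile maximum likelihood:

* `transform = "lambda"` (default): Pagel's $\lambda \in [0, 1]$
  multiplies the off-diagonal Brownian covariances; $\lambda = 0$ is
  ordinary least squares (tested to 1e-8), $\lambda = 1$ full Brownian
  structure.
* `transform = "ou"`: an Ornstein–Uhlenbeck-style decay,
  $\mathrm{corr}_{ij} = e^{-\alpha d_{ij}}$ with $d_{ij}$ the patristic
  distance, searched on $\alpha \in [10^{-6}, 50/\max d]$. This honours
  analyses that report the correlation parameter as $\alpha$; the fitted
  parameter and transform are always recorded in output.

The profile is maximised by an 11-point grid followed by golden-section
refinement in the bracketing interval — single `optimize()` calls can miss
the boundary optimum at $\lambda = 0$ or $1$. Wald t-tests use
$n - p$ degrees of freedom ($p$ columns of the design, intercept
included). p-values are floored at $10^{-16}$ before entering Fisher's C
so a single extreme claim cannot produce an infinite statistic.

**Binary responses.** d-separation tests on binary (0/1) traits default to
the linear 0/1 GLS — deterministic, fast, and the convention of
regression-based path analysis on binary data. An approximate latent-scale
logistic variant (`phylo_logistic_fit()`, IRLS with a
phylogenetically blended working covariance) is opt-in; at $\lambda = 0$
it reproduces ordinary logistic regression to 1e-4, and complete
separation triggers a warning plus a Firth-style penalty. Which estimator
a published analysis used for binary traits is often unstated; both are
provided and the choice is recorded.

**Missing data.** The bivariate screen deletes listwise per regression
(each candidate keeps its maximal sample); the path search deletes
listwise across *all* model variables so every model is scored on the same
$n$ — CICc comparisons require a common sample size.

## Phylogenetic signal for binary traits

`d_statistic()` implements the Fritz–Purvis D statistic. The observed
quantity $d_{obs}$ sums, over internal nodes, the absolute differences
between nodal values of each unordered daughter pair, nodal values being
daughter means computed tips-to-root. $d_{obs}$ is located between two
simulated calibration means:

$$D = \frac{d_{obs} - \overline{d}_{Brownian}}
           {\overline{d}_{random} - \overline{d}_{Brownian}},$$

so tip-shuffled traits give $D \approx 1$ and threshold-Brownian traits
$D \approx 0$ *by construction* (verified at $|{\rm mean} - {\rm
target}| < 0.1$ over 200 replicates on a 128-tip tree). $p_{random}$ is
the fraction of shuffled replicates at least as clumped as observed, with
a $1/(B+1)$ floor.

**Polytomies.** The default sums over all unordered daughter pairs at a
polytomy. On highly polytomous classification trees this lets a
high-degree root node dominate $d$ and can compress — even invert — the
span between the two calibration means, destabilising D.
`polytomy = "resolve"` randomly bifurcates polytomies first (seeded,
zero-length branches) and is the recommended setting for
classification-derived trees.

`mantel_test()` reports both the raw upper-triangle cross-product $z$
(whose magnitude depends on the units of the two matrices) and the
standardised Mantel $r$, with a one-tailed permutation p-value. The raw
$z$ is reported because unstandardised sum statistics of this form appear
in the comparative literature; a raw $z$ is not comparable across studies
without the underlying matrices.

## Trees from classifications

`tree_from_classification()` converts nested group memberships
(family, subgroup, ...) into a rooted tree: taxa sharing a prefix of
groups share an internal node, each classification level contributes one
unit of branch length, and tip edges are padded so the tree is ultrametric
(all root-to-tip depths equal max level count + 1). Unary chains collapse,
so singleton families attach at the root. No published convention fixes
branch lengths for classification trees; unit-per-level is the default,
`scaling = "grafen"` is offered, and the choice is visible in the tree
itself. Such trees are proxies: they encode shared descent only at the
resolution of the classification, and their polytomies are structural, not
evidence of simultaneous divergence.

## The synthetic-data generator

`simulate_traits()` draws exogenous variables as Brownian traits on the
tree; each endogenous variable is the coefficient-weighted sum of its
standardised observed parents plus a residual whose correlation structure
blends the tree with independence (`noise_signal` in $[0,1]$, default 1),
scaled toward unit marginal variance (residual variance
$\max(0.05,\,1-\sum\beta^2)$, so a singly-parented node with $\beta = 0.8$
has standardised coefficient exactly 0.8). Binary traits are
liability-thresholded at the empirical quantile, so requested prevalences
are matched *exactly* — `hunter_gatherer_fixture()` reproduces a study-shaped
dataset of 68 taxa in 35 families with a 48/68-present binary focal trait,
two continuous environmental variables constrained as mutually exogenous,
and a seven-edge generating DAG.

What the generator emulates: phylogenetic signal in both liabilities and
residuals, exact binary marginals, a known causal structure with
standardised effects, family-clustered geography. What it does not:
horizontal transmission (borrowing between neighbours independent of the
tree), measurement and coding error, missing data mechanisms, and
non-Gaussian liabilities. Passing recovery tests on these data therefore
demonstrates correctness of the machinery under the model's own
assumptions, not robustness of causal discovery on real comparative data.

## Numerical choices and degenerate inputs

* Ties in model ranking break by smaller C, then fewer edges, then the
  lexicographically earliest edge list — rankings are reproducible.
* The claim response for a non-adjacent pair is the pair member downstream
  in the model (or later in declared order when incomparable); in GLS the
  claim p-value is direction-symmetric, so this is a canonicalisation, not
  a modelling choice.
* Degenerate fits fail loudly: zero-variance responses, rank-deficient
  designs (naming the collinear columns), taxa missing from the tree
  (listing offenders), and samples too small for the CICc correction
  ($n \le q + 1$) mark a model unscored rather than aborting the search.
* All stochastic results carry their seed and permutation count;
  `report_json()` output is byte-identical across reruns of the same
  configuration.

## Problem sizes used in validation

The shipped validation suite exercises: exhaustive enumeration oracles at
2–4 variables (3/25/543 DAGs) plus randomised constraint specifications;
the six-variable constrained space (153,600 models) scored end-to-end on
the 68-taxon fixture; D calibration with 200 replicates of 99 permutations
on 128 tips; null calibration of the search over 40 datasets of 200 tips;
and parameter recovery from a known five-variable DAG at 300 tips and
standardised effects of 0.8 across 10 seeded replicates. These sizes make
the full suite run in a few minutes while keeping every Monte-Carlo
assertion comfortably inside its tolerance.

## Known limitations

* CICc retention at $\Delta \le 2$ near-always includes saturated models
  (an extra edge costs ~2 CICc while a true claim contributes ~2 to C on
  average), so the averaged model tends to include reversed orientations
  of well-supported adjacencies — reported as bidirectional pairs. Treat
  orientation claims with corresponding caution.
* d-separation claims within one model are only asymptotically
  independent; Fisher's C inherits that approximation.
* The logistic binary variant is a documented approximation, not a full
  phylogenetic GLMM.
* No latent variables, correlated errors, Markov-equivalence reduction, or
  search heuristics: exhaustiveness within the declared constraints is the
  point, and the node-count guard is the price.
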