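---
title: "Methods: multilayer ecological analysis of chaperone-client networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multilayer ecological analysis of chaperone-client networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccinet)
```

## The system and the model

ccinet treats chaperone-client interactions (CCI) as a multilayer bipartite
ecological network. A small set of chaperones (15 mitochondrial chaperones in
the motivating system) interacts with a large set of client proteins
(~1000); every environment — one cancer type, in the motivating system — is
one binary layer over the same node sets. The analysis asks three questions:
how does the environment modulate which interactions a chaperone realizes,
can interactions in one environment predict those in another, and how robust
is each layer to targeted chaperone removal?

All containers are tidy: a network is an edge tibble plus node universes
(`cci_network`), and every analysis function returns a tibble, so results
chain with the pipe.

## Building layers from coexpression

A layer is inferred from a genes x samples expression matrix: Spearman rank
correlation (midranks for ties, which matters for FPKM-like data with zeros)
between every chaperone and every client, a two-sided p-value from the
t approximation on $n-2$ degrees of freedom, and a Bonferroni correction
whose family is all chaperone x client tests within the layer (15 x 1142 =
17,130 at full scale; the family is a package choice — networks are built
per environment). An edge requires a *positive* significant correlation.

Because cohorts differ in size, raw per-cohort networks differ in power. The
bootstrap-consensus construction (`bootstrap_consensus()`) therefore draws a
fixed number of samples without replacement (the smallest cohort size; 288
at full scale), rebuilds the correlation network, repeats this 1000 times,
and keeps a pair as an interaction only if it is significant and positive in
at least 95% of attempts. The threshold is inclusive: exactly 95% qualifies.
The non-bootstrap single-pass network (`correlate_layer()`) is exposed too,
but the pipeline default is the consensus network, which supersedes it
downstream.

## Niche statistics

With $L_c^\alpha$ the links of chaperone $c$ in layer $\alpha$ and $P_c$ the
size of the union of its client sets across layers:

* specialization $S_c = P_c / N_{\text{clients}}$ and its per-layer analogue
  $S_c^\alpha = L_c^\alpha / N_{\text{clients}}$ (the denominator is the
  network's client-set size, never a hard-coded constant);
* realized niche $R_c^\alpha = L_c^\alpha / P_c$;
* partner fidelity $J_c$: the median over unordered layer pairs of the
  Jaccard similarity between $c$'s client sets in the two layers;
* within-layer niche overlap $J_{xy}^\alpha$: the Jaccard similarity of two
  chaperones' client sets inside one layer.

The Jaccard similarity of two *empty* sets is left undefined and excluded
from medians rather than being scored 0 or 1; either convention would bias
the fidelity of sparse chaperones, so the pair simply carries no
information. Medians use the standard midpoint convention for even counts.

## Weighted nestedness

Nestedness here is not a property of a single CCI layer but of the
chaperone x environment matrix of realized niches: environments that let a
chaperone realize few of its interactions tend to be subsets of those that
let it realize many, and likewise across chaperones. It is measured as the
spectral radius $\rho$ of that weighted matrix — the largest eigenvalue of
the symmetric bipartite embedding $[[0, B], [B^\top, 0]]$, equal to the
largest singular value of $B$. This definition is invariant to row and
column permutations and monotone in the entries (a Perron–Frobenius
property), both verified numerically in the tests.

Significance uses the curveball algorithm: repeated trades between random
row pairs that re-deal the columns held by exactly one of the two rows,
preserving every row and column sum exactly. Each null replicate shuffles
every layer independently, the statistic matrix is rebuilt — with $P_c$
*recomputed* from the shuffled layers — and the one-tailed p-value is the
fraction of null $\rho$ values strictly exceeding the observed one (ties
count toward the null). The default of 5 trades per row follows published
mixing guidance and is configurable; `curveball_trace()` exposes a mixing
diagnostic, and the tests check the sampler against the brute-force
enumeration of a small fixed-margin class.

Two degeneracies are worth knowing about. First, because curveball
preserves per-layer row sums, the $S_c^\alpha$ matrix is *invariant* under
this null; the test is informative only for the realized-niche matrix,
whose null varies through $P_c$. Both builders are exposed, but only the
realized-niche test is meaningful. Second, a perfectly nested *single*
matrix (as produced by `generate_nested_matrix()`) is the unique member of
its fixed-margin class — its column sums are the conjugate partition of its
row sums — so curveball cannot move it at all and its p-value is trivially 0.
The nestedness property is therefore exercised where the analysis actually
applies it: `generate_nested_network()` plants a nested realized-niche
gradient in a multilayer network (each chaperone holds nested prefix subsets
of a private client preference order, with link counts decreasing across
chaperones and layers), which curveball *can* randomize.

## The multilayer mixed-membership block model

Each chaperone $i$ carries an outgoing membership vector $u_i$ over $K$
groups, each client $j$ an incoming vector $v_j$, and each layer $\alpha$ a
$K \times K$ affinity matrix $w^{(\alpha)}$; the expected edge count is the
bilinear form $M_{ij}^{(\alpha)} = \sum_{k,l} u_{ik} v_{jl}
w_{kl}^{(\alpha)}$. The bipartite constraint is structural: chaperones have
only $u$, clients only $v$. Binary adjacencies are treated as Poisson
counts, giving the log-likelihood $\sum_{\alpha,i,j} [A_{ij}^{(\alpha)}
\log M_{ij}^{(\alpha)} - M_{ij}^{(\alpha)}]$.

Fitting is by multiplicative EM updates (the standard
Kullback–Leibler-divergence non-negative factorization updates, extended to
the layer tensor and to an observation mask). These never decrease the
log-likelihood; the test suite asserts per-iteration monotonicity on random
instances. Numerical choices: parameters initialize uniform(0,1); the best
of 10 random restarts is kept (fewer in the cheaper prediction loops);
convergence is an absolute log-likelihood change below 1e-6 checked every
10 iterations, capped at 500 iterations (a cap hit returns the model with
`converged = FALSE` and a warning — on large instances the likelihood is
already flat to ~1e-3 by then, which does not move assignments); a floor of
1e-12 guards $\log M$ and the update denominators; nodes whose update
denominator vanishes (no observed cells) get zero membership and are
reported unassigned.

$K$ is chosen by BIC $= -2\log L + p \log n$ over an inclusive range
(2..15 at full scale), with $p = K(n_{\text{chap}} + n_{\text{client}}) +
K^2 L$ free parameters and $n$ the number of observed adjacency cells —
each cell is one observation under the likelihood. The mixed-membership
normalization could be argued to remove one parameter per node; the count
above is the package's documented convention and is configurable only by
editing the formula, since model comparison only needs it to be consistent
across $K$. Hard groups take the argmax of the normalized membership, ties
to the lowest group index.

## Link prediction

The hold-out unit is the adjacency *cell*, not the present edge: the Poisson
likelihood is defined over all cells and the ROC needs negatives, so an
80% hold-out of "links" is realized as inverted 5-fold cross-validation over
cells (train on one fold — the visible 20% — and score the other four).
Masked cells are excluded from the likelihood via the mask argument of the
fitter, and a leakage test asserts that perturbing masked cells leaves the
fit unchanged. Within-layer prediction fits the target layer alone;
cross-layer prediction fits exactly two layers — the 20% visible target plus
the full auxiliary — and scores the masked target cells by the target
layer's $M$. $K = 2$ is fixed for all prediction runs (the BIC-selected
grouping at full scale), and the grid averages 20 repetitions of 5-fold
cross-validation per cell at full scale. AUC uses the midrank
(Mann–Whitney) formulation, cross-checked against brute-force pair counting.

## Co-extinction robustness

Chaperones are removed sequentially from one layer; a client is co-extinct
once its last connected chaperone is gone. The curve of surviving-client
fraction (denominator: clients with at least one link initially — clients
never connected carry no information about collapse; a switch to the full
client set would only rescale the curve) against fraction removed is scored
by trapezoidal area $T$ on the $k/N$ grid including both endpoints. Removal
orders: (1) most-to-least connected, using *static* initial degrees with
identifier tie-breaks (a dynamic-recompute mode exists behind a flag);
(2)/(3) most-to-least connected within module 1 then module 2, and the
reverse, where module numbers order the SBM hard groups by descending size
(ties by lowest member identifier); (4) random, averaged over 100 seeded
replicates with dispersion reported. Scenario-wise $T$ is then correlated
(two-tailed Spearman) with each layer's mean realized niche.

## The synthetic-data generator

The generator exists so that every stage is testable without external data.
`generate_sbm_multilayer()` draws memberships from a symmetric Dirichlet
(concentration 0 = hard one-hot memberships), puts `within_rate` (default
0.3, giving layer densities in the range the consensus networks show) on
the affinity diagonal and `within_rate / affinity_contrast` off it, and
draws each edge Bernoulli(min(1, M)) — binary incidence, with clipped rates
counted and reported, rather than Poisson thresholding. Cross-layer partner
fidelity is controlled by sharing versus resampling the affinity matrix
across layers. `generate_expression()` gives every chaperone a latent
standard-normal signal per sample and makes each linked client that signal
plus Gaussian noise, calibrated through the bivariate-normal rank
correlation $r = 2\sin(\pi \rho_s / 6)$ so linked pairs hit a target
Spearman correlation; a client with several chaperones uses their summed
(variance-normalized) signals; everything is shifted to be non-negative,
which is rank-preserving. No generative model for expression is implied by
the analysis itself; this latent-factor choice is the package's own, the
simplest mechanism that makes coexpression recovery tunable by one
parameter. It deliberately does not mimic FPKM marginal distributions,
tumor purity, or batch effects — so passing recovery tests demonstrates the
pipeline's statistical machinery, not robustness to those artifacts.

## Problem sizes used in the tests

Unit tests run on networks of roughly 3–15 chaperones, 10–300 clients and
1–12 layers. The deeper checks use: 1000 curveball replicates of a
15 x 1142 matrix (margin conservation); a 15 x 1000 x 12 planted network
with contrast 10 for SBM recovery and BIC selection over K = 2..6; 1000
shuffles for the nestedness null on a 15 x 300 x 8 nested network; and
3–4 repetitions of 5-fold cross-validation for the prediction properties.
These sizes were chosen so the full suite runs comfortably on one CPU while
keeping every statistic well inside its asymptotic regime.

## Known limitations

* Co-extinction has no rewiring: a removed chaperone's clients cannot be
  adopted by another chaperone, so $T$ is a lower bound on biological
  robustness.
* The curveball null is conservative (fixed margins), inflating type II
  error; significant results are correspondingly trustworthy.
* The coexpression stage assumes monotone dependence; non-monotone
  regulation is invisible to Spearman correlation.
* BIC's parameter count for a mixed-membership model is a convention, not a
  theorem; comparisons across K are internally consistent but absolute BIC
  values should not be compared across packages.

## A worked example

```{r example, eval = FALSE}
library(ccinet)

sim <- generate_sbm_multilayer(
  n_chaperones = 15, n_clients = 200, n_layers = 4,
  K = 2, affinity_contrast = 10, membership_concentration = 0, seed = 1
)
net <- sim$network

niche_table(net)
partner_fidelity_scores(net)
nestedness_test(net, n_shuffles = 200, seed = 1)

sel <- select_K(net, K_min = 2, K_max = 4, n_restarts = 3, seed = 1)
glance(sel$best_model)

mods <- module_numbers(hard_assignments(sel$best_model))
robustness_suite(net, mods, n_random_reps = 50, seed = 1)
```
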