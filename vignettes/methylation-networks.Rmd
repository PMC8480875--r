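---
title: "Methods: inferring, sparsifying and perturbing epigenetic-clock methylation networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(methylnet)
```

This vignette is the package's own account of the methods it
implements: the models, the tunable parameters and their defaults, the
numerical choices, and the places where the design was genuinely open
and a decision had to be made. It states no empirical numbers beyond
what the test suite and `scripts/acceptance.R` themselves compute.

## 1. The clock and its two branches

A linear epigenetic clock maps a methylation profile
$m \in [0,1]^N$ to an age estimate through
$S = \sum_i H_i m_i$:

$$a = \begin{cases}(a_t + 1)\,S + a_t & S \ge 0\\
\exp(S + \ln(a_t+1)) - 1 & S < 0,\end{cases}$$

with adult threshold $a_t = 20$ years by default. The two branches join
continuously at $S = 0$ (both give $a_t$), which `horvath_age()`
implements exactly as written, with no global intercept beyond $a_t$.
A published clock carrying an extra intercept can be represented by a
constant pseudo-CpG held at level 1 whose coefficient is the intercept;
this is documented rather than default, so the transform stays a pure
function of the coefficient table.

All perturbation analysis assumes the linear (adult) branch, because
the derivative of the exponential branch depends on the operating
point; adult cohorts live in the linear branch, and the synthetic clock
fit refuses ages at or below $a_t$ for the same reason.

## 2. Neighbourhood Lasso inference

Each CpG $j$ is modelled on the remaining CpGs,
$m_j = \sum_{i \ne j}\beta_{ji} m_i + \beta_0$, by L1-penalised
regression with the penalty chosen by 10-fold cross-validation
(`glmnet::cv.glmnet` behind `fit_node_lasso()`). Decisions worth
recording:

* **No predictor standardisation by default.** Beta values already
  share the $[0,1]$ scale, and the link weights $|\beta_{ji}|$ are
  compared *across* node pairs when thresholding; per-predictor
  rescaling would distort exactly the quantity the threshold acts on.
  A `standardize` flag exists for sensitivity analysis.
* **Penalty path**: 100 log-spaced values down to $10^{-3}$ of the
  all-zero penalty; the CV-optimal `lambda.min` is the default fit and
  the more conservative `lambda.1se` is switchable.
* **Fold assignment is seeded, balanced and shared** across all
  per-node fits of one network, making `build_network()` invariant to
  sample order given fixed folds, and whole runs reproducible from one
  integer.

### What this inference can and cannot identify

Per-node regression identifies each node's *Markov blanket* — its
parents, children and co-parents in a directed generative model — not
the direction of individual links. If the data were generated by a
sparse DAG, the recoverable object is the DAG's **moral graph**
(undirected skeleton plus couplings between co-parents of a shared
target): a true link $i \to j$ also surfaces reversed in $i$'s own
regression, and two parents of one child acquire a genuine conditional
dependence. The package therefore evaluates synthetic support recovery
(`support_recovery()`) as undirected pairs against
`planted_support()`, the moral graph of the planted truth, after
screening inferred links at a $|\beta| \ge 0.15$ floor — the
cross-validated fits retain a halo of small-magnitude coefficients
around the true structure, and the floor (fixed once, after pilot runs
on the generator's default regime) separates that halo from planted
couplings of order 1. Directed-edge precision would be structurally
capped near one half regardless of sample size, which is a property of
neighbourhood selection itself, not of this implementation.

## 3. Efficiency-based sparsification

The unthresholded network is dense. `scan_thresholds()` keeps links
with $w_{ij} \ge w^*$ and selects $w^*$ by maximising

$$J(w^*) = \frac{E_g + E_l}{\rho_L},$$

where $E_g$ is the mean inverse directed shortest-path length over
ordered pairs (unreachable pairs contribute 0), $E_l$ the mean over
nodes of $E_g$ on each node's neighbour subgraph, and
$\rho_L = L/[N(N-1)]$ the link density. Numerical choices:

* Shortest paths are **unweighted** on the thresholded digraph: the
  efficiency criterion is topological, and mixing weight magnitudes
  into path lengths would double-count the quantity being thresholded.
* The neighbour set for $E_l$ is the **union of in- and
  out-neighbours**, with the node itself removed and directed links
  kept; an out-neighbours-only mode is available, since the criterion
  is also used in the literature in that form.
* The default grid is 200 evenly spaced candidates between the
  smallest and largest observed weight; candidates emptying the graph
  are excluded from the argmax (their $J$ is undefined), and ties break
  toward the smaller threshold, i.e. the denser network.

## 4. Hierarchy: m-reach, GRC and the configuration-model null

The $m$-reach of a node is the fraction of the other $N-1$ nodes
reachable along directed paths of length $\le m$; the $N-1$ denominator
(self excluded) makes a node that reaches everyone score exactly 1.
GRC$(m)$ averages the gap to the maximal reach, again over $N-1$. The
default horizon is $m = 3$, with the null comparison reported for
$m \in \{2,3,4,5\}$ in full pipeline runs (`grc_null_profile()` reuses
one randomized ensemble across horizons).

The null ensemble preserves every node's in- and out-degree exactly:
repeated double-link end swaps, rejecting any swap that would create a
self-loop or duplicate link, with the *accepted* swap count equal to
`swaps_per_link` (default 10) times the link count. Multigraph states
never occur, so every sample is a simple digraph, and both degree
sequences are asserted on every draw. Degenerate cases are made
explicit rather than papered over: a degree sequence admitting no swap
(an out-star, or any graph with fewer than two links) yields a
flagged degenerate null with `z = NA` instead of a division by zero,
and a rigid-but-not-provably-fixed graph raises an error reporting the
acceptance rate. Desk-scale runs default to 1,000 null samples;
publication-scale ensembles (20,000) are a parameter away.

Level assignment sorts nodes by decreasing reach and opens a new level
when the gap to the current level's top reaches one tenth of the
standard deviation of all reach values; exactly equal reaches always
share a level (the zero-spread boundary case is resolved toward
grouping, so a constant reach profile is a single level).

## 5. Structural control

`control_centrality()` computes $C(i)$ combinatorially: take the
subgraph reachable from $i$, attach an auxiliary external source $s$
with the single link $s \to i$, and count the links of a maximum
matching in the bipartite (out-copy / in-copy) representation. Link
weights are ignored — structural controllability depends only on the
unweighted pattern. Two conventions were open:

* **The node counts itself**: the $s \to i$ link participates in the
  matching, so $C(i) \ge 1$ and the head of an $n$-chain scores $n$,
  matching the structural-controllability convention that one driver
  controls an entire directed path. The exclusive variant is
  `include_self = FALSE`.
* **Relative centrality divides by the full $N$**, not the reachable
  subgraph's size, so values are comparable across nodes.

Only the matching *size* enters $C(i)$, so any maximum-matching
algorithm gives the same result; the package delegates to igraph's
bipartite matching. `sweep_averaged_control()` averages $c(i)$ over 60
evenly spaced thresholds in $[0.04, 0.1]$ by default. That band is
meaningful only on data whose link weights extend down to that scale;
on networks whose weights are all larger the sweep is constant, and the
band should be set relative to the observed weight range (both bounds
are plain arguments). Thresholds that empty the entire network are
dropped (an all-empty sweep is an error); a node isolated by a
threshold controls only itself and contributes $c = 1/N$ through the
matching itself.

## 6. Perturbation propagation

A perturbation $\Delta m_i$ applied at node $i$ reaches node $j$
through chains of links; with signed coefficient matrix $B$ restricted
to the surviving (thresholded) links, the effective coefficient is the
truncated walk sum

$$\beta^{\mathrm{eff}}_{ji} = \sum_{\ell=1}^{\ell_{\max}} (B^\ell)_{ji},$$

computed by repeated sparse matrix–vector products (never dense
powers). Decisions:

* **Walks, not simple paths.** The nested sums carry no index
  -distinctness constraint, so revisiting nodes is allowed and the
  diagonal term (walks returning to $i$) feeds back into $i$'s own
  coordinate. A simple-path mode exists for sensitivity analysis; on a
  DAG the two coincide, and the tests compare them.
* **Signs are retained through thresholding** (the threshold acts on
  $|\beta|$ only), so propagated contributions can cancel.
* $\ell_{\max} = 4$ by default; $\ell_{\max} = 0$ reproduces the
  isolated-CpG sensitivity $(a_t+1)H_i$ exactly, and truncation is
  consistent: the derivative at $\ell_{\max}$ equals the derivative at
  $\ell_{\max}-1$ plus exactly the order-$\ell_{\max}$ walk term.
* The perturbation size defaults to $2\langle\sigma(m)\rangle$ — twice
  the mean (sample-convention, $n-1$) per-CpG standard deviation across
  the cohort — so the probe is of the order of the variation actually
  present. Perturbed levels are *not* clipped to $[0,1]$: the model is
  a local linear response, and clipping would silently break its
  linearity.

Displacement geometry (`displacement_geometry()`, `project_cloud()`)
embeds samples in methylation space (one axis per CpG): the component
of $m(q)$ along $H$ determines the linear-branch age estimate exactly
($a = (a_t+1)\lVert H\rVert\,\mathrm{along} + a_t$, asserted in the
tests), and the angle between a perturbation's displacement vector and
$H$ measures how well the induced change aligns with the ageing
direction. A zero displacement has no angle and is flagged rather than
returned as NaN from a division.

## 7. The synthetic cohort generator

`generate_cohort()` produces the structure the analysis assumes: a
planted sparse coefficient network, age-dependent drift and Gaussian
noise, solved as
$m_k = \mu_k + s_k\,\mathrm{age} + \sum_i B_{ki} m_i + \varepsilon_k$.
Choices, each made once:

* **Acyclic planted topology** (links only from earlier to later CpGs
  in a fixed order): guarantees a well-defined solve order and finite
  walk sums, so the perturbation ground-truth comparison has a closed
  form. Link probability is set so the expected link count equals
  `edge_density` times $N(N-1)$.
* **Coefficient scale 1** (entries $\pm[0.5, 1.5]$): order-1 couplings,
  the regime in which a weight threshold of a few tenths is meaningful
  — mirroring real inferred networks whose efficiency-optimal
  thresholds land there.
* **Age slopes $\pm[5\times10^{-4}, 2\times10^{-3}]$ per year**:
  realistic adult methylation drift (a few hundredths to ~0.16 beta
  over an 80-year span). Ages are uniform on $(21, 101)$ — an adult
  cohort spanning the same range as large blood-methylation studies,
  with the lower bound above $a_t$ so the synthetic clock fit stays in
  the linear branch. Noise is $\sigma = 0.02$ per observation.
* **Affine rescaling into $[0.05, 0.95]$**, never clipping: keeps
  levels valid beta values while preserving exact linearity, and the
  planted network is re-expressed in the rescaled coordinates
  ($B'_{ki} = b_k B_{ki}/b_i$) so it remains the literal truth for the
  data handed to inference.
* The synthetic clock (`fit_synthetic_clock()`) solves the linear
  branch by minimum-norm least squares via SVD, truncating negligible
  singular values; this keeps exactly-solvable (rank-deficient,
  noiseless) designs exact instead of ridge-biased, and a constant
  matrix triggers an explicit rank-deficiency warning.

What the generator does **not** emulate: array technical artefacts
(detection p-values, dye bias, batch effects), non-uniform age
distributions (a mixture option would be a natural extension),
cyclic feedback (available behind the DAG default only as future
work), and the unknown dependence structure of real methylomes beyond
the linear model class. Passing tests therefore demonstrate
correctness of the algorithms under the linear structural model, not
that real methylation networks satisfy that model.

## 8. Problem sizes and reproducibility

The test suite validates the graph statistics against independent
brute-force oracles — boolean-matrix-power reachability ($N \le 8$,
hundreds of random digraphs), exhaustive matching enumeration
($N \le 6$), explicit walk enumeration ($\ell_{\max} \le 4$) — and the
inference against planted truths on cohorts of 30 CpGs × 600 samples
over 20 seeds, sizes at which each check completes in seconds to a
couple of minutes on one core while still exercising every code path.
`scripts/acceptance.R` re-runs the pipeline at the same scale. Every
random decision (cohort draw, CV folds, null ensemble, threshold
sweep, replicate sampling) descends from a single integer seed through
a fixed stream-splitting rule, so any reported number is reproducible
bit-for-bit from the manifest alone.

## 9. Known limitations

* Lasso link direction is nominal: $i \to j$ records "$i$ predicts
  $j$", not causal flow (Section 2); downstream hierarchy and control
  statistics inherit this interpretation.
* The efficiency criterion assumes a single meaningful threshold; flat
  or multi-modal $J$ curves are reported as scanned but only the argmax
  is selected.
* Walk-sum propagation can diverge on cyclic networks with large
  coefficients as $\ell_{\max}$ grows; the truncation is the model,
  and no convergence claim is made beyond it.
* The control sweep band and the weight threshold live on the same
  scale as the regression coefficients; cohorts measured on other
  scales need both adjusted together.
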