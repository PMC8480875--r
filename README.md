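# methylnet

Hierarchy, control and perturbation analysis of epigenetic-clock
methylation networks.

## What this package is for

Linear epigenetic clocks estimate the age of a DNA sample from the
methylation levels (beta values) of a panel of CpG dinucleotides.
Because ageing drives *coordinated* changes across the methylome, the
clock CpGs are not independent dials: shifting the methylation of one
site is expected to cascade into others. `methylnet` treats the clock
CpGs as an interacting system. It is aimed at computational biologists
who want to ask, for a given clock panel and cohort:

* which CpGs sit at the top of the inter-CpG influence network,
* which single CpG, used as a driver, could structurally control the
  largest part of the panel, and
* where a single methylation perturbation would move the
  clock-estimated age the most once its propagation over the network is
  accounted for.

## The model

**Clock.** For a methylation profile *m* and clock coefficients *H*
with adult threshold *a*<sub>t</sub>, the estimated age is

> a = (a<sub>t</sub> + 1) Σ<sub>i</sub> H<sub>i</sub> m<sub>i</sub> + a<sub>t</sub>  if Σ H<sub>i</sub> m<sub>i</sub> ≥ 0,
> a = exp(Σ H<sub>i</sub> m<sub>i</sub> + ln(a<sub>t</sub> + 1)) − 1  otherwise.

**Network inference.** Each CpG *j* is regressed on all other CpGs with
cross-validated Lasso, m<sub>j</sub> = Σ<sub>i≠j</sub> β<sub>ji</sub> m<sub>i</sub> + β<sub>0</sub>;
a directed link *i* → *j* with weight w<sub>ij</sub> = |β<sub>ji</sub>| is kept
wherever β<sub>ji</sub> ≠ 0. The dense graph is sparsified at the weight
threshold *w\** maximising the efficiency quality
J = (E<sub>g</sub> + E<sub>l</sub>) / ρ<sub>L</sub>
(global plus local efficiency over link density).

**Hierarchy.** The *m*-reach r<sub>m</sub>(i) is the fraction of other
nodes reachable from *i* in at most *m* directed steps; the Global
Reaching Centrality GRC(m) = Σ<sub>i</sub> [r<sub>m,max</sub> − r<sub>m</sub>(i)] / (N − 1)
is compared against a degree-preserving link-swap null ensemble.

**Control.** The control centrality C(i) is the maximum number of nodes
drivable by one external signal at *i*: a maximum bipartite matching on
the subgraph reachable from *i* with an auxiliary source link s → i.
Averaging c(i) = C(i)/N over a sweep of weight thresholds gives a finer
ranking than any single network.

**Perturbation.** A shift Δm<sub>i</sub> = 2⟨σ(m)⟩ applied at one CpG
propagates along walks of length ≤ ℓ<sub>max</sub>; the induced age
change is Δa = (a<sub>t</sub>+1)[H<sub>i</sub> + Σ<sub>j</sub> H<sub>j</sub> β<sup>eff</sup><sub>ji</sub>] Δm<sub>i</sub>
with β<sup>eff</sup> the truncated walk sum of the signed coefficient
matrix.

A synthetic-cohort generator with a planted sparse acyclic coefficient
network, age-dependent mean drift and Gaussian noise makes every stage
testable against known truth.

## Worked example

```r
library(methylnet)

cohort <- generate_cohort(n_cpgs = 20, n_samples = 300, seed = 42)
net    <- build_network(cohort$matrix, n_folds = 10, seed = 1)
scan   <- scan_thresholds(net)
pruned <- threshold_network(net, scan$w_star)
hier   <- hierarchy_analysis(pruned, m = 3, null_samples = 500, seed = 1)
ctrl   <- sweep_averaged_control(net, w_lo = 0.3, w_hi = 0.7)
pert   <- perturb_all(pruned, cohort$clock, cohort$matrix, l_max = 4)
rank   <- ranking_table(setNames(pert$delta_a_abs, pert$cpg_id),
                        hier$reach, ctrl$averaged, k = 5)
```

which prints (abridged):

```
> print(scan)
threshold_scan: 200 candidates, optimum w* = 0.505386 (J = 4.95)
> print(pruned)
signed_network: 20 nodes, 30 links (threshold w* = 0.505386), mean total degree 3.00
> print(hier)
hierarchy_result: m = 3, GRC = 0.7036, 8 levels over 20 nodes
grc_null (m = 3): observed 0.7036 vs null 0.5532 +/- 0.0691 (z = 2.17, p = 0.002)
> print(rank)
ranking_table: top-5 lists; overlap counts:
            delta_a_abs reach c_avg
delta_a_abs           5     2     1
reach                 2     5     4
c_avg                 1     4     5
```

Reading: the efficiency scan keeps the ~30 strongest of 262 inferred
links; the pruned network is more hierarchical than its
degree-preserving null (z ≈ 2.2); the top-5 lists by m-reach and by
sweep-averaged control centrality share 4 of 5 CpGs (their Pearson
correlation here is 0.94), while the largest attainable age shifts
concentrate on partially different nodes — the same qualitative picture
the per-node tables in `rank$table` let you explore. Note the control
sweep band is expressed on the scale of the link weights; the default
`[0.04, 0.1]` band is appropriate only when weights extend that low.

Real cohorts enter the same pipeline through `read_beta_matrix()`
(plain TSV/CSV or GEO series-matrix layout, plus a `sample_id`/`age`
metadata table) and `read_clock()`, or in one call through
`run_full()`, which writes every stage table, a summary JSON and a
reproducibility manifest to an output directory.

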