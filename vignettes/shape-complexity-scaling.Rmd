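---
title: "Shape-complexity scaling factors for distance-based clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-complexity scaling factors for distance-based clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapescale)
```

## The problem

Distance-based clustering methods — k-means above all — are only as good as
the geometry they are handed. The near-universal preprocessing habit is to
divide each dimension by its standard deviation $\sigma_k$, which equalizes
marginal spreads but is blind to cluster structure: a dimension whose large
variance *is* the cluster signal gets shrunk, and a high-variance dimension
that carries no signal at all ends up with the same weight as every other.
This package determines candidate per-dimension scaling factors $\alpha_k$,
applied *on top of* the division by $\sigma_k$ (each entry $X_{ik}$ becomes
$(\alpha_k/\sigma_k) X_{ik}$), so that $\alpha_k \equiv 1$ recovers the
standard recipe and departures from 1 express how the standard recipe
should be amended.

## Shape complexity

Write $\rho_{ijk} = (X_{ik}-X_{jk})/\sigma_k$ for the standardized
difference of samples $i$ and $j$ along dimension $k$, and
$r_{ij}^2 = \sum_k \alpha_k^2\rho_{ijk}^2$ for their scaled distance. The
*shape complexity* of the configuration is

$$
SC \;=\; \underbrace{\Big(\sum_{i<j} r_{ij}^2\Big)^{1/2}}_{g}\;
         \underbrace{\sum_{i<j} r_{ij}^{-1}}_{h} ,
$$

summing over all unordered pairs of *distinct* samples. Increasing any one
distance always increases $g$ and decreases $h$, but not evenly: since
$\partial g/\partial r_{ij}=g^{-1}r_{ij}$, the largest distances dominate
$g$'s response, while $\partial h/\partial r_{ij}=-r_{ij}^{-2}$ makes the
smallest distances dominate $h$'s. If one accepts the (idealized) reading
that large distances are inter-cluster and small ones intra-cluster, then a
scaling factor whose increase grows $g$ relatively faster than it shrinks
$h$ is stretching the cluster gaps, and one with the opposite effect is
inflating the clusters themselves. The balanced regime
$g_k'/g = -h_k'/h$ for every $k$ targets the *midrange* distances — the
ones most easily mistaken between the two roles — and finding it is a
stationarity problem for $SC$.

Two structural facts drive everything else:

* **Radial invariance.** $SC(t\alpha) = SC(\alpha)$ for every $t>0$;
  equivalently $\sum_k \alpha_k SC_k' = 0$ everywhere. Only the
  *direction* of $\alpha$ matters for clustering, since all distances
  scale together along a ray.
* **Pair-sum identity.** With $\sigma_k$ computed over all
  $n_{orig}$ samples (denominator $n_{orig}-1$) and
  $N = n_{orig}(n_{orig}-1)$, each dimension satisfies
  $\sum_{i<j}\rho_{ijk}^2 = N$, so $g = (N\sum_k\alpha_k^2)^{1/2}$ in
  closed form on duplicate-free data.

Both facts are verified to tight tolerances in the test suite (1e-9 and
1e-10 relative, respectively), alongside a finite-difference check of the
analytic gradient.

### Duplicates and $\sigma_k$

$h$ diverges on coincident samples, so exact duplicate rows are set aside
before any pairwise quantity is formed ([sc_data()] records the
duplicate-free index). The standard deviations, however, keep using *all*
rows: that is what makes the pair-sum identity hold with
$N = n_{orig}(n_{orig}-1)$, and it also keeps $\sigma_k$ an honest property
of the full sample. Whether $\sigma_k$ ought instead to be recomputed after
duplicate removal is genuinely undecidable from the available descriptions;
we chose the full-sample convention because the identity above forces it,
and we verified that the Iris scaling factors it produces match the
published ones to three decimals. The practical consequence: the identity
(and the closed form for $g$) is exact only when the data are
duplicate-free, and the tests that assert it use duplicate-free fixtures.
Clustering and evaluation always use all rows — only $SC$ and its
optimization live on the unique ones.

## The optimization problem

Radial invariance makes whole rays equivalent, so attention is restricted
to the sphere $\sum_k\alpha_k^2 = d$, which contains the all-ones point
(plain $1/\sigma_k$ scaling). Imposing first-order stationarity of $SC$ on
the sphere and using the pair-sum identity collapses to an orthogonality
condition between the vector of $r_{ij}^{-3}$ and the difference of any
two $\rho^2$-columns; with the dimension pair fixed to $(1,2)$ this gives
the nonlinear program solved here ("Problem P"):

$$
\min_\alpha\;\Big(\sum_{i<j} r_{ij}^{-3} N^{-1}
   (\rho_{ij1}^2-\rho_{ij2}^2)\Big)^2
\quad\text{s.t.}\quad \sum_k\alpha_k^2 = d,\;\; \alpha_k \ge 10^{-5}.
$$

The stationarity argument requires the condition for *every* dimension
pair, and the package exposes an `objective_variant = "all_pairs"` that
sums the squared residual over all $k<\ell$; the default remains the
$(1,2)$ pair for fidelity to the published formulation. The positivity
constraint is relaxed to $\alpha_k \ge 10^{-5}$ exactly as published, which
doubles as a division-by-zero guard. The constant $N^{-1}$ does not move
the argmin and is kept for numerical-scale fidelity.

### How the solver works

No equality-constrained NLP solver ships with base R, and none is assumed
here. Instead the sphere constraint is eliminated *exactly*: parameterize
$\alpha(\beta) = \sqrt d\,\beta/\lVert\beta\rVert$ and minimize the
composed objective over the box $\beta_k \ge 10^{-5}$ with L-BFGS-B
(`stats::optim`). The composed objective is scale-free in $\beta$, every
iterate maps to a point satisfying the sphere constraint to machine
precision, and the box keeps the projection well-defined. Feasibility of
the reported $\alpha$ (sphere residual $\le$ 1e-6, bounds respected) is
re-checked before a trial is declared converged. The objective gradient is
finite-differenced by default — mirroring the published protocol — with an
optional exact chain-rule gradient (`gradient = "analytic"`) that reaches
the same optima about three times faster.

The alternative program — maximize $SC$ subject only to
$\alpha_k \ge 10^{-5}$ — is solved in $\theta = \log\alpha$, where the box
bound maps exactly to $\theta_k \ge \log 10^{-5}$ and the scale-free
geometry of $SC$ is far better conditioned. Because $SC$ depends only on
the direction of $\alpha$, maximizing solutions are meaningful up to a
common factor, and components are routinely driven to the lower bound
(dimensions switched off) while others grow very large. Reported solutions
satisfy the first-order condition at interior coordinates (checked in the
tests via the scaled gradient $\alpha_k SC_k'$).

### The trial protocol

Local solvers find local solutions, so the fitting function [sc_fit()]
follows the published multi-start protocol: by default 1000 independent
trials, each started uniformly at random in $[0.5, 1.5]^d$ (Problem P) or
$[10^{-5}, 1]^d$ (max-SC), with an iteration cap of 5000; trials that do
not converge within the cap are retained but flagged, and consumers
discard them (observed discard fractions are well under 1%). Per-trial
seeds are derived from the master seed up front, so the sequence is
reproducible and order-independent. Each converged trial is a *candidate*
scaling scheme; sifting the candidates — by a reference partition when one
exists ([trial_sweep()]), or by inspecting what they do to the data and
its distance histogram ([distance_histogram()]) when not — is part of the
method, not an afterthought. Stopping tolerances (`factr = 1e7`,
`pgtol = 0`, sphere residual 1e-6) are deliberately ordinary L-BFGS-B
settings, overridable through [sc_control()]; only first-order conditions
are addressed, as in the source formulation — no second-order check is
attempted.

## Evaluating partitions

Two chance-corrected external indices score an obtained partition against
a reference.

**ARI_fnc.** k-means output always has exactly $C$ non-empty clusters, so
the right null model for a Rand-type correction is the uniform
distribution over partitions into *exactly $C$* blocks — not the
fixed-marginals permutation null of the classical adjusted Rand index.
Writing $RI = \binom{n}{2}^{-1}(TS+TD)$,

$$
ARI_{fnc} = \frac{RI - E_{fnc}[RI]}{1 - E_{fnc}[RI]},
\qquad
E_{fnc}[RI] = UV + (1-U)(1-V),
$$

with $U = {n-1\brace C}\big/{n\brace C}$ the probability that a fixed pair
is co-clustered under that null, and $V$ the fraction of pairs
co-clustered in the reference. The Stirling numbers are computed with
exact big-integer arithmetic (base-$10^7$ digit vectors; only addition and
small-integer multiplication are needed by the recurrence), and $U$ is
formed from high-precision logarithms of the exact digit vectors, so no
floating overflow occurs even for thousands of samples. The test suite
checks $E_{fnc}[RI]$ against the enumerated mean of $RI$ over all
$C$-block partitions for small $n$, which is the definitional oracle.

**AMI_max.** Mutual information between the partitions, corrected by its
expectation under the fixed-marginals permutation model and normalized by
$\max\{H(R), H(O)\}$. The expectation uses the standard exact
hypergeometric cell-wise sum (log-factorials via `lgamma`), checked
against exhaustive permutation enumeration at small $n$. A correction
under the same fixed-$C$ null as ARI_fnc would be conceptually preferable,
but no such generalization is available; the permutation-model expectation
is the accepted stand-in. Entropies use natural logarithms internally —
immaterial, since the ratio cancels the base. Empirically the two indices
rank partitions almost identically (rank correlation > 0.9 across sweeps),
so conclusions do not hinge on the choice.

## Clustering engine

Clustering is delegated to `stats::kmeans` (Hartigan–Wong) behind
[cluster_kmeans()], which adds the two guarantees the evaluation layer
needs: exactly $C$ non-empty clusters (up to 10 re-draws on an empty
cluster, then an error — rare in practice) and determinism under a caller
seed without disturbing the ambient RNG stream. The default of 20 random
restarts stabilizes the within-SS optimum, which makes the benchmark index
values reproducible without reference to any particular RNG stream.

One caveat the Iris benchmark exposes: the published max-SC worked example
(scaling by the printed $\alpha$ with $\alpha_1=\alpha_2=10^{-5}$,
$\alpha_3 \approx 5.09\times10^{17}$, $\alpha_4 \approx 2.48\times10^{17}$,
then $ARI_{fnc} = 0.922$) sits on a k-means solution that is *not* the
within-SS optimum. A single Hartigan–Wong start from seed 1234 — the
published protocol, reproduced verbatim in the acceptance test — lands on
the 0.922 partition, while restart-stabilized runs find a slightly lower
within-SS optimum that scores 0.886. Both partitions are legitimate
k-means output; the discrepancy is a useful reminder that index values
attached to k-means runs carry the optimizer's local-minimum lottery with
them. The package default (20 restarts) reports the stabilized value.

## The synthetic generator

[make_mixture()] emulates the data regime the method is about:
axis-aligned Gaussian clusters with stated means and per-dimension scales,
optional *pure-noise dimensions* (no cluster signal, large scale — the
canonical way variance-based scaling gets misled), and optional exact
duplicate rows to exercise the deduplication path. The package's core
scientific self-test draws three unit-scale clusters at centres $(0,0)$,
$(3,0)$, $(0,3)$ — moderate overlap, the midrange-distance regime —
with one signal-free dimension of scale 100, and checks across 20
generator seeds that the best sweep trial matches or beats $1/\sigma$
scaling in at least 90% of them (strict improvement in the large
majority). At wider separations the property still holds but degenerates
into ties at $ARI_{fnc}=1$, which tests nothing; hence the overlapping
default for this check.

What the generator does *not* emulate: correlated dimensions, non-Gaussian
cluster shapes, heavy tails, and the measurement idiosyncrasies of the
real benchmark tables. A green synthetic sweep therefore establishes that
the machinery behaves as designed under the stated model, not that any
particular real dataset will enjoy the same improvement.

## Benchmark preprocessing

* [corrected_iris()] returns the 150 x 4 Iris table with the two
  published corrections (sample 35 ends 0.2; sample 38 reads 4.9, 3.6,
  1.4, 0.1). R's built-in copy already carries both, and is verified
  rather than edited; a raw UCI-style matrix is corrected in place. The
  corrected table has one duplicated row, hence 149 unique samples.
* [dr3_reduce()] is centered, *unscaled* PCA keeping the first three
  component scores, with a fixed sign convention (largest-magnitude
  loading positive) so results are independent of eigensolver sign
  choices and row order. The retained-variance fraction travels as an
  attribute.
* [truncate_means_10()] keeps the ten mean-value columns of the
  30-dimension diagnostic breast-cancer layout.
* [simple_impute()] is plain column-mean imputation, a deliberately
  simple, documented substitute for the proprietary model-based synthesis
  used upstream of the original benchmarks; it adds a deterministic 1e-9
  jitter (with a logged message) if imputation would fabricate a
  duplicate row. Because imputed values differ from the originals,
  benchmark figures that depend on imputed data are treated as
  qualitative context only, and no acceptance check relies on them.
* Deduplication happens *after* all other preprocessing, on the matrix
  actually fed to the optimizer — the ordering is unstated in the source
  material, and this choice keeps "duplicate" meaning "identical input to
  SC".

## Numerical choices, in one place

| Quantity | Value | Why |
|---|---|---|
| $\alpha$ lower bound | $10^{-5}$ | published relaxation of $\alpha_k>0$; guards $r^{-1}$, $r^{-3}$ |
| sphere residual accepted | 1e-6 | feasibility of converged trials |
| iteration cap | 5000 | published trial protocol |
| init boxes | $[0.5,1.5]^d$ / $[10^{-5},1]^d$ | published trial protocol (Problem P / max-SC) |
| identity tolerances | 1e-9 / 1e-10 rel. | radial invariance / pair-sum and closed-form $g$ |
| gradient check | 1e-5 rel., step 1e-6 | central differences vs analytic |
| k-means restarts | 20 | stabilize the within-SS optimum |
| imputation jitter | multiples of 1e-9 | break fabricated duplicates, deterministically |

## Limitations

Memory and time are $O(n^2 d)$ in the number of unique samples — the pair
table is dense — which is the practical ceiling of the approach; nothing
here subsamples or approximates $SC$. All solutions are local and
first-order only. The method is a candidate generator, not a blind
procedure: on some datasets the sweep's consensus is excellent, on others
(Iris included) the histogram of index values peaks well below the best
achievable trial, and only outside knowledge — or a reference partition —
separates the two situations.

## A short session

```{r, eval = FALSE}
library(shapescale)

ir <- corrected_iris()
fit <- sc_fit(ir$x, n_trials = 1000, seed = 11)
summary(fit)

sw <- trial_sweep(ir$x, ir$labels, C = 3, n_trials = 1000, seed = 11)
sw          # ARI_fnc in [0.548, 0.886] on this seed
plot(sw)    # solution cloud and ARI_fnc histogram
```
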