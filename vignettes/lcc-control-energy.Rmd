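---
title: "Control energy and the longest control chain in structural brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Control energy and the longest control chain in structural brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(lccontrol)
```

## The model

`lccontrol` analyses directed binary networks under linear dynamics
$\dot{\mathbf{x}} = \mathbf{A}\mathbf{x} + \mathbf{B}\mathbf{u}$, where
$\mathbf{A}$ is the structural adjacency matrix (entry $(j, i) = 1$ iff the
link $i \to j$ exists) and $\mathbf{B}$ couples one independent control
signal to each input node. The intended application is structural brain
connectomes: undirected weighted matrices from diffusion tractography,
binarized (`binarize()`) and expanded into bidirectional link pairs
(`bidirect()`). Three quantities organize everything else:

* **Minimum driver count.** A maximum matching of the split-node bipartite
  graph leaves $N_u$ in-copies unmatched; $N_i = \max(1, N_u)$ independent
  signals are necessary and sufficient for structural controllability.
  $N_u$ is invariant across maximum matchings even though the unmatched
  *sets* are not — `enumerate_unmatched_sets()` makes that concrete on
  small graphs.
* **Control energy.** The finite-horizon controllability Gramian
  $\mathbf{W}_B(t_f) = \int_0^{t_f} e^{\mathbf{A}\tau} \mathbf{B}
  \mathbf{B}^T e^{\mathbf{A}^T\tau} d\tau$ is positive definite iff the
  system is controllable, and $\varepsilon(t_f) =
  \mathrm{Trace}(\mathbf{W}_B(t_f))$ is the energy proxy: larger trace,
  less average energy to move through state space. The trace is preferred
  over $\mathrm{Trace}(\mathbf{W}^{-1})$ because the two obey the
  inverse-proportionality bound $\mathrm{Trace}(\mathbf{W}^{-1}) >
  N^2/\mathrm{Trace}(\mathbf{W})$ (`trace_inverse_check()`) while the
  inverse is numerically hopeless on ill-conditioned Gramians. All
  reporting is in $\log_{10}\varepsilon(t_f)$, unnormalized.
* **Longest control chain.** $\mathrm{LCC} = \max_{w} \min_{v \in S}
  d(v, w)$, the worst directed distance from the input set to any node.
  Distances run *from* inputs *toward* controlled nodes; on bidirectional
  connectomes the direction is invisible, but it matters for general
  digraphs and is fixed here once.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `t_f` | 1 | control horizon of the Gramian (dimensionless time) |
| `r_const` in `properties()` | 1 | normalization of degree heterogeneity $H$ |
| `l` (placement) | — | target LCC, in hops |
| `epsilon` (rewiring) | 1e-6 | residual chance a link is never proposed |
| `n_replicates` | 20 | null-model replicates per network |
| `hub_quantile` | 0.1 | top degree fraction treated as hubs |

Two of these deserve comment.

**Heterogeneity.** $H = \max(H^{in}, H^{out})$ with $H^{in/out} =
\frac{1}{rN^2}\sum_i\sum_j |k_i - k_j|$. Without the absolute value the
double sum is identically zero, so the absolute-difference form — the
standard mean pairwise degree gap — is the only meaningful reading. The
constant $r$ is genuinely free; we default to $r = 1$ (raw mean absolute
gap, in links) and expose it because $r = c$ (the mean degree) gives the
dimensionless variant of order 0.5–0.7 on 90-region connectomes, which is
the scale usually quoted for such data.

**Link counting.** `properties()` reports the *directed* link count
`n_links` and, for symmetric networks, the undirected count `n_links / 2`.
The mean degree is `n_links / N` (equal to the mean undirected degree on
bidirectionalized networks). Connectome summary tables are often ambiguous
on this point; reporting both removes the ambiguity.

## Numerical choices

* **Gramian evaluation** uses the Van Loan block-exponential: the matrix
  exponential of $t_f\begin{pmatrix}-\mathbf{A} &
  \mathbf{B}\mathbf{B}^T\\ 0 & \mathbf{A}^T\end{pmatrix}$ contains the
  integral exactly up to `expm` accuracy. The integral has a finite horizon
  and $\mathbf{A}$ is typically unstable (nonnegative adjacency), so
  Lyapunov solvers do not apply. The result is symmetrized; tests
  cross-check against composite-Simpson quadrature of the defining
  integral at relative error below $10^{-8}$.
* **Per-node energies** exploit additivity of the trace over input
  columns: all $n$ single-input energies are the diagonal of
  $\int_0^{t_f} e^{\mathbf{A}^T\tau}e^{\mathbf{A}\tau} d\tau$, one
  $2n \times 2n$ exponential instead of $n$.
* **Controllability verdicts.** The Gramian test ($\lambda_{\min} >$ tol,
  default $n\,\epsilon_{mach}\,\lambda_{\max}$) is meaningful only for
  small, well-conditioned systems: at $n = 90$ with a sparse input set the
  true $\lambda_{\min}$ sits far below machine noise. For anything
  structural we therefore rely on the exact graph-theoretic test
  (`structurally_controllable_graph()`): input-accessibility plus generic
  rank of $[\mathbf{A}\ \mathbf{B}]$ via bipartite matching — integer
  arithmetic, no tolerance. The Kalman rank is reported as a diagnostic
  for $n \le 50$.
* **Matching determinism.** Augmenting-path search scans out-copies and
  neighbors in ascending label order, so results are reproducible without
  any RNG; alternative unmatched sets are enumerated exhaustively (small
  graphs only, with an explicit link-count guard).
* **Ties and degeneracies.** Greedy placement breaks coverage ties by
  higher degree then lower label; hub orderings break degree ties by
  ascending label; $\ell = 0$ returns the full node set with a warning;
  unreachable nodes yield an infinite LCC rather than an error, which the
  placement search treats as plain infeasibility. Mean distances average
  over ordered pairs with finite distance only. Fully tied strata in the
  rank-sum test return the null-mean statistic with $p = 1$ rather than a
  0/0.

## Design choices that were genuinely open

**Placement solves the cover problem.** Reaching LCC $\le \ell$ is exactly
the minimum distance-$\ell$ dominating-set problem, and that is what
`min_inputs_for_lcc()` minimizes (exact subset enumeration up to 15 nodes,
greedy max-coverage beyond). Whether the chosen set also makes
$(\mathbf{A}, \mathbf{B})$ structurally controllable is logically separate:
on symmetric connectomes, whose matchings are perfect, every nonempty cover
is controllable, but a digraph cover can leave a dilation (for instance, a
bidirected star's center covers everything at $\ell = 1$ yet cannot control
its leaves alone). We report the verdict in the `controllable` field and
offer `ensure_controllability = TRUE` — exact mode then enumerates only
controllable covers; greedy mode augments the cover with unmatched
in-copies. The default stays with the pure cover, which is the
combinatorial object the LCC theory is about.

**Rewiring trials count attempts.** The null-model budget
$\lceil(|E|/2)\ln(1/\epsilon)\rceil$ is a coupon-collector argument on
*proposals*; rejected proposals (self-loops, duplicate links) therefore
consume budget. Symmetric networks are rewired on undirected edges with
both directions written, otherwise randomization would destroy the
bidirectionality the networks have by construction. Rich-club destruction
swaps a hub–hub with a low–low link into two hub–low links; "hub" means
the top 10% of nodes by degree, an explicit (and exposed) choice since no
canonical threshold exists.

**Motifs are induced.** id78 (mutual open path) and id238 (mutual
triangle) are counted as induced 3-node subgraphs via closed forms on the
mutual-dyad graph — id238 $= T$, id78 $= \sum_v \binom{k_v}{2} - 3T$ —
with exhaustive triple enumeration as the test oracle. Non-mutual
connected triples in asymmetric digraphs are tallied separately (`other`)
and excluded from $M$, which is defined on bidirectional networks.

## What the synthetic generator does and does not emulate

`generate_brain_like()` targets the summary statistics of 90-region AAL
connectomes: ~1150 directed links (mean degree ≈ 12.8), a right-skewed
(lognormal, `sdlog = 0.5`) degree sequence giving a mean absolute pairwise
degree gap around 0.5–0.7 of the mean degree, mean inter-node distance
around 2, a small number of isolated regions (default 1), and a rich club —
hub–hub density raised to 0.8 by degree-preserving swaps, so hubs are
mutually adjacent the way connectome hubs are. The degree sequence is
sampled to match the (min, max, mean) envelope rather than a parametric
power law, because connectome degree distributions at this resolution are
characterized only by those summaries; the rich club is produced by
targeted hub-ward swaps after a Viger–Latapy connected configuration-model
draw, with connectivity-breaking swaps rejected. Generators are pure
functions of their seed.

Not emulated: spatial embedding (fiber length, hemispheric symmetry),
link weights, community structure beyond what the rich club induces, and
subject-level individual differences. Passing tests on this ensemble
therefore show that the *pipeline* behaves as the theory predicts on
networks with connectome-scale density, heterogeneity and hub structure —
not that any particular subject's connectome would give identical numbers.
Synthetic single-input LCCs concentrate on 2–4 (real connectomes, with
their degree-1 periphery, sit at 3–5); the energy–LCC relation is the same.

## Problem sizes

The shipped tests run exact-versus-brute-force comparisons on a few
hundred random graphs of 4–15 nodes, Gramian cross-checks on 6-node
systems, and ensemble checks on seven 90-node synthetic connectomes with
20-replicate null models; the acceptance script uses the same sizes. These
are the sizes at which the exhaustive oracles are exact and the full
pipeline still runs in minutes; nothing in the implementation caps network
size below the matrix-exponential's practical range (a few hundred nodes).

## Known limitations

* Exact placement is exponential and deliberately guarded at 15 nodes;
  beyond that only the greedy bound (worst case $\ln n$ times optimal) is
  available.
* The Gramian overflows for large $t_f$ or spectral radius (the error
  message suggests rescaling); energies are only comparable at a common
  $t_f$.
* `enumerate_unmatched_sets()` is exhaustive and limited to ~30 links.
* The rank-sum strata test needs at least two strata with two members
  each; single-stratum scans (possible on very regular networks) raise an
  informative error.
* Null-model and census randomization are seeded R RNG; reproducibility
  is per-seed, not across R RNG-kind changes.
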