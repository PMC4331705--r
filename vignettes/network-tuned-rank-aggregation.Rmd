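---
title: "Network-tuned aggregation of gene rank lists: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-tuned aggregation of gene rank lists: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netaggr)
```

## The problem

Modern genomics experiments rarely yield a single answer. The same question
— which genes respond to a perturbation, which genes are targets of a
transcription factor — is asked across replicate studies, platforms and
analysis pipelines, and each study returns a *rank list* of genes. Rank
aggregation combines `m` such lists over a common universe of `n` genes
into one prioritized list. Classic aggregators treat genes independently,
yet genes that interact in a molecular network tend to share function and
therefore tend to deserve similar ranks. `netaggr` implements rank
aggregation that borrows strength across a protein–protein interaction
network: each list is first *smoothed* over the network, and the smoothed
lists are then aggregated.

## From ranks to normal scores

Each integer rank `r[i, j]` (gene `i`, list `j`) becomes a rank ratio
`ra[i, j] = r[i, j] / n` in `(0, 1]`, and then a normal score

```
z[i, j] = -qnorm(ra[i, j]),
```

the negated standard-normal quantile, so that a full permutation column is
approximately standard normal and top-ranked genes carry the largest
scores. The ratio `1` of the worst-ranked gene would map to `-Inf`; it is
replaced by `ratio_cap = 0.9999` first. We apply the cap to *any* ratio at
or above the threshold, not only to exact ones: for universes larger than
10,000 genes the ratio `(n - 1)/n` itself exceeds `0.9999`, and capping the
whole upper tail preserves monotonicity instead of inverting the two worst
genes.

## Network smoothing

Two updates are available, both leaving the scores unchanged in their
no-network limits so plain aggregation is an exact special case.

**Diffusion-kernel averaging (CGI).** Node similarity is the diffusion
kernel `S = expm(-tau * L)`, with `L = D - H` the graph Laplacian, cosine
normalized to `K[u, v] = S[u, v] / sqrt(S[u, u] S[v, v])`. `S` is a
stochastic matrix (unit row sums, nonnegative entries) and `K` is symmetric
positive semidefinite with unit diagonal and entries in `[0, 1]`. The
update is the kernel-weighted average

```
R[i, j] = (z[i, j] + lambda * sum_{l != i} |z[l, j]| * K[l, i]) /
          (1      + lambda * sum_{l != i}            K[l, i]).
```

Neighbors contribute through the *absolute value* of their score while the
focal gene keeps its sign. We implement this literally; it has the
side-effect that strongly bottom-ranked neighbors (very negative `z`) also
pull a gene up. Whether that is intended or a carry-over from the
expression-based origin of the formula (where scores are nonnegative
association strengths) is debatable, so `cgi_update()` exposes
`neighbor_abs = FALSE` as a documented alternative while keeping the
literal form as the default.

**PageRank-style propagation (GeneRank).** The tuned scores solve

```
(I - d * H %*% solve(D)) %*% R[, j] = (1 - d) * z[, j],
```

with damping `d` in `[0, 1)`. Columns of `H D^{-1}` at zero-degree genes
are set to zero — the only finite, continuous extension — so isolated genes
retain `(1 - d)` of their own score. The iterative solver starts from
`z[, j]` and stops when the max absolute update drops below `tol = 1e-6`
or after `max_iter = 1000` sweeps; because `d < 1` makes the iteration a
contraction, the fixed point does not depend on the start, and we therefore
ignore the L1 normalization sometimes applied to the starting vector — only
the limit is used for ranking. A direct linear solve is available and the
two must agree to within `10 * tol` (this is asserted in the test suite).

## Aggregation statistics

Both statistics act on each gene's ascending-sorted ratio vector, so they
are invariant to the order of the input lists. Smaller values are better.

**Endeavour order statistic.** `Q(r)` is the joint probability that the
order statistics of `m` independent uniforms fall below the observed sorted
ratios, computed by the alternating recursion
`V_k = sum_l (-1)^(l-1) V_{k-l} / l! * r[m-k+1]^l`, `Q = m! V_m`. The
recursion is evaluated in plain double precision: for the list counts this
statistic is used with (tens of lists; TF counts per gene set are bounded
at 40 by the default filter) it is numerically benign, and a guard refuses
`m > 100`.

**Robust rank aggregation (RRA).** `rho(r) = min_j P(Bin(m, r[j]) >= j)`,
the best binomial tail over order-statistic positions: a gene scores well
if it is unusually high in *some* subset of the lists, which is what makes
the aggregate robust to individual lists that are pure noise. We use the
raw minimum, without a multiplicity correction over `j`; the original RRA
publication applies a Bonferroni factor, and `rra_rho(correction =
"bonferroni")` provides it, but the uncorrected minimum is the package
default because only the induced ordering matters here and the correction
is monotone for fixed `m`.

Final ranks sort the statistic ascending with ties broken by gene
identifier (stable) — the package-wide tie rule that makes every output
bit-reproducible.

## Parameter tuning and evaluation

The tunables that matter:

| parameter | meaning | default grid |
|---|---|---|
| `tau >= 0` | diffusion time; how far similarity spreads | 0.01, 0.1, 0.5, 1 |
| `lambda >= 0` | weight of the CGI neighborhood term | 0, 0.1, 0.5, 1, 2, 5 |
| `d in [0, 1)` | GeneRank damping; share of propagated mass | 0, 0.1, 0.3, 0.5, 0.7, 0.9 |

The grids are package defaults chosen to span the no-network point through
network-dominated regimes on a roughly logarithmic scale; both grids are
config-overridable. Given a training set of genes known to be relevant,
`select_parameters()` scores every grid point by the one-sided Wilcoxon
rank-sum p-value testing that training genes sit at the top of the
aggregated list, and keeps the argmin (ties broken by grid order). The
exact null distribution is used when both comparison groups have at most
20 genes, the normal approximation with tie correction otherwise.

`cross_validate()` wraps this in repeated k-fold cross-validation (10
rounds of 10 folds by default, hence 100 p-value records per method and
gene set). Deliberately, the *single* held-out fold is the training set —
emulating the realistic situation where only a small fraction of relevant
genes is known — and the remaining nine folds form the validation set. The
validation Wilcoxon test excludes the training genes from the background:
they were used for selection, so leaving them in would contaminate the
null group. Baseline (`tuner = "none"`) and network arms generate
identical partitions under the same seed, which makes
`log10(p_base / p_net)` (`log_p_fold`, positive = network helped) a paired
comparison fold by fold.

One computational observation shapes the implementation: the tuned,
aggregated candidate ranking for a grid point does not depend on which
fold is held out. `cross_validate()` therefore materializes each candidate
once and reuses it across all folds and rounds; only the cheap Wilcoxon
tests vary per fold. Likewise the Laplacian is eigendecomposed once per
network (blockwise over connected components — the exponential of a
block-diagonal matrix is block-diagonal) and the whole `tau` grid of
kernels is assembled from the same decomposition.

## The synthetic fixture generator

`generate_fixture()` produces the three inputs — network, rank lists, gene
set — with planted, controllable signal. Positives form a dense
planted-partition module (`p_in = 0.3` inside vs `p_out = 0.01` outside by
default), and each list ranks latent scores `mu * 1{positive} +
N(0, sd_j)`. The defaults (500 genes, 5 lists, 40 positives, `mu = 1.5`,
unit noise) describe a moderate-signal study: the positives are enriched
near the top of each list but far from cleanly separated, and the module
is dense enough that network smoothing has real information to exploit.
Latent noise is normal by construction, so the generated lists match the
distributional assumption of the normal-score transform and test failures
cannot be blamed on transform mismatch. Setting `concordance < 1` moves
positives out of the module (breaking the premise that relevance and
proximity coincide), `mu = 0` gives a null fixture for calibration, and an
inflated entry in `list_sds` emulates an unreliable list.

What the generator does *not* emulate: scale-free degree distributions of
real interactomes, realistic gene-set size spectra, correlated noise
between lists derived from the same platform, or hub-driven false
positives. Green tests on fixtures therefore demonstrate that the
machinery behaves as designed under its own assumptions, not that the
method will improve any particular real data set.

## Perturbation experiments

Three network surgeries probe where the improvement comes from:
`permute_labels()` keeps the topology but randomizes which gene sits where
(any benefit must vanish — and on fixtures it does, with median
log-p-fold indistinguishable from zero or below); `inject_noise(alpha)`
replaces `alpha`% of edges with uniformly sampled non-edges of the
*original* graph (never re-adding a pair removed in the same call),
conserving the edge count; `merge_networks()` unions edge sets as when
pooling interaction databases. All randomized operations take an explicit
integer seed and no function touches the global random stream.

## Numerical and degenerate-input choices

* `tau = 0`, `lambda = 0`, `d = 0` return the inputs exactly (bit
  identical), not merely up to round-off — the branches short-circuit.
* Kernel entries are clipped to `[0, 1]` and re-symmetrized after the
  eigendecomposition to absorb round-off at the 1e-15 level; the diagonal
  is set to exactly 1.
* Isolated network genes: zero Laplacian row, so their kernel row is the
  identity row and CGI leaves them untouched; GeneRank gives them
  `(1 - d) z`.
* Genes missing from the network file become isolated nodes (the
  alternative — dropping them — would leave ranked genes without tuned
  scores); network genes outside the rank-list universe are dropped.
* All rank lists must cover one shared universe; a missing gene is an
  error, never imputed, because a rank ratio is only defined relative to a
  fixed `n`.
* Tied input ranks propagate to identical ratios (no jitter); downstream
  orderings resolve ties by gene identifier.
* p-values are floored at the smallest positive double so `log_p_fold`
  stays finite.

## Limitations

Unweighted, undirected networks only; a single network per run (merge
first if you have several); dense `n x n` kernels, appropriate up to a few
thousand genes per connected component; no identifier mapping between
naming schemes; no p-value calibration of the Endeavour Q (it is used only
for ordering); and parameter tuning requires at least a handful of known
genes — with none available, run `tuner = "none"` or fall back to the
default mid-grid values.
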