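# netaggr — network-tuned aggregation of multiple gene rank lists

`netaggr` combines several gene rank lists (replicate experiments,
platforms, per-regulator co-expression rankings, ...) into one prioritized
gene list, using a protein–protein interaction network to borrow strength
between neighboring genes. It is aimed at anyone who has `m` rankings of
the same `n` genes plus an interactome and wants a single, better ranking:
target-gene prioritization for transcription factors, disease-gene
screens, pathway-member prediction.

## The method in brief

1. **Normal scores.** Each rank `r[i,j]` becomes a rank ratio
   `ra[i,j] = r[i,j]/n` and then a normal score `z[i,j] = -Φ⁻¹(ra[i,j])`
   (ratios of 1 are capped at 0.9999), so top genes carry the largest
   scores.
2. **Network smoothing**, one of:
   - **CGI** — diffusion-kernel weighted averaging. With
     `K` the cosine-normalized kernel of `S = e^{-τL}`, `L = D − H`:

     `R[i,j] = (z[i,j] + λ Σ_{l≠i} |z[l,j]| K[l,i]) / (1 + λ Σ_{l≠i} K[l,i])`
   - **GeneRank** — PageRank-style propagation solving
     `(I − d·H D⁻¹) R_j = (1 − d) z_j`, `d ∈ [0, 1)`.
3. **Aggregation**, one of:
   - **Endeavour order statistic** `Q = m!·V_m` via the alternating
     `V_k` recursion on the ascending-sorted ratios;
   - **RRA** `ρ = min_j P(Bin(m, r_(j)) ≥ j)`, the best binomial tail,
     robust to individual noisy lists.

   Smaller statistic = better final rank; ties break by gene identifier.

Parameters (τ, λ) or d are tuned on a training gene set by minimizing a
one-sided Wilcoxon rank-sum p-value, and methods are benchmarked by
repeated 10-fold cross-validation in which each held-out fold serves as
the (small) training set and the rest as validation. Both composition
orders are supported: tune-then-aggregate (CGI_RRA, GR_Endeavour, ...)
and aggregate-then-tune (RRA_CGI, Endeavour_GR, ...).

## Worked example

Synthetic fixture: 300 genes, 4 rank lists, 25 positive genes forming a
dense network module and shifted up in every list.

```r
library(netaggr)

fx <- generate_fixture(fixture_config(n_genes = 300, n_lists = 4,
                                      n_positives = 25, seed = 7))

# plain robust rank aggregation
plain <- aggregate_ranks(fx$ranks, method = "rra")
print(plain)
#> aggregation_result [rra]: 300 genes; top of list:
#>  gene    statistic rank
#>  g090 1.828704e-05    1
#>  g249 3.152000e-05    2
#>  g287 7.433481e-05    3
#>  g022 1.000000e-04    4
#>  g166 1.852623e-04    5
#>  g215 3.149033e-04    6

# tune CGI on 5 known genes, then compare on the held-out 20
training <- fx$positives[1:5]
sel <- select_parameters(fx$ranks, fx$network, training,
                         tuning_grid(), tuner = "cgi", aggregator = "rra")
sel$params[c("tau", "lam")]
#> $tau   0.1
#> $lam   5

validation <- setdiff(fx$positives, training)
p_plain <- wilcoxon_enrichment_p(plain, validation, excluded = training)
p_tuned <- wilcoxon_enrichment_p(sel$result, validation, excluded = training)
c(plain = p_plain, cgi_rra = p_tuned, log_p_fold = log_p_fold(p_plain, p_tuned))
#> plain RRA:  p = 4.96e-12
#> CGI_RRA:    p = 6.42e-14
#> log-p-fold: 1.89
```

The Wilcoxon p-value tests whether the held-out positives sit near the top
of the final list (training genes are excluded from the background). Here
network tuning shrinks it by almost two orders of magnitude
(`log-p-fold = 1.89 > 0` means the network helped); the tuned list places
all 25 planted genes in its top 50, the plain list 22.

The same pipeline runs from the shell on TSV/SIF/GMT files via
`inst/cli/netaggr.R` (subcommands `fixture`, `aggregate`, `evaluate`), and
`cross_validate()` / `cmd_evaluate()` produce the full repeated-CV
comparison including label-permutation and edge-noise controls. See the
vignette in `vignettes/` for the model details and design choices.

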