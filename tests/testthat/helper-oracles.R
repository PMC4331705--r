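# Independent oracles and small fixture builders shared across tests.

# Endeavour Q by deterministic nested Gauss-Legendre quadrature.
# The innermost integrand is constant and each integration raises the
# polynomial degree by one, so `nodes` >= m is exact for m lists. Entirely
# independent of the V_k recursion used by the package.
quadrature_q <- function(ratios, nodes = 6L) {
  m <- length(ratios)
  r <- sort(ratios)
  gl <- pracma::gaussLegendre(nodes, -1, 1)
  level <- function(k, lower) {
    if (k > m) return(1)
    a <- lower
    b <- r[k]
    s <- (a + b) / 2 + (b - a) / 2 * gl$x
    vals <- vapply(s, function(si) level(k + 1L, si), numeric(1L))
    (b - a) / 2 * sum(gl$w * vals)
  }
  factorial(m) * level(1L, 0)
}

# Endeavour Q by Monte Carlo: P(all m ascending-sorted uniforms are
# componentwise below the sorted ratios).
mc_q <- function(ratios, n_draws = 1e5L) {
  m <- length(ratios)
  r <- sort(ratios)
  u <- matrix(runif(n_draws * m), n_draws, m)
  us <- if (m == 1L) u else t(apply(u, 1L, sort))
  hits <- rowSums(sweep(us, 2L, r, `<=`)) == m
  list(estimate = mean(hits),
       se = sqrt(mean(hits) * (1 - mean(hits)) / n_draws))
}

# RRA rho via explicit factorial-based binomial tail sums (no pbinom).
factorial_rho <- function(ratios) {
  m <- length(ratios)
  r <- sort(ratios)
  beta <- vapply(seq_len(m), function(j) {
    l <- j:m
    sum(exp(lgamma(m + 1) - lgamma(l + 1) - lgamma(m - l + 1)) *
          r[j]^l * (1 - r[j])^(m - l))
  }, numeric(1L))
  min(beta)
}

# Erdos-Renyi gene_network over `n` genes, possibly with isolated nodes.
random_gene_network <- function(n, p, seed) {
  genes <- sprintf("n%03d", seq_len(n))
  netaggr:::with_seed(seed, {
    u <- matrix(runif(n * n), n, n)
    idx <- which((u < p) & upper.tri(u), arr.ind = TRUE)
    gene_network(cbind(genes[idx[, 1L]], genes[idx[, 2L]]), universe = genes)
  })
}

# Random z-score matrix over a network's universe.
random_scores <- function(net, m, seed) {
  netaggr:::with_seed(seed, {
    v <- matrix(rnorm(length(net$genes) * m), length(net$genes), m,
                dimnames = list(net$genes, paste0("l", seq_len(m))))
    score_matrix(v, meaning = "z")
  })
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# numeric payload of a score_matrix, for value-level (bit) comparisons
score_values <- function(x) {
  v <- unclass(x)
  attr(v, "meaning") <- NULL
  v
}
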