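#' Construct an undirected gene network
#'
#' Builds a simple undirected graph over a gene universe from an edge list.
#' Self-loops are dropped, duplicate and reversed-duplicate edges are
#' collapsed. When a `universe` is supplied, edges touching genes outside it
#' are dropped and universe genes with no edges become isolated nodes, so
#' network-tuned scores stay defined for every ranked gene.
#'
#' @param edges two-column character matrix or data frame of endpoints; may
#'   have zero rows.
#' @param universe optional gene universe (character). Defaults to the
#'   sorted set of endpoint identifiers.
#' @return An object of class `"gene_network"`: a list with elements
#'   `genes` (the universe) and `adj` (sparse symmetric 0/1 adjacency
#'   matrix `H` with zero diagonal).
#' @export
gene_network <- function(edges, universe = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  if (!is.matrix(edges) || ncol(edges) != 2L) {
    stop("`edges` must be a two-column matrix of gene identifiers", call. = FALSE)
  }
  storage.mode(edges) <- "character"

  loops <- edges[, 1L] == edges[, 2L]
  if (any(loops)) {
    message("dropping ", sum(loops), " self-loop(s)")
    edges <- edges[!loops, , drop = FALSE]
  }

  if (is.null(universe)) {
    universe <- gene_universe(sort(unique(c(edges))))
  } else {
    universe <- gene_universe(universe)
    known <- edges[, 1L] %in% universe & edges[, 2L] %in% universe
    if (!all(known)) {
      message("dropping ", sum(!known), " edge(s) touching genes outside the universe")
      edges <- edges[known, , drop = FALSE]
    }
  }

  n <- length(universe)
  i <- match(edges[, 1L], universe)
  j <- match(edges[, 2L], universe)
  adj <- Matrix::sparseMatrix(
    i = c(i, j), j = c(j, i), x = 1,
    dims = c(n, n), dimnames = list(universe, universe)
  )
  adj@x[] <- 1  # collapse duplicate edges to 0/1
  structure(list(genes = universe, adj = adj), class = "gene_network")
}

#' Extract the edge list of a network
#'
#' @param net a `gene_network`.
#' @return Two-column character matrix, one row per undirected edge, with
#'   endpoints ordered lexicographically within and across rows.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  idx <- Matrix::which(Matrix::triu(net$adj, k = 1L) != 0, arr.ind = TRUE)
  e <- cbind(net$genes[idx[, 1L]], net$genes[idx[, 2L]])
  swap <- e[, 1L] > e[, 2L]
  e[swap, ] <- e[swap, c(2L, 1L), drop = FALSE]
  e[order(e[, 1L], e[, 2L]), , drop = FALSE]
}

#' Node degrees of a network
#'
#' @param net a `gene_network`.
#' @return Named integer vector of degrees over the universe.
#' @export
network_degrees <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  d <- Matrix::rowSums(net$adj)
  names(d) <- net$genes
  d
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d genes, %d edges\n",
              length(x$genes), sum(x$adj != 0) / 2))
  invisible(x)
}

#' Merge networks by edge union
#'
#' Node set of the result is the union of node sets; edge set is the union
#' of edge sets, as when several interaction databases are pooled into one
#' integrated network.
#'
#' @param nets list of `gene_network` objects (at least one).
#' @return A `gene_network` over the union universe (sorted).
#' @export
merge_networks <- function(nets) {
  if (!is.list(nets) || length(nets) == 0L ||
      !all(vapply(nets, inherits, logical(1L), "gene_network"))) {
    stop("`nets` must be a non-empty list of gene_network objects", call. = FALSE)
  }
  genes <- sort(unique(unlist(lapply(nets, `[[`, "genes"))))
  edges <- do.call(rbind, lapply(nets, network_edges))
  gene_network(edges, universe = genes)
}

#' Randomly permute the gene labels of a network
#'
#' Reassigns node identifiers uniformly at random while keeping the wiring
#' untouched, so the permuted network has the same topology (and degree
#' multiset) but carries no information about which genes are neighbors.
#' Used as a negative control for network-tuned aggregation.
#'
#' @param net a `gene_network`.
#' @param seed integer seed; the same seed reproduces the same permutation.
#' @return A `gene_network` over the same universe.
#' @export
permute_labels <- function(net, seed) {
  stopifnot(inherits(net, "gene_network"))
  n <- length(net$genes)
  perm <- with_seed(seed, sample.int(n))
  # node i takes the label genes[perm[i]]: adj_new[perm[i], perm[j]] = adj[i, j]
  ip <- order(perm)
  adj <- net$adj[ip, ip, drop = FALSE]
  dimnames(adj) <- list(net$genes, net$genes)
  structure(list(genes = net$genes, adj = adj), class = "gene_network")
}

#' Replace a fraction of edges with random non-edges
#'
#' Emulates false positive and false negative interactions: `alpha_pct`
#' percent of the edges (rounded) are removed, sampled without replacement,
#' and the same number of new edges is added. Each added edge is a uniformly
#' sampled unordered pair that was a non-edge in the *original* network and
#' has not already been added, so the edge count is conserved and no removed
#' edge can reappear within the same call.
#'
#' @param net a `gene_network`.
#' @param alpha_pct percentage of edges to replace, in `[0, 100]`.
#' @param seed integer seed.
#' @return A `gene_network` with the same universe and the same number of
#'   edges.
#' @export
inject_noise <- function(net, alpha_pct, seed) {
  stopifnot(inherits(net, "gene_network"))
  if (!is.numeric(alpha_pct) || length(alpha_pct) != 1L ||
      is.na(alpha_pct) || alpha_pct < 0 || alpha_pct > 100) {
    stop("`alpha_pct` must lie in [0, 100]", call. = FALSE)
  }
  genes <- net$genes
  n <- length(genes)
  edges <- network_edges(net)
  n_edges <- nrow(edges)
  k <- round(alpha_pct / 100 * n_edges)
  if (k == 0L) return(net)

  n_non_edges <- n * (n - 1) / 2 - n_edges
  if (n_non_edges < k) {
    stop("not enough non-adjacent pairs to host ", k, " replacement edge(s)",
         call. = FALSE)
  }

  # unordered pair {i, j}, i < j, encoded as (i - 1) * n + j
  code <- function(i, j) (pmin(i, j) - 1) * n + pmax(i, j)
  orig_codes <- code(match(edges[, 1L], genes), match(edges[, 2L], genes))

  with_seed(seed, {
    drop_idx <- sample.int(n_edges, k)
    added <- numeric(0L)
    while (length(added) < k) {
      i <- sample.int(n, 1L)
      j <- sample.int(n, 1L)
      if (i == j) next
      cd <- code(i, j)
      if (cd %in% orig_codes || cd %in% added) next
      added <- c(added, cd)
    }
  })

  kept <- edges[-drop_idx, , drop = FALSE]
  ai <- (added - 1) %/% n + 1
  aj <- added - (ai - 1) * n
  new_edges <- rbind(kept, cbind(genes[ai], genes[aj]))
  gene_network(new_edges, universe = genes)
}
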