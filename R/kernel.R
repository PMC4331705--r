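#' Graph Laplacian of a network
#'
#' @param net a `gene_network`.
#' @return Dense numeric matrix `L = D - H`, where `H` is the adjacency
#'   matrix and `D` the diagonal degree matrix. Rows sum to zero; isolated
#'   nodes contribute all-zero rows.
#' @export
laplacian <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  H <- as.matrix(net$adj)
  L <- diag(Matrix::rowSums(net$adj), nrow = nrow(H)) - H
  dimnames(L) <- list(net$genes, net$genes)
  L
}

# Symmetric eigendecomposition of the Laplacian, one block per connected
# component (the exponential of a block-diagonal matrix is block-diagonal,
# and cross-component kernel entries are exactly zero). Reused across tau
# values when a whole tuning grid of kernels is needed.
laplacian_eigen_blocks <- function(net) {
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    net$adj, mode = "undirected", diag = FALSE))
  L <- laplacian(net)
  lapply(seq_len(comp$no), function(b) {
    idx <- which(comp$membership == b)
    if (length(idx) == 1L) {
      list(idx = idx, values = 0, vectors = matrix(1, 1L, 1L))
    } else {
      e <- eigen(L[idx, idx, drop = FALSE], symmetric = TRUE)
      list(idx = idx, values = e$values, vectors = e$vectors)
    }
  })
}

kernel_from_blocks <- function(blocks, genes, tau) {
  n <- length(genes)
  S <- matrix(0, n, n, dimnames = list(genes, genes))
  for (b in blocks) {
    Eb <- b$vectors %*% (t(b$vectors) * exp(-tau * b$values))
    S[b$idx, b$idx] <- (Eb + t(Eb)) / 2
  }
  d <- sqrt(diag(S))
  K <- S / outer(d, d)
  K <- pmin(pmax(K, 0), 1)  # clip eigen-roundoff outside [0, 1]
  K <- (K + t(K)) / 2
  diag(K) <- 1
  structure(list(genes = genes, K = K, S = S, tau = tau),
            class = "kernel_matrix")
}

#' Normalized diffusion kernel of a network
#'
#' Computes `S = expm(-tau * L)` via the symmetric eigendecomposition of the
#' Laplacian (block-wise over connected components) and cosine-normalizes it
#' to `K[u, v] = S[u, v] / sqrt(S[u, u] * S[v, v])`. `S` has nonnegative
#' entries and unit row sums; `K` is symmetric with unit diagonal and
#' entries in `[0, 1]`. At `tau = 0` both are the identity. Larger `tau`
#' diffuses similarity further across the network.
#'
#' @param net a `gene_network`.
#' @param tau diffusion time, a nonnegative real.
#' @return An object of class `"kernel_matrix"`: list with `genes`,
#'   normalized kernel `K`, raw exponential `S`, and `tau`.
#' @export
diffusion_kernel <- function(net, tau) {
  stopifnot(inherits(net, "gene_network"))
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0) {
    stop("`tau` must be a single nonnegative number", call. = FALSE)
  }
  n <- length(net$genes)
  if (tau == 0) {
    I <- diag(1, n)
    dimnames(I) <- list(net$genes, net$genes)
    return(structure(list(genes = net$genes, K = I, S = I, tau = 0),
                     class = "kernel_matrix"))
  }
  kernel_from_blocks(laplacian_eigen_blocks(net), net$genes, tau)
}

#' Diffusion kernels for a grid of tau values
#'
#' The Laplacian is eigendecomposed once and reused, so evaluating a whole
#' tuning grid costs little more than a single kernel. The kernel for a
#' given network is also what gets reused across rank lists and gene sets
#' during tuning.
#'
#' @param net a `gene_network`.
#' @param taus numeric vector of nonnegative diffusion times.
#' @return Named list of `kernel_matrix` objects, names = `taus`.
#' @export
diffusion_kernels <- function(net, taus) {
  if (length(taus) == 0L || any(is.na(taus)) || any(taus < 0)) {
    stop("`taus` must be nonnegative numbers", call. = FALSE)
  }
  blocks <- NULL
  out <- lapply(taus, function(tau) {
    if (tau == 0) return(diffusion_kernel(net, 0))
    if (is.null(blocks)) blocks <<- laplacian_eigen_blocks(net)
    kernel_from_blocks(blocks, net$genes, tau)
  })
  names(out) <- as.character(taus)
  out
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("kernel_matrix: %d genes, tau = %g\n", length(x$genes), x$tau))
  invisible(x)
}
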