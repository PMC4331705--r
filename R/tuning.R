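#' Update normal scores with network information (CGI)
#'
#' Kernel-weighted averaging of each gene's own score with its network
#' neighborhood. For gene `i` in list `j`,
#' \deqn{R_{i,j} = \frac{z_{i,j} + \lambda \sum_{l \ne i} |z_{l,j}| K_{l,i}}
#'                     {1 + \lambda \sum_{l \ne i} K_{l,i}},}
#' where `K` is the normalized diffusion kernel. Neighbors contribute
#' through the absolute value of their score while the focal gene keeps its
#' sign, so a gene surrounded by strongly (de)regulated neighbors is pulled
#' up. `lambda = 0`, or an identity kernel (`tau = 0`), returns the input
#' scores unchanged, making plain aggregation an exact special case.
#'
#' @param z a [score_matrix()] of normal scores.
#' @param kernel a `kernel_matrix` from [diffusion_kernel()] over the same
#'   universe.
#' @param lam nonnegative weight of the neighborhood term.
#' @param neighbor_abs if `TRUE` (default) neighbors enter via `|z|`;
#'   `FALSE` uses signed neighbor scores instead.
#' @return A [score_matrix()] with meaning `"tuned"`.
#' @export
cgi_update <- function(z, kernel, lam, neighbor_abs = TRUE) {
  if (!inherits(z, "score_matrix")) {
    stop("`z` must be a score_matrix", call. = FALSE)
  }
  if (!inherits(kernel, "kernel_matrix")) {
    stop("`kernel` must be a kernel_matrix", call. = FALSE)
  }
  if (!identical(rownames(z), kernel$genes)) {
    stop("`z` and `kernel` must share the same gene universe", call. = FALSE)
  }
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0) {
    stop("`lam` must be a single nonnegative number", call. = FALSE)
  }
  zm <- unclass(z)
  if (lam == 0) {
    return(score_matrix(zm, meaning = "tuned"))
  }
  K <- kernel$K
  contrib <- if (neighbor_abs) abs(zm) else zm
  # K has unit diagonal, so K %*% contrib - contrib drops the self term and
  # colSums(K) - diag(K) is the off-diagonal kernel mass at each gene
  num <- zm + lam * (K %*% contrib - contrib)
  den <- 1 + lam * (colSums(K) - diag(K))
  R <- num / den
  dimnames(R) <- dimnames(zm)
  score_matrix(R, meaning = "tuned")
}

#' Update normal scores with network information (GeneRank)
#'
#' PageRank-style propagation: for each list `j`, the tuned score vector
#' solves \deqn{(I - d\,H D^{-1}) R_j = (1 - d)\, z_j,} where `H` is the
#' adjacency matrix, `D` the degree matrix and `d` in `[0, 1)` balances the
#' original score against mass received from neighbors. Columns of
#' `H D^{-1}` at zero-degree genes are defined as zero, the only finite
#' continuous extension, so isolated genes keep `(1 - d)` of their own score
#' plus whatever flows in. With `method = "iterative"` the fixed point is
#' reached by the damped iteration `R^(k) = (1 - d) z + d H D^{-1} R^(k-1)`
#' started at `z` (a contraction for `d < 1`, so the start does not affect
#' the limit); `method = "direct"` solves the linear system. `d = 0` returns
#' the input scores unchanged.
#'
#' @param z a [score_matrix()] of normal scores.
#' @param net a `gene_network` over the same universe.
#' @param d damping parameter in `[0, 1)`.
#' @param tol convergence threshold on the max absolute update
#'   (default `1e-6`).
#' @param max_iter iteration cap (default `1000`).
#' @param method `"iterative"` (default) or `"direct"`.
#' @return A [score_matrix()] with meaning `"tuned"`.
#' @export
generank_solve <- function(z, net, d, tol = 1e-6, max_iter = 1000L,
                           method = c("iterative", "direct")) {
  method <- match.arg(method)
  if (!inherits(z, "score_matrix")) {
    stop("`z` must be a score_matrix", call. = FALSE)
  }
  if (!inherits(net, "gene_network")) {
    stop("`net` must be a gene_network", call. = FALSE)
  }
  if (!identical(rownames(z), net$genes)) {
    stop("`z` and `net` must share the same gene universe", call. = FALSE)
  }
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0 || d >= 1) {
    stop("`d` must lie in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(tol) || tol <= 0) {
    stop("`tol` must be positive", call. = FALSE)
  }
  zm <- unclass(z)
  if (d == 0) {
    return(score_matrix(zm, meaning = "tuned"))
  }
  deg <- Matrix::rowSums(net$adj)
  inv_deg <- ifelse(deg > 0, 1 / deg, 0)
  M <- as.matrix(net$adj) %*% diag(inv_deg, nrow = length(deg))  # H D^{-1}

  if (method == "direct") {
    A <- diag(1, nrow(M)) - d * M
    R <- tryCatch(solve(A, (1 - d) * zm),
                  error = function(e) stop("singular GeneRank system: ",
                                           conditionMessage(e), call. = FALSE))
  } else {
    R <- zm
    for (k in seq_len(max_iter)) {
      R_new <- (1 - d) * zm + d * (M %*% R)
      delta <- max(abs(R_new - R))
      R <- R_new
      if (delta < tol) break
    }
  }
  R <- as.matrix(R)
  dimnames(R) <- dimnames(zm)
  score_matrix(R, meaning = "tuned")
}
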