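#' Endeavour order-statistic Q for one rank-ratio vector
#'
#' The joint cumulative probability that the order statistics of `m`
#' independent uniforms fall below the ascending-sorted observed ratios:
#' \deqn{Q(r) = m! \int_0^{r_{(1)}} \int_{s_1}^{r_{(2)}} \cdots
#'   \int_{s_{m-1}}^{r_{(m)}} ds_m \cdots ds_1.}
#' Evaluated by the alternating recursion
#' `V_k = sum_{l=1}^{k} (-1)^(l-1) * V_{k-l} / l! * r_{(m-k+1)}^l`, with
#' `V_0 = 1` and `Q = m! * V_m`. Smaller Q = stronger joint support across
#' lists. The double-precision recursion is reliable for the moderate list
#' counts this statistic is used with; `m > 100` is refused.
#'
#' @param ratios numeric vector of `m` rank ratios in `[0, 1]` (any order).
#' @return Q in `[0, 1]`.
#' @export
#' @examples
#' endeavour_q(c(0.2, 0.5)) # 0.16
endeavour_q <- function(ratios) {
  check_ratio_vector(ratios)
  m <- length(ratios)
  if (m > 100L) {
    stop("endeavour_q is limited to m <= 100 lists", call. = FALSE)
  }
  r <- sort(ratios)
  V <- c(1, numeric(m)) # V[k + 1] = V_k
  for (k in seq_len(m)) {
    l <- seq_len(k)
    V[k + 1L] <- sum((-1)^(l - 1) * V[k - l + 1L] / factorial(l) *
                       r[m - k + 1L]^l)
  }
  min(max(factorial(m) * V[m + 1L], 0), 1)
}

#' Robust rank aggregation statistic rho for one rank-ratio vector
#'
#' Under the null that all ratios are independent uniforms, the probability
#' that the j-th order statistic is at most the observed j-th smallest ratio
#' is the binomial tail `beta_j = P(Bin(m, r_(j)) >= j)`. The statistic is
#' `rho = min_j beta_j`, so a gene scores well if it is unusually high in
#' *some* subset of the lists, which keeps the aggregate robust to lists
#' that are pure noise. No multiplicity correction over `j` is applied by
#' default; `correction = "bonferroni"` multiplies by `m` (capped at 1).
#'
#' @param ratios numeric vector of `m` rank ratios in `[0, 1]`.
#' @param correction `"none"` (default) or `"bonferroni"`.
#' @return rho in `(0, 1]`.
#' @export
#' @examples
#' rra_rho(c(0.5, 0.5, 0.5)) # 0.125
rra_rho <- function(ratios, correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  check_ratio_vector(ratios)
  m <- length(ratios)
  r <- sort(ratios)
  beta <- pbinom(seq_len(m) - 1L, m, r, lower.tail = FALSE)
  rho <- min(beta)
  if (correction == "bonferroni") rho <- min(1, m * rho)
  rho
}

check_ratio_vector <- function(ratios) {
  if (length(ratios) == 0L) {
    stop("ratio vector must not be empty", call. = FALSE)
  }
  if (!is.numeric(ratios) || anyNA(ratios) ||
      any(ratios < 0) || any(ratios > 1)) {
    stop("rank ratios must be numbers in [0, 1]", call. = FALSE)
  }
  invisible(ratios)
}

#' Aggregate a rank matrix into one prioritized gene list
#'
#' Computes the per-gene aggregation statistic — [endeavour_q()] or
#' [rra_rho()] — on each gene's ascending-sorted ratio vector across lists,
#' then ranks genes by ascending statistic (smaller = better), ties broken
#' by gene identifier. Integer-rank input is converted to ratios first.
#'
#' @param rm a [rank_matrix()] (either kind).
#' @param method `"endeavour"` or `"rra"`.
#' @param rra_correction passed to [rra_rho()].
#' @return An `aggregation_result`: data frame in universe order with
#'   columns `gene`, `statistic`, `rank`, and attribute `method`.
#' @export
aggregate_ranks <- function(rm, method = c("endeavour", "rra"),
                            rra_correction = c("none", "bonferroni")) {
  method <- match.arg(method)
  rra_correction <- match.arg(rra_correction)
  if (!inherits(rm, "rank_matrix")) {
    stop("`rm` must be a rank_matrix", call. = FALSE)
  }
  if (matrix_kind(rm) == "rank") rm <- ranks_to_ratios(rm)
  ra <- unclass(rm)
  n <- nrow(ra)
  m <- ncol(ra)
  genes <- rownames(ra)

  # row-wise ascending sort, then the statistic vectorized over genes
  rs <- if (m == 1L) ra else t(apply(ra, 1L, sort))

  if (method == "endeavour") {
    if (m > 100L) stop("endeavour aggregation is limited to m <= 100 lists",
                       call. = FALSE)
    V <- matrix(0, n, m + 1L)
    V[, 1L] <- 1
    for (k in seq_len(m)) {
      acc <- 0
      rk <- rs[, m - k + 1L]
      for (l in seq_len(k)) {
        acc <- acc + (-1)^(l - 1) * V[, k - l + 1L] / factorial(l) * rk^l
      }
      V[, k + 1L] <- acc
    }
    stat <- pmin(pmax(factorial(m) * V[, m + 1L], 0), 1)
  } else {
    beta <- vapply(seq_len(m), function(j) {
      pbinom(j - 1L, m, rs[, j], lower.tail = FALSE)
    }, numeric(n))
    beta <- matrix(beta, nrow = n)
    stat <- do.call(pmin, lapply(seq_len(m), function(j) beta[, j]))
    if (rra_correction == "bonferroni") stat <- pmin(1, m * stat)
  }

  ord <- order(stat, genes)
  final <- integer(n)
  final[ord] <- seq_len(n)
  structure(
    data.frame(gene = genes, statistic = stat, rank = final,
               stringsAsFactors = FALSE, row.names = NULL),
    method = method, class = c("aggregation_result", "data.frame")
  )
}

#' @export
print.aggregation_result <- function(x, ...) {
  cat(sprintf("aggregation_result [%s]: %d genes; top of list:\n",
              attr(x, "method", exact = TRUE), nrow(x)))
  top <- as.data.frame(head(x[order(x$rank), , drop = FALSE], 6L))
  class(top) <- "data.frame"
  print(top, row.names = FALSE)
  invisible(x)
}
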