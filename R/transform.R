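#' Convert integer ranks to rank ratios
#'
#' Divides every rank by the universe size `n`, mapping ranks `1..n` to
#' ratios in `(0, 1]` (smaller = better). Tied input ranks propagate to
#' identical ratios.
#'
#' @param rm a [rank_matrix()] of kind `"rank"`.
#' @return A [rank_matrix()] of kind `"ratio"`.
#' @export
ranks_to_ratios <- function(rm) {
  if (!inherits(rm, "rank_matrix") || matrix_kind(rm) != "rank") {
    stop("`rm` must be a rank_matrix of kind 'rank'", call. = FALSE)
  }
  rank_matrix(unclass(rm) / nrow(rm), kind = "ratio")
}

#' Transform rank ratios to normal scores
#'
#' Maps each rank ratio `ra` to `z = -qnorm(ra)`, the negated standard
#' normal quantile, so that a full permutation column becomes (approximately)
#' standard normal and the best-ranked genes get the largest scores. Ratios
#' at or above `ratio_cap` are first replaced by `ratio_cap` so the score of
#' the worst-ranked gene (`ra = 1`) stays finite; capping everything above
#' the threshold, not just exact ones, preserves monotonicity when
#' `(n - 1) / n` itself exceeds the cap.
#'
#' @param rm a [rank_matrix()] of kind `"ratio"`.
#' @param ratio_cap substitution value for ratios at the upper boundary,
#'   in `(0, 1)`. Default `0.9999`.
#' @return A [score_matrix()] with meaning `"z"`.
#' @export
ratios_to_zscores <- function(rm, ratio_cap = 0.9999) {
  if (!inherits(rm, "rank_matrix") || matrix_kind(rm) != "ratio") {
    stop("`rm` must be a rank_matrix of kind 'ratio'", call. = FALSE)
  }
  if (!is.numeric(ratio_cap) || length(ratio_cap) != 1L ||
      is.na(ratio_cap) || ratio_cap <= 0 || ratio_cap >= 1) {
    stop("`ratio_cap` must lie in (0, 1)", call. = FALSE)
  }
  ra <- unclass(rm)
  if (any(ra <= 0)) {
    stop("rank ratios must be positive", call. = FALSE)
  }
  ra <- pmin(ra, ratio_cap)
  z <- -qnorm(ra)
  attributes(z) <- attributes(ra)
  score_matrix(z, meaning = "z")
}

#' Convert score columns back to integer ranks
#'
#' Per column, the largest score gets rank 1. Ties are broken by gene
#' identifier (lexicographic, stable), the package-wide rule that keeps all
#' outputs bit-reproducible.
#'
#' @param sm a [score_matrix()].
#' @return A [rank_matrix()] of kind `"rank"`; every column is a permutation
#'   of `1..n`.
#' @export
scores_to_ranks <- function(sm) {
  if (!inherits(sm, "score_matrix")) {
    stop("`sm` must be a score_matrix", call. = FALSE)
  }
  s <- unclass(sm)
  genes <- rownames(s)
  r <- apply(s, 2L, function(col) {
    ord <- order(-col, genes)
    out <- integer(length(col))
    out[ord] <- seq_along(col)
    out
  })
  dimnames(r) <- dimnames(s)
  rank_matrix(r, kind = "rank")
}
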