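#' Construct a gene universe
#'
#' The gene universe is the ordered set of unique gene identifiers shared by
#' all rank lists, score matrices, networks and kernels in an analysis. It is
#' represented as a plain character vector; all matrix-valued objects in the
#' package carry it as their rownames.
#'
#' @param genes character vector of gene identifiers.
#' @return A character vector of unique, non-empty identifiers in the given
#'   order.
#' @export
#' @examples
#' gene_universe(c("YAL001C", "YAL002W"))
gene_universe <- function(genes) {
  genes <- as.character(genes)
  if (length(genes) == 0L) {
    stop("gene universe must contain at least one gene", call. = FALSE)
  }
  if (anyNA(genes) || !all(nzchar(genes))) {
    stop("gene identifiers must be non-missing, non-empty strings", call. = FALSE)
  }
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0L) {
    stop(
      "duplicate gene identifiers in universe: ",
      paste(head(dup, 5L), collapse = ", "),
      call. = FALSE
    )
  }
  genes
}

# shared validation: x must be a numeric matrix with a valid universe as
# rownames and non-empty column names
check_gene_matrix <- function(x, what) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(x))) {
    stop(what, " must have gene identifiers as rownames", call. = FALSE)
  }
  gene_universe(rownames(x))
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("list", seq_len(ncol(x)))
  }
  x
}

#' Create a rank matrix
#'
#' A rank matrix stores one column per input list over a shared gene
#' universe (rownames). `kind = "rank"` holds integer ranks in `1..n`
#' (rank 1 = best); `kind = "ratio"` holds rank ratios `rank / n` in
#' `(0, 1]`.
#'
#' @param values numeric matrix, genes in rows (rownames = identifiers),
#'   lists in columns.
#' @param kind `"rank"` for integer ranks, `"ratio"` for rank ratios.
#' @return The validated matrix with class `"rank_matrix"` and attribute
#'   `kind`.
#' @export
rank_matrix <- function(values, kind = c("rank", "ratio")) {
  kind <- match.arg(kind)
  values <- check_gene_matrix(values, "rank matrix")
  n <- nrow(values)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("rank matrix entries must be finite", call. = FALSE)
  }
  if (kind == "rank") {
    if (any(values != round(values)) || any(values < 1) || any(values > n)) {
      stop("integer ranks must be whole numbers in 1..n (n = ", n, ")",
           call. = FALSE)
    }
  } else {
    if (any(values <= 0) || any(values > 1)) {
      stop("rank ratios must lie in (0, 1]", call. = FALSE)
    }
  }
  structure(values, kind = kind, class = c("rank_matrix", "matrix", "array"))
}

#' Create a score matrix
#'
#' Real-valued per-gene association scores, one column per list, over a
#' shared gene universe. `meaning = "z"` marks normal scores from the rank
#' transform; `meaning = "tuned"` marks network-updated scores. Larger
#' scores correspond to better (smaller) ranks.
#'
#' @param values numeric matrix of finite scores (rownames = identifiers).
#' @param meaning `"z"` or `"tuned"`.
#' @return The validated matrix with class `"score_matrix"` and attribute
#'   `meaning`.
#' @export
score_matrix <- function(values, meaning = c("z", "tuned")) {
  meaning <- match.arg(meaning)
  values <- check_gene_matrix(values, "score matrix")
  if (anyNA(values) || any(!is.finite(values))) {
    stop("score matrix entries must be finite", call. = FALSE)
  }
  structure(values, meaning = meaning, class = c("score_matrix", "matrix", "array"))
}

matrix_kind <- function(x) attr(x, "kind", exact = TRUE)

#' @export
print.rank_matrix <- function(x, ...) {
  cat(sprintf("rank_matrix [%s]: %d genes x %d lists\n",
              matrix_kind(x), nrow(x), ncol(x)))
  print(head(unclass(x), 6L), ...)
  invisible(x)
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix [%s]: %d genes x %d lists\n",
              attr(x, "meaning", exact = TRUE), nrow(x), ncol(x)))
  print(head(unclass(x), 6L), ...)
  invisible(x)
}
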