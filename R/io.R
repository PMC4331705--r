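# Read a two-column TSV (gene, value), skipping '#' comments and blank
# lines; errors name the file and offending line number.
read_two_column <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    stop("no records in ", path, call. = FALSE)
  }
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L) {
    stop("malformed line ", idx[bad[1L]], " in ", path,
         " (expected 2 tab-separated fields)", call. = FALSE)
  }
  genes <- vapply(parts, `[[`, character(1L), 1L)
  raw <- vapply(parts, `[[`, character(1L), 2L)
  values <- suppressWarnings(as.numeric(raw))
  if (anyNA(values)) {
    b <- which(is.na(values))[1L]
    stop("non-numeric value '", raw[b], "' at line ", idx[b], " in ", path,
         call. = FALSE)
  }
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0L) {
    stop("duplicate gene '", dup[1L], "' in ", path, call. = FALSE)
  }
  list(genes = genes, values = values)
}

#' Read gene rank lists from tab-separated files
#'
#' Each file holds two tab-separated columns: gene identifier and value.
#' All files must cover the same gene set; the shared universe is their
#' (sorted) union and a gene missing from any one file is an error rather
#' than being imputed, since rank ratios are only meaningful over a common
#' universe. In `mode = "score"` the value column holds association scores,
#' converted per list to integer ranks (largest score = rank 1, ties broken
#' by gene identifier); in `mode = "rank"` it holds integer ranks directly.
#'
#' @param paths character vector of file paths, one per rank list.
#' @param mode `"rank"` (values are integer ranks) or `"score"`.
#' @return A [rank_matrix()] of kind `"rank"`, columns named after the
#'   file base names.
#' @export
read_rank_lists <- function(paths, mode = c("rank", "score")) {
  mode <- match.arg(mode)
  if (length(paths) == 0L) stop("no input files given", call. = FALSE)
  tabs <- lapply(paths, read_two_column)
  universe <- gene_universe(sort(unique(unlist(lapply(tabs, `[[`, "genes")))))
  cols <- lapply(seq_along(tabs), function(k) {
    tab <- tabs[[k]]
    missing <- setdiff(universe, tab$genes)
    if (length(missing) > 0L) {
      stop(length(missing), " gene(s) missing from ", paths[k],
           " (e.g. ", missing[1L], "); all lists must share one universe",
           call. = FALSE)
    }
    v <- tab$values[match(universe, tab$genes)]
    if (mode == "score") {
      ord <- order(-v, universe)
      r <- integer(length(v))
      r[ord] <- seq_along(v)
      v <- r
    }
    v
  })
  values <- do.call(cbind, cols)
  rownames(values) <- universe
  colnames(values) <- make.unique(sub("\\.[^.]*$", "", basename(paths)))
  rank_matrix(values, kind = "rank")
}

#' Read an interaction network from an edge-list file
#'
#' Accepts two-column TSV (`gene<TAB>gene`) or three-column SIF
#' (`gene<TAB>type<TAB>gene`; the interaction type is ignored). Comment
#' (`#`) and blank lines are skipped. Parsing is delegated to
#' [gene_network()], which drops self-loops, collapses duplicate and
#' reversed edges, and reconciles the node set with `universe` if given.
#'
#' @param path path to the edge-list file.
#' @param universe optional gene universe to restrict/extend the node set.
#' @return A [gene_network()].
#' @export
read_network <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    stop("no edges in ", path, call. = FALSE)
  }
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != 2L & nf != 3L)
  if (length(bad) > 0L) {
    stop("malformed line ", idx[bad[1L]], " in ", path,
         " (expected 2 or 3 tab-separated fields)", call. = FALSE)
  }
  a <- vapply(parts, `[[`, character(1L), 1L)
  b <- mapply(function(p, k) p[[k]], parts, ifelse(nf == 2L, 2L, 3L))
  gene_network(cbind(a, b), universe = universe)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, fields `name`, `description`, then member
#' genes. Members are deduplicated within a line; sets without members are
#' skipped with a warning. Transcription-factor (or other regulator)
#' associations come from an optional companion two-column TSV
#' (`set name<TAB>TF id`). If a `universe` is supplied, out-of-universe
#' members are dropped with a message.
#'
#' @param path path to the GMT file.
#' @param tf_path optional path to the TF association TSV.
#' @param universe optional gene universe to restrict members to.
#' @return An object of class `"gene_set_collection"`: a named list, each
#'   element a list with `genes` and `tfs` character vectors.
#' @export
read_gene_sets <- function(path, tf_path = NULL, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- list()
  dropped_total <- 0L
  for (p in parts) {
    if (length(p) < 3L) {
      warning("skipping gene set '", p[[1L]], "': fewer than 1 member",
              call. = FALSE)
      next
    }
    members <- unique(p[-(1:2)])
    members <- members[nzchar(members)]
    if (!is.null(universe)) {
      out <- setdiff(members, universe)
      dropped_total <- dropped_total + length(out)
      members <- intersect(members, universe)
    }
    if (length(members) == 0L) {
      warning("skipping gene set '", p[[1L]], "': no members", call. = FALSE)
      next
    }
    sets[[p[[1L]]]] <- list(genes = members, tfs = character())
  }
  if (dropped_total > 0L) {
    message("dropped ", dropped_total, " out-of-universe member(s)")
  }
  if (!is.null(tf_path)) {
    tf <- read_two_column_chr(tf_path)
    for (k in seq_along(tf$set)) {
      nm <- tf$set[k]
      if (!is.null(sets[[nm]])) {
        sets[[nm]]$tfs <- unique(c(sets[[nm]]$tfs, tf$tf[k]))
      }
    }
  }
  structure(sets, class = "gene_set_collection")
}

read_two_column_chr <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L) {
    stop("malformed line in ", path, call. = FALSE)
  }
  list(set = vapply(parts, `[[`, character(1L), 1L),
       tf = vapply(parts, `[[`, character(1L), 2L))
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d set(s)\n", length(x)))
  for (nm in head(names(x), 10L)) {
    cat(sprintf("  %s: %d genes, %d TFs\n",
                nm, length(x[[nm]]$genes), length(x[[nm]]$tfs)))
  }
  invisible(x)
}

#' Write an aggregated ranking to a TSV file
#'
#' Writes columns `gene`, `statistic`, `rank`, ordered by final rank
#' (statistic ascending, ties broken by gene identifier). An empty result
#' produces a header-only file.
#'
#' @param result an `aggregation_result` from [aggregate_ranks()], or any
#'   data frame with `gene`, `statistic` and `rank` columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ranked_list <- function(result, path) {
  if (!is.data.frame(result) ||
      !all(c("gene", "statistic", "rank") %in% names(result))) {
    stop("`result` must have columns gene, statistic, rank", call. = FALSE)
  }
  out <- result[order(result$rank), c("gene", "statistic", "rank")]
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write to ", path, call. = FALSE)
  invisible(path)
}

#' Read back a ranking written by [write_ranked_list()]
#'
#' @param path path to the TSV file.
#' @return Data frame with `gene`, `statistic`, `rank`, ordered by rank.
#' @export
read_ranked_list <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "numeric", "integer"),
                   comment.char = "#")
  names(df) <- c("gene", "statistic", "rank")
  df[order(df$rank), , drop = FALSE]
}
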