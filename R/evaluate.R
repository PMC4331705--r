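#' Construct a tuning grid
#'
#' Candidate values for the diffusion time `tau` and neighborhood weight
#' `lambda` of [cgi_update()], and the damping `d` of [generank_solve()].
#' The defaults span the no-network point (`lambda = 0`, `d = 0`) through
#' strongly network-dominated settings.
#'
#' @param taus nonnegative diffusion times.
#' @param lams nonnegative CGI neighborhood weights.
#' @param ds GeneRank damping values in `[0, 1)`.
#' @return An object of class `"tuning_grid"`.
#' @export
tuning_grid <- function(taus = c(0.01, 0.1, 0.5, 1),
                        lams = c(0, 0.1, 0.5, 1, 2, 5),
                        ds = c(0, 0.1, 0.3, 0.5, 0.7, 0.9)) {
  if (length(taus) == 0L || any(is.na(taus)) || any(taus < 0)) {
    stop("`taus` must be nonnegative", call. = FALSE)
  }
  if (length(lams) == 0L || any(is.na(lams)) || any(lams < 0)) {
    stop("`lams` must be nonnegative", call. = FALSE)
  }
  if (length(ds) == 0L || any(is.na(ds)) || any(ds < 0) || any(ds >= 1)) {
    stop("`ds` must lie in [0, 1)", call. = FALSE)
  }
  structure(list(taus = taus, lams = lams, ds = ds), class = "tuning_grid")
}

#' One-sided Wilcoxon rank-sum enrichment p-value
#'
#' Tests whether the `positives` sit higher (smaller final ranks) in an
#' aggregated list than the remaining genes. Genes in `excluded` are removed
#' from the comparison altogether — during validation the training genes are
#' excluded because they were used for parameter selection. The exact null
#' distribution is used when both groups have at most 20 genes; otherwise
#' the normal approximation with continuity and tie correction.
#'
#' @param result an `aggregation_result` from [aggregate_ranks()].
#' @param positives character vector of positive genes (subset of the
#'   universe).
#' @param excluded character vector of genes to drop from the comparison;
#'   must be disjoint from `positives`.
#' @return One-sided p-value in `(0, 1]`.
#' @export
wilcoxon_enrichment_p <- function(result, positives, excluded = character()) {
  if (!inherits(result, "aggregation_result")) {
    stop("`result` must be an aggregation_result", call. = FALSE)
  }
  positives <- unique(as.character(positives))
  excluded <- unique(as.character(excluded))
  if (length(intersect(positives, excluded)) > 0L) {
    stop("`positives` and `excluded` must be disjoint", call. = FALSE)
  }
  unknown <- setdiff(positives, result$gene)
  if (length(unknown) > 0L) {
    stop(length(unknown), " positive gene(s) not in the universe (e.g. ",
         unknown[1L], ")", call. = FALSE)
  }
  is_pos <- result$gene %in% positives
  is_exc <- result$gene %in% excluded
  r_pos <- result$rank[is_pos]
  r_bg <- result$rank[!is_pos & !is_exc]
  if (length(r_pos) == 0L || length(r_bg) == 0L) {
    stop("both the positive and background groups must be non-empty",
         call. = FALSE)
  }
  exact <- length(r_pos) <= 20L && length(r_bg) <= 20L
  p <- suppressWarnings(
    wilcox.test(r_pos, r_bg, alternative = "less", exact = exact)$p.value
  )
  min(max(p, .Machine$double.xmin), 1)
}

# normalize rank/score input to normal scores
as_zscores <- function(lists, ratio_cap = 0.9999) {
  if (inherits(lists, "score_matrix")) return(lists)
  if (inherits(lists, "rank_matrix")) {
    if (matrix_kind(lists) == "rank") lists <- ranks_to_ratios(lists)
    return(ratios_to_zscores(lists, ratio_cap = ratio_cap))
  }
  stop("`lists` must be a rank_matrix or score_matrix", call. = FALSE)
}

# Enumerate the tuned-and-aggregated candidate rankings for a tuning grid.
# Tuned scores do not depend on the training fold, so cross-validation
# computes each candidate once and reuses it across folds and rounds.
tuned_candidates <- function(lists, net, grid, tuner, aggregator,
                             kernels = NULL, neighbor_abs = TRUE) {
  z <- as_zscores(lists)
  if (tuner == "none") {
    return(list(list(params = list(tau = NA_real_, lam = NA_real_,
                                   d = NA_real_),
                     result = aggregate_ranks(scores_to_ranks(z), aggregator))))
  }
  out <- list()
  if (tuner == "cgi") {
    if (is.null(kernels)) kernels <- diffusion_kernels(net, grid$taus)
    for (tau in grid$taus) {
      kern <- kernels[[as.character(tau)]]
      for (lam in grid$lams) {
        tuned <- cgi_update(z, kern, lam, neighbor_abs = neighbor_abs)
        out[[length(out) + 1L]] <- list(
          params = list(tau = tau, lam = lam, d = NA_real_),
          result = aggregate_ranks(scores_to_ranks(tuned), aggregator)
        )
      }
    }
  } else if (tuner == "gr") {
    for (d in grid$ds) {
      tuned <- generank_solve(z, net, d, method = "direct")
      out[[length(out) + 1L]] <- list(
        params = list(tau = NA_real_, lam = NA_real_, d = d),
        result = aggregate_ranks(scores_to_ranks(tuned), aggregator)
      )
    }
  } else {
    stop("unknown tuner: ", tuner, call. = FALSE)
  }
  out
}

#' Select tuning parameters on a training gene set
#'
#' Exhaustive grid search: every candidate parameter setting is tuned,
#' aggregated, and scored by [wilcoxon_enrichment_p()] with the training
#' genes as positives; the setting with the lowest p-value wins, ties broken
#' by grid order.
#'
#' @param lists a [rank_matrix()] or [score_matrix()] of the input lists.
#' @param net a `gene_network` over the same universe.
#' @param training non-empty character vector of training genes.
#' @param grid a [tuning_grid()].
#' @param tuner `"cgi"` or `"gr"`.
#' @param aggregator `"endeavour"` or `"rra"`.
#' @param kernels optional precomputed [diffusion_kernels()] for
#'   `grid$taus` (CGI only).
#' @return List with `params` (tau/lam or d), `p` (achieved training
#'   p-value) and `result` (the selected aggregation).
#' @export
select_parameters <- function(lists, net, training, grid,
                              tuner = c("cgi", "gr"),
                              aggregator = c("endeavour", "rra"),
                              kernels = NULL) {
  tuner <- match.arg(tuner)
  aggregator <- match.arg(aggregator)
  if (length(training) == 0L) {
    stop("`training` must be non-empty", call. = FALSE)
  }
  cands <- tuned_candidates(lists, net, grid, tuner, aggregator,
                            kernels = kernels)
  ps <- vapply(cands, function(cand) {
    wilcoxon_enrichment_p(cand$result, training)
  }, numeric(1L))
  best <- which.min(ps)
  list(params = cands[[best]]$params, p = ps[best],
       result = cands[[best]]$result)
}

#' Repeated k-fold cross-validation of network-tuned aggregation
#'
#' Per round, the positive genes are randomly partitioned into `folds`
#' near-equal subsets. Each subset in turn plays the role of the small set
#' of *known* genes: it is the training set on which parameters are
#' selected (via [select_parameters()]), while the union of the other
#' subsets is the validation set whose enrichment is then tested with the
#' training genes excluded from the background. A full run emits
#' `rounds * folds` p-value records. With `tuner = "none"` no parameters
#' are tuned and the run reproduces plain Endeavour/RRA on identical
#' partitions, so baseline and network arms pair fold-by-fold under the
#' same seed.
#'
#' @param lists a [rank_matrix()] or [score_matrix()].
#' @param net a `gene_network` (ignored when `tuner = "none"`).
#' @param positives character vector of known genes; at least `folds` of
#'   them.
#' @param grid a [tuning_grid()].
#' @param tuner `"cgi"`, `"gr"` or `"none"`.
#' @param aggregator `"endeavour"` or `"rra"`.
#' @param rounds number of independent repetitions (default 10).
#' @param folds number of folds per round (default 10).
#' @param seed integer seed controlling the partitions.
#' @param kernels optional precomputed [diffusion_kernels()].
#' @return An `eval_result` data frame with columns `round`, `fold`,
#'   `n_train`, `tau`, `lam`, `d`, `p_train`, `p` and attributes `tuner`,
#'   `aggregator`.
#' @export
cross_validate <- function(lists, net, positives, grid = tuning_grid(),
                           tuner = c("cgi", "gr", "none"),
                           aggregator = c("endeavour", "rra"),
                           rounds = 10L, folds = 10L, seed = 1L,
                           kernels = NULL) {
  tuner <- match.arg(tuner)
  aggregator <- match.arg(aggregator)
  positives <- unique(as.character(positives))
  if (length(positives) < folds) {
    stop("need at least `folds` = ", folds, " positive genes, got ",
         length(positives), call. = FALSE)
  }
  n_pos <- length(positives)
  fold_ids <- with_seed(seed, {
    lapply(seq_len(rounds), function(r) {
      rep_len(seq_len(folds), n_pos)[sample.int(n_pos)]
    })
  })
  cands <- tuned_candidates(lists, net, grid, tuner, aggregator,
                            kernels = kernels)
  p_train_mat <- NULL

  rows <- vector("list", rounds * folds)
  k <- 0L
  for (r in seq_len(rounds)) {
    ids <- fold_ids[[r]]
    for (f in seq_len(folds)) {
      training <- positives[ids == f]
      validation <- positives[ids != f]
      if (length(cands) == 1L) {
        best <- 1L
        p_train <- wilcoxon_enrichment_p(cands[[1L]]$result, training)
      } else {
        ps <- vapply(cands, function(cand) {
          wilcoxon_enrichment_p(cand$result, training)
        }, numeric(1L))
        best <- which.min(ps)
        p_train <- ps[best]
      }
      p_val <- wilcoxon_enrichment_p(cands[[best]]$result, validation,
                                     excluded = training)
      pr <- cands[[best]]$params
      k <- k + 1L
      rows[[k]] <- data.frame(round = r, fold = f,
                              n_train = length(training),
                              tau = pr$tau, lam = pr$lam, d = pr$d,
                              p_train = p_train, p = p_val)
    }
  }
  out <- do.call(rbind, rows)
  structure(out, tuner = tuner, aggregator = aggregator,
            class = c("eval_result", "data.frame"))
}

#' Log-fold improvement of the network-tuned p-value over the baseline
#'
#' `log10(p_base / p_net)`: positive when integrating the network yields a
#' smaller (better) validation p-value than plain aggregation.
#'
#' @param p_base baseline p-value(s) in `(0, 1]`.
#' @param p_net network-tuned p-value(s) in `(0, 1]`.
#' @return Numeric vector of log10 fold changes.
#' @export
log_p_fold <- function(p_base, p_net) {
  if (any(p_base <= 0) || any(p_base > 1) || any(p_net <= 0) || any(p_net > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  log10(p_base / p_net)
}

#' Pair baseline and network-tuned cross-validation records
#'
#' Joins two [cross_validate()] results on `(round, fold)` — valid because
#' the same seed gives identical partitions — and computes the per-fold
#' [log_p_fold()].
#'
#' @param base `eval_result` from the `tuner = "none"` arm.
#' @param tuned `eval_result` from the network arm, same seed.
#' @return Data frame with `round`, `fold`, `n_train`, `p_base`, `p_net`,
#'   `log_p_fold`.
#' @export
paired_log_p_fold <- function(base, tuned) {
  stopifnot(inherits(base, "eval_result"), inherits(tuned, "eval_result"))
  m <- merge(base[, c("round", "fold", "n_train", "p")],
             tuned[, c("round", "fold", "p")],
             by = c("round", "fold"), suffixes = c("_base", "_net"))
  names(m)[names(m) == "p_base"] <- "p_base"
  m$log_p_fold <- log_p_fold(m$p_base, m$p_net)
  m[order(m$round, m$fold), , drop = FALSE]
}

#' Spearman correlation of network improvement with training-set size
#'
#' Within each cross-validation round, gene sets are summarized by their
#' mean [log_p_fold()] and correlated (Spearman) with the number of
#' training genes across sets, with a one-sided test for positive
#' correlation. Returns the mean and standard deviation of the per-round
#' correlations and the mean one-sided p-value.
#'
#' @param records data frame with columns `gene_set`, `round`,
#'   `log_p_fold` (e.g. stacked [paired_log_p_fold()] outputs).
#' @param training_sizes named numeric vector: training-set size per gene
#'   set.
#' @return List with `mean_correlation`, `sd_correlation`, `mean_p` and the
#'   per-round data frame `rounds`.
#' @export
correlation_with_training_size <- function(records, training_sizes) {
  if (!all(c("gene_set", "round", "log_p_fold") %in% names(records))) {
    stop("`records` must have columns gene_set, round, log_p_fold",
         call. = FALSE)
  }
  sets <- unique(records$gene_set)
  if (length(sets) < 3L) {
    stop("need at least 3 gene sets to correlate, got ", length(sets),
         call. = FALSE)
  }
  if (is.null(names(training_sizes)) || !all(sets %in% names(training_sizes))) {
    stop("`training_sizes` must be named with every gene set", call. = FALSE)
  }
  per_round <- lapply(sort(unique(records$round)), function(r) {
    sub <- records[records$round == r, , drop = FALSE]
    mlpf <- tapply(sub$log_p_fold, sub$gene_set, mean)
    x <- as.numeric(training_sizes[names(mlpf)])
    y <- as.numeric(mlpf)
    if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
      warning("constant values in round ", r, "; correlation undefined",
              call. = FALSE)
      return(data.frame(round = r, correlation = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(
      cor.test(x, y, method = "spearman", alternative = "greater")
    )
    data.frame(round = r, correlation = unname(ct$estimate), p = ct$p.value)
  })
  per_round <- do.call(rbind, per_round)
  list(mean_correlation = mean(per_round$correlation, na.rm = TRUE),
       sd_correlation = sd(per_round$correlation, na.rm = TRUE),
       mean_p = mean(per_round$p, na.rm = TRUE),
       rounds = per_round)
}

#' Filter gene sets by size and regulator count
#'
#' Keeps sets with at least `min_genes` member genes and a TF count between
#' `min_tfs` and `max_tfs` inclusive — enough known genes for stable
#' statistics, and a bounded number of per-TF rank lists to aggregate.
#'
#' @param gsc a `gene_set_collection`.
#' @param min_genes minimum member-gene count (default 30).
#' @param min_tfs minimum TF count (default 5).
#' @param max_tfs maximum TF count (default 40).
#' @return The filtered `gene_set_collection`.
#' @export
filter_gene_sets <- function(gsc, min_genes = 30L, min_tfs = 5L,
                             max_tfs = 40L) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  keep <- vapply(gsc, function(s) {
    length(s$genes) >= min_genes &&
      length(s$tfs) >= min_tfs && length(s$tfs) <= max_tfs
  }, logical(1L))
  structure(gsc[keep], class = "gene_set_collection")
}

#' Build per-TF co-expression rank lists from an expression matrix
#'
#' For each transcription factor, genes are ranked by descending absolute
#' Pearson correlation between their expression profile and the TF's
#' profile (strong co-expression of either sign ranks high). The TF stays
#' in its own list with `|r| = 1` so that every list covers the same
#' universe. Zero-variance profiles get correlation 0 with a warning.
#'
#' @param expr numeric matrix, genes in rows (rownames = identifiers),
#'   conditions in columns (at least 3).
#' @param tfs character vector of TF identifiers present in `expr`.
#' @return A [rank_matrix()] of kind `"rank"`, one column per TF.
#' @export
coexpression_rank_lists <- function(expr, tfs) {
  expr <- check_gene_matrix(expr, "expression matrix")
  if (ncol(expr) < 3L) {
    stop("need at least 3 conditions", call. = FALSE)
  }
  tfs <- as.character(tfs)
  missing <- setdiff(tfs, rownames(expr))
  if (length(missing) > 0L) {
    stop("TF(s) not in the expression matrix: ",
         paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  zero_var <- apply(expr, 1L, sd) == 0
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance profile(s); correlations set to 0",
            call. = FALSE)
  }
  scores <- vapply(tfs, function(tf) {
    prof <- expr[tf, ]
    if (sd(prof) == 0) {
      r <- rep(0, nrow(expr))
    } else {
      r <- suppressWarnings(as.numeric(cor(t(expr), prof)))
      r[is.na(r)] <- 0
    }
    s <- abs(r)
    s[rownames(expr) == tf] <- 1
    s
  }, numeric(nrow(expr)))
  scores <- matrix(scores, nrow = nrow(expr),
                   dimnames = list(rownames(expr), tfs))
  scores_to_ranks(score_matrix(scores, meaning = "tuned"))
}
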