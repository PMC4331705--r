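#' Configuration for the synthetic fixture generator
#'
#' Describes a planted-partition benchmark: a set of positive genes whose
#' network module is wired densely (`p_in`) against a sparse background
#' (`p_out`), and whose latent association scores are shifted upward by
#' `mu` in every rank list. This emulates the working assumption of
#' network-tuned aggregation — functionally related genes are both
#' network-proximal and high-ranked — with controllable strength.
#'
#' @param n_genes universe size (default 500).
#' @param n_lists number of rank lists (default 5).
#' @param n_positives number of planted positive genes (default 40).
#' @param p_in edge probability inside the planted module (default 0.3).
#' @param p_out background edge probability (default 0.01).
#' @param mu latent mean score shift of positive genes, on the normal-score
#'   scale (default 1.5; 0 gives a pure null fixture).
#' @param list_sds per-list noise standard deviations, recycled to
#'   `n_lists` (default 1 for every list; raise one entry to emulate an
#'   unreliable list).
#' @param concordance fraction of positives placed inside the dense module
#'   (default 1); the module is padded with background genes when < 1.
#' @param n_tfs number of pseudo-TF annotations attached to the planted
#'   gene set (default 5, enough to pass [filter_gene_sets()]).
#' @param seed integer seed.
#' @return An object of class `"fixture_config"`.
#' @export
fixture_config <- function(n_genes = 500L, n_lists = 5L, n_positives = 40L,
                           p_in = 0.3, p_out = 0.01, mu = 1.5,
                           list_sds = 1, concordance = 1, n_tfs = 5L,
                           seed = 1L) {
  stopifnot(n_genes >= 2L, n_lists >= 1L,
            n_positives >= 1L, n_positives < n_genes)
  if (!(p_out >= 0 && p_out <= p_in && p_in <= 1)) {
    stop("need 0 <= p_out <= p_in <= 1", call. = FALSE)
  }
  if (mu < 0) stop("`mu` must be nonnegative", call. = FALSE)
  if (concordance < 0 || concordance > 1) {
    stop("`concordance` must lie in [0, 1]", call. = FALSE)
  }
  list_sds <- rep_len(list_sds, n_lists)
  if (any(list_sds <= 0)) stop("`list_sds` must be positive", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes), n_lists = as.integer(n_lists),
                 n_positives = as.integer(n_positives), p_in = p_in,
                 p_out = p_out, mu = mu, list_sds = list_sds,
                 concordance = concordance, n_tfs = as.integer(n_tfs),
                 seed = as.integer(seed)),
            class = "fixture_config")
}

#' Generate a synthetic planted-signal fixture
#'
#' Produces, under one seed: a planted-partition network (the module wired
#' with `p_in`, everything else with `p_out`), integer rank lists obtained
#' by ranking latent scores `mu * 1{positive} + N(0, sd_j)` per list
#' (largest score = rank 1), and a one-set gene set collection holding the
#' positives with pseudo-TF annotations. Identical seeds give identical
#' fixtures.
#'
#' @param cfg a [fixture_config()].
#' @return List with elements `network` (a `gene_network`), `ranks` (a
#'   [rank_matrix()] of kind `"rank"`), `gene_sets` (a
#'   `gene_set_collection`), `positives` (character) and `config`.
#' @export
generate_fixture <- function(cfg) {
  stopifnot(inherits(cfg, "fixture_config"))
  n <- cfg$n_genes
  genes <- sprintf("g%0*d", nchar(n), seq_len(n))

  with_seed(cfg$seed, {
    positives <- sort(sample(genes, cfg$n_positives))
    n_in <- round(cfg$concordance * cfg$n_positives)
    module <- sample(positives, n_in)
    pad <- sample(setdiff(genes, positives), cfg$n_positives - n_in)
    module <- c(module, pad)
    in_module <- genes %in% module

    prob <- matrix(cfg$p_out, n, n)
    prob[in_module, in_module] <- cfg$p_in
    u <- matrix(runif(n * n), n, n)
    adj_upper <- (u < prob) & upper.tri(u)
    edge_idx <- which(adj_upper, arr.ind = TRUE)
    if (nrow(edge_idx) == 0L) {
      stop("degenerate densities: the generated graph has no edges",
           call. = FALSE)
    }
    net <- gene_network(cbind(genes[edge_idx[, 1L]], genes[edge_idx[, 2L]]),
                        universe = genes)

    latent <- cfg$mu * (genes %in% positives)
    scores <- vapply(seq_len(cfg$n_lists), function(j) {
      latent + rnorm(n, sd = cfg$list_sds[j])
    }, numeric(n))
    scores <- matrix(scores, nrow = n,
                     dimnames = list(genes,
                                     paste0("list", seq_len(cfg$n_lists))))
    ranks <- scores_to_ranks(score_matrix(scores, meaning = "tuned"))

    gsc <- structure(
      list(planted = list(genes = positives,
                          tfs = sprintf("TF%02d", seq_len(cfg$n_tfs)))),
      class = "gene_set_collection"
    )

    list(network = net, ranks = ranks, gene_sets = gsc,
         positives = positives, config = cfg)
  })
}
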