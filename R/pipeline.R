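#' Network-tuned aggregation of rank lists in one call
#'
#' Wires the full pipeline: rank ratios, normal scores, network update (CGI
#' or GeneRank) and aggregation (Endeavour or RRA), in either composition
#' order. `order = "tune-then-aggregate"` updates each list with the network
#' and then aggregates (the CGI_Endeavour / CGI_RRA / GR_Endeavour / GR_RRA
#' family); `order = "aggregate-then-tune"` first aggregates the raw lists,
#' converts the aggregate statistic back to a single rank list, and updates
#' that one list with the network (the Endeavour_CGI / RRA_GR family).
#' `tuner = "none"` is plain aggregation.
#'
#' @param rm a [rank_matrix()] (either kind).
#' @param net a `gene_network`; may be `NULL` when `tuner = "none"`.
#' @param tuner `"none"`, `"cgi"` or `"gr"`.
#' @param aggregator `"endeavour"` or `"rra"`.
#' @param order composition order, see above.
#' @param tau CGI diffusion time (ignored unless `tuner = "cgi"`).
#' @param lam CGI neighborhood weight.
#' @param d GeneRank damping.
#' @param ratio_cap passed to [ratios_to_zscores()].
#' @param neighbor_abs passed to [cgi_update()].
#' @param kernel optional precomputed `kernel_matrix` (CGI only).
#' @return An `aggregation_result`.
#' @export
network_tuned_aggregate <- function(rm, net = NULL,
                                    tuner = c("none", "cgi", "gr"),
                                    aggregator = c("endeavour", "rra"),
                                    order = c("tune-then-aggregate",
                                              "aggregate-then-tune"),
                                    tau = 0.1, lam = 1, d = 0.5,
                                    ratio_cap = 0.9999, neighbor_abs = TRUE,
                                    kernel = NULL) {
  tuner <- match.arg(tuner)
  aggregator <- match.arg(aggregator)
  order <- match.arg(order)
  if (!inherits(rm, "rank_matrix")) {
    stop("`rm` must be a rank_matrix", call. = FALSE)
  }
  if (matrix_kind(rm) == "rank") rm <- ranks_to_ratios(rm)

  if (tuner == "none") {
    return(aggregate_ranks(rm, aggregator))
  }
  if (is.null(net) && is.null(kernel)) {
    stop("a network (or precomputed kernel) is required when tuner != 'none'",
         call. = FALSE)
  }
  if (!is.null(net) && !identical(net$genes, rownames(rm))) {
    n_off <- length(union(setdiff(net$genes, rownames(rm)),
                          setdiff(rownames(rm), net$genes)))
    stop("network and rank lists disagree on the universe (",
         n_off, " gene(s) differ)", call. = FALSE)
  }

  tune_scores <- function(z) {
    if (tuner == "cgi") {
      kern <- if (is.null(kernel)) diffusion_kernel(net, tau) else kernel
      cgi_update(z, kern, lam, neighbor_abs = neighbor_abs)
    } else {
      generank_solve(z, net, d)
    }
  }

  if (order == "tune-then-aggregate") {
    z <- ratios_to_zscores(rm, ratio_cap = ratio_cap)
    tuned <- tune_scores(z)
    aggregate_ranks(scores_to_ranks(tuned), aggregator)
  } else {
    agg <- aggregate_ranks(rm, aggregator)
    one <- matrix(agg$rank, ncol = 1L,
                  dimnames = list(agg$gene, "aggregate"))
    z1 <- ratios_to_zscores(ranks_to_ratios(rank_matrix(one, "rank")),
                            ratio_cap = ratio_cap)
    tuned <- tune_scores(z1)
    final <- scores_to_ranks(tuned)
    genes <- rownames(final)
    structure(
      data.frame(gene = genes, statistic = -as.numeric(unclass(tuned)),
                 rank = as.integer(unclass(final)[, 1L]),
                 stringsAsFactors = FALSE, row.names = NULL),
      method = paste0(aggregator, "_", tuner),
      class = c("aggregation_result", "data.frame")
    )
  }
}
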