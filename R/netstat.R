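#' Induce a condition-specific subnetwork
#'
#' Retains the edges whose miRNA belongs to `mirna_seed` and whose gene
#' belongs to `gene_seed` (either seed may be `"all"`); isolated nodes are
#' dropped. Seeding by differentially expressed miRNAs yields the
#' miRNA-conditioned network (all their targets kept); seeding by
#' differentially expressed genes yields the gene-conditioned network (all
#' their regulators kept).
#'
#' @param reference a [regulatory_network].
#' @param mirna_seed character vector of miRNA ids, or `"all"`.
#' @param gene_seed character vector of gene ids, or `"all"`.
#' @return The induced [regulatory_network].
#' @export
induce_network <- function(reference, mirna_seed = "all", gene_seed = "all") {
  stopifnot(inherits(reference, "regulatory_network"))
  keep <- rep(TRUE, nrow(reference$edges))
  if (!identical(mirna_seed, "all")) {
    unknown <- setdiff(mirna_seed, reference$mirnas)
    if (length(unknown) > 0) {
      message(length(unknown), " seed miRNA(s) not in the reference network; ignored")
    }
    keep <- keep & reference$edges$mirna %in% mirna_seed
  }
  if (!identical(gene_seed, "all")) {
    unknown <- setdiff(gene_seed, reference$genes)
    if (length(unknown) > 0) {
      message(length(unknown), " seed gene(s) not in the reference network; ignored")
    }
    keep <- keep & reference$edges$gene %in% gene_seed
  }
  if (!any(keep)) stop("induced network is empty")
  regulatory_network(reference$edges$mirna[keep], reference$edges$gene[keep])
}

#' Exclusive out-degree (NOD) of a miRNA
#'
#' The number of the miRNA's in-network targets whose only in-network
#' regulator is that miRNA (gene in-degree 1). This measures the
#' independent, non-redundant regulatory power of the miRNA: knocking it
#' out leaves those targets unregulated within the network.
#'
#' @param net a [regulatory_network].
#' @param mirna a miRNA id present in `net`.
#' @return Non-negative integer count.
#' @export
compute_nod <- function(net, mirna) {
  stopifnot(inherits(net, "regulatory_network"))
  if (!mirna %in% net$mirnas) stop("miRNA not in network: ", mirna)
  indeg <- table(net$edges$gene)
  targets <- net$edges$gene[net$edges$mirna == mirna]
  sum(indeg[targets] == 1)
}

#' Transcription-factor percentage (TFP) of a miRNA
#'
#' The fraction of the miRNA's in-network targets annotated as
#' transcription factors. A miRNA with high TFP sits upstream of much of
#' the regulatory cascade: perturbing it propagates through the TFs it
#' controls.
#'
#' @param net a [regulatory_network].
#' @param mirna a miRNA id present in `net` with out-degree >= 1.
#' @param tf_set character vector of TF gene symbols.
#' @return Proportion in \[0, 1\].
#' @export
compute_tfp <- function(net, mirna, tf_set) {
  stopifnot(inherits(net, "regulatory_network"))
  if (!mirna %in% net$mirnas) stop("miRNA not in network: ", mirna)
  targets <- net$edges$gene[net$edges$mirna == mirna]
  if (length(targets) == 0) stop("TFP undefined for out-degree 0: ", mirna)
  mean(targets %in% tf_set)
}

#' Per-miRNA NOD/TFP with significance against a network null
#'
#' Computes out-degree, NOD and TFP for every miRNA in the network and a
#' one-sided (upper) p-value for each index. The default `"rewire"` mode
#' compares the observed values with `n_null` degree-preserving rewirings
#' of the bipartite graph (edge-swap chains of `swap_factor * n_edges`
#' attempted swaps per replicate), using the add-one estimate
#' `p = (1 + #\{null >= observed\}) / (n_null + 1)`. The `"rank"` mode
#' instead scores each miRNA's observed value against the cross-miRNA
#' empirical distribution (`p = mean(values >= observed)`), a cheap
#' Wilcoxon-type relative ranking.
#'
#' @param net a [regulatory_network].
#' @param tf_set character vector of TF gene symbols.
#' @param n_null number of null replicates (rewire mode), >= 100.
#' @param seed integer seed; results are reproducible for a fixed seed.
#' @param mode `"rewire"` (default) or `"rank"`.
#' @param swap_factor attempted swaps per replicate as a multiple of the
#'   edge count.
#' @return data.frame with columns `mirna_id`, `out_degree`, `nod`, `tfp`,
#'   `p_nod`, `p_tfp`, ordered by `mirna_id`.
#' @export
mirna_network_stats <- function(net, tf_set, n_null = 1000, seed = 1,
                                mode = c("rewire", "rank"),
                                swap_factor = 10) {
  stopifnot(inherits(net, "regulatory_network"))
  mode <- match.arg(mode)
  mirnas <- net$mirnas
  mi <- match(net$edges$mirna, mirnas) - 1L
  genes <- net$genes
  ge <- match(net$edges$gene, genes) - 1L
  indeg <- tabulate(ge + 1L, nbins = length(genes))
  tf_flag <- genes %in% tf_set
  out_degree <- tabulate(mi + 1L, nbins = length(mirnas))
  nod <- integer(length(mirnas))
  tf_cnt <- integer(length(mirnas))
  excl <- indeg[ge + 1L] == 1L
  for (e in seq_along(mi)) {
    i <- mi[e] + 1L
    if (excl[e]) nod[i] <- nod[i] + 1L
    if (tf_flag[ge[e] + 1L]) tf_cnt[i] <- tf_cnt[i] + 1L
  }
  tfp <- tf_cnt / out_degree

  if (mode == "rewire") {
    if (n_null < 100) stop("n_null must be at least 100")
    set.seed(as.integer(seed))
    cnt <- .rewire_null_counts(mi, ge, length(mirnas), length(genes),
                               tf_flag, as.integer(nod), as.integer(tf_cnt),
                               as.integer(n_null), swap_factor)
    p_nod <- (1 + cnt$ge_nod) / (n_null + 1)
    p_tfp <- (1 + cnt$ge_tfp) / (n_null + 1)
  } else {
    p_nod <- vapply(nod, function(v) mean(nod >= v), numeric(1))
    p_tfp <- vapply(tfp, function(v) mean(tfp >= v), numeric(1))
  }
  data.frame(mirna_id = mirnas, out_degree = out_degree, nod = nod,
             tfp = tfp, p_nod = p_nod, p_tfp = p_tfp,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select candidate biomarker miRNAs from two condition networks
#'
#' A miRNA is a candidate when both its NOD and its TFP are significantly
#' high (`p < alpha`, strict) in *both* condition-specific networks. The
#' expression direction is attached from the miRNA differential-expression
#' results when available.
#'
#' @param stats_net1,stats_net2 data.frames from [mirna_network_stats].
#' @param de_mirnas data.frame from [de_mirnas] (may be `NULL`).
#' @param alpha significance threshold in (0, 1).
#' @return data.frame with one row per candidate, sorted by `mirna_id`:
#'   columns `mirna_id`, `nod1`, `tfp1`, `nod2`, `tfp2`, `p_nod1`,
#'   `p_tfp1`, `p_nod2`, `p_tfp2`, `direction`.
#' @export
select_candidates <- function(stats_net1, stats_net2, de_mirnas = NULL,
                              alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  sig1 <- stats_net1[stats_net1$p_nod < alpha & stats_net1$p_tfp < alpha, ]
  sig2 <- stats_net2[stats_net2$p_nod < alpha & stats_net2$p_tfp < alpha, ]
  ids <- sort(intersect(sig1$mirna_id, sig2$mirna_id))
  s1 <- sig1[match(ids, sig1$mirna_id), ]
  s2 <- sig2[match(ids, sig2$mirna_id), ]
  direction <- rep(NA_character_, length(ids))
  if (!is.null(de_mirnas) && nrow(de_mirnas) > 0) {
    hit <- match(ids, de_mirnas$feature_id)
    direction[!is.na(hit)] <- de_mirnas$direction[hit[!is.na(hit)]]
  }
  data.frame(mirna_id = ids,
             nod1 = s1$nod, tfp1 = s1$tfp, nod2 = s2$nod, tfp2 = s2$tfp,
             p_nod1 = s1$p_nod, p_tfp1 = s1$p_tfp,
             p_nod2 = s2$p_nod, p_tfp2 = s2$p_tfp,
             direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}
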