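#' End-to-end biomarker screen
#'
#' Runs the full screening pipeline: assemble the reference network from
#' interaction evidence, screen differentially expressed miRNAs (t test)
#' and genes (six statistics, method chosen by cross-study overlap of the
#' top lists), induce the two condition-specific networks (miRNA-seeded
#' and gene-seeded), compute NOD/TFP with rewiring-null significance in
#' each, and intersect the significant miRNAs into the candidate set.
#'
#' @param evidence interaction evidence data.frame (see
#'   [load_interactions]).
#' @param tf_list character vector of transcription-factor gene symbols.
#' @param mirna_study an [expression_study] of miRNA expression.
#' @param mrna_studies list of [expression_study] of mRNA expression.
#' @param alpha significance threshold used for the miRNA t test and the
#'   NOD/TFP tests.
#' @param top_fraction top fraction of ranked genes kept per study.
#' @param n_null rewiring-null replicates per network.
#' @param seed integer seed for the null model.
#' @param filter_config a [prediction_filter_config].
#' @return list with components `reference`, `de_mirnas`, `de_method`
#'   (name of the selected gene statistic), `de_genes`, `net1`, `net2`,
#'   `stats_net1`, `stats_net2`, `candidates`.
#' @export
run_biomarker_screen <- function(evidence, tf_list, mirna_study,
                                 mrna_studies, alpha = 0.05,
                                 top_fraction = 0.4, n_null = 499,
                                 seed = 1,
                                 filter_config = prediction_filter_config()) {
  predicted <- filter_predictions(evidence, filter_config)
  reference <- build_reference_network(evidence, predicted)

  de_mi <- de_mirnas(mirna_study, alpha = alpha)
  lists_by_method <- lapply(stats::setNames(.de_methods, .de_methods),
                            function(m) {
                              de_genes(mrna_studies, method = m,
                                       top_fraction = top_fraction)
                            })
  sel <- select_method_by_overlap(lists_by_method)
  # the first study is the training dataset; its list seeds the
  # gene-conditioned network
  de_gene_list <- lists_by_method[[sel$best]][[1]]

  net1 <- induce_network(reference,
                         mirna_seed = intersect(de_mi$feature_id,
                                                reference$mirnas))
  net2 <- induce_network(reference,
                         gene_seed = intersect(de_gene_list,
                                               reference$genes))
  stats1 <- mirna_network_stats(net1, tf_list, n_null = n_null, seed = seed)
  stats2 <- mirna_network_stats(net2, tf_list, n_null = n_null,
                                seed = seed + 1L)
  cand <- select_candidates(stats1, stats2, de_mi, alpha = alpha)
  list(reference = reference, de_mirnas = de_mi, de_method = sel$best,
       de_genes = de_gene_list, net1 = net1, net2 = net2,
       stats_net1 = stats1, stats_net2 = stats2, candidates = cand)
}
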