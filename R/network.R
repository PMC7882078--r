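#' Directed bipartite miRNA-to-gene regulatory network
#'
#' A `regulatory_network` stores a deduplicated directed edge set from
#' miRNAs to target genes, together with the two node sets derived from the
#' edges. The graph is bipartite: an identifier may not appear on both
#' sides.
#'
#' @param mirna character vector of miRNA identifiers (edge tails).
#' @param gene character vector of gene symbols (edge heads), same length.
#' @return An object of class `regulatory_network` with components
#'   `edges` (two-column character data.frame `mirna`, `gene`), `mirnas`
#'   and `genes` (sorted unique node sets).
#' @examples
#' net <- regulatory_network(c("m1", "m1", "m2"), c("g1", "g2", "g2"))
#' network_summary(net)
#' @export
regulatory_network <- function(mirna, gene) {
  mirna <- as.character(mirna)
  gene <- as.character(gene)
  if (length(mirna) != length(gene)) {
    stop("`mirna` and `gene` must have the same length")
  }
  keep <- !duplicated(paste(mirna, gene, sep = "\r"))
  edges <- data.frame(mirna = mirna[keep], gene = gene[keep],
                      stringsAsFactors = FALSE)
  mirnas <- sort(unique(edges$mirna))
  genes <- sort(unique(edges$gene))
  overlap <- intersect(mirnas, genes)
  if (length(overlap) > 0) {
    stop("network is not bipartite; identifiers on both sides: ",
         paste(utils::head(overlap, 5), collapse = ", "))
  }
  structure(list(edges = edges, mirnas = mirnas, genes = genes),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("regulatory_network: %d miRNAs, %d genes, %d edges\n",
              length(x$mirnas), length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Summarize a regulatory network
#'
#' Node and edge counts plus mean per-node degrees on each side. The mean
#' miRNA (out-)degree equals `n_edges / n_mirnas` and the mean gene
#' (in-)degree equals `n_edges / n_genes`.
#'
#' @param net a [regulatory_network].
#' @return A list with `n_mirnas`, `n_genes`, `n_edges`,
#'   `avg_mirna_degree`, `avg_gene_degree`.
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  if (nrow(net$edges) == 0) stop("cannot summarize an empty network")
  list(n_mirnas = length(net$mirnas),
       n_genes = length(net$genes),
       n_edges = nrow(net$edges),
       avg_mirna_degree = nrow(net$edges) / length(net$mirnas),
       avg_gene_degree = nrow(net$edges) / length(net$genes))
}

#' Write a network as a two-column tab-separated edge list
#'
#' @param net a [regulatory_network].
#' @param path output file path; columns `mirna` and `gene` with header.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "regulatory_network"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a network from a two-column tab-separated edge list
#'
#' @param path file with header columns `mirna` and `gene`.
#' @return A [regulatory_network].
#' @export
read_edge_list <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mirna", "gene") %in% names(tab))) {
    stop("edge list must have columns 'mirna' and 'gene': ", path)
  }
  regulatory_network(tab$mirna, tab$gene)
}
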