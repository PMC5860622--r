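#' Published per-dataset interactome summary statistics
#'
#' The reported summary table for interolog predictions over 11
#' *Schmidtea mediterranea* transcriptome datasets, shipped as reference
#' data: per dataset, the total contig count, contigs with a resolved
#' human homolog, distinct human homologs, contigs entering the predicted
#' interactome, predicted interaction count, average degree
#' (interactions/nodes) and the percentage of predicted interactions whose
#' human pair is a reference-interactome edge. Used to cross-check the
#' summarization and correlation operations against printed values.
#'
#' @return Data frame with one row per transcriptome dataset.
#' @export
published_network_summaries <- function() {
  path <- system.file("extdata", "smed_network_summaries.tsv",
                      package = "interologr", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
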