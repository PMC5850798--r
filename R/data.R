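#' Published zebrafish 3R-ohnolog anatomical enrichment summary
#'
#' The 25 anatomical structures reported as significantly enriched
#' (FDR < 10%, weight algorithm) for expression of zebrafish 3R ohnologs
#' in the in situ hybridization analysis this package re-implements:
#' per structure, the number of genes with annotated expression, the
#' observed and expected numbers of 3R ohnologs, the enrichment fold
#' (observed/expected, two decimals), p-value and FDR. Used as a worked
#' example and as a consistency check that [fold_enrichment()] reproduces
#' the printed fold column from the printed observed/expected pairs.
#'
#' @return data.frame with columns `term_id`, `term_name`, `n_expressed`,
#'   `n_observed`, `n_expected`, `fold`, `p`, `fdr`.
#' @export
ohnolog_enrichment_reference <- function() {
  read.delim(system.file("extdata", "zebrafish_3r_enrichment_table.tsv",
                         package = "ohnologR"),
             stringsAsFactors = FALSE)
}
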