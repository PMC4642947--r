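# Published aggregate rows for the FliM/FliG switch-complex networks.

#' Published switch-complex network aggregate rows
#'
#' The raw per-network aggregates (sum of positive correlations, element
#' counts) published for the flagellar switch FliM_M/FliG coevolution
#' networks, together with the published strength S_M and connectivity C
#' values and their printed precision.  Each group (\code{matrix} column)
#' carries its own \code{randomized} reference row.  These rows serve as
#' inputs to \code{\link{metricsFromAggregates}}: recomputing C and S_M
#' from the raw columns and the randomized row reproduces the published
#' values, the round-trip check on the metric arithmetic.
#'
#' The masked (CW/CCW) mutation-network rows are flagged: their published
#' S_M values are not recoverable from the printed aggregates under the
#' whole-matrix randomized normalization (their normalization convention
#' is ambiguous), while their C values are.
#'
#' @return data.frame with columns matrix, label, sum_pos, n_corr, n_pos,
#'   n_matrix, C, C_digits, S_M, S_M_digits, mutation_network.
#' @export
referenceAggregates <- function() {
  path <- system.file("extdata", "switch_network_aggregates.tsv",
                      package = "CoevoNet", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
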