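#' Published per-source quality table of the AqSolDB sub-datasets
#'
#' The per-source quality rows reported for the nine AqSolDB
#' sub-datasets (A-I): raw and filtered sizes, the number of multi-lab
#' values behind each SD estimate, and the pooled multi-lab SD in LogS.
#' Shipped as a plain-text reference so the selection logic can be
#' exercised (and its published decisions reproduced) without
#' downloading the database; recomputing these quantities from the raw
#' accession is described in the README.
#'
#' @return Data frame with columns `source_id`, `size`, `filtered_size`,
#'   `n_sd`, `sd`.
#' @export
reference_quality_table <- function() {
  utils::read.csv(system.file("extdata", "aqsoldb_table1.csv",
                              package = "soluq", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
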