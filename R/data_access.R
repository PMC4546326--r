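#' Published lung-SCC candidate driven genes
#'
#' A small bundled table of candidate CNV-driven genes reported for a lung
#' squamous-cell carcinoma tumor/normal cohort: chromosome, gene symbol,
#' gene-level log2 absolute copy number (neutral = 1) and log2 fold change
#' (tumor vs normal), plus the karyotype band. Useful as a worked example
#' for [classify_driven()] and [chromosome_summary()].
#'
#' @return data.frame with columns `chromosome`, `gene`,
#'   `log2_copy_number`, `log2_fc`, `karyotype_band`.
#' @examples
#' cand <- lusc_candidates()
#' driven <- classify_driven(cand)
#' nrow(driven)
#' chromosome_summary(driven)
#' @export
lusc_candidates <- function() {
  path <- system.file("extdata", "lusc_candidates.tsv", package = "cnvdrive",
                      mustWork = TRUE)
  read_tsv(path)
}
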