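#' Intersect CNV genes with the expression platform and the DEG list
#'
#' The funnel from recurrent CNV genes to driven-gene candidates: first
#' restrict the CNV gene list to genes actually measured on the expression
#' platform, then to those passing the DEG screen.
#'
#' @param cnv_genes character vector of recurrent CNV gene symbols.
#' @param deg_genes character vector of DEG symbols.
#' @param measured_genes character vector of all genes on the platform.
#' @return list with `measured` (CNV genes measured on the platform) and
#'   `deg` (those that are also DEGs), both in `cnv_genes` order.
#' @export
overlap_genes <- function(cnv_genes, deg_genes, measured_genes) {
  measured <- cnv_genes[cnv_genes %in% measured_genes]
  list(measured = measured, deg = measured[measured %in% deg_genes])
}

#' Classify CNV-driven genes by sign concordance
#'
#' A gene is CNV-driven when its expression change agrees in direction with
#' its copy-number change: up-regulated and duplicated (log2 copy number
#' above the neutral value 1, log2 fold change positive), or down-regulated
#' and deleted. Concordance is evaluated on signs relative to the neutral
#' values only — no magnitude condition is applied at this step.
#'
#' @param candidates data.frame with columns `gene`, `chromosome`,
#'   `log2_copy_number`, `log2_fc`; optional extra columns (e.g. a
#'   karyotype band) are carried through.
#' @return data.frame of class `"driven_genes"`: the concordant rows, with
#'   `cnv_state` and `deg_direction` added, sorted by chromosome then
#'   decreasing `|log2_fc|`.
#' @export
classify_driven <- function(candidates) {
  stopifnot(all(c("gene", "chromosome", "log2_copy_number", "log2_fc")
                %in% names(candidates)))
  cn_sign <- sign(candidates$log2_copy_number - 1)
  if (any(cn_sign == 0)) {
    stop("copy-number-neutral candidate(s): ",
         paste(candidates$gene[cn_sign == 0], collapse = ", "),
         " (should have been filtered upstream)", call. = FALSE)
  }
  fc_sign <- sign(candidates$log2_fc)
  keep <- cn_sign == fc_sign
  out <- candidates[keep, , drop = FALSE]
  out$cnv_state <- ifelse(out$log2_copy_number > 1, "duplication", "deletion")
  out$deg_direction <- ifelse(out$log2_fc > 0, "up", "down")
  out <- out[order(out$chromosome, -abs(out$log2_fc)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("driven_genes", "data.frame")
  out
}

#' Count driven genes per chromosome
#'
#' @param driven a [classify_driven()] table (or any data.frame with a
#'   `chromosome` column).
#' @return named integer vector, chromosomes with at least one driven gene.
#' @export
chromosome_summary <- function(driven) {
  if (!nrow(driven)) return(stats::setNames(integer(), character()))
  tab <- table(driven$chromosome)
  stats::setNames(as.integer(tab), names(tab))
}

#' Build the driven-gene candidate table from pipeline stage outputs
#'
#' Joins the frequency-filtered CNV gene summary with the DEG table and
#' runs [classify_driven()]. Genes not measured on the expression platform
#' drop out at the join; the measured/DEG funnel sizes are attached as the
#' `"funnel"` attribute.
#'
#' @param cnv_summary output of [frequency_filter()] (needs `gene`,
#'   `chromosome`, `mean_case_log2cn`).
#' @param degs output of [screen_degs()].
#' @param measured_genes all genes on the expression platform.
#' @return a `"driven_genes"` table (see [classify_driven()]).
#' @export
find_driven_genes <- function(cnv_summary, degs, measured_genes) {
  funnel <- overlap_genes(cnv_summary$gene, degs$gene, measured_genes)
  cand <- cnv_summary[cnv_summary$gene %in% funnel$deg, , drop = FALSE]
  cand <- merge(cand, degs[, c("gene", "log2_fc")], by = "gene")
  cand$log2_copy_number <- cand$mean_case_log2cn
  cand <- cand[, c("gene", "chromosome", "log2_copy_number", "log2_fc")]
  out <- classify_driven(cand)
  attr(out, "funnel") <- list(n_cnv = length(unique(cnv_summary$gene)),
                              n_measured = length(funnel$measured),
                              n_deg = length(funnel$deg),
                              n_driven = nrow(out))
  out
}

#' @export
print.driven_genes <- function(x, ...) {
  f <- attr(x, "funnel")
  cat("CNV-driven genes:", nrow(x), "\n")
  if (!is.null(f)) {
    cat("  funnel: ", f$n_cnv, " CNV genes -> ", f$n_measured,
        " measured -> ", f$n_deg, " DEGs -> ", f$n_driven,
        " sign-concordant\n", sep = "")
  }
  print.data.frame(x, ...)
  invisible(x)
}
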