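#' Per-gene log2 fold change between tumor and normal groups
#'
#' Values are assumed to be on the log2 scale already, so the fold change is
#' a difference of group means: `log2FC(g) = mean(tumor) - mean(normal)`.
#' With `paired = TRUE` the estimate is instead the mean of within-patient
#' tumor-minus-normal differences (numerically identical for complete data,
#' but robust to patient-level shifts); pairing is by the `pairs` map.
#'
#' Genes with all values missing in either group cannot be estimated and
#' are dropped with a warning.
#'
#' @param expr an `"expression_matrix"` (see [read_expression()]).
#' @param paired use the matched-pair estimator?
#' @param pairs named character vector mapping each tumor sample id to its
#'   matched normal sample id (required when `paired = TRUE`).
#' @return named numeric vector of log2 fold changes, one per estimable
#'   gene.
#' @export
compute_log2fc <- function(expr, paired = FALSE, pairs = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  v <- expr$values
  tumor <- v[, expr$groups == "tumor", drop = FALSE]
  normal <- v[, expr$groups == "normal", drop = FALSE]
  if (paired) {
    if (is.null(pairs)) stop("paired = TRUE requires a pairs map", call. = FALSE)
    stopifnot(all(names(pairs) %in% colnames(tumor)),
              all(pairs %in% colnames(normal)))
    d <- tumor[, names(pairs), drop = FALSE] -
      normal[, unname(pairs), drop = FALSE]
    fc <- rowMeans(d, na.rm = TRUE)
    bad <- rowSums(!is.na(d)) == 0
  } else {
    fc <- rowMeans(tumor, na.rm = TRUE) - rowMeans(normal, na.rm = TRUE)
    bad <- rowSums(!is.na(tumor)) == 0 | rowSums(!is.na(normal)) == 0
  }
  if (any(bad)) {
    warning(sum(bad), " gene(s) with a fully missing group excluded from ",
            "fold-change estimation: ",
            paste(utils::head(rownames(v)[bad], 5), collapse = ", "),
            if (sum(bad) > 5) ", ..." else "")
    fc <- fc[!bad]
  }
  fc
}

#' Screen differentially expressed genes by fold change
#'
#' Keeps genes with `|log2FC| > cutoff` (strict inequality; a gene at
#' exactly the cutoff is not a DEG) and labels the direction of change.
#'
#' @param log2fc named numeric vector from [compute_log2fc()].
#' @param cutoff fold-change cutoff on the log2 scale (default 1, i.e. a
#'   two-fold change).
#' @return data.frame with columns `gene`, `log2_fc`, `direction`
#'   (`"up"`/`"down"`), ordered by decreasing `|log2_fc|`.
#' @export
screen_degs <- function(log2fc, cutoff = 1) {
  stopifnot(is.numeric(log2fc), all(is.finite(log2fc)), cutoff >= 0)
  keep <- abs(log2fc) > cutoff
  out <- data.frame(gene = names(log2fc)[keep],
                    log2_fc = unname(log2fc[keep]),
                    stringsAsFactors = FALSE)
  out$direction <- ifelse(out$log2_fc > 0, "up", "down")
  out <- out[order(-abs(out$log2_fc)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
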