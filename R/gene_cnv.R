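#' Map CNV events onto gene models, per sample
#'
#' A gene is called in a sample when an event of that sample covers it.
#' Under the default `containment = "full"` the event interval must entirely
#' contain the gene interval ("genes located within CNV regions"); under
#' `"any_overlap"` any overlap of at least one base suffices. When several
#' events of one sample cover a gene with conflicting states, the call with
#' the larger departure from neutral (`|log2cn - 1|`) wins; exact ties are
#' broken deterministically (higher log2cn, then smaller event start).
#'
#' The interval index is per-chromosome [IRanges::IRanges]; tests verify it
#' against a brute-force quadratic containment scan.
#'
#' @param events data.frame from [call_cnv_events()].
#' @param genes gene models from [read_gene_models()] (0-based half-open,
#'   same convention as the events).
#' @param samples character vector of all sample ids (a sample with no
#'   events still yields neutral calls).
#' @param containment `"full"` (default) or `"any_overlap"`.
#' @return A list with two gene x sample matrices: `state` (character,
#'   `"deletion"`/`"neutral"`/`"duplication"`) and `log2cn` (numeric,
#'   neutral = 1).
#' @export
map_events_to_genes <- function(events, genes, samples,
                                containment = c("full", "any_overlap")) {
  containment <- match.arg(containment)
  ng <- nrow(genes)
  state <- matrix("neutral", nrow = ng, ncol = length(samples),
                  dimnames = list(genes$gene, samples))
  log2cn <- matrix(1, nrow = ng, ncol = length(samples),
                   dimnames = list(genes$gene, samples))
  if (!nrow(events)) return(list(state = state, log2cn = log2cn))
  stopifnot(all(events$sample %in% samples))

  type <- if (containment == "full") "within" else "any"
  for (chr in unique(genes$chromosome)) {
    gsel <- which(genes$chromosome == chr)
    esel <- which(events$chromosome == chr)
    if (!length(esel)) next
    # 0-based half-open [s, e) -> 1-based closed [s + 1, e]
    q <- IRanges::IRanges(start = genes$start[gsel] + 1L,
                          end = genes$end[gsel])
    s <- IRanges::IRanges(start = events$start[esel] + 1L,
                          end = events$end[esel])
    hits <- IRanges::findOverlaps(q, s, type = type)
    if (!length(hits)) next
    gi <- gsel[S4Vectors::queryHits(hits)]
    ei <- esel[S4Vectors::subjectHits(hits)]
    # one winner per (gene, sample): order so the preferred call comes last
    # and later assignments overwrite earlier ones
    dev <- abs(events$log2_copy_number[ei] - 1)
    o <- order(dev, events$log2_copy_number[ei], -events$start[ei])
    gi <- gi[o]; ei <- ei[o]
    si <- match(events$sample[ei], samples)
    idx <- cbind(gi, si)
    state[idx] <- events$state[ei]
    log2cn[idx] <- events$log2_copy_number[ei]
  }
  list(state = state, log2cn = log2cn)
}

#' Per-gene CNV profiles with case/control frequencies
#'
#' Combines the per-sample calls of [map_events_to_genes()] into one summary
#' row per gene: the fraction of case samples with a non-neutral call, the
#' same for controls, the per-state case fractions and the recurrent
#' (modal non-neutral) state. Frequencies are computed over all samples of
#' the group, with missing data already filled neutral upstream.
#'
#' @inheritParams map_events_to_genes
#' @param groups named character vector over `samples`
#'   (`"case"`/`"control"`).
#' @return data.frame of class `"gene_cnv_profile"`, one row per gene:
#'   `gene`, `chromosome`, `case_frequency`, `control_frequency`,
#'   `dup_case_frequency`, `del_case_frequency`, `recurrent_state`,
#'   `mean_case_log2cn` (mean over case carriers of the recurrent state;
#'   `NA` when there are none), plus the call matrices as attributes.
#' @export
gene_cnv_profiles <- function(events, genes, groups,
                              containment = c("full", "any_overlap")) {
  samples <- names(groups)
  calls <- map_events_to_genes(events, genes, samples, containment)
  is_case <- groups == "case"
  n_case <- sum(is_case)
  n_control <- sum(!is_case)
  stopifnot(n_case > 0, n_control > 0)

  cs <- calls$state[, is_case, drop = FALSE]
  dup_f <- rowMeans(cs == "duplication")
  del_f <- rowMeans(cs == "deletion")
  case_f <- dup_f + del_f
  control_f <- rowMeans(calls$state[, !is_case, drop = FALSE] != "neutral")
  rec <- ifelse(case_f == 0, NA_character_,
                ifelse(dup_f >= del_f, "duplication", "deletion"))

  mean_cn <- vapply(seq_len(nrow(genes)), function(i) {
    if (is.na(rec[i])) return(NA_real_)
    carrier <- cs[i, ] == rec[i]
    if (!any(carrier)) return(NA_real_)
    mean(calls$log2cn[i, is_case, drop = TRUE][carrier])
  }, numeric(1))

  out <- data.frame(gene = genes$gene, chromosome = genes$chromosome,
                    case_frequency = case_f, control_frequency = control_f,
                    dup_case_frequency = dup_f, del_case_frequency = del_f,
                    recurrent_state = rec, mean_case_log2cn = mean_cn,
                    stringsAsFactors = FALSE)
  attr(out, "state") <- calls$state
  attr(out, "log2cn") <- calls$log2cn
  class(out) <- c("gene_cnv_profile", "data.frame")
  out
}

#' Case-recurrence / control-absence frequency filter
#'
#' Retains a gene as CNV-related when its CNV is recurrent in cases and
#' absent from controls: `case_frequency > min_case_fraction` (strict, the
#' "more than 80% of cases" rule) and `control_frequency <=
#' max_control_fraction` (default 0: not detected in any control). In
#' addition the calls must be directionally consistent: one single state
#' (duplication or deletion) must itself exceed `min_case_fraction` of the
#' cases — a gene duplicated in half the cases and deleted in another 40%
#' is not a recurrent event.
#'
#' @param profiles output of [gene_cnv_profiles()].
#' @param min_case_fraction strict lower bound on the case frequency
#'   (default 0.8).
#' @param max_control_fraction upper bound on the control frequency
#'   (default 0).
#' @return the retained rows of `profiles` (plain data.frame), with
#'   `recurrent_state` set to the qualifying state.
#' @export
frequency_filter <- function(profiles, min_case_fraction = 0.8,
                             max_control_fraction = 0) {
  stopifnot(min_case_fraction >= 0, min_case_fraction <= 1,
            max_control_fraction >= 0, max_control_fraction <= 1)
  state_f <- pmax(profiles$dup_case_frequency, profiles$del_case_frequency)
  keep <- state_f > min_case_fraction &
    profiles$control_frequency <= max_control_fraction
  out <- as.data.frame(profiles)[keep, , drop = FALSE]
  out$recurrent_state <- ifelse(
    out$dup_case_frequency >= out$del_case_frequency,
    "duplication", "deletion")
  rownames(out) <- NULL
  out
}

#' Mean log2 copy number of a gene over its case carriers
#'
#' The gene-level "log2(copy number)" summary: the mean log2 absolute copy
#' number over the case samples carrying the gene's recurrent state.
#'
#' @param profile one row of a [gene_cnv_profiles()] table (or any list
#'   with `mean_case_log2cn`).
#' @return numeric scalar.
#' @export
summarize_gene_copy_number <- function(profile) {
  v <- profile$mean_case_log2cn
  if (length(v) != 1 || is.na(v)) {
    stop("gene has no case carriers of a recurrent state", call. = FALSE)
  }
  v
}
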