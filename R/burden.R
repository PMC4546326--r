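#' Tabulate CNV events per chromosome, state and length bin
#'
#' Produces the full (chromosome x state x bin) grid of case and control
#' event counts. The grid is an exhaustive partition of the input: summing
#' `n_case + n_control` over all cells recovers the number of events.
#'
#' @param events data.frame from [call_cnv_events()] with a `group` column
#'   (`"case"`/`"control"`).
#' @param chromosomes integer vector of chromosomes to tabulate
#'   (default 1:22); events on other chromosomes are an error.
#' @return data.frame with columns `chromosome`, `state`, `length_bin`,
#'   `n_case`, `n_control`.
#' @export
count_events <- function(events, chromosomes = 1:22) {
  if (nrow(events) && !all(events$chromosome %in% chromosomes)) {
    stop("event(s) on chromosomes outside the tabulated set", call. = FALSE)
  }
  grid <- expand.grid(chromosome = chromosomes,
                      state = c("deletion", "duplication"),
                      length_bin = c("B1", "B2", "B3"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$chromosome, grid$state, grid$length_bin), ,
               drop = FALSE]
  rownames(grid) <- NULL
  key <- function(chr, st, bin) paste(chr, st, bin, sep = "|")
  gk <- key(grid$chromosome, grid$state, grid$length_bin)
  cnt <- function(sel) {
    tab <- table(factor(key(sel$chromosome, sel$state, sel$length_bin),
                        levels = gk))
    as.integer(tab)
  }
  grid$n_case <- cnt(events[events$group == "case", , drop = FALSE])
  grid$n_control <- cnt(events[events$group == "control", , drop = FALSE])
  grid
}

#' Per-sample-normalized case/control burden ratio
#'
#' Returns `(n_case / n_case_samples) / (n_control / n_control_samples)`.
#' With equal cohort sizes this reduces to the naive count ratio
#' `n_case / n_control`; the normalization guards against unequal cohort
#' sizes. When there are no control events the ratio is undefined and
#' reported as `NA` (not infinity).
#'
#' @param n_case,n_control event counts (>= 0).
#' @param n_case_samples,n_control_samples cohort sizes (> 0).
#' @return numeric ratio, `NA` where `n_control == 0`.
#' @export
burden_ratio <- function(n_case, n_control, n_case_samples,
                         n_control_samples) {
  stopifnot(all(n_case >= 0), all(n_control >= 0),
            n_case_samples > 0, n_control_samples > 0)
  r <- (n_case / n_case_samples) / (n_control / n_control_samples)
  r[n_control == 0] <- NA_real_
  r
}

# |log ratio| permutation statistic on per-sample counts, extended to the
# zero-count edge cases:
#   both counts 0        -> 0   (no events, no signal)
#   control 0, case > 0  -> Inf (maximal case enrichment)
#   case 0, control > 0  -> Inf (maximal case depletion; test is two-sided)
burden_stat <- function(case_total, control_total, n_case_samples,
                        n_control_samples) {
  if (case_total == 0 && control_total == 0) return(0)
  if (case_total == 0 || control_total == 0) return(Inf)
  abs(log((case_total / n_case_samples) /
          (control_total / n_control_samples)))
}

#' Sample-label permutation test for one burden cell
#'
#' Tests whether the case/control burden in one (chromosome, state,
#' length-bin) cell differs from what sample exchangeability predicts. The
#' unit of permutation is the sample: case/control labels are reshuffled
#' over samples, each sample keeping its own events, and the
#' per-sample-normalized ratio is recomputed each replicate. The statistic
#' is the absolute log ratio (two-sided: both enrichment and depletion in
#' cases count as extreme). The p-value uses the add-one empirical
#' estimator `p = (1 + #exceeding) / (n_replicates + 1)`, so `p >=
#' 1/(n_replicates + 1)` always.
#'
#' Replicates where the ratio is undefined (zero control events) count as
#' non-exceeding when the observed statistic is finite. When the observed
#' cell itself has zero control events (or zero case events) its statistic
#' is infinite and only replicates that are likewise one-sided count as
#' exceeding.
#'
#' @param events data.frame from [call_cnv_events()].
#' @param groups named character vector mapping every sample id (including
#'   samples with no events) to `"case"` or `"control"`.
#' @param chromosome,state,length_bin the cell to test.
#' @param n_replicates number of label permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @return the empirical two-sided p-value.
#' @export
permutation_test <- function(events, groups, chromosome, state, length_bin,
                             n_replicates = 1000, seed = 1L) {
  g <- check_groups(groups)
  sel <- events$chromosome == chromosome & events$state == state &
    events$length_bin == length_bin
  per_sample <- table(factor(events$sample[sel], levels = names(g)))
  per_sample <- as.numeric(per_sample)
  permutation_p(per_sample, g == "case", n_replicates, seed)
}

check_groups <- function(groups) {
  stopifnot(!is.null(names(groups)), all(groups %in% c("case", "control")))
  if (sum(groups == "case") < 2 || sum(groups == "control") < 2) {
    stop("permutation test needs >= 2 samples per group", call. = FALSE)
  }
  groups
}

# core permutation on a per-sample count vector; is_case logical
permutation_p <- function(per_sample, is_case, n_replicates, seed) {
  n_case_samples <- sum(is_case)
  n_control_samples <- sum(!is_case)
  obs <- burden_stat(sum(per_sample[is_case]), sum(per_sample[!is_case]),
                     n_case_samples, n_control_samples)
  total <- sum(per_sample)
  set.seed(seed)
  exceed <- 0L
  n <- length(per_sample)
  for (b in seq_len(n_replicates)) {
    idx <- sample.int(n, n_case_samples)
    case_total <- sum(per_sample[idx])
    stat <- burden_stat(case_total, total - case_total,
                        n_case_samples, n_control_samples)
    # zero-control replicates are non-exceeding against a finite observation
    if (is.finite(obs)) {
      if (is.finite(stat) && stat >= obs) exceed <- exceed + 1L
    } else {
      if (is.infinite(stat)) exceed <- exceed + 1L
    }
  }
  (1 + exceed) / (n_replicates + 1)
}

#' Full CNV burden table with ratios and permutation p-values
#'
#' The per-chromosome, per-state, per-length-bin burden analysis: event
#' counts in cases and controls, the per-sample-normalized case/control
#' ratio, the sample-label permutation p-value for every cell, and (as a
#' clearly labelled extra, not part of the original design) Benjamini-
#' Hochberg q-values across cells. All cells share one stream of label
#' permutations, so the table is reproducible byte-for-byte under a fixed
#' seed.
#'
#' @param events combined case + control events from [call_cnv_events()].
#' @param groups named character vector over all samples
#'   (`"case"`/`"control"`).
#' @param chromosomes chromosomes to tabulate (default 1:22).
#' @param n_replicates permutation replicates per cell (default 1000).
#' @param seed integer seed.
#' @return data.frame of class `"burden_table"`: `chromosome`, `state`,
#'   `length_bin`, `n_case`, `n_control`, `ratio`, `p_value`, `q_value`.
#' @export
burden_table <- function(events, groups, chromosomes = 1:22,
                         n_replicates = 1000, seed = 1L) {
  g <- check_groups(groups)
  is_case <- g == "case"
  n_case_samples <- sum(is_case)
  n_control_samples <- sum(!is_case)
  tab <- count_events(events, chromosomes)
  tab$ratio <- burden_ratio(tab$n_case, tab$n_control,
                            n_case_samples, n_control_samples)

  # per-sample x per-cell count matrix; one permutation stream shared by
  # every cell keeps the table reproducible and fast
  cell_key <- paste(tab$chromosome, tab$state, tab$length_bin, sep = "|")
  ev_key <- paste(events$chromosome, events$state, events$length_bin,
                  sep = "|")
  M <- table(factor(events$sample, levels = names(g)),
             factor(ev_key, levels = cell_key))
  M <- matrix(as.numeric(M), nrow = length(g),
              dimnames = list(names(g), cell_key))

  obs_case <- colSums(M[is_case, , drop = FALSE])
  obs_control <- colSums(M[!is_case, , drop = FALSE])
  obs_stat <- mapply(burden_stat, obs_case, obs_control,
                     MoreArgs = list(n_case_samples = n_case_samples,
                                     n_control_samples = n_control_samples))
  totals <- colSums(M)

  set.seed(seed)
  exceed <- numeric(ncol(M))
  n <- nrow(M)
  for (b in seq_len(n_replicates)) {
    idx <- sample.int(n, n_case_samples)
    case_tot <- colSums(M[idx, , drop = FALSE])
    control_tot <- totals - case_tot
    stat <- rep(0, ncol(M))
    one_sided <- xor(case_tot == 0, control_tot == 0)
    stat[one_sided] <- Inf
    ok <- case_tot > 0 & control_tot > 0
    stat[ok] <- abs(log((case_tot[ok] / n_case_samples) /
                        (control_tot[ok] / n_control_samples)))
    fin <- is.finite(obs_stat)
    exceed[fin] <- exceed[fin] +
      (is.finite(stat[fin]) & stat[fin] >= obs_stat[fin])
    exceed[!fin] <- exceed[!fin] + is.infinite(stat[!fin])
  }
  tab$p_value <- (1 + exceed) / (n_replicates + 1)
  tab$q_value <- stats::p.adjust(tab$p_value, method = "BH")
  class(tab) <- c("burden_table", "data.frame")
  tab
}
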