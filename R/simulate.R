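#' Configuration for the paired tumor/normal simulator
#'
#' Defines a toy genome, paired case/control cohorts, planted recurrent
#' focal copy-number events and the expression model used to validate the
#' whole pipeline end-to-end. Defaults describe the reference validation
#' scenario: 20 cases and 20 matched controls on a three-chromosome genome
#' (40/30/20 Mb), 200 genes of 2-8 kb, 10 planted driver genes duplicated
#' or deleted in 90% of cases with a concordant two-fold (|log2| = 2)
#' expression shift, log-normal expression noise of 0.3 on the log2 scale,
#' and a background of one random event per length bin per sample.
#'
#' Segment means of duplications are drawn so that the log2 absolute copy
#' number is uniform on (1.4, 1.8) (mean 1.6); deletions uniform on
#' (0.2, 0.6). The copy-number-neutral ground is exactly log2cn = 1
#' (segment mean 0).
#'
#' @param seed integer seed; all stochastic draws flow from it in a fixed
#'   order (genome, then segments, then expression).
#' @param n_cases,n_controls cohort sizes.
#' @param chromosome_lengths named numeric vector, chromosome -> length in
#'   bp.
#' @param n_genes number of non-overlapping genes to place.
#' @param gene_length_range min/max gene length in bp.
#' @param n_drivers number of planted driver genes (used when
#'   `driver_spec` is `NULL`).
#' @param carrier_fraction fraction of cases carrying each planted event.
#' @param driver_shift absolute expression shift of planted drivers, log2
#'   units; the sign follows the planted state.
#' @param driver_spec optional data.frame (`gene_index`, `state`,
#'   `carrier_fraction`, `shift`) overriding the default driver layout;
#'   `shift` may disagree in sign with `state` to plant discordant decoys.
#' @param background_rate named numeric vector `c(B1=, B2=, B3=)`: expected
#'   background events per sample per length bin (cases and controls
#'   alike).
#' @param noise_sd standard deviation of expression noise, log2 scale.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_cases = 20L, n_controls = 20L,
                       chromosome_lengths = c(`1` = 4e7, `2` = 3e7,
                                              `3` = 2e7),
                       n_genes = 200L,
                       gene_length_range = c(2000L, 8000L),
                       n_drivers = 10L,
                       carrier_fraction = 0.9,
                       driver_shift = 2,
                       driver_spec = NULL,
                       background_rate = c(B1 = 1, B2 = 1, B3 = 1),
                       noise_sd = 0.3) {
  stopifnot(n_cases >= 1, n_controls >= 1, n_genes >= 1,
            all(chromosome_lengths > 0),
            all(background_rate >= 0), noise_sd >= 0,
            carrier_fraction > 0, carrier_fraction <= 1)
  if (is.null(driver_spec)) {
    if (n_drivers > 0) {
      # spread planted drivers evenly over the (genomically ordered) genes
      gi <- unique(round(seq(1, n_genes, length.out = n_drivers)))
      driver_spec <- data.frame(
        gene_index = gi,
        state = rep(c("duplication", "deletion"), length.out = length(gi)),
        carrier_fraction = carrier_fraction,
        shift = driver_shift, stringsAsFactors = FALSE)
      driver_spec$shift <- ifelse(driver_spec$state == "duplication",
                                  abs(driver_shift), -abs(driver_shift))
    } else {
      driver_spec <- data.frame(gene_index = integer(), state = character(),
                                carrier_fraction = numeric(),
                                shift = numeric(), stringsAsFactors = FALSE)
    }
  }
  stopifnot(all(driver_spec$gene_index >= 1),
            all(driver_spec$gene_index <= n_genes),
            all(driver_spec$state %in% c("duplication", "deletion")),
            all(driver_spec$carrier_fraction > 0),
            all(driver_spec$carrier_fraction <= 1),
            all(c("B1", "B2", "B3") %in% names(background_rate)))
  structure(list(seed = as.integer(seed), n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 chromosome_lengths = chromosome_lengths,
                 n_genes = as.integer(n_genes),
                 gene_length_range = gene_length_range,
                 driver_spec = driver_spec,
                 background_rate = background_rate,
                 noise_sd = noise_sd),
            class = "sim_config")
}

# background event length per bin (bp); B3 capped at 150 kb so events stay
# focal relative to the toy chromosomes
sim_event_length <- function(bin, n) {
  switch(bin,
         B1 = round(stats::runif(n, 1000, 10000)),
         B2 = round(stats::runif(n, 10001, 50000)),
         B3 = round(stats::runif(n, 50001, 150000)))
}

# log2 absolute copy number draws; duplication mean 1.6, deletion mean 0.4
sim_log2cn <- function(state, n) {
  ifelse(state == "duplication",
         stats::runif(n, 1.4, 1.8),
         stats::runif(n, 0.2, 0.6))
}

#' Simulate non-overlapping gene models on the toy genome
#'
#' Genes are placed uniformly at random, chromosome chosen proportionally
#' to its length, and re-drawn on collision. Deterministic given the
#' config seed.
#'
#' @param config a [sim_config()].
#' @return gene-model data.frame (`gene`, `chromosome`, `start`, `end`,
#'   `strand`), 0-based half-open.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- as.integer(names(config$chromosome_lengths))
  lens <- unname(config$chromosome_lengths)
  n <- config$n_genes
  placed <- vector("list", n)
  occupied <- lapply(seq_along(chroms), function(i) NULL)
  for (g in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(1000L)) {
      ci <- sample.int(length(chroms), 1, prob = lens)
      gl <- round(stats::runif(1, config$gene_length_range[1],
                               config$gene_length_range[2]))
      if (gl >= lens[ci]) next
      s <- floor(stats::runif(1, 0, lens[ci] - gl))
      e <- s + gl
      occ <- occupied[[ci]]
      if (!is.null(occ) && any(s < occ[, 2] & occ[, 1] < e)) next
      occupied[[ci]] <- rbind(occ, c(s, e))
      placed[[g]] <- data.frame(gene = sprintf("G%04d", g),
                                chromosome = chroms[ci], start = s, end = e,
                                strand = if (stats::runif(1) < 0.5) "+" else "-",
                                stringsAsFactors = FALSE)
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("could not place ", n, " non-overlapping genes on the ",
           "configured genome", call. = FALSE)
    }
  }
  out <- do.call(rbind, placed)
  # driver_spec$gene_index refers to rows of this (genomically sorted) table
  out <- out[order(out$chromosome, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate paired case/control copy-number segment profiles
#'
#' Each planted driver gene is fully covered by an event of its assigned
#' state (the gene interval extended by uniform margins of up to 20 kb per
#' side) in `ceiling(carrier_fraction * n_cases)` case samples and in no
#' control sample. Background events of both states are then scattered
#' uniformly over the genome in every sample, cases and controls alike,
#' with Poisson counts per length bin as configured. Deterministic given
#' the config seed.
#'
#' @param config a [sim_config()].
#' @param genes gene models from [simulate_genome()].
#' @return list with `case_segments`, `control_segments` (data.frames in
#'   the internal segment layout) and `truth` (planted drivers:
#'   `gene`, `state`, `shift`, `carrier_fraction`, `carriers`
#'   comma-separated sample ids).
#' @export
simulate_segments <- function(config, genes) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  chroms <- as.integer(names(config$chromosome_lengths))
  lens <- unname(config$chromosome_lengths)
  case_ids <- sprintf("case_%02d", seq_len(config$n_cases))
  control_ids <- sprintf("control_%02d", seq_len(config$n_controls))

  rows <- list()
  truth <- list()
  spec <- config$driver_spec
  for (i in seq_len(nrow(spec))) {
    gi <- spec$gene_index[i]
    g <- genes[gi, ]
    n_carriers <- ceiling(spec$carrier_fraction[i] * config$n_cases)
    carriers <- sort(sample(case_ids, n_carriers))
    margin_l <- round(stats::runif(n_carriers, 0, 20000))
    margin_r <- round(stats::runif(n_carriers, 0, 20000))
    start <- pmax(0, g$start - margin_l)
    end <- pmin(lens[match(g$chromosome, chroms)], g$end + margin_r)
    if (any(end - start < 1000)) {
      # a driver event must itself be a CNV (>= 1 kb); gene lengths below
      # 1 kb with zero margins could violate that
      short <- end - start < 1000
      end[short] <- start[short] + 1000
    }
    log2cn <- sim_log2cn(rep(spec$state[i], n_carriers), n_carriers)
    rows[[length(rows) + 1]] <- data.frame(
      sample = carriers, group = "case", chromosome = g$chromosome,
      start = start, end = end, segment_mean = log2cn - 1,
      stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(gene = g$gene, state = spec$state[i],
                             shift = spec$shift[i],
                             carrier_fraction = spec$carrier_fraction[i],
                             carriers = paste(carriers, collapse = ","),
                             stringsAsFactors = FALSE)
  }

  background_for <- function(sample_id, group) {
    out <- list()
    for (bin in c("B1", "B2", "B3")) {
      k <- stats::rpois(1, config$background_rate[[bin]])
      if (!k) next
      ci <- sample.int(length(chroms), k, replace = TRUE, prob = lens)
      len <- sim_event_length(bin, k)
      len <- pmin(len, lens[ci] - 1)
      s <- floor(stats::runif(k, 0, lens[ci] - len))
      st <- ifelse(stats::runif(k) < 0.5, "duplication", "deletion")
      out[[bin]] <- data.frame(sample = sample_id, group = group,
                               chromosome = chroms[ci], start = s,
                               end = s + len,
                               segment_mean = sim_log2cn(st, k) - 1,
                               stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  # every sample gets one neutral anchor segment so it is present in the
  # SEG file even with no CNV (real level-3 files tile the genome; the
  # anchor is dropped at event calling but keeps cohort sizes recoverable)
  anchor <- function(id, group) {
    data.frame(sample = id, group = group, chromosome = chroms[1],
               start = 0, end = 1e6, segment_mean = 0,
               stringsAsFactors = FALSE)
  }
  for (id in case_ids) {
    rows[[length(rows) + 1]] <- rbind(anchor(id, "case"),
                                      background_for(id, "case"))
  }
  control_rows <- lapply(control_ids, function(id) {
    rbind(anchor(id, "control"), background_for(id, "control"))
  })

  empty <- data.frame(sample = character(), group = character(),
                      chromosome = integer(), start = numeric(),
                      end = numeric(), segment_mean = numeric(),
                      stringsAsFactors = FALSE)
  case_segments <- do.call(rbind, c(rows, list(empty)))
  control_segments <- do.call(rbind, c(control_rows, list(empty)))
  rownames(case_segments) <- rownames(control_segments) <- NULL
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene = character(), state = character(), shift = numeric(),
               carrier_fraction = numeric(), carriers = character(),
               stringsAsFactors = FALSE)
  list(case_segments = case_segments, control_segments = control_segments,
       truth = truth)
}

#' Simulate the tumor/normal expression matrix
#'
#' Gene g in sample s is `baseline_g + shift_g * carrier(g, s) +
#' N(0, noise_sd)` on the log2 scale. Tumor samples are the cases of the
#' segment simulation, and `carrier(g, s) = 1` exactly when sample s
#' carries the planted event on g; normals and non-drivers get no shift.
#' Per-gene baselines are uniform on (4, 12). Deterministic given the
#' config seed.
#'
#' @param config a [sim_config()].
#' @param genes gene models from [simulate_genome()].
#' @param truth planted-driver table from [simulate_segments()].
#' @return an `"expression_matrix"` with tumor samples named like the case
#'   samples and normal samples `normal_01`, ...
#' @export
simulate_expression <- function(config, genes, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  tumor_ids <- sprintf("case_%02d", seq_len(config$n_cases))
  normal_ids <- sprintf("normal_%02d", seq_len(config$n_controls))
  samples <- c(tumor_ids, normal_ids)
  ng <- nrow(genes)
  baseline <- stats::runif(ng, 4, 12)
  values <- matrix(baseline, nrow = ng, ncol = length(samples),
                   dimnames = list(genes$gene, samples))
  for (i in seq_len(nrow(truth))) {
    gi <- match(truth$gene[i], genes$gene)
    carriers <- strsplit(truth$carriers[i], ",", fixed = TRUE)[[1]]
    values[gi, carriers] <- values[gi, carriers] + truth$shift[i]
  }
  if (config$noise_sd > 0) {
    values <- values + matrix(stats::rnorm(length(values), 0,
                                           config$noise_sd),
                              nrow = ng)
  }
  groups <- stats::setNames(rep(c("tumor", "normal"),
                                c(length(tumor_ids), length(normal_ids))),
                            samples)
  expression_matrix(values, groups)
}

#' Simulate a complete paired tumor/normal dataset
#'
#' Runs [simulate_genome()], [simulate_segments()] and
#' [simulate_expression()] in that order from the single config seed.
#'
#' @param config a [sim_config()].
#' @return list with `genes`, `case_segments`, `control_segments`,
#'   `expression` and `truth`.
#' @export
simulate_dataset <- function(config) {
  genes <- simulate_genome(config)
  seg <- simulate_segments(config, genes)
  expr <- simulate_expression(config, genes, seg$truth)
  list(genes = genes, case_segments = seg$case_segments,
       control_segments = seg$control_segments, expression = expr,
       truth = seg$truth)
}
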