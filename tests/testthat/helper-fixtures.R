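# fixtures built in code, shared across test files

# random normalized segment table (internal convention)
random_segment_table <- function(n, seed) {
  set.seed(seed)
  start <- sample.int(1e6, n)
  data.frame(sample = sample(sprintf("s%02d", 1:8), n, replace = TRUE),
             group = sample(c("case", "control"), n, replace = TRUE),
             chromosome = sample(1:22, n, replace = TRUE),
             start = start,
             end = start + sample(500:200000, n, replace = TRUE),
             segment_mean = round(stats::rnorm(n, 0, 0.5), 4),
             stringsAsFactors = FALSE)
}

# write a SEG file in the standard 1-based inclusive dialect
write_seg_1based <- function(df, path, num_probes = TRUE) {
  out <- data.frame(sample = df$sample, chromosome = df$chromosome,
                    start = df$start + 1, end = df$end)
  if (num_probes) out$num_probes <- 50L
  out$segment_mean <- df$segment_mean
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  path
}

# brute-force per-gene per-sample containment scan: the quadratic oracle
# for map_events_to_genes
brute_force_gene_calls <- function(events, genes, samples,
                                   containment = "full") {
  state <- matrix("neutral", nrow = nrow(genes), ncol = length(samples),
                  dimnames = list(genes$gene, samples))
  log2cn <- matrix(1, nrow = nrow(genes), ncol = length(samples),
                   dimnames = list(genes$gene, samples))
  for (gi in seq_len(nrow(genes))) {
    for (si in seq_along(samples)) {
      best <- NULL
      for (ei in seq_len(nrow(events))) {
        if (events$sample[ei] != samples[si]) next
        if (events$chromosome[ei] != genes$chromosome[gi]) next
        hit <- if (containment == "full") {
          events$start[ei] <= genes$start[gi] &&
            events$end[ei] >= genes$end[gi]
        } else {
          events$start[ei] < genes$end[gi] &&
            genes$start[gi] < events$end[ei]
        }
        if (!hit) next
        if (is.null(best)) { best <- ei; next }
        d_new <- abs(events$log2_copy_number[ei] - 1)
        d_old <- abs(events$log2_copy_number[best] - 1)
        if (d_new > d_old ||
            (d_new == d_old &&
             (events$log2_copy_number[ei] > events$log2_copy_number[best] ||
              (events$log2_copy_number[ei] == events$log2_copy_number[best] &&
               events$start[ei] < events$start[best])))) {
          best <- ei
        }
      }
      if (!is.null(best)) {
        state[gi, si] <- events$state[best]
        log2cn[gi, si] <- events$log2_copy_number[best]
      }
    }
  }
  list(state = state, log2cn = log2cn)
}

# exhaustive sample-label enumeration oracle for the permutation test:
# proportion of all C(n, n_case) case-label assignments whose statistic
# meets or exceeds the observed one (same edge-case conventions)
exhaustive_permutation_p <- function(per_sample, is_case) {
  n <- length(per_sample)
  k <- sum(is_case)
  stat_of <- function(idx) {
    ct <- sum(per_sample[idx]); nt <- sum(per_sample) - ct
    if (ct == 0 && nt == 0) return(0)
    if (ct == 0 || nt == 0) return(Inf)
    abs(log((ct / k) / (nt / (n - k))))
  }
  obs <- stat_of(which(is_case))
  combos <- utils::combn(n, k)
  stats <- apply(combos, 2, stat_of)
  if (is.finite(obs)) {
    mean(is.finite(stats) & stats >= obs)
  } else {
    mean(is.infinite(stats))
  }
}

# exhaustive enumeration oracle for the hypergeometric upper tail:
# enumerate all C(N, n) draws of the query from the universe
exhaustive_hypergeom_p <- function(k, K, n, N) {
  universe <- seq_len(N)
  hits <- seq_len(K)
  draws <- utils::combn(N, n)
  overlaps <- apply(draws, 2, function(d) length(intersect(d, hits)))
  mean(overlaps >= k)
}
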