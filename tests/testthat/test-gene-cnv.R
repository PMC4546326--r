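make_event <- function(sample, chrom, start, end, log2cn,
                       group = "case") {
  data.frame(sample = sample, group = group, chromosome = chrom,
             start = start, end = end, segment_mean = log2cn - 1,
             log2_copy_number = log2cn,
             state = ifelse(log2cn > 1, "duplication", "deletion"),
             length_bin = assign_length_bin(end - start),
             stringsAsFactors = FALSE)
}

test_that("containment semantics: full vs any_overlap", {
  genes <- data.frame(gene = "G1", chromosome = 1L, start = 100, end = 200,
                      strand = "+")
  inside <- make_event("s1", 1L, 0, 10000, 1.5)
  partial <- make_event("s1", 1L, 150, 10000, 1.5)

  full <- map_events_to_genes(inside, genes, "s1", "full")
  expect_equal(full$state["G1", "s1"], "duplication")
  expect_equal(full$log2cn["G1", "s1"], 1.5)

  full2 <- map_events_to_genes(partial, genes, "s1", "full")
  expect_equal(full2$state["G1", "s1"], "neutral")
  any2 <- map_events_to_genes(partial, genes, "s1", "any_overlap")
  expect_equal(any2$state["G1", "s1"], "duplication")
})

test_that("conflicting overlapping calls resolve to the larger deviation", {
  genes <- data.frame(gene = "G1", chromosome = 1L, start = 100, end = 200,
                      strand = "+")
  ev <- rbind(make_event("s1", 1L, 0, 10000, 1.2),
              make_event("s1", 1L, 50, 20000, 0.3))  # |0.3-1| > |1.2-1|
  calls <- map_events_to_genes(ev, genes, "s1")
  expect_equal(calls$state["G1", "s1"], "deletion")
  expect_equal(calls$log2cn["G1", "s1"], 0.3)
})

test_that("interval-indexed mapping equals the brute-force containment scan", {
  for (seed in 1:8) {
    set.seed(seed)
    n_genes <- sample(10:50, 1)
    n_events <- sample(50:200, 1)
    samples <- sprintf("s%02d", 1:6)
    genes <- data.frame(
      gene = sprintf("G%03d", seq_len(n_genes)),
      chromosome = sample(1:3, n_genes, replace = TRUE),
      start = sample.int(5e5, n_genes),
      strand = "+", stringsAsFactors = FALSE)
    genes$end <- genes$start + sample(500:5000, n_genes, replace = TRUE)
    start <- sample.int(5e5, n_events)
    log2cn <- round(runif(n_events, 0.2, 1.8), 3)
    log2cn[abs(log2cn - 1) < 0.05] <- 1.5
    events <- make_event(sample(samples, n_events, replace = TRUE),
                         sample(1:3, n_events, replace = TRUE),
                         start, start + sample(1000:60000, n_events,
                                               replace = TRUE),
                         log2cn)
    for (cont in c("full", "any_overlap")) {
      fast <- map_events_to_genes(events, genes, samples, cont)
      slow <- brute_force_gene_calls(events, genes, samples, cont)
      expect_identical(fast$state, slow$state)
      expect_identical(fast$log2cn, slow$log2cn)
    }
  }
})

test_that("frequency filter applies strict case recurrence and control absence", {
  profiles <- data.frame(
    gene = c("A", "B", "C", "D"),
    chromosome = 1L,
    case_frequency = c(0.81, 0.80, 1.0, 0.90),
    control_frequency = c(0, 0, 0.05, 0),
    dup_case_frequency = c(0.81, 0.80, 1.0, 0.50),
    del_case_frequency = c(0, 0, 0, 0.40),
    recurrent_state = "duplication",
    mean_case_log2cn = 1.5, stringsAsFactors = FALSE)
  kept <- frequency_filter(profiles)
  # B: exactly 80% fails the strict "more than 80%" rule
  # C: any control detection fails the control-absence rule
  # D: 50% dup + 40% del is recurrent overall but has no consistent state
  expect_equal(kept$gene, "A")
  expect_equal(kept$recurrent_state, "duplication")
})

test_that("frequency filter is monotone in min_case_fraction", {
  set.seed(4)
  n <- 40
  dup <- round(runif(n), 2)
  del <- round(runif(n) * (1 - dup), 2)
  profiles <- data.frame(
    gene = sprintf("G%02d", 1:n), chromosome = 1L,
    case_frequency = dup + del, control_frequency = 0,
    dup_case_frequency = dup, del_case_frequency = del,
    recurrent_state = NA_character_, mean_case_log2cn = 1.5,
    stringsAsFactors = FALSE)
  thresholds <- seq(0, 1, by = 0.1)
  kept <- lapply(thresholds, function(t) {
    frequency_filter(profiles, min_case_fraction = t)$gene
  })
  for (i in seq_along(thresholds)[-1]) {
    expect_true(all(kept[[i]] %in% kept[[i - 1]]))
  }
})

test_that("gene copy-number summary is the carrier mean", {
  genes <- data.frame(gene = "G1", chromosome = 1L, start = 100, end = 2000,
                      strand = "+")
  ev <- rbind(make_event("s1", 1L, 0, 10000, 1.0 + 0.0),
              make_event("s1", 1L, 0, 10000, 1.5),
              make_event("s2", 1L, 0, 10000, 1.5))
  ev <- ev[-1, ]  # two carriers at 1.5
  groups <- setNames(c("case", "case", "control"), c("s1", "s2", "s3"))
  prof <- gene_cnv_profiles(ev, genes, groups)
  expect_equal(summarize_gene_copy_number(prof[1, ]), 1.5)

  ev2 <- rbind(make_event("s1", 1L, 0, 10000, 1.0001),
               make_event("s2", 1L, 0, 10000, 2.0))
  # carriers at 1.0001 and 2.0 -> arithmetic mean
  prof2 <- gene_cnv_profiles(ev2, genes, groups)
  expect_equal(summarize_gene_copy_number(prof2[1, ]),
               mean(c(1.0001, 2.0)))

  ev3 <- make_event("s3", 1L, 0, 10000, 1.5, group = "control")
  prof3 <- gene_cnv_profiles(ev3, genes, groups)
  expect_error(summarize_gene_copy_number(prof3[1, ]), "no case carriers")
})

test_that("planted duplication copy number (generator mean 1.6) is recovered", {
  # duplication log2cn draws are uniform(1.4, 1.8): carrier-mean estimates
  # over 100 simulated driver profiles recover 1.6 within +/- 0.1
  means <- vapply(1:100, function(seed) {
    cfg <- sim_config(seed = seed, n_genes = 20, n_drivers = 1,
                      driver_spec = data.frame(
                        gene_index = 5, state = "duplication",
                        carrier_fraction = 0.9, shift = 2),
                      background_rate = c(B1 = 0, B2 = 0, B3 = 0))
    genes <- simulate_genome(cfg)
    seg <- simulate_segments(cfg, genes)
    events <- call_cnv_events(rbind(seg$case_segments, seg$control_segments))
    groups <- setNames(rep(c("case", "control"), c(20, 20)),
                       c(sprintf("case_%02d", 1:20),
                         sprintf("control_%02d", 1:20)))
    prof <- gene_cnv_profiles(events, genes, groups)
    summarize_gene_copy_number(prof[prof$gene == genes$gene[5], ])
  }, numeric(1))
  expect_lt(abs(mean(means) - 1.6), 0.1)
  expect_true(mean(abs(means - 1.6) < 0.1) > 0.9)
})
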