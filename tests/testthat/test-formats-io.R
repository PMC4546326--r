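test_that("SEG coordinates are normalized to 0-based half-open", {
  f <- withr::local_tempfile()
  writeLines(c("sample\tchromosome\tstart\tend\tnum_probes\tsegment_mean",
               "s1\t1\t1001\t2000\t10\t0.5",
               "s2\tchr2\t1\t1500\t20\t-0.3",
               "s3\t22\t5000\t5999\t5\t0.0"), f)
  seg <- read_segments(f, seg_dialect(), group = "case")
  expect_equal(seg$start, c(1000, 0, 4999))
  expect_equal(seg$end, c(2000, 1500, 5999))
  expect_equal(seg$end - seg$start, c(1000, 1500, 1000))
  expect_equal(seg$chromosome, c(1L, 2L, 22L))
  expect_true(all(seg$group == "case"))

  # reading an internal-convention file is the identity on coordinates
  f2 <- withr::local_tempfile()
  write_segments(seg, f2)
  again <- read_segments(f2, seg_dialect(one_based = FALSE,
                                         end_inclusive = FALSE,
                                         has_num_probes = FALSE),
                         group = "case")
  expect_equal(again, seg)
})

test_that("sex chromosomes and malformed rows are rejected with context", {
  f <- withr::local_tempfile()
  writeLines(c("sample\tchromosome\tstart\tend\tnum_probes\tsegment_mean",
               "s1\tX\t100\t2000\t10\t0.5"), f)
  expect_error(read_segments(f, seg_dialect()), "X")

  writeLines(c("sample\tchromosome\tstart\tend\tnum_probes\tsegment_mean",
               "s1\t1\t100\t2000\t10\t0.5",
               "s1\t1\tabc\t2000\t10\t0.5"), f)
  expect_error(read_segments(f, seg_dialect()), "line 3")

  writeLines(c("sample\tchromosome\tstart\tend\tnum_probes\tsegment_mean",
               "s1\t1\t100\t2000"), f)
  expect_error(read_segments(f, seg_dialect()), "expected 6")
})

test_that("segment write/read round trip is byte-identical", {
  for (seed in 1:5) {
    df <- random_segment_table(40, seed)
    f1 <- withr::local_tempfile()
    f2 <- withr::local_tempfile()
    write_segments(df, f1)
    back <- read_segments(f1, seg_dialect(one_based = FALSE,
                                          end_inclusive = FALSE,
                                          has_num_probes = FALSE))
    write_segments(back, f2)
    expect_identical(readLines(f1), readLines(f2))
    expect_equal(back[, c("sample", "chromosome", "start", "end",
                          "segment_mean")],
                 df[, c("sample", "chromosome", "start", "end",
                        "segment_mean")])
  }
})

test_that("coordinate normalization is idempotent", {
  df <- random_segment_table(30, 99)
  f <- withr::local_tempfile()
  internal <- seg_dialect(one_based = FALSE, end_inclusive = FALSE,
                          has_num_probes = FALSE)
  write_segments(df, f)
  once <- read_segments(f, internal)
  write_segments(once, f)
  twice <- read_segments(f, internal)
  expect_identical(once, twice)
})

test_that("expression matrix reader enforces its invariants", {
  f <- withr::local_tempfile(); g <- withr::local_tempfile()
  writeLines(c("gene\ts1\ts2\ts3\ts4",
               "A\t3\t5\t2\t2",
               "B\t1\t1\t1\t1"), f)
  writeLines(c("sample\tgroup", "s1\ttumor", "s2\ttumor",
               "s3\tnormal", "s4\tnormal"), g)
  expr <- read_expression(f, g)
  expect_s3_class(expr, "expression_matrix")
  expect_equal(dim(expr$values), c(2, 4))
  expect_equal(sum(expr$groups == "tumor"), 2)
  expect_equal(sum(expr$groups == "normal"), 2)

  writeLines(c("gene\ts1\ts2\ts3\ts4",
               "A\t3\t5\t2\t2",
               "A\t1\t1\t1\t1"), f)
  expect_error(read_expression(f, g), "duplicated")

  writeLines(c("gene\ts1\ts2\ts3\ts4", "A\t3\t5\t2\t2"), f)
  writeLines(c("sample\tgroup", "s1\ttumor", "s2\ttumor",
               "s3\ttumor", "s4\ttumor"), g)
  expect_error(read_expression(f, g), "non-empty")
})

test_that("expression write/read round trip is the identity", {
  set.seed(11)
  v <- matrix(round(rnorm(20, 8, 2), 4), nrow = 5,
              dimnames = list(paste0("G", 1:5), paste0("s", 1:4)))
  expr <- expression_matrix(v, setNames(c("tumor", "tumor", "normal",
                                          "normal"), paste0("s", 1:4)))
  f <- withr::local_tempfile(); g <- withr::local_tempfile()
  write_expression(expr, f, g)
  back <- read_expression(f, g)
  expect_equal(back$values, expr$values)
  expect_equal(back$groups, expr$groups)
})

test_that("gene model and GMT readers parse and validate", {
  f <- withr::local_tempfile()
  writeLines(c("1\t100\t500\tGENE1\t+", "2\t0\t900\tGENE2\t-"), f)
  gm <- read_gene_models(f)
  expect_equal(gm$gene, c("GENE1", "GENE2"))
  expect_equal(gm$chromosome, c(1L, 2L))
  expect_equal(gm$start, c(100, 0))
  expect_equal(gm$end, c(500, 900))

  writeLines(c("1\t100\t500\tGENE1\t+", "2\t0\t900\tGENE1\t-"), f)
  expect_error(read_gene_models(f), "duplicated")

  s <- withr::local_tempfile()
  writeLines(c("SET1\tfirst set\tA\tB\tC", "SET2\tsecond\tB"), s)
  sets <- read_gene_sets(s)
  expect_equal(names(sets), c("SET1", "SET2"))
  expect_equal(sets$SET1$genes, c("A", "B", "C"))

  writeLines(c("SET1\tno members"), s)
  expect_error(read_gene_sets(s), "no member genes")

  # round trip
  writeLines(c("SET1\tfirst set\tA\tB\tC", "SET2\tsecond\tB"), s)
  sets <- read_gene_sets(s)
  s2 <- withr::local_tempfile()
  write_gene_sets(sets, s2)
  expect_identical(read_gene_sets(s2), sets)
})

test_that("circos track export writes one track per group x state plus DEGs", {
  genes <- data.frame(gene = c("A", "B"), chromosome = c(1L, 2L),
                      start = c(1000, 5000), end = c(3000, 9000),
                      strand = c("+", "-"))
  segments <- data.frame(
    sample = c("c1", "n1"), group = c("case", "control"),
    chromosome = c(1L, 2L), start = c(0, 2000), end = c(20000, 42000),
    segment_mean = c(0.5, -0.6), stringsAsFactors = FALSE)
  events <- call_cnv_events(segments)
  degs <- data.frame(gene = c("A", "B"), log2_fc = c(2.5, -1.4),
                     direction = c("up", "down"), stringsAsFactors = FALSE)
  d <- withr::local_tempdir()
  paths <- write_circos_tracks(events, degs, genes, d)
  expect_length(paths, 5)
  expect_true(all(file.exists(paths)))
  n_lines <- vapply(paths, function(p) length(readLines(p)), integer(1))
  expect_equal(unname(n_lines[c("case_duplication", "control_deletion")]),
               c(1L, 1L))
  expect_equal(unname(n_lines[c("case_deletion", "control_duplication")]),
               c(0L, 0L))
  expect_equal(unname(n_lines["deg"]), 2L)

  # empty inputs: all tracks exist, all empty
  d2 <- withr::local_tempdir()
  paths2 <- write_circos_tracks(events[0, ], degs[0, ], genes, d2)
  expect_true(all(vapply(paths2, function(p) length(readLines(p)),
                         integer(1)) == 0L))
})

test_that("track row counts equal event counts per group x state", {
  df <- random_segment_table(120, 3)
  events <- call_cnv_events(df)
  genes <- data.frame(gene = "A", chromosome = 1L, start = 0, end = 1000,
                      strand = "+")
  degs <- data.frame(gene = character(), log2_fc = numeric(),
                     direction = character())
  d <- withr::local_tempdir()
  paths <- write_circos_tracks(events, degs, genes, d)
  for (grp in c("case", "control")) {
    for (st in c("deletion", "duplication")) {
      expected <- sum(events$group == grp & events$state == st)
      got <- length(readLines(paths[[paste(grp, st, sep = "_")]]))
      expect_equal(got, expected)
    }
  }
})
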