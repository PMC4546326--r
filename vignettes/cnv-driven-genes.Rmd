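---
title: "Identifying CNV-driven genes from paired copy-number and expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying CNV-driven genes from paired copy-number and expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvdrive)
```

## The problem

Somatic copy-number variants (CNVs) — DNA segments of at least 1 kb present
at a copy number different from the diploid two — are a major source of
expression change in solid tumors. A gene that is recurrently amplified in
tumors *and* over-expressed (or recurrently deleted *and* under-expressed)
is a candidate **CNV-driven gene**: its expression change is plausibly
caused by the dosage change rather than by downstream regulation. cnvdrive
implements an integrated screen for such genes from two inputs that most
cancer cohorts provide: per-sample copy-number segment profiles (SEG files,
tumor and matched normal) and a tumor/normal expression matrix.

The pipeline has five analytic stages:

1. **Event calling** — segments are classified into deletion/duplication
   events and stratified into length bins.
2. **Burden analysis** — per-chromosome, per-bin event counts in cases vs
   controls, with a sample-label permutation test.
3. **Gene-level CNV calling** — events are mapped onto gene models; genes
   recurrently altered in cases and never in controls are retained.
4. **DEG screening** — genes with |log2 fold change| > 1 between tumor and
   normal groups.
5. **Driver classification** — CNV genes that are also DEGs are kept when
   the expression direction matches the copy-number direction, followed by
   optional hypergeometric gene-set enrichment of the result.

## Conventions and the copy-number scale

Two scales appear throughout and are easy to confuse:

* the **segment mean** carried by SEG files is `log2(CN / 2)` — the log2
  ratio of the measured copy number to the diploid reference, so 0 means
  two copies;
* the **log2 absolute copy number** used for gene-level reporting is
  `log2(CN) = segment_mean + 1`, so the diploid state sits at exactly 1,
  values above 1 are duplications and values below 1 deletions.

The `+1` conversion (`segment_mean_to_log2cn()`) is the only reading under
which "greater than one means increase, less than one means depletion", a
diploid reference of copy number 2, and gene-level values slightly above 1
for single-copy gains are simultaneously coherent. A segment whose mean is
missing in a sample is filled with 0 (neutral) and produces no event.

Internally all intervals are **0-based half-open**; SEG input defaults to
the common 1-based inclusive dialect and is normalized on read
(`seg_dialect()` declares other layouts). Only autosomes 1–22 are accepted:
sex chromosomes have group-specific baseline copy numbers that the diploid
convention does not describe.

State classification uses a dead-band of `epsilon = 1e-9` around 1, so
segments that are neutral up to floating-point noise are not called. Length
bins are B1 = [1, 10] kb, B2 = (10, 50] kb, B3 = (50, ∞) kb; shared
endpoints go to the lower bin so the bins tile `[1 kb, ∞)` exactly, and
sub-1 kb segments are excluded because they do not meet the CNV size
definition.

## The burden permutation test

For every (chromosome, state, length-bin) cell, `burden_table()` reports
case and control event counts and the per-sample-normalized ratio
`(n_case / N_case) / (n_control / N_control)`, which reduces to the naive
count ratio for equal cohort sizes and is reported as missing (not
infinity) when controls have no events.

Significance comes from a permutation test whose unit is the **sample**:
case/control labels are reshuffled over samples, each sample keeping its
own events, which preserves within-sample event correlation. The statistic
is `|log ratio|` (two-sided — enrichment and depletion in cases are both
extreme) and the p-value is the add-one empirical estimator
`(1 + #exceeding) / (B + 1)` with B = 1000 replicates by default, so p is
never 0 and never undercuts `1/(B+1)`. Replicates with an undefined ratio
(zero control events) count as non-exceeding when the observed statistic is
finite; when the observed cell itself is one-sided its statistic is
infinite and only equally one-sided replicates count, which keeps p defined
for case-only cells. All cells share one permutation stream, so the full
table is byte-reproducible under a fixed seed. No multiple-testing
correction is applied across the 22 × 2 × 3 cells in the primary columns —
the p-values mirror the per-cell design — but a Benjamini–Hochberg
`q_value` column is emitted alongside, clearly labelled as auxiliary.

With small expected counts the permutation p-value is valid but
conservative (super-uniform), a generic property of discrete test
statistics rather than a defect of the estimator; the calibration check
below therefore uses a scenario with large cell counts where the statistic
is effectively continuous.

## Gene-level calling and the frequency filter

"Genes located within CNV regions" is read as **full containment** of the
gene interval in the event interval (default `containment = "full"`;
`"any_overlap"` is available as an escape hatch). Containment queries run
on an IRanges interval index; the test suite checks the index against a
brute-force quadratic scan on random instances. When several events of one
sample cover a gene with conflicting states, the call with the larger
departure from neutral (`|log2cn − 1|`) wins, with deterministic
tie-breaks.

A gene is retained as CNV-related when

* its CNV is detected in **more than** 80% of cases (strict inequality:
  exactly 80% fails),
* it is detected in **no** control sample (`max_control_fraction = 0`, the
  strictest reading of "not detected in controls"), and
* one single state accounts for that recurrence — a gene duplicated in 50%
  of cases and deleted in another 40% is not a recurrent event. This
  consistent-state requirement is a design choice: the driver definition
  needs one copy-number direction per gene.

The gene-level `log2(copy number)` is the mean log2 absolute copy number
over the case samples carrying the recurrent state.

## DEG screen and driver classification

The expression matrix is assumed to be on the log2 scale already (the
pipeline starts downstream of platform normalization). The fold change is
the difference of group means, `mean(tumor) − mean(normal)`; a matched-pair
mode (mean of within-patient differences) is available for paired designs.
The screen keeps `|log2FC| > 1` (strict), with no significance filter —
fold-change-only screening is the stated design. Up- plus down-counts equal
the DEG count by construction.

A candidate is **CNV-driven** when `sign(log2cn − 1) = sign(log2FC)`:
duplicated-and-up or deleted-and-down. Concordance is evaluated on signs
relative to the neutral values (1 and 0), never on magnitudes. The bundled
`lusc_candidates()` table — 16 candidate genes from a published lung
squamous-cell-carcinoma cohort with their gene-level log2 copy number and
log2 fold change — illustrates the classifier: all 16 rows are
duplicated-and-up, 7 on chromosome 1 and 3 on chromosome 3:

```{r}
driven <- classify_driven(lusc_candidates())
nrow(driven)
chromosome_summary(driven)
```

Enrichment of the driven list uses the upper-tail hypergeometric
probability `P(X ≥ k)` against a user-supplied GMT collection, with the
universe defaulting to the genes measured on the expression platform (not
the whole genome — the driven list can only ever contain measured genes).
The EASE variant (one overlapping gene removed before taking the tail),
used by the DAVID service, is available behind `ease = TRUE`; results of
the two differ for small overlaps, and term lists obtained from DAVID's
annotation snapshots are not comparable across database versions.

## The synthetic-data generator

`simulate_dataset()` builds a complete paired dataset so every stage is
testable without downloads: a toy genome (three chromosomes of 40/30/20 Mb),
200 non-overlapping genes of 2–8 kb placed uniformly, per-sample segment
profiles, and a log2 expression matrix.

* **Planted drivers**: each driver gene is fully covered by an event of its
  assigned state in `⌈carrier_fraction × n_cases⌉` cases (the gene interval
  extended by uniform margins of up to 20 kb per side) and in no control.
  Duplication events draw log2cn uniformly on (1.4, 1.8) (mean 1.6),
  deletions on (0.2, 0.6).
* **Background**: every sample, case and control alike, receives Poisson
  numbers of random events per length bin (default rate 1 per bin per
  sample) at uniform positions — so background events can hit non-driver
  genes by chance; it is the frequency filter's job, not the generator's,
  to remove them.
* **Expression**: gene g in sample s is `baseline_g + shift_g · carrier(g,s)
  + N(0, noise_sd)`, with per-gene baselines uniform on (4, 12) log2 units,
  `noise_sd = 0.3` by default, and shifts only on planted drivers. Shifts
  may deliberately disagree in sign with the planted state to create
  discordant decoys that the driver classifier must reject.

The reference validation scenario is 20 cases / 20 controls with 10 drivers
at carrier fraction 0.9 and |shift| = 2. All draws flow from one integer
seed in a fixed order (genome, segments, expression), making every dataset
fully reproducible.

What the generator does **not** emulate: SNP6 probe-level noise,
segmentation artefacts, GC waves, subclonal mixtures, correlated event
placement (chromothripsis), or expression covariance between genes. Passing
tests on synthetic data therefore demonstrate the correctness of the
pipeline's logic under its stated model, not robustness to real-array
artefacts.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle and the
whole pipeline against its own generator, at sizes chosen to keep the
default run fast:

* interval mapping vs a quadratic brute-force scan on 100 random instances
  (≤ 50 genes × ≤ 200 events);
* Monte-Carlo permutation p vs exhaustive label enumeration on 2-vs-2 and
  3-vs-3 cohorts at 10,000 replicates;
* the hypergeometric tail vs exhaustive enumeration of all draws for
  universes up to N = 12;
* parameter recovery: across 20 seeds of the reference scenario the
  pipeline recovers at least 9 of 10 planted drivers with no false driver
  calls in at least 90% of seeds;
* null calibration: with no planted signal and background rate 10 per bin
  per sample (large counts, see above), permutation p-values over 200
  simulated datasets stay within Kolmogorov–Smirnov distance 0.15 of
  uniform.

## Known limitations

* The frequency filter's zero-tolerance control rule is brittle on real
  cohorts with noisy normals; `max_control_fraction` exposes the knob.
* Recurrence is assessed per gene with no significance model for focal
  peaks (no GISTIC-style analysis); segment re-segmentation and merging are
  out of scope.
* The DEG screen is fold-change-only by design; users wanting
  moderated-variance tests should run limma upstream and feed the resulting
  matrix in.
* The permutation unit is the sample, never the segment; with very few
  samples the attainable p-values are coarse.
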