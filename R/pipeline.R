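#' Build a pipeline configuration
#'
#' One object carrying every input path and every threshold the pipeline
#' applies. `NULL` paths disable the corresponding optional stage
#' (enrichment needs `gene_sets`).
#'
#' @param cases,controls SEG paths for the case and control cohorts.
#' @param expression,sample_groups expression matrix and its group side-car.
#' @param gene_models BED-like gene-model path.
#' @param gene_sets optional GMT path; enables the enrichment stage.
#' @param out_dir output directory for stage results.
#' @param seg_one_based,seg_end_inclusive,seg_has_num_probes,seg_has_header
#'   SEG dialect flags (see [seg_dialect()]).
#' @param epsilon neutral dead-band for state classification.
#' @param containment gene-in-event rule, `"full"` or `"any_overlap"`.
#' @param min_case_fraction,max_control_fraction frequency-filter bounds.
#' @param deg_cutoff fold-change cutoff on the log2 scale.
#' @param alpha enrichment significance cut-off.
#' @param n_replicates permutation replicates for the burden test.
#' @param seed integer seed for the permutation stream.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(cases, controls, expression, sample_groups,
                            gene_models, gene_sets = NULL,
                            out_dir = "cnvdrive_out",
                            seg_one_based = TRUE, seg_end_inclusive = TRUE,
                            seg_has_num_probes = TRUE, seg_has_header = TRUE,
                            epsilon = 1e-9,
                            containment = "full",
                            min_case_fraction = 0.8,
                            max_control_fraction = 0,
                            deg_cutoff = 1, alpha = 0.05,
                            n_replicates = 1000, seed = 1L) {
  stopifnot(epsilon > 0, min_case_fraction >= 0, min_case_fraction <= 1,
            max_control_fraction >= 0, max_control_fraction <= 1,
            deg_cutoff >= 0, alpha > 0, alpha <= 1, n_replicates >= 1)
  structure(list(cases = cases, controls = controls,
                 expression = expression, sample_groups = sample_groups,
                 gene_models = gene_models, gene_sets = gene_sets,
                 out_dir = out_dir,
                 seg_one_based = seg_one_based,
                 seg_end_inclusive = seg_end_inclusive,
                 seg_has_num_probes = seg_has_num_probes,
                 seg_has_header = seg_has_header,
                 epsilon = epsilon,
                 containment = match.arg(containment,
                                         c("full", "any_overlap")),
                 min_case_fraction = min_case_fraction,
                 max_control_fraction = max_control_fraction,
                 deg_cutoff = deg_cutoff, alpha = alpha,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML path.
#' @return [read_pipeline_config()]: a `"pipeline_config"`;
#'   [write_pipeline_config()]: `path`, invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config a `"pipeline_config"`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the integrated CNV / expression pipeline
#'
#' Stages, in dependency order: read and normalize inputs; call CNV events;
#' burden table with permutation p-values; gene-level CNV profiles and the
#' frequency filter; fold-change DEG screen; sign-concordance driven-gene
#' classification; optional gene-set enrichment of the driven genes
#' (universe = genes measured on the expression platform); Circos track
#' export. Every stage output is written as TSV under `config$out_dir`
#' together with a JSON run manifest (config hash, seed, per-stage row
#' counts). Reruns with the same config and inputs are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return list of class `"cnvdrive_run"` with elements `events`, `burden`,
#'   `gene_profiles`, `cnv_genes`, `log2fc`, `degs`, `driven`,
#'   `enrichment` (or `NULL`), `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  required <- c(config$cases, config$controls, config$expression,
                config$sample_groups, config$gene_models, config$gene_sets)
  missing <- required[!file.exists(required)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  dialect <- seg_dialect(has_header = config$seg_has_header,
                         one_based = config$seg_one_based,
                         end_inclusive = config$seg_end_inclusive,
                         has_num_probes = config$seg_has_num_probes)
  cases <- read_segments(config$cases, dialect, group = "case")
  controls <- read_segments(config$controls, dialect, group = "control")
  expr <- read_expression(config$expression, config$sample_groups)
  genes <- read_gene_models(config$gene_models)

  segments <- rbind(cases, controls)
  events <- call_cnv_events(segments, epsilon = config$epsilon)
  groups <- stats::setNames(
    rep(c("case", "control"),
        c(length(unique(cases$sample)), length(unique(controls$sample)))),
    c(unique(cases$sample), unique(controls$sample)))

  chroms <- sort(unique(c(genes$chromosome, events$chromosome)))
  burden <- burden_table(events, groups, chromosomes = chroms,
                         n_replicates = config$n_replicates,
                         seed = config$seed)

  profiles <- gene_cnv_profiles(events, genes, groups,
                                containment = config$containment)
  cnv_genes <- frequency_filter(profiles,
                                min_case_fraction = config$min_case_fraction,
                                max_control_fraction =
                                  config$max_control_fraction)

  log2fc <- compute_log2fc(expr)
  degs <- screen_degs(log2fc, cutoff = config$deg_cutoff)
  driven <- find_driven_genes(cnv_genes, degs, expr$genes)

  enrichment <- NULL
  if (!is.null(config$gene_sets) && nrow(driven)) {
    sets <- read_gene_sets(config$gene_sets)
    enrichment <- enrich(driven$gene, sets, universe = expr$genes,
                         alpha = config$alpha)
  }

  # stage outputs
  out <- function(name) file.path(config$out_dir, name)
  write_tsv(events, out("cnv_events.tsv"))
  write_tsv(as.data.frame(burden), out("burden.tsv"))
  write_tsv(as.data.frame(cnv_genes), out("cnv_genes.tsv"))
  write_tsv(degs, out("degs.tsv"))
  write_tsv(as.data.frame(driven), out("driven_genes.tsv"))
  if (!is.null(enrichment)) {
    write_tsv(as.data.frame(enrichment), out("enrichment.tsv"))
  }
  write_circos_tracks(events, degs, genes, out("circos"))

  cfg_path <- out("config.yaml")
  write_pipeline_config(config, cfg_path)
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    thresholds = list(epsilon = config$epsilon,
                      containment = config$containment,
                      min_case_fraction = config$min_case_fraction,
                      max_control_fraction = config$max_control_fraction,
                      deg_cutoff = config$deg_cutoff,
                      alpha = config$alpha,
                      n_replicates = config$n_replicates),
    rows = list(segments = nrow(segments), events = nrow(events),
                burden_cells = nrow(burden), cnv_genes = nrow(cnv_genes),
                degs = nrow(degs), driven = nrow(driven),
                enrichment = if (is.null(enrichment)) 0L
                             else nrow(enrichment)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  structure(list(events = events, burden = burden,
                 gene_profiles = profiles, cnv_genes = cnv_genes,
                 log2fc = log2fc, degs = degs, driven = driven,
                 enrichment = enrichment, manifest = manifest,
                 config = config),
            class = "cnvdrive_run")
}

#' @export
print.cnvdrive_run <- function(x, ...) {
  r <- x$manifest$rows
  cat("cnvdrive run\n")
  cat("  CNV events:         ", r$events, "\n")
  cat("  recurrent CNV genes:", r$cnv_genes, "\n")
  cat("  DEGs:               ", r$degs, "\n")
  cat("  CNV-driven genes:   ", r$driven, "\n")
  if (r$enrichment > 0) cat("  enriched terms:     ", r$enrichment, "\n")
  invisible(x)
}

#' @export
summary.cnvdrive_run <- function(object, ...) {
  print(object)
  f <- attr(object$driven, "funnel")
  if (!is.null(f)) {
    cat("funnel: ", f$n_cnv, " CNV genes -> ", f$n_measured,
        " on platform -> ", f$n_deg, " DEGs -> ", f$n_driven,
        " sign-concordant driven genes\n", sep = "")
  }
  if (nrow(object$driven)) {
    cs <- chromosome_summary(object$driven)
    cat("driven genes per chromosome: ",
        paste(sprintf("chr%s: %d", names(cs), cs), collapse = ", "), "\n")
  }
  invisible(object)
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' Emits the four pipeline inputs (case/control SEG in the internal
#' 0-based half-open dialect, expression TSV + group side-car, BED-like
#' gene models) plus the planted-driver ground truth.
#'
#' @param sim output of [simulate_dataset()].
#' @param out_dir output directory, created if needed.
#' @return named character vector of written paths, invisibly.
#' @export
write_simulated_dataset <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(cases = file.path(out_dir, "cases.seg"),
         controls = file.path(out_dir, "controls.seg"),
         expression = file.path(out_dir, "expression.tsv"),
         sample_groups = file.path(out_dir, "sample_groups.tsv"),
         gene_models = file.path(out_dir, "genes.bed"),
         truth = file.path(out_dir, "truth.tsv"))
  write_segments(sim$case_segments, p[["cases"]])
  write_segments(sim$control_segments, p[["controls"]])
  write_expression(sim$expression, p[["expression"]], p[["sample_groups"]])
  write_gene_models(sim$genes, p[["gene_models"]])
  write_tsv(sim$truth, p[["truth"]])
  invisible(p)
}
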