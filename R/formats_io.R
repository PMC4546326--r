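#' Declare the dialect of a SEG segment file
#'
#' Copy-number segment files come in slightly different flavours: with or
#' without a header line, with or without a probe-count column, and with
#' coordinates that are 1-based inclusive (the common SEG convention) or
#' 0-based half-open (BED-style). `seg_dialect()` captures those choices so
#' [read_segments()] can normalize everything to the package's internal
#' convention: 0-based half-open intervals on autosomes 1-22.
#'
#' @param has_header logical; does the file start with a column-name line?
#' @param one_based logical; are start coordinates 1-based?
#' @param end_inclusive logical; does `end` point at the last covered base
#'   (inclusive) rather than one past it (half-open)?
#' @param has_num_probes logical; is there a probe-count column between `end`
#'   and `segment_mean`?
#' @return A list of class `"seg_dialect"`.
#' @examples
#' seg_dialect()                      # standard SEG: 1-based inclusive
#' seg_dialect(one_based = FALSE,
#'             end_inclusive = FALSE) # internal/BED-style coordinates
#' @export
seg_dialect <- function(has_header = TRUE, one_based = TRUE,
                        end_inclusive = TRUE, has_num_probes = TRUE) {
  stopifnot(is.logical(has_header), is.logical(one_based),
            is.logical(end_inclusive), is.logical(has_num_probes))
  structure(list(has_header = has_header, one_based = one_based,
                 end_inclusive = end_inclusive,
                 has_num_probes = has_num_probes),
            class = "seg_dialect")
}

#' Read a SEG segment file
#'
#' Parses a tab-delimited segment file (sample, chromosome, start, end,
#' optional probe count, segment mean) and normalizes it to the internal
#' convention: 0-based half-open coordinates, integer chromosomes 1-22.
#' The segment mean is the log2 ratio of the measured copy number to the
#' diploid reference, so 0 means two copies.
#'
#' Malformed rows are an error (never silently skipped); the error names the
#' offending line. Sex chromosomes are rejected.
#'
#' @param path path to the segment file.
#' @param dialect a [seg_dialect()] describing the file's conventions.
#' @param group optional group label ("case" or "control") attached to every
#'   segment; `NA` leaves it unset.
#' @return A data.frame with columns `sample`, `group`, `chromosome`,
#'   `start`, `end`, `segment_mean` (0-based half-open coordinates).
#' @seealso [write_segments()], [call_cnv_events()]
#' @export
read_segments <- function(path, dialect = seg_dialect(), group = NA) {
  if (!file.exists(path)) stop("segment file not found: ", path, call. = FALSE)
  stopifnot(inherits(dialect, "seg_dialect"))
  if (!is.na(group)) group <- match.arg(group, c("case", "control"))

  lines <- readLines(path)
  body_start <- if (dialect$has_header) 2L else 1L
  ncol_expect <- if (dialect$has_num_probes) 6L else 5L
  keep <- which(nzchar(trimws(lines)))
  keep <- keep[keep >= body_start]

  out <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(fields) != ncol_expect) {
      stop("malformed segment row at line ", ln, ": expected ", ncol_expect,
           " tab-separated fields, found ", length(fields), call. = FALSE)
    }
    start <- suppressWarnings(as.numeric(fields[3]))
    end <- suppressWarnings(as.numeric(fields[4]))
    if (is.na(start) || is.na(end)) {
      stop("malformed segment row at line ", ln,
           ": unparseable coordinates '", fields[3], "', '", fields[4], "'",
           call. = FALSE)
    }
    sm_field <- fields[ncol_expect]
    if (sm_field %in% c("", "NA", "na", ".")) {
      segment_mean <- NA_real_  # missing: filled neutral by fill_missing()
    } else {
      segment_mean <- suppressWarnings(as.numeric(sm_field))
      if (is.na(segment_mean)) {
        stop("malformed segment row at line ", ln,
             ": unparseable segment mean '", sm_field, "'", call. = FALSE)
      }
    }
    out[[i]] <- list(sample = fields[1], chromosome = fields[2],
                     start = start, end = end, segment_mean = segment_mean)
  }
  df <- do.call(rbind.data.frame, c(out, stringsAsFactors = FALSE))
  if (length(keep) == 0L) {
    df <- data.frame(sample = character(), chromosome = character(),
                     start = numeric(), end = numeric(),
                     segment_mean = numeric(), stringsAsFactors = FALSE)
  }

  df$chromosome <- if (nrow(df)) normalize_chromosome(df$chromosome) else integer()
  # normalize to 0-based half-open
  df$start <- df$start - as.integer(dialect$one_based)
  df$end <- df$end - as.integer(dialect$one_based) +
    as.integer(dialect$end_inclusive)
  bad <- df$start >= df$end | df$start < 0
  if (any(bad)) {
    stop("segment(s) with non-positive length or negative start at input line(s): ",
         paste(keep[bad], collapse = ", "), call. = FALSE)
  }
  data.frame(sample = df$sample, group = rep(as.character(group), nrow(df)),
             chromosome = df$chromosome, start = df$start, end = df$end,
             segment_mean = df$segment_mean, stringsAsFactors = FALSE)
}

#' Write segments in the internal normalized convention
#'
#' Emits a tab-delimited table with header `sample chromosome start end
#' segment_mean`, 0-based half-open coordinates and bare integer chromosome
#' labels. Reading the result back with
#' `seg_dialect(one_based = FALSE, end_inclusive = FALSE,
#' has_num_probes = FALSE)` reproduces the input table.
#'
#' @param segments data.frame as returned by [read_segments()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  cols <- c("sample", "chromosome", "start", "end", "segment_mean")
  stopifnot(all(cols %in% names(segments)))
  write_tsv(segments[, cols, drop = FALSE], path)
}

#' Read a log2 expression matrix with tumor/normal sample labels
#'
#' The expression file is tab-delimited: first column `gene` (unique gene
#' symbols), remaining columns one per sample, values on the log2 scale.
#' The side-car group file maps every sample id to a group label, `tumor`
#' or `normal`; both groups must be non-empty.
#'
#' @param path path to the expression TSV.
#' @param groups_path path to the two-column (`sample`, `group`) TSV.
#' @return A list of class `"expression_matrix"` with elements `values`
#'   (gene x sample numeric matrix), `genes`, `samples` and `groups`
#'   (named character vector, `"tumor"`/`"normal"`).
#' @export
read_expression <- function(path, groups_path) {
  if (!file.exists(path)) stop("expression file not found: ", path, call. = FALSE)
  if (!file.exists(groups_path)) {
    stop("sample group file not found: ", groups_path, call. = FALSE)
  }
  df <- read_tsv(path)
  if (names(df)[1] != "gene") {
    stop("expression matrix must have 'gene' as its first column", call. = FALSE)
  }
  if (anyDuplicated(df$gene)) {
    stop("duplicated gene symbol(s) in expression matrix: ",
         paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "),
         call. = FALSE)
  }
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- df$gene

  gdf <- read_tsv(groups_path)
  stopifnot(all(c("sample", "group") %in% names(gdf)))
  if (anyDuplicated(gdf$sample)) {
    stop("sample(s) with more than one group label: ",
         paste(unique(gdf$sample[duplicated(gdf$sample)]), collapse = ", "),
         call. = FALSE)
  }
  groups <- stats::setNames(gdf$group, gdf$sample)
  expression_matrix(values, groups)
}

#' Construct and validate an expression matrix object
#'
#' @param values gene x sample numeric matrix (log2 scale), with rownames
#'   (gene symbols) and colnames (sample ids).
#' @param groups named character vector mapping every sample id to
#'   `"tumor"` or `"normal"`.
#' @return A list of class `"expression_matrix"`.
#' @export
expression_matrix <- function(values, groups) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (anyDuplicated(rownames(values))) {
    stop("duplicated gene symbols", call. = FALSE)
  }
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing)) {
    stop("sample(s) without a group label: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  groups <- groups[colnames(values)]
  if (!all(groups %in% c("tumor", "normal"))) {
    stop("group labels must be 'tumor' or 'normal'", call. = FALSE)
  }
  if (!all(c("tumor", "normal") %in% groups)) {
    stop("both tumor and normal groups must be non-empty", call. = FALSE)
  }
  structure(list(values = values, genes = rownames(values),
                 samples = colnames(values), groups = groups),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", length(x$genes), "genes x",
      length(x$samples), "samples (",
      sum(x$groups == "tumor"), "tumor /", sum(x$groups == "normal"),
      "normal )\n")
  invisible(x)
}

#' Write an expression matrix and its sample-group side-car
#'
#' @param expr an `"expression_matrix"` object.
#' @param path output path for the expression TSV.
#' @param groups_path output path for the sample-group TSV.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, groups_path) {
  stopifnot(inherits(expr, "expression_matrix"))
  df <- data.frame(gene = expr$genes, expr$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
  write_tsv(data.frame(sample = expr$samples,
                       group = unname(expr$groups[expr$samples]),
                       stringsAsFactors = FALSE), groups_path)
  invisible(path)
}

#' Read BED-like gene models
#'
#' Five tab-separated columns, no header: chromosome, start, end, gene
#' symbol, strand. Coordinates are 0-based half-open (BED convention), which
#' is also the package's internal convention. Strand is carried along but
#' ignored by overlap logic (copy number is strand-free).
#'
#' @param path path to the gene-model file.
#' @return data.frame with columns `gene`, `chromosome`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("gene model file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chromosome", "start", "end",
                                        "gene", "strand"))
  df$chromosome <- normalize_chromosome(df$chromosome)
  if (anyDuplicated(df$gene)) {
    stop("duplicated gene symbol(s) in gene models: ",
         paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(df$start >= df$end)) {
    stop("gene model(s) with start >= end", call. = FALSE)
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  df[, c("gene", "chromosome", "start", "end", "strand")]
}

#' Write gene models in the BED-like layout read by [read_gene_models()]
#' @param genes data.frame with columns `gene`, `chromosome`, `start`,
#'   `end`, `strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  utils::write.table(genes[, c("chromosome", "start", "end", "gene", "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' One set per line: term id, description, then member gene symbols, all
#' tab-separated. Symbols are upper-cased so membership tests are
#' case-insensitive. Empty sets are an error.
#'
#' @param path path to the GMT file.
#' @return A named list of class `"gene_set_collection"`; each element has
#'   `description` and `genes`.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("gene set file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop("GMT line ", i, " ('", fields[1],
           "') has no member genes", call. = FALSE)
    }
    genes <- unique(toupper(fields[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (!length(genes)) {
      stop("GMT line ", i, " ('", fields[1],
           "') has no member genes", call. = FALSE)
    }
    sets[[fields[1]]] <- list(description = fields[2], genes = genes)
  }
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#' @param sets a `"gene_set_collection"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(id) {
    paste(c(id, sets[[id]]$description, sets[[id]]$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export Circos-ready track files
#'
#' Emits plain-text tracks (chromosome, start, end, value) consumable by the
#' standard circular-plot tool; no plotting is performed here. One track per
#' group x state combination of the CNV events (value = log2 copy number)
#' plus one DEG track whose value is the signed log2 fold change, so up- and
#' down-regulated genes can be colour-coded.
#'
#' @param events CNV events from [call_cnv_events()] (must carry `group`).
#' @param degs DEG table from [screen_degs()].
#' @param genes gene models (used to place DEGs on the genome); DEGs absent
#'   from the annotation are dropped.
#' @param out_dir output directory, created if needed.
#' @return Named character vector of the five written file paths, invisibly.
#' @export
write_circos_tracks <- function(events, degs, genes, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (grp in c("case", "control")) {
    for (st in c("deletion", "duplication")) {
      sel <- events[events$group == grp & events$state == st, , drop = FALSE]
      p <- file.path(out_dir, paste0("cnv_", grp, "_", st, ".txt"))
      trk <- data.frame(chromosome = sel$chromosome, start = sel$start,
                        end = sel$end, value = sel$log2_copy_number)
      utils::write.table(trk, p, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      paths[paste(grp, st, sep = "_")] <- p
    }
  }
  hit <- merge(degs, genes, by = "gene")
  p <- file.path(out_dir, "deg.txt")
  trk <- data.frame(chromosome = hit$chromosome, start = hit$start,
                    end = hit$end, value = hit$log2_fc)
  trk <- trk[order(trk$chromosome, trk$start), , drop = FALSE]
  utils::write.table(trk, p, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  paths["deg"] <- p
  invisible(paths)
}
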