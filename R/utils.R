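#' @keywords internal
"_PACKAGE"

# Autosome label normalization: "chr1" and "1" are both accepted; sex
# chromosomes and anything else are rejected (burden tables cover chr 1-22).
normalize_chromosome <- function(x) {
  lab <- sub("^chr", "", as.character(x), ignore.case = TRUE)
  n <- suppressWarnings(as.integer(lab))
  bad <- is.na(n) | n < 1L | n > 22L | lab != as.character(n)
  if (any(bad)) {
    stop("unsupported chromosome label(s) (autosomes 1-22 only): ",
         paste(unique(as.character(x)[bad]), collapse = ", "),
         call. = FALSE)
  }
  n
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable column writer used by every TSV emitter so round trips are
# byte-identical
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
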