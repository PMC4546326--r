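#' Convert a SEG segment mean to log2 absolute copy number
#'
#' The segment mean in a SEG file is the log2 ratio of the measured copy
#' number to the diploid reference (copy number 2), so 0 means two copies.
#' Adding 1 yields the log2 of the absolute copy number
#' (`log2(CN) = log2(CN/2) + 1`), which places the diploid state at exactly
#' 1: values above 1 are copy-number increases, values below 1 depletions.
#' This is the scale on which gene-level copy numbers are reported.
#'
#' @param segment_mean numeric vector of segment means (log2 CN/2).
#' @return log2 absolute copy number, same length.
#' @examples
#' segment_mean_to_log2cn(0)    # 1: diploid
#' segment_mean_to_log2cn(-1)   # 0: single copy
#' @export
segment_mean_to_log2cn <- function(segment_mean) {
  if (!is.numeric(segment_mean) || any(!is.finite(segment_mean))) {
    stop("segment_mean must be finite numeric", call. = FALSE)
  }
  segment_mean + 1
}

#' Classify a log2 copy number as deletion, neutral or duplication
#'
#' Three-way classification around the diploid value 1 with a small
#' dead-band so floating-point-neutral segments are not called: values in
#' `[1 - epsilon, 1 + epsilon]` are neutral.
#'
#' @param log2cn numeric vector of log2 absolute copy numbers.
#' @param epsilon half-width of the neutral dead-band (default 1e-9).
#' @return character vector in `{"deletion", "neutral", "duplication"}`.
#' @export
classify_state <- function(log2cn, epsilon = 1e-9) {
  if (!is.numeric(log2cn) || any(!is.finite(log2cn))) {
    stop("log2cn must be finite numeric", call. = FALSE)
  }
  stopifnot(epsilon > 0)
  out <- rep("neutral", length(log2cn))
  out[log2cn > 1 + epsilon] <- "duplication"
  out[log2cn < 1 - epsilon] <- "deletion"
  out
}

#' Assign a CNV length bin
#'
#' CNVs are stratified into three size classes: 1-10 kb, 10-50 kb and
#' >50 kb. Shared endpoints go to the lower bin, so the bins tile
#' `[1000, Inf)` exactly: B1 = \[1000, 10000\], B2 = (10000, 50000\],
#' B3 = (50000, Inf). Segments shorter than 1 kb are not CNVs (the
#' definition requires >= 1 kb) and get `NA`.
#'
#' @param length_bp integer vector of segment lengths in base pairs.
#' @return character vector in `{"B1", "B2", "B3", NA}`.
#' @export
assign_length_bin <- function(length_bp) {
  stopifnot(is.numeric(length_bp), all(length_bp >= 1))
  out <- rep(NA_character_, length(length_bp))
  out[length_bp >= 1000 & length_bp <= 10000] <- "B1"
  out[length_bp > 10000 & length_bp <= 50000] <- "B2"
  out[length_bp > 50000] <- "B3"
  out
}

#' Length-bin labels and their size ranges
#' @return Named character vector describing the three bins.
#' @export
length_bin_labels <- function() {
  c(B1 = "1-10 kb", B2 = "10-50 kb", B3 = ">50 kb")
}

#' Fill missing segment means with the neutral value
#'
#' A segment whose mean is missing in a sample is treated as copy-number
#' neutral: the segment mean is set to 0, hence the log2 copy number to 1,
#' and the segment produces no CNV event.
#'
#' @param segment_mean numeric vector, possibly with `NA`s.
#' @return numeric vector with `NA`s replaced by 0.
#' @export
fill_missing <- function(segment_mean) {
  segment_mean[is.na(segment_mean)] <- 0
  segment_mean
}

#' Call classified CNV events from normalized segments
#'
#' Applies, in order: the missing-value fill ([fill_missing()]), the
#' segment-mean to log2-copy-number conversion, the three-way state
#' classification and the length-bin assignment. Segments that are
#' copy-number neutral or shorter than 1 kb are dropped: they are not CNVs.
#'
#' @param segments data.frame from [read_segments()] (columns `sample`,
#'   `group`, `chromosome`, `start`, `end`, `segment_mean`).
#' @param epsilon neutral dead-band passed to [classify_state()].
#' @return data.frame of events with the segment columns plus
#'   `log2_copy_number`, `state` and `length_bin`.
#' @export
call_cnv_events <- function(segments, epsilon = 1e-9) {
  sm <- fill_missing(segments$segment_mean)
  log2cn <- segment_mean_to_log2cn(sm)
  state <- classify_state(log2cn, epsilon)
  len <- segments$end - segments$start
  bin <- assign_length_bin(pmax(len, 1))
  keep <- state != "neutral" & !is.na(bin)
  ev <- segments[keep, , drop = FALSE]
  ev$segment_mean <- sm[keep]
  ev$log2_copy_number <- log2cn[keep]
  ev$state <- state[keep]
  ev$length_bin <- bin[keep]
  rownames(ev) <- NULL
  ev
}
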