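#' Hypergeometric over-representation analysis of a gene list
#'
#' Tests each gene set for over-representation in a query list against a
#' background universe, with the upper-tail hypergeometric probability
#' `P(X >= k)` of observing at least `k` query genes in a set of size `K`
#' when `n` genes are drawn from a universe of size `N`. Sets are
#' intersected with the universe before testing; the query must be a subset
#' of the universe. Gene symbols are matched case-insensitively.
#'
#' `ease = TRUE` applies the more conservative EASE variant used by the
#' DAVID service, which removes one overlapping gene before taking the tail
#' (`P(X >= k - 1)` on the reduced table; `k = 0` or `k = 1` then gives
#' p = 1).
#'
#' @param query character vector of query gene symbols.
#' @param gene_sets a `"gene_set_collection"` from [read_gene_sets()].
#' @param universe character vector of background gene symbols (e.g. all
#'   genes measured on the expression platform).
#' @param alpha significance cut-off used for the `significant` flag
#'   (default 0.05).
#' @param ease use the EASE-score variant (default `FALSE`).
#' @return data.frame of class `"enrichment_result"`, one row per non-empty
#'   set, sorted by ascending p-value: `term`, `description`, `k`, `K`,
#'   `n`, `N`, `p_value`, `q_value` (Benjamini-Hochberg, auxiliary),
#'   `significant`, `genes_hit` (comma-separated).
#' @export
enrich <- function(query, gene_sets, universe, alpha = 0.05, ease = FALSE) {
  universe <- unique(toupper(universe))
  query <- unique(toupper(query))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  if (!length(query)) stop("empty query", call. = FALSE)
  extra <- setdiff(query, universe)
  if (length(extra)) {
    stop("query gene(s) outside the universe: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(gene_sets), function(id) {
    members <- intersect(gene_sets[[id]]$genes, universe)
    K <- length(members)
    if (!K) return(NULL)
    hit <- intersect(query, members)
    k <- length(hit)
    data.frame(term = id, description = gene_sets[[id]]$description,
               k = k, K = K, n = n, N = N,
               p_value = hypergeom_tail_p(k, K, n, N, ease = ease),
               genes_hit = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop("no gene set overlaps the universe", call. = FALSE)
  }
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < alpha
  out <- out[order(out$p_value, out$term), ,
             drop = FALSE]
  out <- out[, c("term", "description", "k", "K", "n", "N", "p_value",
                 "q_value", "significant", "genes_hit")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` where `X ~ Hypergeometric(N, K, n)`: the number of successes
#' when drawing `n` genes without replacement from a universe of `N` genes
#' of which `K` belong to the set. `k = 0` gives 1 (the certain event).
#'
#' @param k observed overlap.
#' @param K set size within the universe.
#' @param n query size.
#' @param N universe size.
#' @param ease subtract one success before taking the tail (EASE score).
#' @return the tail probability, in `(0, 1]`.
#' @export
hypergeom_tail_p <- function(k, K, n, N, ease = FALSE) {
  stopifnot(k >= 0, k <= min(K, n), K <= N, n <= N)
  if (ease) k <- max(k - 1, 0)
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
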