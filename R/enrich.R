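# Overrepresentation analysis of predicted target lists: exact hypergeometric
# upper-tail p-values, BH FDR across terms, and the annotation-frequency
# specificity filter (terms annotating < 15% of gene products are "specific").

#' Hypergeometric overrepresentation p-value
#'
#' Exact upper tail `P(X >= k)` for the number of query genes falling in a
#' term, where `X ~ Hypergeometric(N, K, n)`: a universe of `N` genes of which
#' `K` carry the annotation, sampled `n` at a time (the query).
#'
#' @param k observed overlap between query and term.
#' @param K term size within the universe.
#' @param n query size.
#' @param N universe size.
#' @return upper-tail probability in \[0, 1\]; `k = 0` gives exactly 1.
#' @export
hypergeom_p <- function(k, K, n, N) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L, length(N) == 1L)
  if (any(c(k, K, n, N) < 0) || k > min(n, K) || K > N || n > N) {
    stop("inconsistent hypergeometric counts")
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Overrepresentation analysis of a gene list
#'
#' One hypergeometric upper-tail test per term, with term members intersected
#' with the universe first, BH adjustment across the tested terms, and the
#' frequency-based specificity flag. The significance threshold applies to the
#' raw p-value (the web-tool convention this reproduces); the FDR is reported
#' alongside.
#'
#' @param query character vector of query gene symbols (must lie in universe).
#' @param universe character vector of background gene symbols.
#' @param collection gene-set list from [read_gene_sets()] or
#'   [simulate_gene_sets()].
#' @param alpha raw-p significance threshold (default 0.01).
#' @param freq_cutoff specificity cutoff on the annotation frequency
#'   (default 0.15, strict `<`).
#' @return `enrichment_table` data.frame: term_id, term_name, k, K, n, N,
#'   p_hyper, fdr_bh, frequency, specific, significant; sorted by p.
#' @export
run_ora <- function(query, universe, collection, alpha = 0.01, freq_cutoff = 0.15) {
  universe <- unique(norm_gene_symbol(universe))
  query <- unique(norm_gene_symbol(query))
  if (!length(query)) stop("empty query gene list")
  extra <- setdiff(query, universe)
  if (length(extra)) {
    stop("query genes missing from universe: ", paste(utils::head(extra, 3), collapse = ", "))
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(collection, function(s) {
    members <- intersect(s$members, universe)
    K <- length(members)
    k <- length(intersect(members, query))
    p <- if (K == 0) 1 else hypergeom_p(k, K, n, N)
    data.frame(term_id = s$term_id, term_name = s$term_name,
               k = k, K = K, n = n, N = N, p_hyper = p,
               frequency = s$frequency, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_bh <- bh_adjust(out$p_hyper)
  out$specific <- !is.na(out$frequency) & out$frequency < freq_cutoff
  out$significant <- out$p_hyper < alpha
  out <- out[order(out$p_hyper, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Specificity filter on annotation frequency
#'
#' Keeps terms whose annotation frequency (proportion of gene products
#' annotated to the term) is strictly below the cutoff; more frequent terms
#' are too general. Terms without a frequency are kept, flagged non-specific,
#' with a warning.
#'
#' @param table an `enrichment_table`.
#' @param cutoff frequency cutoff in (0, 1] (default 0.15).
#' @return filtered table (idempotent).
#' @export
specificity_filter <- function(table, cutoff = 0.15) {
  stopifnot(cutoff > 0, cutoff <= 1)
  has_freq <- !is.na(table$frequency)
  if (any(!has_freq)) {
    warning(sum(!has_freq), " term(s) lack a frequency value; kept unflagged")
  }
  keep <- !has_freq | table$frequency < cutoff
  out <- table[keep, , drop = FALSE]
  out$specific <- !is.na(out$frequency) & out$frequency < cutoff
  rownames(out) <- NULL
  class(out) <- class(table)
  out
}
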