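# Signed bipartite miRNA -> target network and node-strength scoring.
# Each retained miRNA-gene pair becomes one edge weighted +1 when the miRNA is
# upregulated and -1 when downregulated; a gene's node strength is the sum of
# its incident edge weights. Because miRNAs repress their targets, positive
# strength predicts target downregulation and negative strength predicts
# upregulation.

#' Build the signed miRNA-target network
#'
#' Restricts the interaction pairs to differentially expressed miRNAs and
#' assigns each edge the sign of its miRNA's direction (+1 up, -1 down).
#' Pairs whose miRNA is not in the DE list are dropped (their count is kept
#' as an attribute).
#'
#' @param pairs data.frame of unique interaction pairs
#'   (`mirna_id`, `gene_symbol`), e.g. from [read_interactions()].
#' @param de_mirnas data.frame with `feature_id` and `direction`
#'   (`"up"`/`"down"`), typically a filtered `de_table`.
#' @return object of class `target_network` with elements `edges`
#'   (mirna_id, gene_symbol, weight) and `mirna_direction` (named character).
#' @export
build_signed_network <- function(pairs, de_mirnas) {
  stopifnot(nrow(de_mirnas) > 0L)
  ids <- norm_mirna_id(de_mirnas$feature_id)
  dir <- as.character(de_mirnas$direction)
  if (anyNA(dir) || !all(dir %in% c("up", "down"))) {
    stop("DE miRNA with missing or unknown direction")
  }
  if (anyDuplicated(ids)) stop("duplicate miRNA ids in DE list")
  direction <- stats::setNames(dir, ids)
  pairs <- unique(data.frame(mirna_id = norm_mirna_id(pairs$mirna_id),
                             gene_symbol = norm_gene_symbol(pairs$gene_symbol),
                             stringsAsFactors = FALSE))
  keep <- pairs$mirna_id %in% ids
  edges <- pairs[keep, , drop = FALSE]
  edges$weight <- ifelse(direction[edges$mirna_id] == "up", 1L, -1L)
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 mirna_direction = direction,
                 n_dropped_pairs = sum(!keep)),
            class = "target_network")
}

#' Node strengths and predicted target directions
#'
#' Sums the signed edge weights incident to each gene. A positive strength
#' (more edges from upregulated miRNAs) predicts the target to be
#' downregulated; negative strength predicts upregulation; zero strength
#' (cancelling edges) yields no prediction.
#'
#' @param network a `target_network`.
#' @return data.frame sorted as built: gene_symbol, degree, n_up_edges,
#'   n_down_edges, node_strength, predicted_direction.
#' @export
node_strength <- function(network) {
  stopifnot(inherits(network, "target_network"))
  edges <- network$edges
  if (nrow(edges) == 0L) stop("empty network")
  genes <- sort(unique(edges$gene_symbol))
  up <- tapply(edges$weight > 0, edges$gene_symbol, sum)[genes]
  down <- tapply(edges$weight < 0, edges$gene_symbol, sum)[genes]
  strength <- as.integer(up - down)
  data.frame(
    gene_symbol = genes,
    degree = as.integer(up + down),
    n_up_edges = as.integer(up),
    n_down_edges = as.integer(down),
    node_strength = strength,
    predicted_direction = ifelse(strength > 0, "down",
                                 ifelse(strength < 0, "up", "none")),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Invert every miRNA direction in a network
#'
#' Metamorphic helper: flipping all miRNA directions negates every edge
#' weight and hence every node strength, swapping predicted up and down.
#' Applying it twice restores the original network.
#'
#' @param network a `target_network`.
#' @return the flipped `target_network`.
#' @export
flip_directions <- function(network) {
  stopifnot(inherits(network, "target_network"))
  network$edges$weight <- -network$edges$weight
  network$mirna_direction <- ifelse(network$mirna_direction == "up", "down", "up")
  names(network$mirna_direction) <- names(network$mirna_direction) %||% NULL
  network
}

#' Top predicted targets by absolute node strength
#'
#' Sorts the prediction table by |node strength| descending, breaking ties
#' alphabetically by gene symbol, and optionally truncates to the first `k`
#' genes or to genes above a minimum absolute strength. `min_abs_strength = 2`
#' reproduces the emphasis rule that de-emphasizes genes with
#' |strength| <= 1.
#'
#' @param predictions prediction table from [node_strength()].
#' @param k optional number of top genes to keep.
#' @param min_abs_strength optional minimum |node_strength| (inclusive).
#' @return sorted (possibly truncated) prediction table.
#' @export
top_targets <- function(predictions, k = NULL, min_abs_strength = NULL) {
  stopifnot(nrow(predictions) > 0L)
  ord <- order(-abs(predictions$node_strength), predictions$gene_symbol)
  out <- predictions[ord, , drop = FALSE]
  if (!is.null(min_abs_strength)) {
    out <- out[abs(out$node_strength) >= min_abs_strength, , drop = FALSE]
  }
  if (!is.null(k)) out <- utils::head(out, k)
  rownames(out) <- NULL
  out
}

#' @export
print.target_network <- function(x, ...) {
  cat("Signed miRNA-target network\n")
  cat("  miRNAs: ", length(unique(x$edges$mirna_id)),
      " (", sum(x$mirna_direction == "up"), " up, ",
      sum(x$mirna_direction == "down"), " down)\n", sep = "")
  cat("  target genes: ", length(unique(x$edges$gene_symbol)), "\n", sep = "")
  cat("  edges: ", nrow(x$edges), " (", sum(x$edges$weight > 0), " +1, ",
      sum(x$edges$weight < 0), " -1)\n", sep = "")
  if (x$n_dropped_pairs > 0) {
    cat("  pairs dropped (miRNA not DE): ", x$n_dropped_pairs, "\n", sep = "")
  }
  invisible(x)
}

#' @export
plot.target_network <- function(x, max_genes = 30L, ...) {
  s <- node_strength(x)
  s <- top_targets(s, k = max_genes)
  graphics::barplot(rev(s$node_strength), names.arg = rev(s$gene_symbol),
                    horiz = TRUE, las = 1, cex.names = 0.6,
                    col = ifelse(rev(s$node_strength) > 0, "steelblue", "salmon"),
                    xlab = "node strength (+ predicts target down)", ...)
  invisible(x)
}
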