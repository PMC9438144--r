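# Validation of predicted target directions against measured mRNA fold
# changes: a predicted target is validated ("consistent") when the sign of its
# measured mRNA log2 fold change is opposite to the sign of its node strength
# (positive strength predicts downregulation and vice versa).

#' Join predicted targets with a measured mRNA DE table
#'
#' Inner join on (normalized) gene symbol. Universe sizes and the overlap
#' count are attached as attributes.
#'
#' @param predictions prediction table from [node_strength()].
#' @param mrna_de data.frame with `gene` and `log2fc` columns
#'   (see [read_mrna_de()]).
#' @return data.frame gene_symbol, node_strength, predicted_direction,
#'   mrna_log2fc.
#' @export
intersect_targets <- function(predictions, mrna_de) {
  if (is.null(mrna_de) || nrow(mrna_de) == 0L) stop("empty mRNA DE table")
  genes_m <- norm_gene_symbol(mrna_de$gene)
  genes_p <- norm_gene_symbol(predictions$gene_symbol)
  idx <- match(genes_p, genes_m)
  keep <- !is.na(idx)
  out <- data.frame(
    gene_symbol = genes_p[keep],
    node_strength = predictions$node_strength[keep],
    predicted_direction = predictions$predicted_direction[keep],
    mrna_log2fc = mrna_de$log2fc[idx[keep]],
    stringsAsFactors = FALSE
  )
  attr(out, "n_predicted") <- nrow(predictions)
  attr(out, "n_mrna_de") <- nrow(mrna_de)
  attr(out, "n_overlap") <- nrow(out)
  out
}

#' Flag direction-consistent (validated) targets
#'
#' A gene is consistent when its node strength is nonzero, its measured mRNA
#' log2FC is nonzero, and the two signs are opposite. Zero strength or zero
#' logFC cannot be validated (no direction on one side) and is flagged
#' inconsistent.
#'
#' @param joined output of [intersect_targets()].
#' @return `validation_table` data.frame with a logical `consistent` column;
#'   attributes `n_overlap` and `n_consistent`.
#' @export
direction_consistency <- function(joined) {
  if (nrow(joined) == 0L) stop("no overlapping genes to validate")
  consistent <- joined$node_strength != 0 & joined$mrna_log2fc != 0 &
    sign(joined$mrna_log2fc) == -sign(joined$node_strength)
  out <- joined
  out$consistent <- consistent
  attr(out, "n_overlap") <- nrow(out)
  attr(out, "n_consistent") <- sum(consistent)
  class(out) <- c("validation_table", "data.frame")
  out
}

#' Summarize validation across contrasts
#'
#' @param tables named list of `validation_table`s, one per contrast.
#' @return data.frame with one row per contrast: n_overlap, n_consistent,
#'   consistent_fraction; the per-contrast consistent gene lists (ordered by
#'   |node strength| then |mRNA log2FC|, both descending) are attached as the
#'   `consistent_genes` attribute.
#' @export
consistency_report <- function(tables) {
  stopifnot(length(tables) >= 1L)
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    stop("tables must be a named list (one name per contrast)")
  }
  rows <- lapply(names(tables), function(nm) {
    tab <- tables[[nm]]
    data.frame(contrast = nm,
               n_overlap = nrow(tab),
               n_consistent = sum(tab$consistent),
               consistent_fraction = mean(tab$consistent),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  genes <- lapply(tables, function(tab) {
    cons <- tab[tab$consistent, , drop = FALSE]
    cons <- cons[order(-abs(cons$node_strength), -abs(cons$mrna_log2fc),
                       cons$gene_symbol), , drop = FALSE]
    rownames(cons) <- NULL
    cons
  })
  attr(out, "consistent_genes") <- genes
  out
}
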