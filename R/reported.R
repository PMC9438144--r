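# Access to the published worked examples bundled with the package: the
# migraine PBMC study's prioritized DE miRNA lists and its predicted-target
# validation pairs, transcribed from the printed report tables. The DE lists
# keep the original decimal commas; readers normalize them.

#' Read a reported (published) DE miRNA list
#'
#' Bundled lists: `"interictal_vs_healthy"` and `"ictal_vs_interictal"`.
#' Columns are the signed linear fold change, the raw p-value and the
#' published average rank (computed over the full tested miRNA set, which is
#' why it can exceed the number of listed rows). The direction and log2FC are
#' derived on read.
#'
#' @param contrast which reported list to load, or a path to a file in the
#'   same format.
#' @return data.frame feature_id, fc_signed, p_raw, avg_rank_reported,
#'   log2fc, direction.
#' @export
read_reported_de <- function(contrast = c("interictal_vs_healthy", "ictal_vs_interictal")) {
  path <- if (file.exists(contrast[1L])) contrast[1L] else {
    contrast <- match.arg(contrast)
    system.file("extdata", sprintf("reported_de_%s.tsv", contrast),
                package = "mirtarnet", mustWork = TRUE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  out <- data.frame(feature_id = trimws(df$feature_id),
                    fc_signed = parse_decimal(df$fc_signed),
                    p_raw = parse_decimal(df$p_raw),
                    avg_rank_reported = parse_decimal(df$avg_rank_reported),
                    stringsAsFactors = FALSE)
  out$log2fc <- signed_fc_to_log2(out$fc_signed)
  out$direction <- ifelse(out$fc_signed >= 0, "up", "down")
  out
}

#' Read a reported predicted-target validation table
#'
#' Bundled pairs of measured mRNA log2 fold change and predicted node
#' strength for the genes the study lists as validated, per contrast.
#'
#' @param contrast which reported table to load, or a path.
#' @return data.frame gene_symbol, mrna_log2fc, node_strength,
#'   predicted_direction.
#' @export
read_reported_validation <- function(contrast = c("interictal_vs_healthy", "ictal_vs_interictal")) {
  path <- if (file.exists(contrast[1L])) contrast[1L] else {
    contrast <- match.arg(contrast)
    system.file("extdata", sprintf("reported_validation_%s.tsv", contrast),
                package = "mirtarnet", mustWork = TRUE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  s <- as.integer(df$node_strength)
  data.frame(gene_symbol = norm_gene_symbol(df$gene),
             mrna_log2fc = as.numeric(df$mrna_log2fc),
             node_strength = s,
             predicted_direction = ifelse(s > 0, "down", ifelse(s < 0, "up", "none")),
             stringsAsFactors = FALSE)
}
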