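# Readers and writers for every external file the pipeline touches.
# All readers validate strictly and report line-addressed errors; every
# writer/reader pair round-trips losslessly.

#' Read a miRNA count matrix
#'
#' Expects a tab-separated file whose first column holds feature (miRNA)
#' identifiers and whose header row holds sample identifiers. Counts must be
#' non-negative integers.
#'
#' @param path path to a counts TSV.
#' @return integer matrix (features x samples) with feature ids as rownames
#'   and sample ids as colnames.
#' @export
read_counts <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop_parse(path, 1L, "need a header and at least one feature row")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  sample_ids <- trimws(header[-1L])
  if (length(sample_ids) < 2L) stop_parse(path, 1L, "need at least 2 samples")
  if (anyDuplicated(sample_ids)) stop_parse(path, 1L, "duplicate sample ids")
  n_col <- length(header)
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  feature_ids <- character(length(body))
  counts <- matrix(0L, nrow = length(body), ncol = length(sample_ids))
  for (i in seq_along(body)) {
    row <- body[[i]]
    line_no <- i + 1L
    if (length(row) != n_col) {
      stop_parse(path, line_no, sprintf("ragged row: %d fields, expected %d", length(row), n_col))
    }
    feature_ids[i] <- trimws(row[1L])
    if (!nzchar(feature_ids[i])) stop_parse(path, line_no, "empty feature id")
    vals <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(vals)) stop_parse(path, line_no, "non-numeric count")
    if (any(vals < 0)) stop_parse(path, line_no, sprintf("negative count %s", vals[vals < 0][1L]))
    if (any(vals != round(vals))) stop_parse(path, line_no, "non-integer count")
    counts[i, ] <- as.integer(vals)
  }
  dup <- feature_ids[duplicated(feature_ids)]
  if (length(dup)) {
    stop_parse(path, which(feature_ids == dup[1L])[2L] + 1L,
               sprintf("duplicate feature id %s", sQuote(dup[1L])))
  }
  dimnames(counts) <- list(feature_ids, sample_ids)
  counts
}

#' Write a count matrix as TSV
#'
#' @param counts integer matrix with feature rownames and sample colnames.
#' @param path output path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(feature_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a study design table
#'
#' CSV with columns `sample_id`, `group` (one of healthy, interictal, ictal)
#' and `patient_id` (may be empty for unpaired samples). When `counts` is
#' supplied, every sample of the count matrix must appear exactly once.
#'
#' @param path path to design CSV.
#' @param counts optional count matrix for cross-validation.
#' @return data.frame with columns sample_id, group (factor), patient_id.
#' @export
read_design <- function(path, counts = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample_id", "group", "patient_id")
  missing_cols <- setdiff(need[1:2], names(df))
  if (length(missing_cols)) {
    stop_parse(path, 1L, paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  if (!"patient_id" %in% names(df)) df$patient_id <- NA_character_
  df$sample_id <- trimws(df$sample_id)
  df$patient_id <- trimws(df$patient_id)
  df$patient_id[!nzchar(df$patient_id)] <- NA_character_
  bad <- which(!df$group %in% c("healthy", "interictal", "ictal"))
  if (length(bad)) stop_parse(path, bad[1L] + 1L, sprintf("unknown group %s", sQuote(df$group[bad[1L]])))
  if (anyDuplicated(df$sample_id)) {
    stop_parse(path, which(duplicated(df$sample_id))[1L] + 1L, "duplicate sample_id")
  }
  df$group <- factor(df$group, levels = c("healthy", "interictal", "ictal"))
  if (!is.null(counts)) {
    if (!setequal(colnames(counts), df$sample_id)) {
      stop("design samples do not match count matrix columns", call. = FALSE)
    }
    df <- df[match(colnames(counts), df$sample_id), , drop = FALSE]
    rownames(df) <- NULL
  }
  df[, c("sample_id", "group", "patient_id")]
}

#' Write a study design table
#' @param design data.frame with sample_id, group, patient_id.
#' @param path output CSV path.
#' @export
write_design <- function(design, path) {
  out <- design
  out$group <- as.character(out$group)
  out$patient_id[is.na(out$patient_id)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default interaction-database score thresholds
#'
#' The two predicted tiers are filtered with strict inequalities: prediction
#' scores must exceed 80.0 and mirSVR scores must fall below -1.2; the
#' experimentally validated tier is kept unfiltered.
#'
#' @return named list with `score_min` and `mirsvr_max`.
#' @export
interaction_thresholds <- function() list(score_min = 80.0, mirsvr_max = -1.2)

#' Read and filter a miRNA-target interaction database
#'
#' TSV with columns `mirna_id`, `gene_symbol`, `source`
#' (validated / predicted_score / predicted_mirsvr) and `score` (may be empty
#' for the validated tier). Records in the predicted tiers are kept only when
#' their score passes the strict threshold for that tier; surviving
#' (miRNA, gene) pairs are deduplicated across tiers.
#'
#' @param path interaction TSV path.
#' @param thresholds list as returned by [interaction_thresholds()].
#' @return data.frame of unique pairs: mirna_id (lower-cased), gene_symbol.
#' @export
read_interactions <- function(path, thresholds = interaction_thresholds()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(score = "character"))
  need <- c("mirna_id", "gene_symbol", "source")
  if (!all(need %in% names(df))) {
    stop_parse(path, 1L, paste("missing columns:", paste(setdiff(need, names(df)), collapse = ", ")))
  }
  if (!"score" %in% names(df)) df$score <- NA_character_
  df$mirna_id <- norm_mirna_id(df$mirna_id)
  df$gene_symbol <- norm_gene_symbol(df$gene_symbol)
  if (any(!nzchar(df$mirna_id) | !nzchar(df$gene_symbol))) {
    bad <- which(!nzchar(df$mirna_id) | !nzchar(df$gene_symbol))[1L]
    stop_parse(path, bad + 1L, "empty miRNA id or gene symbol")
  }
  known <- c("validated", "predicted_score", "predicted_mirsvr")
  bad <- which(!df$source %in% known)
  if (length(bad)) {
    stop_parse(path, bad[1L] + 1L, sprintf("unknown source tier %s", sQuote(df$source[bad[1L]])))
  }
  score <- suppressWarnings(as.numeric(df$score))
  pred <- df$source != "validated"
  if (any(pred & is.na(score))) {
    stop_parse(path, which(pred & is.na(score))[1L] + 1L, "missing score in predicted tier")
  }
  keep <- df$source == "validated" |
    (df$source == "predicted_score" & score > thresholds$score_min) |
    (df$source == "predicted_mirsvr" & score < thresholds$mirsvr_max)
  pairs <- unique(df[keep, c("mirna_id", "gene_symbol")])
  rownames(pairs) <- NULL
  pairs
}

#' Write interaction records as TSV
#' @param records data.frame with mirna_id, gene_symbol, source, score.
#' @param path output path.
#' @export
write_interactions <- function(records, path) {
  out <- records
  if (!"score" %in% names(out)) out$score <- NA_real_
  out$score <- ifelse(is.na(out$score), "", format(out$score, trim = TRUE, digits = 15))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: `term_id TAB description TAB gene1 TAB gene2 ...`. A per-term
#' annotation frequency (proportion of gene products annotated to the term,
#' in (0, 1]) may be encoded in the description as `freq=<x>`.
#'
#' @param path GMT path.
#' @return list of gene sets; each element has term_id, term_name, members,
#'   frequency (NA when absent).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) stop_parse(path, i, "GMT line needs id, description and >=1 member")
    members <- norm_gene_symbol(fields[-(1:2)])
    members <- unique(members[nzchar(members)])
    if (!length(members)) stop_parse(path, i, "empty member list")
    desc <- fields[2L]
    freq <- NA_real_
    m <- regmatches(desc, regexpr("freq=[0-9.eE+-]+", desc))
    if (length(m) && nzchar(m)) {
      freq <- as.numeric(sub("freq=", "", m, fixed = TRUE))
      if (is.na(freq) || freq <= 0 || freq > 1) stop_parse(path, i, "frequency must be in (0,1]")
      desc <- trimws(sub("\\s*freq=[0-9.eE+-]+", "", desc))
    }
    sets[[i]] <- list(term_id = trimws(fields[1L]), term_name = desc,
                      members = members, frequency = freq)
  }
  names(sets) <- vapply(sets, `[[`, "", "term_id")
  if (anyDuplicated(names(sets))) stop_parse(path, 1L, "duplicate term ids")
  sets
}

#' Write a gene-set collection as GMT
#' @param sets list as returned by [read_gene_sets()].
#' @param path output path.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    desc <- s$term_name
    if (!is.na(s$frequency) && !grepl("freq=", desc, fixed = TRUE)) {
      desc <- sprintf("%s freq=%.17g", desc, s$frequency)
    }
    paste(c(s$term_id, desc, s$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an mRNA differential-expression table
#'
#' TSV with columns `gene`, `log2fc`, `p`, standing in for the companion
#' mRNA-seq study's DE output. Decimal commas are accepted.
#'
#' @param path mRNA DE TSV path.
#' @return data.frame with gene, log2fc, p.
#' @export
read_mrna_de <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("gene", "log2fc", "p")
  if (!all(need %in% names(df))) {
    stop_parse(path, 1L, paste("missing columns:", paste(setdiff(need, names(df)), collapse = ", ")))
  }
  out <- data.frame(gene = norm_gene_symbol(df$gene),
                    log2fc = parse_decimal(df$log2fc),
                    p = parse_decimal(df$p),
                    stringsAsFactors = FALSE)
  if (any(!nzchar(out$gene))) stop_parse(path, which(!nzchar(out$gene))[1L] + 1L, "empty gene symbol")
  if (any(out$p < 0 | out$p > 1, na.rm = TRUE)) {
    stop_parse(path, which(out$p < 0 | out$p > 1)[1L] + 1L, "p outside [0,1]")
  }
  out
}

#' Write a generic results table as TSV
#' @param records data.frame.
#' @param path output path.
#' @export
write_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a signed target network as SIF, GraphML and node attributes
#'
#' Writes `<prefix>.sif` with lines `mirna <relation> gene` where the relation
#' is `up_mirna_edge` (+1 edge, miRNA upregulated) or `down_mirna_edge` (-1),
#' `<prefix>.graphml` carrying edge weights and node strengths, and
#' `<prefix>_nodes.tsv` with per-gene strength, predicted direction and an
#' `emphasized` flag that is TRUE only for |strength| > 1 (genes at
#' |strength| <= 1 are the ones a rendered figure would de-emphasize).
#'
#' @param network a [target_network] object.
#' @param strengths prediction table from [node_strength()]; computed when NULL.
#' @param path_prefix output path prefix.
#' @return invisibly, the three file paths written.
#' @export
write_network <- function(network, strengths = NULL, path_prefix) {
  stopifnot(inherits(network, "target_network"))
  if (is.null(strengths)) strengths <- node_strength(network)
  edges <- network$edges
  relation <- ifelse(edges$weight > 0, "up_mirna_edge", "down_mirna_edge")
  sif_path <- paste0(path_prefix, ".sif")
  writeLines(paste(edges$mirna_id, relation, edges$gene_symbol), sif_path)

  graphml_path <- paste0(path_prefix, ".graphml")
  verts <- data.frame(
    name = c(unique(edges$mirna_id), strengths$gene_symbol),
    type = c(rep("mirna", length(unique(edges$mirna_id))),
             rep("gene", nrow(strengths))),
    node_strength = c(rep(NA_real_, length(unique(edges$mirna_id))),
                      as.numeric(strengths$node_strength)),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$mirna_id, to = edges$gene_symbol,
               weight = as.numeric(edges$weight), stringsAsFactors = FALSE),
    directed = TRUE, vertices = verts
  )
  igraph::write_graph(g, graphml_path, format = "graphml")

  nodes_path <- paste0(path_prefix, "_nodes.tsv")
  attr_tab <- strengths
  attr_tab$emphasized <- abs(attr_tab$node_strength) > 1
  write_table(attr_tab, nodes_path)
  invisible(c(sif = sif_path, graphml = graphml_path, nodes = nodes_path))
}
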