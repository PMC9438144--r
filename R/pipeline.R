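# Orchestration: run the full analysis for each contrast -- DE, signed target
# network, node strengths, mRNA-level validation and per-direction
# overrepresentation -- and record a self-describing run manifest.

#' Pipeline configuration
#'
#' Collects the input paths, contrast list and every threshold the pipeline
#' applies. A precomputed DE table can be injected per contrast (path to a
#' reported-format TSV, see [read_reported_de()]), in which case the
#' normalization/DE stage is skipped for that contrast.
#'
#' @param counts,design,interactions,mrna_de,gene_sets input file paths
#'   (`mrna_de` and `gene_sets` may be NULL to skip those stages; `counts` and
#'   `design` may be NULL when every contrast has an injected DE table).
#' @param out_dir output directory.
#' @param contrasts character vector of contrasts to run.
#' @param de_tables optional named list (by contrast) of injected DE table paths.
#' @param fc_thresh,p_thresh DE filter thresholds.
#' @param score_min,mirsvr_max interaction score thresholds.
#' @param freq_cutoff,ora_alpha enrichment thresholds.
#' @param rank_scope scope for [average_rank()].
#' @param seed integer seed recorded in the manifest.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(counts = NULL, design = NULL, interactions,
                            mrna_de = NULL, gene_sets = NULL, out_dir,
                            contrasts = c("interictal_vs_healthy", "ictal_vs_interictal"),
                            de_tables = NULL,
                            fc_thresh = 1.2, p_thresh = 0.05,
                            score_min = 80.0, mirsvr_max = -1.2,
                            freq_cutoff = 0.15, ora_alpha = 0.01,
                            rank_scope = "all_tested", seed = 1L) {
  cfg <- list(counts = counts, design = design, interactions = interactions,
              mrna_de = mrna_de, gene_sets = gene_sets, out_dir = out_dir,
              contrasts = contrasts, de_tables = de_tables,
              thresholds = list(fc = fc_thresh, p = p_thresh,
                                score_min = score_min, mirsvr_max = mirsvr_max,
                                freq_cutoff = freq_cutoff, ora_alpha = ora_alpha),
              rank_scope = rank_scope, seed = as.integer(seed))
  with(cfg$thresholds, stopifnot(fc > 0, p > 0, score_min > 0,
                                 freq_cutoff > 0, ora_alpha > 0))
  for (con in contrasts) {
    if (is.null(de_tables[[con]]) && (is.null(counts) || is.null(design))) {
      stop("contrast ", con, " has no injected DE table and no counts/design")
    }
  }
  needed <- c(cfg$interactions, cfg$counts, cfg$design, cfg$mrna_de,
              cfg$gene_sets, unlist(cfg$de_tables))
  missing <- needed[!file.exists(needed)]
  if (length(missing)) stop("input file(s) not found: ", paste(missing, collapse = ", "))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' For every contrast: moderated DE (or an injected DE table), the DE filter,
#' the signed target network, node strengths, direction-consistency validation
#' against the mRNA DE table, and overrepresentation analysis run separately
#' for predicted-down and predicted-up targets. Writes, per contrast, a DE
#' TSV, a node-strength TSV, SIF and GraphML network exports, a validation TSV
#' and an enrichment TSV, plus a JSON run manifest echoing every threshold.
#'
#' @param config a [pipeline_config()].
#' @return the run manifest (named list), invisibly also written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  pairs <- stage("interactions", read_interactions(
    config$interactions, thresholds = list(score_min = th$score_min,
                                           mirsvr_max = th$mirsvr_max)))
  counts <- if (!is.null(config$counts)) stage("counts", read_counts(config$counts))
  design <- if (!is.null(config$design)) stage("design", read_design(config$design, counts))
  mrna <- if (!is.null(config$mrna_de)) stage("mrna_de", read_mrna_de(config$mrna_de))
  sets <- if (!is.null(config$gene_sets)) stage("gene_sets", read_gene_sets(config$gene_sets))

  manifest <- list(
    package = "mirtarnet",
    version = as.character(utils::packageVersion("mirtarnet")),
    seed = config$seed,
    thresholds = th,
    rank_scope = config$rank_scope,
    n_interaction_pairs = nrow(pairs),
    contrasts = list()
  )

  for (con in config$contrasts) {
    res <- list(contrast = con)
    if (!is.null(config$de_tables[[con]])) {
      de_full <- stage("de", read_reported_de(config$de_tables[[con]]))
      de_full$is_de <- abs(de_full$fc_signed) > th$fc & de_full$p_raw < th$p
      de_sub <- de_full[de_full$is_de, , drop = FALSE]
      res$de_source <- "injected"
    } else {
      fit <- stage("de", mirna_de(counts, design, con, fc_thresh = th$fc,
                                  p_thresh = th$p, rank_scope = config$rank_scope))
      de_full <- as.data.frame(fit$table)
      de_sub <- as.data.frame(fit$de)
      res$de_source <- "fitted"
    }
    prefix <- file.path(config$out_dir, con)
    write_table(de_full, paste0(prefix, "_de.tsv"))
    res$n_tested <- nrow(de_full)
    res$n_de <- nrow(de_sub)
    res$n_de_up <- sum(de_sub$direction == "up")
    res$n_de_down <- sum(de_sub$direction == "down")

    if (nrow(de_sub) == 0L) {
      res$skipped <- "no DE miRNAs; downstream stages skipped"
      manifest$contrasts[[con]] <- res
      next
    }
    net <- stage("network", build_signed_network(pairs, de_sub))
    strengths <- stage("network", node_strength(net))
    files <- stage("network", write_network(net, strengths, prefix))
    res$n_edges <- nrow(net$edges)
    res$n_target_genes <- nrow(strengths)
    res$n_pred_down <- sum(strengths$predicted_direction == "down")
    res$n_pred_up <- sum(strengths$predicted_direction == "up")
    res$n_pred_none <- sum(strengths$predicted_direction == "none")

    if (!is.null(mrna)) {
      val <- stage("validation", direction_consistency(intersect_targets(strengths, mrna)))
      write_table(as.data.frame(val), paste0(prefix, "_validation.tsv"))
      res$n_overlap <- attr(val, "n_overlap")
      res$n_consistent <- attr(val, "n_consistent")
    }
    if (!is.null(sets)) {
      universe <- unique(pairs$gene_symbol)
      enr <- NULL
      for (dirn in c("down", "up")) {
        q <- strengths$gene_symbol[strengths$predicted_direction == dirn]
        if (!length(q)) next
        tab <- stage("enrichment", run_ora(q, universe, sets, alpha = th$ora_alpha,
                                           freq_cutoff = th$freq_cutoff))
        tab$query_direction <- dirn
        enr <- rbind(enr, as.data.frame(tab))
      }
      if (!is.null(enr)) {
        write_table(enr, paste0(prefix, "_enrichment.tsv"))
        res$n_terms_tested <- nrow(enr)
        res$n_terms_significant <- sum(enr$significant)
        res$n_terms_specific <- sum(enr$specific)
      }
    }
    manifest$contrasts[[con]] <- res
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Summarize a pipeline run
#'
#' Human-readable per-stage counts from a run manifest.
#'
#' @param manifest a manifest list from [run_pipeline()] or the path to a
#'   `manifest.json`.
#' @return character vector of report lines (also printed).
#' @export
summarize_run <- function(manifest) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stop("manifest not found: ", manifest)
    manifest <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  }
  lines <- c(
    sprintf("mirtarnet run (seed %s)", manifest$seed),
    sprintf("interaction pairs after filtering: %s", manifest$n_interaction_pairs)
  )
  for (res in manifest$contrasts) {
    lines <- c(lines, sprintf("contrast %s [%s DE table]:", res$contrast, res$de_source),
               sprintf("  DE miRNAs: %s of %s tested (%s up, %s down)",
                       res$n_de, res$n_tested, res$n_de_up, res$n_de_down))
    if (!is.null(res$skipped)) {
      lines <- c(lines, paste0("  ", res$skipped))
      next
    }
    lines <- c(lines, sprintf("  network: %s edges, %s target genes (%s predicted down, %s up, %s none)",
                              res$n_edges, res$n_target_genes, res$n_pred_down,
                              res$n_pred_up, res$n_pred_none))
    if (!is.null(res$n_overlap)) {
      lines <- c(lines, sprintf("  validation: %s of %s overlapping targets consistent",
                                res$n_consistent, res$n_overlap))
    }
    if (!is.null(res$n_terms_tested)) {
      lines <- c(lines, sprintf("  enrichment: %s term tests, %s significant, %s specific",
                                res$n_terms_tested, res$n_terms_significant,
                                res$n_terms_specific))
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
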