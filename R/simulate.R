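# Synthetic-data generators. They emulate the statistical structure the
# pipeline assumes -- negative-binomial miRNA counts with planted group
# effects and within-patient correlation for the self-paired phase samples, a
# three-tier interaction database whose scores straddle the filtering
# thresholds, an mRNA DE table whose fold-change signs oppose the planted
# node strengths up to a controlled flip fraction, and a gene-set collection
# with one planted enriched term -- so every downstream stage is testable
# without external data. All randomness flows from one integer seed through
# per-stage derived sub-seeds.

#' Simulation configuration
#'
#' Defaults emulate a migraine PBMC small-RNA study: 12 healthy controls,
#' 16 interictal patients, 8 of whom also contribute a self-paired ictal
#' sample; moderate negative-binomial dispersion; planted log2 effects of
#' magnitude 1.5 on 30 miRNAs.
#'
#' @param n_mirna number of miRNA features.
#' @param n_gene number of target genes in the simulated interaction universe.
#' @param n_per_group named counts for healthy, interictal and ictal samples
#'   (ictal must not exceed interictal: ictal samples are paired to the first
#'   interictal patients).
#' @param planted_de data.frame with `feature_id` and signed `log2fc` columns,
#'   or NULL for the default 30 alternating-sign effects of magnitude
#'   `planted_log2fc`.
#' @param n_planted,planted_log2fc used to build the default planted set.
#' @param de_contrast which contrast the planted effects act on; the
#'   numerator group's mean is shifted by `2^log2fc`.
#' @param dispersion negative-binomial dispersion (1/size).
#' @param bio_sd per-feature biological standard deviation on the log2 mean.
#' @param pairing_correlation within-patient correlation in \[0, 1): fraction
#'   of `bio_sd^2` attributed to a patient-level random effect shared by the
#'   interictal and ictal sample of the same patient.
#' @param lib_size_range range of library sizes (uniform).
#' @param targets_per_mirna number of target genes per planted DE miRNA.
#' @param seed master integer seed.
#' @return validated `simulation_config` list.
#' @export
simulation_config <- function(n_mirna = 600, n_gene = 2000,
                              n_per_group = c(healthy = 12, interictal = 16, ictal = 8),
                              planted_de = NULL, n_planted = 30, planted_log2fc = 1.5,
                              de_contrast = "interictal_vs_healthy",
                              dispersion = 0.1, bio_sd = 0.25,
                              pairing_correlation = 0.5,
                              lib_size_range = c(5e5, 2e6),
                              targets_per_mirna = 20,
                              seed = 1L) {
  cfg <- list(n_mirna = as.integer(n_mirna), n_gene = as.integer(n_gene),
              n_per_group = n_per_group, planted_de = planted_de,
              n_planted = as.integer(n_planted), planted_log2fc = planted_log2fc,
              de_contrast = match.arg(de_contrast,
                c("interictal_vs_healthy", "ictal_vs_interictal", "ictal_vs_healthy")),
              dispersion = dispersion, bio_sd = bio_sd,
              pairing_correlation = pairing_correlation,
              lib_size_range = lib_size_range,
              targets_per_mirna = as.integer(targets_per_mirna),
              seed = as.integer(seed))
  validate_config(cfg)
  if (is.null(cfg$planted_de)) {
    if (cfg$n_planted > 0) {
      ids <- sprintf("hsa-mir-sim-%04d", seq_len(cfg$n_planted))
      cfg$planted_de <- data.frame(
        feature_id = ids,
        log2fc = cfg$planted_log2fc * rep_len(c(1, -1), cfg$n_planted),
        stringsAsFactors = FALSE)
    } else {
      cfg$planted_de <- data.frame(feature_id = character(), log2fc = numeric())
    }
  }
  if (!all(is.finite(cfg$planted_de$log2fc))) stop("planted effect sizes must be finite")
  class(cfg) <- "simulation_config"
  cfg
}

validate_config <- function(cfg) {
  need <- c("healthy", "interictal", "ictal")
  assert_that(all(need %in% names(cfg$n_per_group)),
              "n_per_group must name healthy, interictal and ictal")
  assert_that(cfg$n_mirna > 0 && cfg$n_gene > 0 && all(cfg$n_per_group > 0),
              "invalid config: non-positive dimensions")
  assert_that(cfg$n_per_group[["ictal"]] <= cfg$n_per_group[["interictal"]],
              "ictal samples must pair with interictal patients")
  assert_that(cfg$dispersion > 0, "dispersion must be > 0")
  assert_that(cfg$pairing_correlation >= 0 && cfg$pairing_correlation < 1,
              "pairing_correlation must lie in [0, 1)")
  assert_that(all(cfg$lib_size_range >= 1) && length(cfg$lib_size_range) == 2L,
              "lib_size_range must be a pair of counts >= 1")
  invisible(TRUE)
}

#' Simulate miRNA counts, study design and ground truth
#'
#' Negative-binomial counts with log-linear group effects: each feature has a
#' baseline relative abundance; planted features have their mean multiplied by
#' `2^log2fc` in the numerator group of `de_contrast`. Interictal and ictal
#' samples from the same patient share a per-feature Gaussian random effect on
#' the log2 mean, giving within-patient correlation `pairing_correlation` of
#' the biological variance. The ground truth also plants the target edges of
#' every planted miRNA (used by the interaction-database generator) and the
#' node strengths they imply.
#'
#' @param config a [simulation_config()].
#' @return list with `counts` (integer matrix), `design` (data.frame) and
#'   `truth` (list: true_de_mirnas, true_edges, true_node_strengths).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, "counts"))
  npg <- config$n_per_group
  n_mirna <- config$n_mirna

  feature_ids <- sprintf("hsa-mir-sim-%04d", seq_len(n_mirna))
  planted <- config$planted_de
  stopifnot(all(planted$feature_id %in% feature_ids))

  design <- rbind(
    data.frame(sample_id = sprintf("H%02d", seq_len(npg[["healthy"]])),
               group = "healthy", patient_id = NA_character_),
    data.frame(sample_id = sprintf("INT%02d", seq_len(npg[["interictal"]])),
               group = "interictal",
               patient_id = sprintf("P%02d", seq_len(npg[["interictal"]]))),
    data.frame(sample_id = sprintf("ICT%02d", seq_len(npg[["ictal"]])),
               group = "ictal",
               patient_id = sprintf("P%02d", seq_len(npg[["ictal"]])))
  )
  design$group <- factor(design$group, levels = c("healthy", "interictal", "ictal"))
  n_samp <- nrow(design)

  # baseline relative abundance per feature (log-uniform over ~3 decades)
  base_log2 <- stats::runif(n_mirna, min = 3, max = 12)
  prop <- 2^base_log2 / sum(2^base_log2)

  # planted group effects on the log2 mean
  num_group <- strsplit(config$de_contrast, "_vs_")[[1L]][1L]
  delta <- matrix(0, n_mirna, n_samp, dimnames = list(feature_ids, design$sample_id))
  if (nrow(planted)) {
    rows <- match(planted$feature_id, feature_ids)
    delta[rows, design$group == num_group] <- planted$log2fc
  }

  # biological variation: patient random effect + sample residual, per feature
  rho <- config$pairing_correlation
  sd_pat <- config$bio_sd * sqrt(rho)
  sd_res <- config$bio_sd * sqrt(1 - rho)
  pat_key <- ifelse(is.na(design$patient_id), design$sample_id, design$patient_id)
  pats <- unique(pat_key)
  pat_eff <- matrix(stats::rnorm(n_mirna * length(pats), sd = sd_pat),
                    n_mirna, length(pats), dimnames = list(NULL, pats))
  bio <- pat_eff[, pat_key, drop = FALSE] +
    matrix(stats::rnorm(n_mirna * n_samp, sd = sd_res), n_mirna, n_samp)

  lib <- stats::runif(n_samp, config$lib_size_range[1L], config$lib_size_range[2L])
  mu <- (prop %o% lib) * 2^(delta + bio)
  counts <- matrix(
    stats::rnbinom(n_mirna * n_samp, mu = mu, size = 1 / config$dispersion),
    n_mirna, n_samp, dimnames = list(feature_ids, design$sample_id))
  storage.mode(counts) <- "integer"

  # planted target edges and implied node strengths
  gene_ids <- sprintf("GENE%04d", seq_len(config$n_gene))
  edges <- NULL
  if (nrow(planted)) {
    edges <- do.call(rbind, lapply(seq_len(nrow(planted)), function(i) {
      data.frame(mirna_id = planted$feature_id[i],
                 gene_symbol = sample(gene_ids, config$targets_per_mirna),
                 stringsAsFactors = FALSE)
    }))
  } else {
    edges <- data.frame(mirna_id = character(), gene_symbol = character())
  }
  sign_map <- stats::setNames(ifelse(planted$log2fc > 0, 1L, -1L), planted$feature_id)
  strengths <- if (nrow(edges)) {
    tapply(sign_map[edges$mirna_id], edges$gene_symbol, sum)
  } else {
    integer(0)
  }
  truth <- list(
    true_de_mirnas = stats::setNames(planted$log2fc, planted$feature_id),
    true_edges = edges,
    true_node_strengths = stats::setNames(as.integer(strengths), names(strengths)),
    gene_universe = gene_ids,
    de_contrast = config$de_contrast
  )
  list(counts = counts, design = design, truth = truth)
}

#' Simulate a three-tier miRNA-target interaction database
#'
#' Every true edge is emitted once in one of the three source tiers with a
#' score passing that tier's threshold (validated-tier records carry no
#' score); `n_decoys` additional records pair random miRNAs and genes with
#' scores that fail the thresholds, so filtering the file with the default
#' thresholds recovers exactly the true edge set.
#'
#' @param config a [simulation_config()].
#' @param truth ground truth from [simulate_counts()].
#' @param n_decoys number of failing decoy records (default 200).
#' @return data.frame mirna_id, gene_symbol, source, score.
#' @export
simulate_interaction_db <- function(config, truth, n_decoys = 200) {
  stopifnot(nrow(truth$true_edges) > 0L)
  set.seed(derive_seed(config$seed, "interactions"))
  edges <- truth$true_edges
  tiers <- rep_len(c("validated", "predicted_score", "predicted_mirsvr"), nrow(edges))
  score <- rep(NA_real_, nrow(edges))
  score[tiers == "predicted_score"] <-
    stats::runif(sum(tiers == "predicted_score"), 80.5, 99.5)
  score[tiers == "predicted_mirsvr"] <-
    stats::runif(sum(tiers == "predicted_mirsvr"), -3.0, -1.25)
  true_rec <- data.frame(mirna_id = edges$mirna_id, gene_symbol = edges$gene_symbol,
                         source = tiers, score = score, stringsAsFactors = FALSE)

  all_mirnas <- sprintf("hsa-mir-sim-%04d", seq_len(config$n_mirna))
  key <- paste(edges$mirna_id, edges$gene_symbol)
  decoy <- data.frame(
    mirna_id = sample(all_mirnas, n_decoys, replace = TRUE),
    gene_symbol = sample(truth$gene_universe, n_decoys, replace = TRUE),
    source = sample(c("predicted_score", "predicted_mirsvr"), n_decoys, replace = TRUE),
    stringsAsFactors = FALSE
  )
  decoy <- decoy[!paste(decoy$mirna_id, decoy$gene_symbol) %in% key, , drop = FALSE]
  decoy$score <- ifelse(decoy$source == "predicted_score",
                        stats::runif(nrow(decoy), 10, 80),
                        stats::runif(nrow(decoy), -1.15, -0.05))
  rbind(true_rec, decoy)
}

#' Simulate an mRNA differential-expression table
#'
#' For every gene with nonzero true node strength the measured mRNA log2FC
#' sign is set opposite to the strength sign (the repression direction the
#' network predicts), except for a `flip_fraction` of genes whose sign is
#' inverted. Magnitudes grow with |strength| plus half-normal noise. Genes
#' with zero strength and `n_null` extra genes outside the network are added
#' with symmetric-noise fold changes.
#'
#' @param truth ground truth from [simulate_counts()].
#' @param noise_sd Gaussian noise SD on the log2FC magnitude (default 0.3).
#' @param flip_fraction probability that a gene's sign is flipped, in \[0, 1\].
#' @param seed integer seed.
#' @param n_null number of unrelated null genes appended (default 100).
#' @return data.frame gene, log2fc, p.
#' @export
simulate_mrna_logfc <- function(truth, noise_sd = 0.3, flip_fraction = 0,
                                seed = 1L, n_null = 100) {
  stopifnot(flip_fraction >= 0, flip_fraction <= 1)
  set.seed(derive_seed(seed, "mrna"))
  s <- truth$true_node_strengths
  genes <- names(s)
  base_sign <- -sign(s)
  flip <- stats::runif(length(s)) < flip_fraction
  sgn <- ifelse(flip, -base_sign, base_sign)
  mag <- 0.5 + 0.25 * abs(s) + abs(stats::rnorm(length(s), sd = noise_sd))
  logfc <- ifelse(s == 0, stats::rnorm(length(s), sd = noise_sd), sgn * mag)
  out <- data.frame(gene = genes, log2fc = logfc,
                    p = stats::runif(length(s), 1e-6, 0.04),
                    stringsAsFactors = FALSE)
  if (n_null > 0) {
    out <- rbind(out, data.frame(
      gene = sprintf("NULLGENE%04d", seq_len(n_null)),
      log2fc = stats::rnorm(n_null, sd = noise_sd),
      p = stats::runif(n_null, 1e-6, 0.04)))
  }
  rownames(out) <- NULL
  out
}

#' Simulate a gene-set collection with one planted enriched term
#'
#' The planted term collects the genes with the highest absolute true node
#' strengths (so a query of strongly targeted genes is overrepresented in
#' it) and carries a low annotation frequency; the remaining terms are random
#' draws from the target universe with frequencies spanning both sides of the
#' 0.15 specificity cutoff.
#'
#' @param n_terms total number of terms (>= 2).
#' @param truth ground truth from [simulate_counts()].
#' @param seed integer seed.
#' @param planted_size size of the planted term (default 40).
#' @return gene-set list as from [read_gene_sets()]; the planted term id is in
#'   attribute `planted_term`.
#' @export
simulate_gene_sets <- function(n_terms = 20, truth, seed = 1L, planted_size = 40) {
  stopifnot(n_terms >= 2)
  set.seed(derive_seed(seed, "genesets"))
  s <- truth$true_node_strengths
  universe <- names(s)
  stopifnot(length(universe) > planted_size)
  top <- universe[order(-abs(s), universe)][seq_len(planted_size)]
  sets <- vector("list", n_terms)
  freqs <- seq(0.02, 0.60, length.out = n_terms - 1L)
  sets[[1L]] <- list(term_id = "TERM0001",
                     term_name = "planted strongly-targeted set",
                     members = top, frequency = 0.05)
  for (i in 2:n_terms) {
    size <- sample(15:60, 1L)
    sets[[i]] <- list(term_id = sprintf("TERM%04d", i),
                      term_name = sprintf("random background set %d", i),
                      members = sample(universe, size), frequency = freqs[i - 1L])
  }
  names(sets) <- vapply(sets, `[[`, "", "term_id")
  attr(sets, "planted_term") <- "TERM0001"
  sets
}

#' Write ground truth as JSON (and read it back)
#'
#' @param truth ground-truth list from [simulate_counts()].
#' @param path output JSON path.
#' @export
write_truth <- function(truth, path) {
  truth$true_de_mirnas <- as.list(truth$true_de_mirnas)
  truth$true_node_strengths <- as.list(truth$true_node_strengths)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr$true_de_mirnas <- unlist(tr$true_de_mirnas)
  tr$true_node_strengths <- unlist(tr$true_node_strengths)
  tr
}

#' Generate and write a complete synthetic study
#'
#' Runs all four generators under one master seed and writes every input file
#' the pipeline reads (counts TSV, design CSV, interaction TSV, mRNA DE TSV,
#' GMT) plus a ground-truth JSON.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if needed).
#' @param flip_fraction passed to [simulate_mrna_logfc()].
#' @param n_terms passed to [simulate_gene_sets()].
#' @return named list of file paths plus the in-memory objects.
#' @export
simulate_study <- function(config, dir, flip_fraction = 0, n_terms = 20) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_counts(config)
  db <- simulate_interaction_db(config, sim$truth)
  mrna <- simulate_mrna_logfc(sim$truth, flip_fraction = flip_fraction,
                              seed = config$seed)
  sets <- simulate_gene_sets(n_terms, sim$truth, seed = config$seed)
  paths <- list(counts = file.path(dir, "counts.tsv"),
                design = file.path(dir, "design.csv"),
                interactions = file.path(dir, "interactions.tsv"),
                mrna_de = file.path(dir, "mrna_de.tsv"),
                gene_sets = file.path(dir, "gene_sets.gmt"),
                truth = file.path(dir, "truth.json"))
  write_counts(sim$counts, paths$counts)
  write_design(sim$design, paths$design)
  write_interactions(db, paths$interactions)
  write_table(mrna, paths$mrna_de)
  write_gene_sets(sets, paths$gene_sets)
  sim$truth$true_enriched_terms <- attr(sets, "planted_term")
  write_truth(sim$truth, paths$truth)
  c(paths, list(counts_mat = sim$counts, design_df = sim$design,
                truth_obj = sim$truth, interactions_df = db,
                mrna_df = mrna, gene_sets_obj = sets))
}
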