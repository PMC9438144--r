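test_that("every generator is deterministic under a fixed seed", {
  cfg <- small_sim_config(seed = 101, n_planted = 10)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$design, b$design)
  expect_identical(a$truth, b$truth)

  expect_identical(simulate_interaction_db(cfg, a$truth),
                   simulate_interaction_db(cfg, a$truth))
  expect_identical(simulate_mrna_logfc(a$truth, flip_fraction = 0.3, seed = 101),
                   simulate_mrna_logfc(a$truth, flip_fraction = 0.3, seed = 101))
  expect_identical(simulate_gene_sets(10, a$truth, seed = 101),
                   simulate_gene_sets(10, a$truth, seed = 101))

  # a different seed changes the counts
  cfg2 <- small_sim_config(seed = 102, n_planted = 10)
  expect_false(identical(simulate_counts(cfg2)$counts, a$counts))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_mirna = 0), "non-positive")
  expect_error(simulation_config(dispersion = 0), "dispersion")
  expect_error(simulation_config(pairing_correlation = 1), "pairing_correlation")
  expect_error(simulation_config(
    n_per_group = c(healthy = 4, interictal = 2, ictal = 4)), "pair")
})

test_that("simulated counts carry the planted structure and pairing", {
  cfg <- small_sim_config(seed = 103, n_planted = 12, pairing_correlation = 0.8,
                          n_healthy = 10, n_interictal = 10, n_ictal = 10,
                          bio_sd = 0.8)
  sim <- simulate_counts(cfg)
  expect_true(all(names(sim$truth$true_de_mirnas) %in% rownames(sim$counts)))
  expect_true(all(sim$counts >= 0))

  # planted features shift between groups in the planted direction
  lc <- log_cpm(sim$counts)$log2
  int_mean <- rowMeans(lc[, sim$design$group == "interictal"])
  h_mean <- rowMeans(lc[, sim$design$group == "healthy"])
  diff <- (int_mean - h_mean)[names(sim$truth$true_de_mirnas)]
  expect_gt(cor(diff, sim$truth$true_de_mirnas), 0.9)

  # within-patient correlation: paired residuals correlate across features
  ict <- sim$design$sample_id[sim$design$group == "ictal"]
  pats <- sim$design$patient_id[match(ict, sim$design$sample_id)]
  int <- sim$design$sample_id[match(pats, ifelse(sim$design$group == "interictal",
                                                 sim$design$patient_id, NA))]
  centred <- lc - rowMeans(lc)
  paired_cor <- mean(vapply(seq_along(ict), function(i) {
    cor(centred[, ict[i]], centred[, int[i]])
  }, 0))
  rot <- c(seq_along(ict)[-1], 1L)  # mismatched patients as the null reference
  mismatched_cor <- mean(vapply(seq_along(ict), function(i) {
    cor(centred[, ict[i]], centred[, int[rot[i]]])
  }, 0))
  expect_gt(paired_cor, mismatched_cor + 0.2)

  # node strengths derive from edges and planted signs
  tr <- sim$truth
  recount <- tapply(ifelse(tr$true_de_mirnas[tr$true_edges$mirna_id] > 0, 1L, -1L),
                    tr$true_edges$gene_symbol, sum)
  expect_identical(tr$true_node_strengths[names(recount)],
                   vapply(recount, as.integer, 0L))
})

test_that("threshold filtering of the simulated database recovers the true edges", {
  cfg <- small_sim_config(seed = 104, n_planted = 15)
  sim <- simulate_counts(cfg)
  db <- simulate_interaction_db(cfg, sim$truth, n_decoys = 300)
  # score construction per tier
  expect_true(all(db$score[db$source == "validated"] %in% NA))
  true_key <- paste(sim$truth$true_edges$mirna_id, sim$truth$true_edges$gene_symbol)
  is_true <- paste(db$mirna_id, db$gene_symbol) %in% true_key
  expect_true(all(db$score[is_true & db$source == "predicted_score"] > 80))
  expect_true(all(db$score[is_true & db$source == "predicted_mirsvr"] < -1.2))
  expect_true(all(db$score[!is_true & db$source == "predicted_score"] <= 80))
  expect_true(all(db$score[!is_true & db$source == "predicted_mirsvr"] > -1.2))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_interactions(db, path)
  pairs <- read_interactions(path)
  expect_identical(sort(paste(pairs$mirna_id, pairs$gene_symbol)), sort(true_key))
})

test_that("mRNA fold-change signs oppose strengths up to the flip fraction", {
  cfg <- small_sim_config(seed = 105, n_planted = 15)
  sim <- simulate_counts(cfg)
  s <- sim$truth$true_node_strengths

  check_fraction <- function(flip) {
    mrna <- simulate_mrna_logfc(sim$truth, flip_fraction = flip, seed = 105)
    pred <- data.frame(gene_symbol = names(s), node_strength = as.integer(s),
                       predicted_direction = ifelse(s > 0, "down",
                                                    ifelse(s < 0, "up", "none")))
    pred <- pred[pred$node_strength != 0, ]
    v <- direction_consistency(intersect_targets(pred, mrna))
    mean(v$consistent)
  }
  expect_equal(check_fraction(0), 1)
  expect_equal(check_fraction(1), 0)
})

test_that("gene-set generator plants one low-frequency enriched term", {
  cfg <- small_sim_config(seed = 106, n_planted = 15)
  sim <- simulate_counts(cfg)
  sets <- simulate_gene_sets(12, sim$truth, seed = 106)
  expect_length(sets, 12)
  freqs <- vapply(sets, `[[`, 0, "frequency")
  expect_true(any(freqs < 0.15) && any(freqs >= 0.15))
  planted <- sets[[attr(sets, "planted_term")]]
  s <- sim$truth$true_node_strengths
  # planted members are the strongest-targeted genes
  expect_true(min(abs(s[planted$members])) >=
                max(abs(s[setdiff(names(s), planted$members)])) - 1L)
  expect_error(simulate_gene_sets(1, sim$truth, seed = 1), "n_terms")
})

test_that("truth JSON round-trips through write and read", {
  cfg <- small_sim_config(seed = 107, n_planted = 5)
  sim <- simulate_counts(cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_equal(back$true_de_mirnas, sim$truth$true_de_mirnas)
  expect_equal(back$true_node_strengths, sim$truth$true_node_strengths)
  expect_equal(as.data.frame(back$true_edges), sim$truth$true_edges)
})
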