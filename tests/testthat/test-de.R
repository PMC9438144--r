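make_two_group_design <- function(n_per_side) {
  data.frame(
    sample_id = paste0("s", seq_len(2 * n_per_side)),
    group = factor(rep(c("healthy", "interictal"), each = n_per_side),
                   levels = c("healthy", "interictal", "ictal")),
    patient_id = NA_character_,
    stringsAsFactors = FALSE)
}

test_that("moderated t reduces to the ordinary t when prior df is 0", {
  set.seed(31)
  n <- 6
  lg <- matrix(rnorm(40 * 2 * n, mean = 8), 40, 2 * n,
               dimnames = list(paste0("f", 1:40), paste0("s", 1:(2 * n))))
  design <- make_two_group_design(n)
  tab <- fit_moderated_de(lg, design, "interictal_vs_healthy",
                          weights = rep(1, 40), d0 = 0)
  ord <- match(rownames(lg), tab$feature_id)
  t_classic <- apply(lg, 1, function(x) {
    unname(t.test(x[(n + 1):(2 * n)], x[1:n], var.equal = TRUE)$statistic)
  })
  expect_equal(tab$t[ord], unname(t_classic), tolerance = 1e-10)
  p_classic <- 2 * pt(-abs(t_classic), df = 2 * n - 2)
  expect_equal(tab$p_raw[ord], unname(p_classic), tolerance = 1e-10)
})

test_that("infinite prior df pools every variance to the prior value", {
  set.seed(32)
  n <- 5
  lg <- matrix(rnorm(30 * 2 * n, mean = 6, sd = rep(runif(30, 0.2, 2), 2 * n)),
               30, 2 * n, dimnames = list(paste0("f", 1:30), paste0("s", 1:(2 * n))))
  design <- make_two_group_design(n)
  tab <- fit_moderated_de(lg, design, "interictal_vs_healthy",
                          weights = rep(1, 30), d0 = Inf)
  # with a common pooled variance, t must be exactly proportional to the
  # group-mean difference across features
  ratio <- tab$t / tab$log2fc
  expect_equal(max(ratio) - min(ratio), 0, tolerance = 1e-10)
})

test_that("moderated statistics agree with an established EB implementation", {
  skip_if_not_installed("limma")
  set.seed(33)
  n <- 4
  sd_g <- sqrt(2 / rchisq(120, df = 8))  # heteroscedastic, finite prior df
  lg <- matrix(rnorm(120 * 2 * n, mean = 7, sd = rep(sd_g, 2 * n)), 120, 2 * n,
               dimnames = list(paste0("f", 1:120), paste0("s", 1:(2 * n))))
  design <- make_two_group_design(n)
  tab <- fit_moderated_de(lg, design, "interictal_vs_healthy", weights = rep(1, 120))
  ord <- match(rownames(lg), tab$feature_id)
  fit <- limma::eBayes(limma::lmFit(lg, cbind(1, rep(0:1, each = n))))
  expect_gt(cor(tab$t[ord], fit$t[, 2]), 0.9999)
  expect_equal(attr(tab, "d0"), fit$df.prior, tolerance = 0.05)
  expect_equal(tab$t[ord], unname(fit$t[, 2]), tolerance = 0.02)
})

test_that("paired contrast equals a one-sample t on within-patient differences", {
  set.seed(34)
  n_pat <- 6
  design <- data.frame(
    sample_id = c(paste0("int", 1:n_pat), paste0("ict", 1:n_pat), "h1", "h2"),
    group = factor(c(rep("interictal", n_pat), rep("ictal", n_pat), "healthy", "healthy"),
                   levels = c("healthy", "interictal", "ictal")),
    patient_id = c(paste0("P", 1:n_pat), paste0("P", 1:n_pat), NA, NA),
    stringsAsFactors = FALSE)
  lg <- matrix(rnorm(25 * nrow(design), mean = 8), 25, nrow(design),
               dimnames = list(paste0("f", 1:25), design$sample_id))
  tab <- fit_moderated_de(lg, design, "ictal_vs_interictal",
                          weights = rep(1, 25), d0 = 0)
  ord <- match(rownames(lg), tab$feature_id)
  diffs <- lg[, paste0("ict", 1:n_pat)] - lg[, paste0("int", 1:n_pat)]
  t_paired <- apply(diffs, 1, function(d) unname(t.test(d)$statistic))
  expect_equal(tab$t[ord], unname(t_paired), tolerance = 1e-10)
  expect_equal(tab$log2fc[ord], unname(rowMeans(diffs)), tolerance = 1e-12)
})

test_that("null p-values are approximately uniform across replicates", {
  ks_pass <- vapply(1:30, function(r) {
    cfg <- small_sim_config(seed = 5000 + r, n_mirna = 150, n_gene = 100)
    sim <- simulate_counts(cfg)
    fit <- mirna_de(sim$counts, sim$design, "interictal_vs_healthy")
    suppressWarnings(stats::ks.test(fit$table$p_raw, "punif")$p.value) > 0.01
  }, TRUE)
  expect_gte(sum(ks_pass), 28)
})

test_that("BH adjustment matches closed-form cases and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.001, 0.5)), c(0.002, 0.5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0,1\\]")
  set.seed(36)
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("the DE filter applies strict |FC| and raw-p thresholds", {
  tab <- data.frame(
    feature_id = c("kept_down", "low_fc", "high_p"),
    log2fc = signed_fc_to_log2(c(-1.43, 1.19, 3.0)),
    fc_signed = c(-1.43, 1.19, 3.0),
    t = 0, p_raw = c(0.0186, 0.001, 0.051), p_adj_bh = 1,
    direction = c("down", "up", "up"),
    stringsAsFactors = FALSE)
  out <- filter_de(tab)
  expect_equal(out$feature_id, "kept_down")
  expect_equal(out$direction, "down")
  expect_equal(attr(out, "n_down"), 1L)
  expect_equal(attr(out, "n_up"), 0L)

  # row-order invariance and up + down = total
  shuffled <- tab[c(3, 1, 2), ]
  out2 <- filter_de(shuffled)
  expect_equal(sort(out2$feature_id), sort(out$feature_id))
  expect_equal(attr(out2, "n_up") + attr(out2, "n_down"), nrow(out2))
})

test_that("average rank matches the brute-force double-sort oracle", {
  tab <- data.frame(feature_id = c("a", "b", "c"),
                    fc_signed = c(3, -2, 1), p_raw = c(0.001, 0.01, 0.1),
                    stringsAsFactors = FALSE)
  ranked <- average_rank(tab)
  expect_equal(ranked$avg_rank, c(1, 2, 3))
  expect_equal(ranked$feature_id, c("a", "b", "c"))

  tie <- data.frame(feature_id = c("a", "b", "c"),
                    fc_signed = c(2, -2, 1.5), p_raw = c(0.01, 0.02, 0.03),
                    stringsAsFactors = FALSE)
  ranked_tie <- average_rank(tie)
  fc_ranks_ab <- with(ranked_tie, avg_rank[feature_id %in% c("a", "b")] * 2 -
                        c(1, 2))  # recover FC ranks given p ranks 1 and 2
  expect_equal(fc_ranks_ab, c(1.5, 1.5))

  set.seed(37)
  for (r in 1:10) {
    n <- sample(5:40, 1)
    rnd <- data.frame(feature_id = paste0("f", 1:n),
                      fc_signed = signed_fc(rnorm(n)),
                      p_raw = round(runif(n), 2),  # rounding forces ties
                      stringsAsFactors = FALSE)
    ranked <- average_rank(rnd)
    ora <- oracle_avg_rank(abs(rnd$fc_signed), rnd$p_raw)
    expect_equal(ranked$avg_rank[match(rnd$feature_id, ranked$feature_id)], ora)
  }
  expect_error(average_rank(tab[0, ]), "empty")
})

test_that("signed fold changes convert and invert exactly", {
  expect_equal(signed_fc(1), 2)
  expect_equal(signed_fc(0), 1)
  expect_equal(signed_fc(-1.263), -2.40, tolerance = 5e-3)
  expect_equal(signed_fc_to_log2(-2.40), -1.263, tolerance = 5e-4)
  set.seed(38)
  x <- rnorm(200)
  expect_true(all(abs(signed_fc_to_log2(signed_fc(x)) - x) < 1e-12))
  expect_true(all(abs(signed_fc(x)) >= 1))
})
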