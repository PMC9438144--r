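# Independent oracles and small fixture builders. Each oracle is coded
# step-by-step from the definition, deliberately not sharing code with the
# package implementation.

# Trimmed-mean-of-M-values factor for one sample versus a reference, by
# explicit sorting and set intersection of the kept indices.
oracle_tmm_pair <- function(obs, ref, trim_m = 0.30, trim_a = 0.05) {
  obs <- as.numeric(obs)
  ref <- as.numeric(ref)
  lib_o <- sum(obs)
  lib_r <- sum(ref)
  keep0 <- which(obs > 0 & ref > 0)
  m <- a <- v <- numeric(0)
  for (g in keep0) {
    po <- obs[g] / lib_o
    pr <- ref[g] / lib_r
    m <- c(m, log2(po) - log2(pr))
    a <- c(a, (log2(po) + log2(pr)) / 2)
    v <- c(v, (lib_o - obs[g]) / (lib_o * obs[g]) + (lib_r - ref[g]) / (lib_r * ref[g]))
  }
  if (!length(m) || max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1
  lo_a <- floor(n * trim_a) + 1
  # fractional ranks by explicit counting (ties share their average position)
  frank <- function(x) {
    vapply(x, function(xi) sum(x < xi) + (1 + sum(x == xi)) / 2, 0)
  }
  rm_ <- frank(m)
  ra <- frank(a)
  kept <- which(rm_ >= lo_m & rm_ <= n + 1 - lo_m &
                  ra >= lo_a & ra <= n + 1 - lo_a)
  2^(sum(m[kept] / v[kept]) / sum(1 / v[kept]))
}

oracle_tmm <- function(counts, ref) {
  f <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) f[j] <- oracle_tmm_pair(counts[, j], counts[, ref])
  f / exp(mean(log(f)))
}

# Average rank by explicit pairwise counting (fractional ranks for ties).
oracle_avg_rank <- function(abs_fc, p) {
  n <- length(abs_fc)
  r_fc <- r_p <- numeric(n)
  for (i in seq_len(n)) {
    r_fc[i] <- sum(abs_fc > abs_fc[i]) + (1 + sum(abs_fc == abs_fc[i])) / 2
    r_p[i] <- sum(p < p[i]) + (1 + sum(p == p[i])) / 2
  }
  (r_fc + r_p) / 2
}

# Hypergeometric upper tail by explicit combinatorial enumeration.
oracle_hyper <- function(k, K, n, N) {
  if (k == 0) return(1)
  x <- k:min(n, K)
  sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}

# Small deterministic count matrix for IO tests.
toy_counts <- function() {
  matrix(c(10L, 0L, 5L, 7L, 3L, 12L, 8L, 1L), nrow = 2,
         dimnames = list(c("hsa-mir-a", "hsa-mir-b"),
                         c("s1", "s2", "s3", "s4")))
}

# Random signed network edge list for property tests.
random_network <- function(n_mirna = 8, n_gene = 15, n_edges = 40, seed = 1) {
  set.seed(seed)
  mirnas <- sprintf("hsa-mir-t%02d", seq_len(n_mirna))
  genes <- sprintf("G%03d", seq_len(n_gene))
  pairs <- unique(data.frame(
    mirna_id = sample(mirnas, n_edges, replace = TRUE),
    gene_symbol = sample(genes, n_edges, replace = TRUE),
    stringsAsFactors = FALSE))
  de <- data.frame(feature_id = mirnas,
                   direction = sample(c("up", "down"), n_mirna, replace = TRUE),
                   stringsAsFactors = FALSE)
  list(pairs = pairs, de = de)
}

small_sim_config <- function(seed, n_planted = 0, planted_log2fc = 1.5,
                             n_mirna = 300, n_gene = 500,
                             n_healthy = 8, n_interictal = 8, n_ictal = 2, ...) {
  simulation_config(
    n_mirna = n_mirna, n_gene = n_gene,
    n_per_group = c(healthy = n_healthy, interictal = n_interictal, ictal = n_ictal),
    n_planted = n_planted, planted_log2fc = planted_log2fc, seed = seed, ...)
}
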