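# Count normalization: trimmed-mean-of-M-values scaling factors, log2
# counts-per-million, and mean-variance precision weights.

#' Trimmed-mean-of-M-values (TMM) scaling factors
#'
#' Computes one scaling factor per sample against a reference sample. For each
#' sample the per-feature log ratios M (log2 of depth-normalized counts vs the
#' reference) and average log abundances A are formed over features observed
#' in both libraries; the most extreme 30% of M on each tail and 5% of A on
#' each tail are trimmed, and the factor is the precision-weighted mean of the
#' remaining M-values (weights are the inverse delta-method variances implied
#' by the library sizes). Factors are rescaled to geometric mean 1.
#'
#' @param counts non-negative count matrix (features x samples).
#' @param ref_sample optional reference column name or index; by default the
#'   sample whose upper-quartile depth-normalized count is closest to the mean
#'   across samples.
#' @param trim_m,trim_a tail trim fractions for M and A (defaults 0.30, 0.05).
#' @return numeric vector of scaling factors, one per sample, geometric mean 1.
#' @export
tmm_factors <- function(counts, ref_sample = NULL, trim_m = 0.30, trim_a = 0.05) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample with all-zero counts: ", colnames(counts)[lib == 0][1L])
  if (is.null(ref_sample)) {
    uq <- apply(counts, 2L, function(x) stats::quantile(x[x > 0] / sum(x), probs = 0.75))
    ref <- which.min(abs(uq - mean(uq)))
  } else {
    ref <- if (is.character(ref_sample)) match(ref_sample, colnames(counts)) else as.integer(ref_sample)
    if (is.na(ref) || ref < 1L || ref > ncol(counts)) stop("invalid ref_sample")
  }
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], counts[, ref], trim_m = trim_m, trim_a = trim_a)
  }, 0)
  f / exp(mean(log(f)))
}

# Single-sample TMM factor versus a reference library (unscaled).
tmm_pair <- function(obs, ref, trim_m = 0.30, trim_a = 0.05) {
  obs <- as.numeric(obs)
  ref <- as.numeric(ref)
  n_o <- sum(obs)
  n_r <- sum(ref)
  pos <- obs > 0 & ref > 0
  obs <- obs[pos]
  ref <- ref[pos]
  m <- log2((obs / n_o) / (ref / n_r))
  a <- (log2(obs / n_o) + log2(ref / n_r)) / 2
  # delta-method variance of M under binomial sampling from each library
  v <- (n_o - obs) / (n_o * obs) + (n_r - ref) / (n_r * ref)
  if (!length(m) || max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- rank(m)
  ra <- rank(a)
  keep <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep)) return(1)
  2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))
}

#' Log2 counts-per-million with a prior count
#'
#' Computes `log2((count + prior) / (effective library size + 2 * prior) * 1e6)`
#' where the effective library size is the raw library size times the TMM
#' scaling factor. The linear per-million values (no prior) are returned
#' alongside as the reported abundance column; for short miRNA features no
#' length normalization is meaningful, so per-million counts stand in for
#' per-million transcripts.
#'
#' @param counts count matrix (features x samples).
#' @param factors per-sample scaling factors; defaults to all 1.
#' @param prior_count prior added to each count (default 0.5).
#' @return list with `log2` (matrix), `per_million` (matrix),
#'   `lib_size`, `factors`, `eff_lib_size`.
#' @export
log_cpm <- function(counts, factors = NULL, prior_count = 0.5) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  stopifnot(length(factors) == ncol(counts), all(factors > 0))
  eff <- lib * factors
  lg <- t(log2(t(counts + prior_count) / (eff + 2 * prior_count) * 1e6))
  pm <- t(t(counts) / eff * 1e6)
  dimnames(lg) <- dimnames(counts)
  dimnames(pm) <- dimnames(counts)
  list(log2 = lg, per_million = pm, lib_size = lib, factors = factors,
       eff_lib_size = eff)
}

#' Mean-variance precision weights
#'
#' Fits, per feature, the residual standard deviation of a linear model on the
#' log2 expression values, then smooths sqrt(residual SD) against the mean
#' log2 expression with lowess. Each feature's weight is the inverse fourth
#' power of the trend value at its mean (i.e. the inverse of the implied
#' variance), so low-expression, high-variance features are down-weighted in
#' the moderated fit.
#'
#' @param logexpr log2 expression matrix (features x samples).
#' @param design model matrix (samples x coefficients).
#' @param span lowess span (default 0.5).
#' @return numeric vector of positive weights, one per feature.
#' @export
voom_weights <- function(logexpr, design, span = 0.5) {
  logexpr <- as.matrix(logexpr)
  n <- ncol(logexpr)
  design <- as.matrix(design)
  stopifnot(nrow(design) == n)
  qr_d <- qr(design)
  df_res <- n - qr_d$rank
  if (df_res < 2L) stop("need at least 2 residual degrees of freedom")
  fitted <- t(qr.fitted(qr_d, t(logexpr)))
  res <- logexpr - fitted
  s <- sqrt(rowSums(res^2) / df_res)
  amean <- rowMeans(logexpr)
  sqrt_s <- sqrt(s)
  lo <- stats::lowess(amean, sqrt_s, f = span)
  trend <- stats::approx(lo$x, lo$y, xout = amean, rule = 2, ties = mean)$y
  floor_val <- max(min(sqrt_s[sqrt_s > 0], na.rm = TRUE) / 2, 1e-4)
  trend <- pmax(trend, floor_val)
  w <- 1 / trend^4
  names(w) <- rownames(logexpr)
  w
}
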