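# Differential expression: empirical-Bayes moderated t-statistics on
# normalized log2 expression, the |FC| / p filter, signed fold changes and
# average-rank prioritization.

#' Signed linear fold change from log2 fold change (and back)
#'
#' Reported fold changes are signed linear values with |FC| >= 1:
#' `2^log2fc` for upregulation and `-2^(-log2fc)` for downregulation, so a
#' halving is printed as -2 rather than 0.5. `log2fc = 0` maps to `FC = 1`.
#'
#' @param log2fc numeric vector of log2 fold changes.
#' @return signed linear fold changes.
#' @examples
#' signed_fc(1)       # 2
#' signed_fc(-1.263)  # -2.40
#' @export
signed_fc <- function(log2fc) {
  stopifnot(all(is.finite(log2fc)))
  ifelse(log2fc >= 0, 2^log2fc, -2^(-log2fc))
}

#' @rdname signed_fc
#' @param fc signed linear fold change with |fc| >= 1.
#' @export
signed_fc_to_log2 <- function(fc) {
  stopifnot(all(is.finite(fc)), all(abs(fc) >= 1))
  out <- numeric(length(fc))
  out[fc >= 0] <- log2(fc[fc >= 0])
  out[fc < 0] <- -log2(-fc[fc < 0])
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1, input order preserved).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

# Inverse of the trigamma function by Newton iteration (used to solve the
# method-of-moments equation for the prior degrees of freedom).
trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

# Method-of-moments fit of a scaled inverse-chi-square prior to observed
# residual variances s2 with d residual df, on the log scale:
# returns prior df d0 (possibly Inf) and prior variance s02.
fit_variance_prior <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) return(list(d0 = 0, s02 = stats::median(s2[ok])))
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e)
  excess <- evar - trigamma(d / 2)
  if (is.finite(excess) && excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  list(d0 = d0, s02 = s02)
}

# Moderated one-coefficient inference shared by both designs.
# beta: estimates; s2: residual variances (already on the weighted scale);
# d: residual df; u: unscaled variance multiplier of beta (per feature).
moderate_t <- function(beta, s2, d, u, d0 = NULL) {
  if (is.null(d0)) {
    prior <- fit_variance_prior(s2, d)
    d0 <- prior$d0
    s02 <- prior$s02
  } else {
    s02 <- if (is.finite(d0) && d0 > 0) fit_variance_prior(s2, d)$s02 else
      if (!is.finite(d0)) fit_variance_prior(s2, d)$s02 else NA_real_
  }
  s2_tilde <- if (!is.finite(d0)) rep(s02, length(s2)) else
    if (d0 == 0) s2 else (d0 * s02 + d * s2) / (d0 + d)
  df_total <- if (is.finite(d0)) d0 + d else Inf
  t_stat <- beta / sqrt(s2_tilde * u)
  p <- 2 * stats::pt(-abs(t_stat), df = df_total)
  list(t = t_stat, p = p, df = df_total, d0 = d0, s02 = s02, s2_tilde = s2_tilde)
}

#' Fit moderated differential expression for one contrast
#'
#' Per-feature weighted least squares on normalized log2 expression followed
#' by empirical-Bayes variance shrinkage: the squared residual scale of each
#' feature is shrunk towards a common prior variance,
#' `s2_tilde = (d0 * s02 + d * s2) / (d0 + d)`, with the prior degrees of
#' freedom `d0` and prior variance `s02` estimated by method of moments on the
#' log residual variances. The moderated t-statistic has `d0 + d` degrees of
#' freedom. For the self-paired `ictal_vs_interictal` contrast the model is
#' fit on within-patient differences of normalized expression (a paired
#' moderated t); the two contrasts against healthy controls are unpaired
#' two-group fits. Raw p-values are BH-adjusted across features.
#'
#' @param expr normalized expression as returned by [log_cpm()] (or a plain
#'   log2 matrix).
#' @param design study design data.frame (sample_id, group, patient_id).
#' @param contrast one of `"interictal_vs_healthy"`, `"ictal_vs_interictal"`,
#'   `"ictal_vs_healthy"`.
#' @param weights optional per-feature precision weights; computed with
#'   [voom_weights()] when NULL.
#' @param d0 optional override of the prior degrees of freedom (0 gives the
#'   ordinary t-test; Inf pools all variances to the prior value).
#' @param rank_scope scope for [average_rank()]; `"all_tested"` or `"de_only"`.
#' @param fc_thresh,p_thresh DE filter thresholds used for flagging.
#' @return a `de_table` data.frame: feature_id, log2fc, fc_signed, t, p_raw,
#'   p_adj_bh, direction, avg_rank, is_de, plus per-group mean per-million
#'   abundances when `expr` carries them.
#' @export
fit_moderated_de <- function(expr, design, contrast, weights = NULL, d0 = NULL,
                             rank_scope = "all_tested",
                             fc_thresh = 1.2, p_thresh = 0.05) {
  contrasts_known <- c("interictal_vs_healthy", "ictal_vs_interictal", "ictal_vs_healthy")
  contrast <- match.arg(contrast, contrasts_known)
  lg <- if (is.list(expr)) expr$log2 else as.matrix(expr)
  pm <- if (is.list(expr)) expr$per_million else NULL
  stopifnot(ncol(lg) == nrow(design))
  groups <- strsplit(contrast, "_vs_", fixed = TRUE)[[1L]]
  g_num <- groups[1L]
  g_den <- groups[2L]

  if (contrast == "ictal_vs_interictal") {
    pat_ict <- design$patient_id[design$group == "ictal"]
    pat_int <- design$patient_id[design$group == "interictal"]
    patients <- intersect(pat_ict[!is.na(pat_ict)], pat_int[!is.na(pat_int)])
    if (length(patients) < 2L) stop("paired contrast needs >=2 patients with both phases")
    idx_ict <- match(patients, ifelse(design$group == "ictal", design$patient_id, NA))
    idx_int <- match(patients, ifelse(design$group == "interictal", design$patient_id, NA))
    dmat <- lg[, idx_ict, drop = FALSE] - lg[, idx_int, drop = FALSE]
    n <- length(patients)
    X <- matrix(1, n, 1)
    if (is.null(weights)) weights <- voom_weights(dmat, X)
    beta <- rowMeans(dmat)
    res <- dmat - beta
    df_res <- n - 1L
    s2 <- weights * rowSums(res^2) / df_res
    u <- (1 / n) / weights
  } else {
    keep <- design$group %in% c(g_num, g_den)
    if (sum(design$group == g_num) < 2L || sum(design$group == g_den) < 2L) {
      stop("contrast needs >=2 samples per side")
    }
    sub <- lg[, keep, drop = FALSE]
    grp <- factor(as.character(design$group[keep]), levels = c(g_den, g_num))
    X <- stats::model.matrix(~grp)
    if (is.null(weights)) weights <- voom_weights(sub, X)
    qr_x <- qr(X)
    coefs <- t(qr.coef(qr_x, t(sub)))
    beta <- coefs[, 2L]
    res <- sub - t(qr.fitted(qr_x, t(sub)))
    df_res <- ncol(sub) - qr_x$rank
    s2 <- weights * rowSums(res^2) / df_res
    xtx_inv <- chol2inv(chol(crossprod(X)))
    u <- xtx_inv[2L, 2L] / weights
  }

  mod <- moderate_t(beta, s2, df_res, u, d0 = d0)
  p_raw <- pmin(pmax(mod$p, 0), 1)
  tab <- data.frame(
    feature_id = rownames(lg),
    log2fc = as.numeric(beta),
    fc_signed = signed_fc(as.numeric(beta)),
    t = as.numeric(mod$t),
    p_raw = p_raw,
    p_adj_bh = bh_adjust(p_raw),
    direction = ifelse(beta >= 0, "up", "down"),
    stringsAsFactors = FALSE
  )
  if (!is.null(pm)) {
    for (g in unique(c(g_num, g_den))) {
      tab[[paste0("per_million_mean_", g)]] <-
        rowMeans(pm[, design$group == g, drop = FALSE])
    }
  }
  tab$is_de <- abs(tab$fc_signed) > fc_thresh & tab$p_raw < p_thresh
  tab <- average_rank(tab, scope = rank_scope, fc_thresh = fc_thresh, p_thresh = p_thresh)
  attr(tab, "contrast") <- contrast
  attr(tab, "df_residual") <- df_res
  attr(tab, "d0") <- mod$d0
  attr(tab, "s02") <- mod$s02
  class(tab) <- c("de_table", "data.frame")
  tab
}

#' Filter a DE table to differentially expressed features
#'
#' Keeps features with `|FC| > fc_thresh` and raw `p < p_thresh` (both
#' strict). The raw p-value is used for the filter — the prioritized lists
#' this reproduces are raw-p filtered — while BH-adjusted values remain in the
#' table for reporting.
#'
#' @param de a `de_table`.
#' @param fc_thresh signed linear fold-change threshold (default 1.2).
#' @param p_thresh raw p-value threshold (default 0.05).
#' @return the DE subset, with `n_up` / `n_down` counts as attributes.
#' @export
filter_de <- function(de, fc_thresh = 1.2, p_thresh = 0.05) {
  stopifnot(fc_thresh > 0, p_thresh > 0)
  keep <- abs(de$fc_signed) > fc_thresh & de$p_raw < p_thresh
  out <- de[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_up") <- sum(out$direction == "up")
  attr(out, "n_down") <- sum(out$direction == "down")
  attr(out, "contrast") <- attr(de, "contrast")
  class(out) <- class(de)
  out
}

#' Average-rank prioritization of a DE table
#'
#' Ranks features by |signed FC| (descending) and by raw p (ascending) over
#' the chosen scope; ties receive average (fractional) ranks. The average
#' rank is the mean of the two ranks and the table is returned sorted by it,
#' smallest (most extreme and most significant) first.
#'
#' @param de a DE table with `fc_signed` and `p_raw` columns.
#' @param scope `"all_tested"` ranks over every feature in the table;
#'   `"de_only"` ranks only over features passing the DE filter (others get
#'   `NA` and sort last).
#' @param fc_thresh,p_thresh thresholds defining the DE subset for
#'   `scope = "de_only"`.
#' @return the table with an `avg_rank` column, sorted ascending by it.
#' @export
average_rank <- function(de, scope = c("all_tested", "de_only"),
                         fc_thresh = 1.2, p_thresh = 0.05) {
  scope <- match.arg(scope)
  if (nrow(de) == 0L) stop("empty DE table")
  in_scope <- if (scope == "all_tested") rep(TRUE, nrow(de)) else
    abs(de$fc_signed) > fc_thresh & de$p_raw < p_thresh
  avg <- rep(NA_real_, nrow(de))
  if (any(in_scope)) {
    r_fc <- rank(-abs(de$fc_signed[in_scope]), ties.method = "average")
    r_p <- rank(de$p_raw[in_scope], ties.method = "average")
    avg[in_scope] <- (r_fc + r_p) / 2
  }
  de$avg_rank <- avg
  ord <- order(avg, de$p_raw, de$feature_id, na.last = TRUE)
  out <- de[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit the full miRNA DE model from counts
#'
#' One-call front end: TMM factors, log2 counts-per-million, mean-variance
#' precision weights, moderated t-test for the requested contrast and the
#' DE filter, returned as a classed model object.
#'
#' @param counts miRNA count matrix (features x samples).
#' @param design study design data.frame.
#' @param contrast contrast name, see [fit_moderated_de()].
#' @param fc_thresh,p_thresh DE filter thresholds.
#' @param prior_count prior count for [log_cpm()].
#' @param rank_scope scope for [average_rank()].
#' @param ... passed to [fit_moderated_de()].
#' @return object of class `mirna_de` with elements `table` (full `de_table`),
#'   `de` (filtered subset), `contrast`, `factors`, `thresholds`.
#' @export
mirna_de <- function(counts, design, contrast, fc_thresh = 1.2, p_thresh = 0.05,
                     prior_count = 0.5, rank_scope = "all_tested", ...) {
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  if (anyNA(design$sample_id)) stop("design does not cover all samples")
  factors <- tmm_factors(counts)
  expr <- log_cpm(counts, factors, prior_count = prior_count)
  tab <- fit_moderated_de(expr, design, contrast, rank_scope = rank_scope,
                          fc_thresh = fc_thresh, p_thresh = p_thresh, ...)
  structure(list(table = tab,
                 de = filter_de(tab, fc_thresh, p_thresh),
                 contrast = contrast,
                 factors = factors,
                 thresholds = list(fc = fc_thresh, p = p_thresh)),
            class = "mirna_de")
}

#' @export
print.mirna_de <- function(x, ...) {
  cat("Moderated miRNA differential expression\n")
  cat("  contrast:  ", x$contrast, "\n", sep = "")
  cat("  features:  ", nrow(x$table), " tested\n", sep = "")
  cat(sprintf("  DE (|FC| > %g, p < %g): %d  (%d up, %d down)\n",
              x$thresholds$fc, x$thresholds$p, nrow(x$de),
              attr(x$de, "n_up"), attr(x$de, "n_down")))
  cat(sprintf("  prior df d0 = %.3g, prior variance s0^2 = %.3g\n",
              attr(x$table, "d0"), attr(x$table, "s02")))
  invisible(x)
}

#' @export
summary.mirna_de <- function(object, n = 10L, ...) {
  print(object)
  cat("\nTop features by average rank:\n")
  cols <- c("feature_id", "fc_signed", "p_raw", "p_adj_bh", "avg_rank")
  print(utils::head(as.data.frame(object$de)[, cols], n), digits = 3)
  invisible(object)
}

#' @export
plot.mirna_de <- function(x, ...) {
  tab <- x$table
  graphics::plot(tab$log2fc, -log10(tab$p_raw),
                 pch = 20, col = ifelse(tab$is_de, "firebrick", "grey60"),
                 xlab = "log2 fold change", ylab = "-log10 raw p",
                 main = paste("miRNA DE:", x$contrast), ...)
  graphics::abline(h = -log10(x$thresholds$p), lty = 2)
  graphics::abline(v = c(-1, 1) * log2(x$thresholds$fc), lty = 2)
  invisible(x)
}
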