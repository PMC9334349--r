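#' Detect outlier samples
#'
#' Applies up to four complementary rules to the biological subject
#' samples and reports, per sample, the underlying statistic, the
#' threshold and the resulting flag:
#'
#' * `mv_fraction`: missing-value fraction above `mv_threshold`.
#' * `pc_sd`: PC1 score more than `k_sd` standard deviations from the
#'   mean PC1 score.
#' * `pc_mad`: PC1 score more than `k_sd` scaled MADs (1.4826 x MAD)
#'   from the median — the robust variant of the same rule.
#' * `mahalanobis`: robust squared Mahalanobis distance over the top
#'   `min(10, n - 1)` principal components above the
#'   `mahal_quantile` chi-square quantile.
#'
#' PCA is computed on the subject samples after temporary per-variable
#' median imputation, log10(x + 1) transformation and centering; the
#' dataset itself is never modified (reporting is not mutation, so no
#' process record is appended).  Degenerate inputs are guarded: when the
#' PC1 spread is zero the score rules flag nothing.
#'
#' @param ds a [MassDataset-class].
#' @param methods subset of the four rule names.
#' @param k_sd multiplier for the PC1 spread rules (default 6).
#' @param mv_threshold missing-fraction cutoff (default 0.50).
#' @param mahal_quantile chi-square quantile for the distance rule
#'   (default 0.975).
#' @return an `outlier_report`: data frame `samples` (statistics and
#'   per-rule flags) plus the parameters and thresholds used.
#' @export
detect_outlier_samples <- function(ds,
                                   methods = c("mv_fraction", "pc_sd",
                                               "pc_mad", "mahalanobis"),
                                   k_sd = 6, mv_threshold = 0.50,
                                   mahal_quantile = 0.975) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(is(ds, "MassDataset"))
  subj_ids <- subject_samples(ds)
  if (length(subj_ids) == 0L) subj_ids <- ds@sample_info$sample_id
  expr <- ds@expression_data[, subj_ids, drop = FALSE]
  n <- length(subj_ids)

  report <- data.frame(sample_id = subj_ids, stringsAsFactors = FALSE)
  report$mv_fraction <- colMeans(is.na(expr))
  if ("mv_fraction" %in% methods) {
    report$flag_mv_fraction <- report$mv_fraction > mv_threshold
  }

  pca_needed <- any(c("pc_sd", "pc_mad", "mahalanobis") %in% methods)
  pc_scores <- NULL
  if (pca_needed) {
    if (n < 3) {
      stop("PCA-based outlier rules need at least 3 subject samples",
           call. = FALSE)
    }
    x <- prepare_pca_matrix(expr)
    pc <- prcomp(x, center = FALSE, scale. = FALSE)
    pc_scores <- pc$x
    report$pc1 <- unname(pc_scores[, 1])
  }
  if ("pc_sd" %in% methods) {
    spread <- sd(report$pc1)
    center <- mean(report$pc1)
    report$flag_pc_sd <- if (spread == 0) rep(FALSE, n) else
      abs(report$pc1 - center) > k_sd * spread
  }
  if ("pc_mad" %in% methods) {
    spread <- 1.4826 * mad(report$pc1, constant = 1)
    center <- median(report$pc1)
    # zero MAD: any deviating sample is infinitely many MADs away
    report$flag_pc_mad <- if (spread == 0)
      abs(report$pc1 - center) > 1e-12 else
      abs(report$pc1 - center) > k_sd * spread
  }
  if ("mahalanobis" %in% methods) {
    g <- min(10, n - 1, ncol(pc_scores))
    scores_g <- pc_scores[, seq_len(g), drop = FALSE]
    keep <- apply(scores_g, 2, function(v) sd(v) > 1e-12)
    scores_g <- scores_g[, keep, drop = FALSE]
    g_eff <- ncol(scores_g)
    if (g_eff == 0) {
      report$mahalanobis_d2 <- rep(0, n)
      report$flag_mahalanobis <- rep(FALSE, n)
    } else {
      est <- tryCatch(
        cov.rob(scores_g, method = if (n > 2 * g_eff + 2) "mcd" else "classical"),
        error = function(e) list(center = colMeans(scores_g),
                                 cov = cov(scores_g)))
      d2 <- mahalanobis(scores_g, est$center, est$cov)
      report$mahalanobis_d2 <- unname(d2)
      report$flag_mahalanobis <- d2 > qchisq(mahal_quantile, df = g_eff)
    }
  }
  structure(list(samples = norm_df(report),
                 parameters = list(methods = methods, k_sd = k_sd,
                                   mv_threshold = mv_threshold,
                                   mahal_quantile = mahal_quantile)),
            class = "outlier_report")
}

# Temporary preprocessing for score-based outlier rules: per-variable
# median imputation, log10(x + 1), column (variable) centering; samples
# in rows.
prepare_pca_matrix <- function(expr) {
  filled <- expr
  med <- apply(expr, 1, function(v) median(v, na.rm = TRUE))
  idx <- which(is.na(filled), arr.ind = TRUE)
  if (nrow(idx)) filled[idx] <- med[idx[, 1]]
  x <- t(log10(filled + 1))
  sweep(x, 2, colMeans(x))
}

#' @export
print.outlier_report <- function(x, ...) {
  flags <- grep("^flag_", names(x$samples), value = TRUE)
  n_flagged <- sum(Reduce(`|`, x$samples[flags]))
  cat(sprintf("<outlier_report> %d samples, %d flagged by >=1 rule (%s)\n",
              nrow(x$samples), n_flagged,
              paste(x$parameters$methods, collapse = ", ")))
  invisible(x)
}
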