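# Quality-control metrics: computable at any pipeline stage, read-only.

utils::globalVariables(c("pc1", "pc2", "class", "rsd"))

#' Per-variable relative standard deviation in a sample class
#'
#' RSD = 100 * sd / mean over the observed values of the class, the
#' standard reliability measure for pooled QC replicates; variables with
#' fewer than 2 observed values get `NA` and are excluded from pass-rate
#' denominators.  The conventional biomarker-discovery cutoff is 30%.
#'
#' @param ds a [MassDataset-class].
#' @param sample_class which `class` of samples to use (default `"QC"`).
#' @return named numeric vector of RSDs in percent.
#' @export
qc_rsd <- function(ds, sample_class = "QC") {
  stopifnot(is(ds, "MassDataset"))
  ids <- ds@sample_info$sample_id[ds@sample_info$class == sample_class]
  if (length(ids) == 0L) {
    stop("no samples of class '", sample_class, "'", call. = FALSE)
  }
  x <- ds@expression_data[, ids, drop = FALSE]
  apply(x, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    100 * sd(v) / mean(v)
  })
}

#' Missing-value summary
#'
#' @param ds a [MassDataset-class].
#' @return list with `per_sample` and `per_variable` missing fractions
#'   (named numeric vectors).
#' @export
mv_summary <- function(ds) {
  stopifnot(is(ds, "MassDataset"))
  miss <- is.na(ds@expression_data)
  list(per_sample = colMeans(miss), per_variable = rowMeans(miss))
}

#' Pairwise sample correlation within a class
#'
#' Pearson (or Spearman) correlation of `log10(x + 1)` intensities over
#' pairwise-complete observations; tight QC-QC correlations indicate a
#' stable platform.
#'
#' @param ds a [MassDataset-class].
#' @param sample_class sample class to correlate (default `"QC"`;
#'   `NULL` for all samples).
#' @param method `"pearson"` or `"spearman"`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
sample_correlation <- function(ds, sample_class = "QC",
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is(ds, "MassDataset"))
  ids <- if (is.null(sample_class)) ds@sample_info$sample_id else
    ds@sample_info$sample_id[ds@sample_info$class == sample_class]
  if (length(ids) < 2) {
    stop("need at least 2 samples of class '", sample_class, "'",
         call. = FALSE)
  }
  x <- log10(ds@expression_data[, ids, drop = FALSE] + 1)
  cor(x, use = "pairwise.complete.obs", method = method)
}

#' PCA scores for quality assessment
#'
#' Convenience wrapper over [run_pca()] with temporary per-variable
#' median imputation, for datasets that still contain missing values.
#'
#' @param ds a [MassDataset-class].
#' @param scale scaling passed to [run_pca()] (default `"uv"`).
#' @return list with `scores`, `variance_fraction` and the sample ids.
#' @export
qc_pca_scores <- function(ds, scale = "uv") {
  stopifnot(is(ds, "MassDataset"))
  expr <- ds@expression_data
  med <- apply(expr, 1, function(v) median(v, na.rm = TRUE))
  idx <- which(is.na(expr), arr.ind = TRUE)
  if (nrow(idx)) expr[idx] <- med[idx[, 1]]
  keep <- apply(expr, 1, function(v) sd(v) > 0)
  fit <- pca_matrix(t(log10(expr[keep, , drop = FALSE] + 1)), scale = scale)
  list(scores = fit$scores, variance_fraction = fit$variance_fraction,
       sample_id = colnames(expr))
}

#' Structured quality-control report
#'
#' Computes the five QC aspects — missing-value distribution, QC RSD
#' with pass rate at `cutoff`, per-sample intensity medians, QC-QC
#' correlation, and a PCA overview — and writes them as a versioned JSON
#' report plus PNG plots.  The input dataset is read-only: reporting
#' appends no process record.
#'
#' @param ds a [MassDataset-class].
#' @param path output directory for `qc_report.json` and plots; `NULL`
#'   computes the report without writing files.
#' @param cutoff RSD pass cutoff in percent (default 30).
#' @param stage free-text label of the pipeline stage the report
#'   describes.
#' @return a `qc_report` object (list of all metrics), invisibly when
#'   `path` is given.
#' @export
qc_report <- function(ds, path = NULL, cutoff = 30, stage = "unspecified") {
  stopifnot(is(ds, "MassDataset"))
  mv <- mv_summary(ds)
  has_qc <- any(ds@sample_info$class == "QC")
  rsd <- if (has_qc) qc_rsd(ds) else NULL
  pass_rate <- if (!is.null(rsd) && any(!is.na(rsd))) {
    mean(rsd[!is.na(rsd)] <= cutoff)
  } else NA_real_
  cor_qc <- if (has_qc && sum(ds@sample_info$class == "QC") >= 2) {
    sample_correlation(ds, "QC")
  } else NULL
  pca <- qc_pca_scores(ds)
  report <- structure(list(
    schema_version = 1L,
    stage = stage,
    parameters = list(rsd_cutoff = cutoff, log_base = "log10(x+1)"),
    n_samples = ncol(ds@expression_data),
    n_variables = nrow(ds@expression_data),
    mv_per_sample = as.list(mv$per_sample),
    mv_per_variable = as.list(mv$per_variable),
    qc_rsd = if (is.null(rsd)) NULL else as.list(rsd),
    rsd_pass_rate = pass_rate,
    sample_intensity_median = as.list(apply(ds@expression_data, 2,
                                            function(v) median(v, na.rm = TRUE))),
    qc_correlation = if (is.null(cor_qc)) NULL else
      list(sample_id = colnames(cor_qc), matrix = unname(cor_qc)),
    pca = list(sample_id = pca$sample_id,
               scores = unname(pca$scores[, seq_len(min(2, ncol(pca$scores))),
                                          drop = FALSE]),
               variance_fraction = pca$variance_fraction)
  ), class = "qc_report")

  if (!is.null(path)) {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    writeLines(toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                      pretty = TRUE, null = "null"),
               file.path(path, "qc_report.json"))
    qc_report_plots(ds, report, path)
    log_op("qc_report", list(path = path, stage = stage))
    return(invisible(report))
  }
  report
}

qc_report_plots <- function(ds, report, path) {
  si <- ds@sample_info
  pca_df <- data.frame(
    sample_id = report$pca$sample_id,
    pc1 = report$pca$scores[, 1],
    pc2 = if (ncol(report$pca$scores) > 1) report$pca$scores[, 2] else 0,
    class = si$class[match(report$pca$sample_id, si$sample_id)])
  vf <- report$pca$variance_fraction
  p <- ggplot(pca_df, aes(x = pc1, y = pc2, colour = class)) +
    geom_point(size = 2) +
    labs(x = sprintf("PC1 (%.1f%%)", 100 * vf[1]),
         y = sprintf("PC2 (%.1f%%)", 100 * vf[min(2, length(vf))]),
         title = sprintf("PCA score plot (%s)", report$stage)) +
    theme_bw()
  ggsave_quiet(file.path(path, "pca_scores.png"), p)

  if (!is.null(report$qc_rsd)) {
    rsd_df <- data.frame(rsd = unlist(report$qc_rsd))
    rsd_df <- rsd_df[is.finite(rsd_df$rsd), , drop = FALSE]
    p2 <- ggplot(rsd_df, aes(x = rsd)) +
      geom_histogram(bins = 40, fill = "steelblue") +
      geom_vline(xintercept = report$parameters$rsd_cutoff,
                 linetype = "dashed") +
      labs(x = "QC RSD (%)", y = "variables",
           title = sprintf("QC RSD, pass rate %.1f%%",
                           100 * report$rsd_pass_rate)) +
      theme_bw()
    ggsave_quiet(file.path(path, "qc_rsd.png"), p2)
  }
  invisible(NULL)
}

ggsave_quiet <- function(file, plot, width = 6, height = 4.5) {
  suppressMessages(ggplot2::ggsave(file, plot, width = width,
                                   height = height, dpi = 120))
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> stage '%s': %d x %d", x$stage, x$n_variables,
              x$n_samples))
  if (!is.na(x$rsd_pass_rate)) {
    cat(sprintf(", QC RSD pass rate %.1f%% at %g%%",
                100 * x$rsd_pass_rate, x$parameters$rsd_cutoff))
  }
  cat("\n")
  invisible(x)
}
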