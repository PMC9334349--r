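# Data cleaning: noisy-feature flagging, imputation, normalization,
# batch integration.

qc_samples <- function(ds) ds@sample_info$sample_id[ds@sample_info$class == "QC"]
subject_samples <- function(ds) {
  ds@sample_info$sample_id[ds@sample_info$class != "QC"]
}

#' Flag noisy metabolic features by missing-value frequency
#'
#' A feature is flagged as noise when its missing-value frequency exceeds
#' `qc_mv_threshold` in the QC samples, or exceeds `group_mv_threshold`
#' in every study group (conservative reading; set
#' `any_group = TRUE` for the looser any-group rule).  The flags land in
#' a logical `is_noise` column of `variable_info`; nothing is removed —
#' pair with [filter_variables()] to drop the flagged features.
#'
#' @param ds a [MassDataset-class] whose `sample_info` has a `class`
#'   column distinguishing `"QC"` samples.
#' @param qc_mv_threshold QC missing-frequency cutoff (default 0.20).
#' @param group_mv_threshold per-group missing-frequency cutoff
#'   (default 0.50).
#' @param group_field `sample_info` column defining the study groups of
#'   the non-QC samples.
#' @param any_group if `TRUE`, exceeding the group threshold in any
#'   single group suffices (default `FALSE`: every group).
#' @param record append a process record (default `TRUE`).
#' @return the dataset with `is_noise` added to `variable_info`.
#' @export
flag_noisy_variables <- function(ds, qc_mv_threshold = 0.20,
                                 group_mv_threshold = 0.50,
                                 group_field = "group",
                                 any_group = FALSE, record = TRUE) {
  stopifnot(is(ds, "MassDataset"), is_scalar_number(qc_mv_threshold),
            is_scalar_number(group_mv_threshold))
  assert_scalar_flag(any_group, "any_group")
  assert_scalar_flag(record, "record")
  if (!group_field %in% names(ds@sample_info)) {
    stop("group_field '", group_field, "' not found in sample_info",
         call. = FALSE)
  }
  expr <- ds@expression_data
  qc_ids <- qc_samples(ds)
  if (length(qc_ids) == 0L) {
    warning("no QC samples: the QC missing-value criterion is skipped",
            call. = FALSE)
    qc_flag <- rep(FALSE, nrow(expr))
  } else {
    qc_freq <- rowMeans(is.na(expr[, qc_ids, drop = FALSE]))
    qc_flag <- qc_freq > qc_mv_threshold
  }
  subj <- ds@sample_info[ds@sample_info$class != "QC", , drop = FALSE]
  groups <- unique(subj[[group_field]])
  if (length(groups) == 0L) {
    group_flag <- rep(FALSE, nrow(expr))
  } else {
    per_group <- vapply(groups, function(g) {
      ids <- subj$sample_id[subj[[group_field]] == g]
      rowMeans(is.na(expr[, ids, drop = FALSE])) > group_mv_threshold
    }, logical(nrow(expr)))
    per_group <- matrix(per_group, nrow = nrow(expr))
    group_flag <- if (any_group) apply(per_group, 1, any) else
      apply(per_group, 1, all)
  }
  ds@variable_info$is_noise <- unname(qc_flag | group_flag)
  ds@variable_info_note <- update_note(
    ds@variable_info_note, "is_noise",
    sprintf("missing > %g in QC or > %g in %s study group",
            qc_mv_threshold, group_mv_threshold,
            if (any_group) "any" else "every"))
  if (record) {
    ds <- append_record(ds, "flag_noisy_variables",
                        list(qc_mv_threshold = qc_mv_threshold,
                             group_mv_threshold = group_mv_threshold,
                             group_field = group_field,
                             any_group = any_group,
                             had_qc = length(qc_ids) > 0))
  }
  validObject(ds)
  ds
}

register_operation("flag_noisy_variables", function(ds, params, resources) {
  flag_noisy_variables(ds, qc_mv_threshold = params$qc_mv_threshold %||% 0.20,
                       group_mv_threshold = params$group_mv_threshold %||% 0.50,
                       group_field = params$group_field %||% "group",
                       any_group = params$any_group %||% FALSE)
})

#' Impute missing values
#'
#' Methods: `"knn"` (default; for each variable with missing cells, the
#' `k` variables most similar over mutually observed samples donate a
#' distance-weighted average of their value in the target sample),
#' `"svd"` (iterative low-rank completion of rank `rank`), and the
#' per-variable constants `"zero"`, `"mean"`, `"median"`, `"minimum"`.
#' KNN falls back to the per-variable mean for variables with fewer than
#' 3 mutually observed samples against every neighbour (their ids are
#' stored in the process record).
#'
#' @param ds a [MassDataset-class].  Every variable must have at least
#'   one observed value — run [flag_noisy_variables()] /
#'   [filter_variables()] first.
#' @param method imputation method.
#' @param k number of neighbour variables for KNN (default 10).
#' @param rank target rank for SVD completion (default 5).
#' @param tol convergence tolerance for SVD completion (default 1e-6).
#' @param max_iter iteration cap for SVD completion.
#' @param record append a process record (default `TRUE`).
#' @return the dataset with no missing entries; observed cells untouched.
#'   Imputation is idempotent.
#' @export
impute <- function(ds, method = c("knn", "svd", "zero", "mean", "median",
                                  "minimum"),
                   k = 10, rank = 5, tol = 1e-6, max_iter = 100,
                   record = TRUE) {
  method <- match.arg(method)
  stopifnot(is(ds, "MassDataset"))
  assert_scalar_flag(record, "record")
  expr <- ds@expression_data
  all_missing <- rownames(expr)[rowSums(!is.na(expr)) == 0]
  if (length(all_missing)) {
    stop("variables with zero observed values cannot be imputed: ",
         paste(head(all_missing, 5), collapse = ", "),
         "; flag and remove them first (flag_noisy_variables + filter_variables)",
         call. = FALSE)
  }
  fallback <- character(0)
  if (anyNA(expr)) {
    expr <- switch(
      method,
      zero = { expr[is.na(expr)] <- 0; expr },
      mean = impute_constant(expr, function(v) mean(v, na.rm = TRUE)),
      median = impute_constant(expr, function(v) median(v, na.rm = TRUE)),
      minimum = impute_constant(expr, function(v) min(v, na.rm = TRUE)),
      knn = { out <- impute_knn(expr, k); fallback <- attr(out, "fallback"); out },
      svd = impute_svd(expr, rank, tol, max_iter)
    )
    attr(expr, "fallback") <- NULL
  }
  ds@expression_data <- expr
  if (record) {
    params <- list(method = method)
    if (method == "knn") {
      params$k <- k
      if (length(fallback)) params$mean_fallback_variables <- fallback
    }
    if (method == "svd") params <- c(params, list(rank = rank, tol = tol,
                                                  max_iter = max_iter))
    ds <- append_record(ds, "impute", params)
  }
  validObject(ds)
  ds
}

impute_constant <- function(expr, stat) {
  fill <- apply(expr, 1, stat)
  idx <- which(is.na(expr), arr.ind = TRUE)
  expr[idx] <- fill[idx[, 1]]
  expr
}

impute_knn <- function(expr, k) {
  n_var <- nrow(expr)
  # distances over mutually observed samples, scaled by overlap so that
  # variables with different overlap counts are comparable
  targets <- which(rowSums(is.na(expr)) > 0)
  fallback <- character(0)
  filled <- expr
  for (i in targets) {
    xi <- expr[i, ]
    d <- rep(NA_real_, n_var)
    for (j in seq_len(n_var)) {
      if (j == i) next
      both <- !is.na(xi) & !is.na(expr[j, ])
      if (sum(both) >= 3) {
        d[j] <- sqrt(mean((xi[both] - expr[j, both])^2))
      }
    }
    if (all(is.na(d))) {
      filled[i, is.na(xi)] <- mean(xi, na.rm = TRUE)
      fallback <- c(fallback, rownames(expr)[i])
      next
    }
    nb <- order(d)[seq_len(min(k, sum(!is.na(d))))]
    w_all <- 1 / (d[nb] + 1e-12)
    for (s in which(is.na(xi))) {
      donor <- !is.na(expr[nb, s])
      if (any(donor)) {
        filled[i, s] <- sum(w_all[donor] * expr[nb[donor], s]) /
          sum(w_all[donor])
      } else {
        filled[i, s] <- mean(xi, na.rm = TRUE)
      }
    }
  }
  attr(filled, "fallback") <- fallback
  filled
}

impute_svd <- function(expr, rank, tol, max_iter) {
  miss <- is.na(expr)
  fill <- apply(expr, 1, function(v) mean(v, na.rm = TRUE))
  x <- expr
  idx <- which(miss, arr.ind = TRUE)
  x[idx] <- fill[idx[, 1]]
  r <- min(rank, dim(expr) - 1L)
  for (it in seq_len(max_iter)) {
    sv <- svd(x, nu = r, nv = r)
    approx <- sv$u %*% (diag(sv$d[seq_len(r)], r, r) %*% t(sv$v))
    delta <- sqrt(mean((x[miss] - approx[miss])^2)) /
      (sqrt(mean(x[!miss]^2)) + 1e-12)
    x[miss] <- approx[miss]
    if (delta < tol) break
  }
  x[!miss] <- expr[!miss]
  x
}

register_operation("impute", function(ds, params, resources) {
  impute(ds, method = params$method, k = params$k %||% 10,
         rank = params$rank %||% 5, tol = params$tol %||% 1e-6,
         max_iter = params$max_iter %||% 100)
})

#' Normalize intensities
#'
#' Sample-wise methods compute one dilution factor per sample:
#' `"total"`, `"median"`, `"mean"` use that statistic of the observed
#' intensities (rescaled by the dataset-median factor so the overall
#' intensity scale is preserved); `"pqn"` is probabilistic quotient
#' normalization, dividing each sample by the median of its quotients
#' against the reference spectrum (per-variable median over QC samples,
#' or over all samples when no QC exists).
#'
#' QC-based methods correct signal drift over injection order per
#' variable: the intensity of the QC injections is fitted against
#' injection order on the log2 scale (`"loess_qc"`: LOESS with `span`,
#' degree 1; `"svr_qc"`: epsilon-SVR with RBF kernel on the scaled
#' order), the fitted curve is evaluated at every injection, and each
#' measurement is divided by the relative fit
#' `fit(order) / median(fit at QC orders)` clipped to `[0.1, 10]`.
#' QC methods require at least 4 QC samples, an `injection_order`
#' column, and QC samples at the first and last injection (the fit is
#' not extrapolated).
#'
#' Missingness is preserved: missing in, missing out.
#'
#' @param ds a [MassDataset-class].
#' @param method normalization method.
#' @param span LOESS span (default 0.75).
#' @param svr_cost,svr_epsilon SVR hyperparameters (defaults 1, 0.1).
#' @param record append a process record (default `TRUE`).
#' @return the normalized dataset.
#' @export
normalize_data <- function(ds, method = c("pqn", "total", "median", "mean",
                                          "loess_qc", "svr_qc"),
                           span = 0.75, svr_cost = 1, svr_epsilon = 0.1,
                           record = TRUE) {
  method <- match.arg(method)
  stopifnot(is(ds, "MassDataset"))
  assert_scalar_flag(record, "record")
  expr <- ds@expression_data

  if (method %in% c("total", "median", "mean")) {
    stat <- switch(method, total = function(v) sum(v, na.rm = TRUE),
                   median = function(v) median(v, na.rm = TRUE),
                   mean = function(v) mean(v, na.rm = TRUE))
    factors <- apply(expr, 2, stat)
    if (any(!is.finite(factors) | factors <= 0)) {
      stop("non-positive per-sample factor; check the data", call. = FALSE)
    }
    factors <- factors / median(factors)
    expr <- sweep(expr, 2, factors, "/")
  } else if (method == "pqn") {
    qc_ids <- qc_samples(ds)
    ref_ids <- if (length(qc_ids) >= 2) qc_ids else colnames(expr)
    reference <- apply(expr[, ref_ids, drop = FALSE], 1,
                       function(v) median(v, na.rm = TRUE))
    factors <- apply(expr, 2, function(v) {
      q <- v / reference
      median(q[is.finite(q)], na.rm = TRUE)
    })
    if (any(!is.finite(factors) | factors <= 0)) {
      stop("non-positive PQN factor; check the data", call. = FALSE)
    }
    expr <- sweep(expr, 2, factors, "/")
  } else {
    expr <- normalize_qc_drift(ds, method, span, svr_cost, svr_epsilon)
  }

  ds@expression_data <- expr
  if (record) {
    params <- list(method = method)
    if (method == "loess_qc") params$span <- span
    if (method == "svr_qc") params <- c(params, list(svr_cost = svr_cost,
                                                     svr_epsilon = svr_epsilon))
    ds <- append_record(ds, "normalize_data", params)
  }
  validObject(ds)
  ds
}

normalize_qc_drift <- function(ds, method, span, svr_cost, svr_epsilon) {
  si <- ds@sample_info
  if (!"injection_order" %in% names(si)) {
    stop("QC-based normalization requires an injection_order column",
         call. = FALSE)
  }
  qc <- si$class == "QC"
  if (sum(qc) < 4) {
    stop("QC-based normalization requires at least 4 QC samples",
         call. = FALSE)
  }
  ord <- si$injection_order
  if (!(min(ord[qc]) == min(ord) && max(ord[qc]) == max(ord))) {
    stop("the first and last injections should be QC samples",
         call. = FALSE)
  }
  expr <- ds@expression_data
  o_all <- ord / max(ord)
  o_qc <- o_all[qc]
  for (i in seq_len(nrow(expr))) {
    y <- log2(expr[i, qc])
    ok <- is.finite(y)
    if (sum(ok) < 4) next
    fit_log2 <- tryCatch({
      if (method == "loess_qc") {
        fit <- loess(y[ok] ~ o_qc[ok], span = span, degree = 1,
                     control = stats::loess.control(surface = "direct"))
        predict(fit, newdata = o_all)
      } else {
        fit <- svm(x = matrix(o_qc[ok]), y = y[ok], type = "eps-regression",
                   kernel = "radial", cost = svr_cost, epsilon = svr_epsilon,
                   scale = FALSE)
        as.numeric(predict(fit, matrix(o_all)))
      }
    }, error = function(e) NULL)
    if (is.null(fit_log2) || anyNA(fit_log2)) next
    fit_raw <- 2^fit_log2
    correction <- fit_raw / median(fit_raw[qc])
    correction <- pmin(pmax(correction, 0.1), 10)
    expr[i, ] <- expr[i, ] / correction
  }
  expr
}

register_operation("normalize_data", function(ds, params, resources) {
  normalize_data(ds, method = params$method, span = params$span %||% 0.75,
                 svr_cost = params$svr_cost %||% 1,
                 svr_epsilon = params$svr_epsilon %||% 0.1)
})

#' Integrate multiple acquisition batches
#'
#' For each variable and batch, intensities are rescaled by
#' `overall_statistic / batch_statistic`, where the statistic
#' (`qc_median`, `qc_mean`, `subject_median` or `subject_mean`) is
#' computed per (variable, batch) and "overall" pools all batches.  A
#' variable with an unusable (missing or non-positive) statistic in some
#' batch is left untouched and listed in the process record.
#'
#' @param ds a [MassDataset-class] with a `batch` column in
#'   `sample_info`.
#' @param factor correction-factor statistic.
#' @param record append a process record (default `TRUE`).
#' @return the integrated dataset.
#' @export
integrate_batches <- function(ds, factor = c("qc_median", "qc_mean",
                                             "subject_median", "subject_mean"),
                              record = TRUE) {
  factor <- match.arg(factor)
  stopifnot(is(ds, "MassDataset"))
  assert_scalar_flag(record, "record")
  si <- ds@sample_info
  if (!"batch" %in% names(si)) {
    stop("integrate_batches requires a batch column in sample_info",
         call. = FALSE)
  }
  use_qc <- startsWith(factor, "qc")
  stat_fun <- if (endsWith(factor, "median")) {
    function(v) median(v, na.rm = TRUE)
  } else {
    function(v) mean(v, na.rm = TRUE)
  }
  pool <- if (use_qc) si$class == "QC" else si$class != "QC"
  if (!any(pool)) {
    stop("no samples available for factor '", factor, "'", call. = FALSE)
  }
  batches <- unique(si$batch)
  expr <- ds@expression_data
  skipped <- character(0)
  if (length(batches) > 1) {
    overall <- apply(expr[, pool, drop = FALSE], 1, stat_fun)
    for (i in seq_len(nrow(expr))) {
      stats_b <- vapply(batches, function(b) {
        ids <- si$sample_id[pool & si$batch == b]
        if (length(ids) == 0) return(NA_real_)
        stat_fun(expr[i, ids])
      }, numeric(1))
      if (any(!is.finite(stats_b) | stats_b <= 0) ||
          !is.finite(overall[i]) || overall[i] <= 0) {
        skipped <- c(skipped, rownames(expr)[i])
        next
      }
      for (bi in seq_along(batches)) {
        cols <- si$batch == batches[bi]
        expr[i, cols] <- expr[i, cols] / stats_b[bi] * overall[i]
      }
    }
  }
  ds@expression_data <- expr
  if (record) {
    params <- list(factor = factor, n_batches = length(batches))
    if (length(skipped)) params$skipped_variables <- skipped
    ds <- append_record(ds, "integrate_batches", params)
  }
  validObject(ds)
  ds
}

register_operation("integrate_batches", function(ds, params, resources) {
  integrate_batches(ds, factor = params$factor %||% "qc_median")
})
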