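# Statistics: scaling, univariate tests, fold change,
# correlation/distance/network, PCA, PLS-DA.

#' Scale the expression matrix per variable
#'
#' Centering plus the metabolomics scaling family: unit variance
#' (`"uv"`, divide by the standard deviation), Pareto (`"pareto"`,
#' divide by the square root of the standard deviation — intermediate
#' between no scaling and UV), range (`"range"`, divide by max - min),
#' `"center"` (centering only) and `"none"`.
#'
#' @param ds a [MassDataset-class] without missing values (impute
#'   first).
#' @param method scaling method.
#' @param record append a process record (default `TRUE`).
#' @return the scaled dataset.
#' @export
scale_data <- function(ds, method = c("uv", "pareto", "range", "center",
                                      "none"),
                       record = TRUE) {
  method <- match.arg(method)
  stopifnot(is(ds, "MassDataset"))
  assert_scalar_flag(record, "record")
  expr <- ds@expression_data
  if (anyNA(expr)) {
    stop("scale_data requires a complete matrix; run impute() first",
         call. = FALSE)
  }
  if (method != "none") {
    m <- rowMeans(expr)
    div <- switch(method,
                  uv = apply(expr, 1, sd),
                  pareto = sqrt(apply(expr, 1, sd)),
                  range = apply(expr, 1, function(v) diff(range(v))),
                  center = rep(1, nrow(expr)))
    bad <- rownames(expr)[div == 0]
    if (length(bad)) {
      stop("zero spread, cannot scale: ",
           paste(head(bad, 10), collapse = ", "), call. = FALSE)
    }
    expr <- (expr - m) / div
  }
  ds@expression_data <- expr
  if (record) ds <- append_record(ds, "scale_data", list(method = method))
  validObject(ds)
  ds
}

register_operation("scale_data", function(ds, params, resources) {
  scale_data(ds, method = params$method)
})

#' Per-variable fold change between two groups
#'
#' Ratio of observed-value means on the unlogged scale, case over
#' control, with `log2_fc` alongside.  Missing values are excluded
#' per variable; a zero control mean yields `NA` with a warning listing
#' the variables.
#'
#' @param ds a [MassDataset-class].
#' @param group_field `sample_info` column holding the group labels.
#' @param case,control the two labels to compare.
#' @return data frame with `variable_id`, `fold_change`, `log2_fc`.
#' @export
fold_change <- function(ds, group_field = "group", case = "Case",
                        control = "Control") {
  stopifnot(is(ds, "MassDataset"))
  g <- ds@sample_info[[group_field]]
  if (is.null(g)) {
    stop("group_field '", group_field, "' not found in sample_info",
         call. = FALSE)
  }
  if (!all(c(case, control) %in% g)) {
    stop("group labels not found: ",
         paste(setdiff(c(case, control), g), collapse = ", "), call. = FALSE)
  }
  expr <- ds@expression_data
  case_mean <- rowMeans(expr[, g == case, drop = FALSE], na.rm = TRUE)
  ctrl_mean <- rowMeans(expr[, g == control, drop = FALSE], na.rm = TRUE)
  fc <- case_mean / ctrl_mean
  undefined <- !is.finite(fc)
  if (any(undefined)) {
    fc[undefined] <- NA_real_
    warning("fold change undefined (zero/empty control mean) for: ",
            paste(head(rownames(expr)[undefined], 10), collapse = ", "),
            call. = FALSE)
  }
  data.frame(variable_id = rownames(expr), fold_change = unname(fc),
             log2_fc = unname(log2(fc)), stringsAsFactors = FALSE)
}

#' Univariate differential tests per variable
#'
#' Welch's t-test (the unequal-variance default of the standard
#' reference implementation) or Wilcoxon test between two groups, with
#' multiple-testing correction across variables.  Fold change, log2 fold
#' change, test statistic, raw and adjusted p values are written into
#' `variable_info`.  Variables with fewer than 2 observed values in
#' either group get `NA` p values and are excluded from the adjustment.
#'
#' @param ds a [MassDataset-class].
#' @param group_field `sample_info` column with group labels.
#' @param case,control labels to compare (case vs control).
#' @param method `"t"` (Welch) or `"wilcoxon"` (rank-sum; signed-rank
#'   when `paired`).
#' @param paired paired test; requires `pair_field`.
#' @param pair_field `sample_info` column identifying pairs.
#' @param adjust correction method for [stats::p.adjust()]
#'   (default `"BH"`).
#' @param record append a process record (default `TRUE`).
#' @return the dataset with `fold_change`, `log2_fc`, `statistic`,
#'   `p_value`, `p_value_adjust` columns in `variable_info`.
#' @export
univariate_test <- function(ds, group_field = "group", case = "Case",
                            control = "Control",
                            method = c("t", "wilcoxon"), paired = FALSE,
                            pair_field = NULL, adjust = "BH",
                            record = TRUE) {
  method <- match.arg(method)
  stopifnot(is(ds, "MassDataset"))
  assert_scalar_flag(paired, "paired")
  assert_scalar_flag(record, "record")
  g <- ds@sample_info[[group_field]]
  if (is.null(g) || !all(c(case, control) %in% g)) {
    stop("unknown group labels in '", group_field, "': need ", case,
         " and ", control, call. = FALSE)
  }
  expr <- ds@expression_data
  case_cols <- which(g == case)
  ctrl_cols <- which(g == control)
  if (paired) {
    if (is.null(pair_field) || !pair_field %in% names(ds@sample_info)) {
      stop("paired tests need a pair_field present in sample_info",
           call. = FALSE)
    }
    pairing <- ds@sample_info[[pair_field]]
    shared <- intersect(pairing[case_cols], pairing[ctrl_cols])
    case_cols <- case_cols[match(shared, pairing[case_cols])]
    ctrl_cols <- ctrl_cols[match(shared, pairing[ctrl_cols])]
  }

  n_var <- nrow(expr)
  stat <- p <- rep(NA_real_, n_var)
  for (i in seq_len(n_var)) {
    x <- expr[i, case_cols]
    y <- expr[i, ctrl_cols]
    if (paired) {
      keep <- !is.na(x) & !is.na(y)
      x <- x[keep]; y <- y[keep]
    } else {
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
    }
    if (length(x) < 2 || length(y) < 2) next
    res <- tryCatch(
      if (method == "t") {
        t.test(x, y, paired = paired, var.equal = FALSE)
      } else {
        suppressWarnings(wilcox.test(x, y, paired = paired, exact = FALSE))
      }, error = function(e) NULL)
    if (!is.null(res)) {
      stat[i] <- unname(res$statistic)
      p[i] <- res$p.value
    }
  }
  adj <- rep(NA_real_, n_var)
  defined <- !is.na(p)
  adj[defined] <- p.adjust(p[defined], method = adjust)

  fc <- suppressWarnings(fold_change(ds, group_field, case, control))
  ds@variable_info$fold_change <- fc$fold_change
  ds@variable_info$log2_fc <- fc$log2_fc
  ds@variable_info$statistic <- stat
  ds@variable_info$p_value <- p
  ds@variable_info$p_value_adjust <- adj
  for (col in c("fold_change", "log2_fc", "statistic", "p_value",
                "p_value_adjust")) {
    ds@variable_info_note <- update_note(
      ds@variable_info_note, col,
      sprintf("%s (%s vs %s, %s test, %s adjusted)", col, case, control,
              method, adjust))
  }
  if (record) {
    ds <- append_record(ds, "univariate_test",
                        list(group_field = group_field, case = case,
                             control = control, method = method,
                             paired = paired, adjust = adjust))
  }
  validObject(ds)
  ds
}

register_operation("univariate_test", function(ds, params, resources) {
  univariate_test(ds, group_field = params$group_field %||% "group",
                  case = params$case %||% "Case",
                  control = params$control %||% "Control",
                  method = params$method %||% "t",
                  paired = params$paired %||% FALSE,
                  pair_field = params$pair_field,
                  adjust = params$adjust %||% "BH")
})

#' Correlation matrix over samples or variables
#'
#' @param ds a [MassDataset-class].
#' @param margin `"variable"` (correlate variables) or `"sample"`.
#' @param method `"pearson"` or `"spearman"`.
#' @return correlation matrix (pairwise-complete observations).
#' @export
cor_matrix <- function(ds, margin = c("variable", "sample"),
                       method = c("pearson", "spearman")) {
  margin <- match.arg(margin)
  method <- match.arg(method)
  stopifnot(is(ds, "MassDataset"))
  x <- if (margin == "variable") t(ds@expression_data) else ds@expression_data
  cor(x, use = "pairwise.complete.obs", method = method)
}

#' Distance matrix over samples or variables
#'
#' @param ds a [MassDataset-class].
#' @param margin `"variable"` or `"sample"`.
#' @param metric `"euclidean"` or `"manhattan"`.
#' @return symmetric distance matrix.
#' @export
dist_matrix <- function(ds, margin = c("variable", "sample"),
                        metric = c("euclidean", "manhattan")) {
  margin <- match.arg(margin)
  metric <- match.arg(metric)
  stopifnot(is(ds, "MassDataset"))
  x <- if (margin == "variable") ds@expression_data else t(ds@expression_data)
  as.matrix(dist(x, method = metric))
}

#' Correlation test p values for a correlation matrix
#'
#' Two-sided p values from the t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom.
#'
#' @param cor_mat correlation matrix.
#' @param n number of observations the correlations were computed from.
#' @return matrix of p values (diagonal `NA`).
#' @export
cor_pvalues <- function(cor_mat, n) {
  stopifnot(is.matrix(cor_mat), is_scalar_number(n), n > 2)
  r <- pmin(pmax(cor_mat, -1 + 1e-15), 1 - 1e-15)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(abs(tt), df = n - 2, lower.tail = FALSE)
  diag(p) <- NA_real_
  p
}

#' Correlation network edge list
#'
#' Undirected edges between items whose absolute correlation reaches
#' `r_cutoff` and whose adjusted p value is at most `p_cutoff`;
#' no self loops.  Adjustment is over the upper-triangle tests.
#'
#' @param cor_mat correlation matrix.
#' @param p_mat matrix of raw p values (same layout; see
#'   [cor_pvalues()]).
#' @param r_cutoff minimal `|r|`.
#' @param p_cutoff maximal adjusted p.
#' @param adjust correction method for [stats::p.adjust()].
#' @return list with `nodes` (id data frame) and `edges`
#'   (`from`, `to`, `r`, `p_value`, `p_value_adjust`).
#' @export
correlation_network <- function(cor_mat, p_mat, r_cutoff = 0.8,
                                p_cutoff = 0.05, adjust = "BH") {
  stopifnot(is.matrix(cor_mat), identical(dim(cor_mat), dim(p_mat)))
  ids <- rownames(cor_mat) %||% as.character(seq_len(nrow(cor_mat)))
  ut <- upper.tri(cor_mat)
  idx <- which(ut, arr.ind = TRUE)
  p_raw <- p_mat[ut]
  p_adj <- p.adjust(p_raw, method = adjust)
  r <- cor_mat[ut]
  keep <- !is.na(r) & abs(r) >= r_cutoff & !is.na(p_adj) & p_adj <= p_cutoff
  edges <- data.frame(from = ids[idx[keep, 1]], to = ids[idx[keep, 2]],
                      r = r[keep], p_value = p_raw[keep],
                      p_value_adjust = p_adj[keep],
                      stringsAsFactors = FALSE)
  list(nodes = data.frame(id = ids, stringsAsFactors = FALSE),
       edges = norm_df(edges))
}

# Shared PCA core: x has observations in rows.  Deterministic sign
# convention: within each component the loading of largest magnitude is
# made positive.
pca_matrix <- function(x, scale = c("uv", "pareto", "center", "none")) {
  scale <- match.arg(scale)
  if (scale != "none") {
    x <- sweep(x, 2, colMeans(x))
    if (scale == "uv") {
      s <- apply(x, 2, sd)
      s[s == 0] <- 1
      x <- sweep(x, 2, s, "/")
    } else if (scale == "pareto") {
      s <- sqrt(apply(x, 2, sd))
      s[s == 0] <- 1
      x <- sweep(x, 2, s, "/")
    }
  }
  fit <- prcomp(x, center = FALSE, scale. = FALSE)
  for (k in seq_len(ncol(fit$rotation))) {
    j <- which.max(abs(fit$rotation[, k]))
    if (fit$rotation[j, k] < 0) {
      fit$rotation[, k] <- -fit$rotation[, k]
      fit$x[, k] <- -fit$x[, k]
    }
  }
  var_frac <- fit$sdev^2 / sum(fit$sdev^2)
  list(scores = fit$x, loadings = fit$rotation,
       variance_fraction = var_frac, scaled_matrix = x)
}

#' Principal component analysis of the samples
#'
#' Samples are observations, variables are features; scaling per
#' [scale_data()] conventions is applied to the variables first.  The
#' sign of each component is fixed deterministically (largest-magnitude
#' loading positive), variance fractions sum to 1, and at full rank
#' `scores %*% t(loadings)` reconstructs the scaled matrix.
#'
#' @param ds a [MassDataset-class] without missing values, or a numeric
#'   matrix with observations in rows.
#' @param scale variable scaling: `"uv"`, `"pareto"`, `"center"`,
#'   `"none"`.
#' @return list with `scores`, `loadings`, `variance_fraction`,
#'   `scaled_matrix`.
#' @export
run_pca <- function(ds, scale = "uv") {
  x <- if (is(ds, "MassDataset")) {
    if (anyNA(ds@expression_data)) {
      stop("PCA requires a complete matrix; run impute() first",
           call. = FALSE)
    }
    t(ds@expression_data)
  } else as.matrix(ds)
  pca_matrix(x, scale = scale)
}

#' Partial least squares discriminant analysis
#'
#' NIPALS PLS2 on the unit-variance-scaled matrix against the centered
#' one-hot group response, with variable importance in projection (VIP)
#' scores.  By construction the mean of the squared VIPs equals 1, so
#' VIP > 1 marks variables contributing more than average to the group
#' separation.
#'
#' @param ds a [MassDataset-class] without missing values, or a matrix
#'   with observations in rows (then `groups` must be given).
#' @param group_field `sample_info` column with class labels (at least
#'   two classes).
#' @param n_components number of latent components (default 2).
#' @param groups explicit label vector when `ds` is a matrix.
#' @return list with `scores`, `loadings`, `weights`, `vip`,
#'   `explained_y_variance`, `groups`.
#' @export
run_plsda <- function(ds, group_field = "group", n_components = 2,
                      groups = NULL) {
  if (is(ds, "MassDataset")) {
    if (anyNA(ds@expression_data)) {
      stop("PLS-DA requires a complete matrix; run impute() first",
           call. = FALSE)
    }
    x <- t(ds@expression_data)
    groups <- ds@sample_info[[group_field]]
  } else {
    x <- as.matrix(ds)
    if (is.null(groups)) stop("`groups` required for matrix input",
                              call. = FALSE)
  }
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  if (length(lv) < 2) stop("PLS-DA needs at least two classes", call. = FALSE)
  # unit-variance X, centered one-hot Y
  x <- sweep(x, 2, colMeans(x))
  sx <- apply(x, 2, sd)
  sx[sx == 0] <- 1
  x <- sweep(x, 2, sx, "/")
  y <- vapply(lv, function(l) as.numeric(groups == l),
              numeric(length(groups)))
  y <- sweep(y, 2, colMeans(y))

  n_comp <- min(n_components, ncol(x), nrow(x) - 1)
  p <- ncol(x)
  W <- matrix(0, p, n_comp)
  P <- matrix(0, p, n_comp)
  Tm <- matrix(0, nrow(x), n_comp)
  ssy <- numeric(n_comp)
  ssy_total <- sum(y^2)
  Xa <- x; Ya <- y
  for (a in seq_len(n_comp)) {
    u <- Ya[, which.max(colSums(Ya^2))]
    for (it in 1:500) {
      w <- crossprod(Xa, u)
      w <- w / sqrt(sum(w^2))
      t_score <- Xa %*% w
      q <- crossprod(Ya, t_score) / sum(t_score^2)
      u_new <- Ya %*% q / sum(q^2)
      if (sqrt(sum((u_new - u)^2)) < 1e-10 * sqrt(sum(u^2))) {
        u <- u_new
        break
      }
      u <- u_new
    }
    p_load <- crossprod(Xa, t_score) / sum(t_score^2)
    W[, a] <- w
    P[, a] <- p_load
    Tm[, a] <- t_score
    b <- crossprod(Ya, t_score) / sum(t_score^2)
    ssy[a] <- sum((t_score %*% t(b))^2)
    Xa <- Xa - t_score %*% t(p_load)
    Ya <- Ya - t_score %*% t(b)
  }
  vip <- sqrt(p * as.vector(W^2 %*% ssy) / sum(ssy))
  names(vip) <- colnames(x)
  rownames(W) <- rownames(P) <- colnames(x)
  list(scores = Tm, loadings = P, weights = W, vip = vip,
       explained_y_variance = ssy / ssy_total, groups = groups)
}
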