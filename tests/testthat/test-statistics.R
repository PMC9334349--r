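scaled_values <- function(values, method) {
  expr <- rbind(v1 = values, v2 = values + 1)
  colnames(expr) <- paste0("s", 1:3)
  si <- data.frame(sample_id = paste0("s", 1:3), class = "Subject",
                   stringsAsFactors = FALSE)
  vi <- data.frame(variable_id = c("v1", "v2"), mz = 1:2, rt = 1:2,
                   stringsAsFactors = FALSE)
  ds <- create_mass_dataset(expr, si, vi)
  unname(extract_expression_data(scale_data(ds, method))[1, ])
}

test_that("scaling matches the arithmetic oracles", {
  expect_equal(scaled_values(c(0, 2, 4), "uv"), c(-1, 0, 1))
  expect_equal(scaled_values(c(0, 2, 4), "pareto"),
               c(-2, 0, 2) / sqrt(2), tolerance = 1e-6)
  expect_equal(scaled_values(c(0, 2, 4), "range"), c(-0.5, 0, 0.5))
  expect_equal(scaled_values(c(0, 2, 4), "center"), c(-2, 0, 2))

  ds <- tiny_dataset()
  expect_error(scale_data(impute(ds, "zero"), "uv"), NA)
  flat <- create_mass_dataset(
    matrix(5, 2, 3, dimnames = list(c("a", "b"), c("s1", "s2", "s3"))),
    data.frame(sample_id = c("s1", "s2", "s3")),
    data.frame(variable_id = c("a", "b"), mz = 1:2, rt = 1:2))
  expect_error(scale_data(flat, "uv"), "zero spread.*a")
})

test_that("univariate tests agree with the reference oracles", {
  expr <- rbind(same = c(1, 2, 3, 1, 2, 3),
                shift = c(1, 2, 3, 4, 3, 4))
  expr <- rbind(expr, welch = c(1, 2, 3, 4, 3, 4))
  # build a 4-vs-4 layout for the Welch oracle case
  expr2 <- rbind(welch = c(1, 2, 3, 4, 3, 4, 5, 6),
                 same = c(1, 2, 3, 1, 2, 3, 2, 3))
  colnames(expr2) <- paste0("s", 1:8)
  si <- data.frame(sample_id = paste0("s", 1:8), class = "Subject",
                   group = rep(c("Case", "Control"), each = 4),
                   stringsAsFactors = FALSE)
  vi <- data.frame(variable_id = rownames(expr2), mz = 1:2, rt = 1:2,
                   stringsAsFactors = FALSE)
  ds <- create_mass_dataset(expr2, si, vi)
  out <- extract_variable_info(univariate_test(ds))
  # Welch t for [1,2,3,4] vs [3,4,5,6]
  expect_equal(out$statistic[out$variable_id == "welch"], -2.19089023,
               tolerance = 1e-6)
  expect_equal(out$statistic[out$variable_id == "welch"],
               unname(t.test(c(1, 2, 3, 4), c(3, 4, 5, 6))$statistic))

  # identical groups: t = 0, p = 1
  expr3 <- rbind(null = c(1, 2, 3, 1, 2, 3))
  colnames(expr3) <- paste0("s", 1:6)
  si3 <- data.frame(sample_id = paste0("s", 1:6), class = "Subject",
                    group = rep(c("Case", "Control"), each = 3),
                    stringsAsFactors = FALSE)
  vi3 <- data.frame(variable_id = "null", mz = 1, rt = 1,
                    stringsAsFactors = FALSE)
  out3 <- extract_variable_info(
    univariate_test(create_mass_dataset(expr3, si3, vi3)))
  expect_equal(out3$statistic, 0)
  expect_equal(out3$p_value, 1)
  expect_equal(out3$fold_change, 1)

  expect_error(univariate_test(ds, case = "Tumor"), "Tumor")
})

test_that("BH adjustment follows the step-up procedure", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  # and the dataset-level adjustment matches p.adjust on defined p values
  sim <- small_sim(81, n_subject = 12, mv_rate = 0)
  out <- extract_variable_info(univariate_test(sim$dataset))
  defined <- !is.na(out$p_value)
  expect_equal(out$p_value_adjust[defined],
               p.adjust(out$p_value[defined], "BH"))
  expect_true(all(out$p_value_adjust >= out$p_value, na.rm = TRUE))
})

test_that("fold change is the ratio of observed-value means", {
  sim <- small_sim(82, mv_rate = 0.1)
  fc <- suppressWarnings(fold_change(sim$dataset))
  expr <- extract_expression_data(sim$dataset)
  si <- extract_sample_info(sim$dataset)
  i <- 5
  oracle <- mean(expr[i, si$group == "Case"], na.rm = TRUE) /
    mean(expr[i, si$group == "Control"], na.rm = TRUE)
  expect_equal(fc$fold_change[i], oracle)
  expect_equal(fc$log2_fc[i], log2(oracle))
})

test_that("correlation and distance matrices match closed forms", {
  sim <- small_sim(83, mv_rate = 0)
  ds <- sim$dataset
  cm <- cor_matrix(ds, margin = "variable")
  expect_equal(unname(diag(cm)), rep(1, nrow(cm)))
  expr <- extract_expression_data(ds)
  expect_equal(cm[2, 5], cor(expr[2, ], expr[5, ]))

  dm <- dist_matrix(ds, margin = "sample", metric = "euclidean")
  expect_equal(unname(diag(dm)), rep(0, ncol(expr)))
  expect_equal(dm[1, 3], sqrt(sum((expr[, 1] - expr[, 3])^2)))
  expect_true(isSymmetric(dm))

  toy <- matrix(c(0, 0, 3, 4), nrow = 2,
                dimnames = list(c("v1", "v2"), c("a", "b")))
  tds <- create_mass_dataset(
    toy, data.frame(sample_id = c("a", "b")),
    data.frame(variable_id = c("v1", "v2"), mz = 1:2, rt = 1:2))
  expect_equal(dist_matrix(tds, "sample")["a", "b"], 5)
})

test_that("correlation networks have no self loops and match brute force", {
  set.seed(84)
  n <- 20
  block <- matrix(rnorm(n), n, 5) + matrix(rnorm(n * 5, 0, 0.1), n, 5)
  noise <- matrix(rnorm(n * 5), n, 5)
  x <- cbind(block, noise)
  colnames(x) <- paste0("v", 1:10)
  cm <- cor(x)
  pm <- cor_pvalues(cm, n)
  net <- correlation_network(cm, pm, r_cutoff = 0.8, p_cutoff = 0.05)
  expect_false(any(net$edges$from == net$edges$to))

  # brute-force double loop
  p_adj_mat <- matrix(NA_real_, 10, 10)
  ut <- upper.tri(cm)
  p_adj_mat[ut] <- p.adjust(pm[ut], "BH")
  count <- 0L
  for (i in 1:9) for (j in (i + 1):10) {
    if (abs(cm[i, j]) >= 0.8 && p_adj_mat[i, j] <= 0.05) count <- count + 1L
  }
  expect_identical(nrow(net$edges), count)

  empty <- correlation_network(cm, pm, r_cutoff = 1.01)
  expect_identical(nrow(empty$edges), 0L)
})

test_that("PCA is deterministic, complete, and reconstructs the data", {
  sim <- small_sim(85, mv_rate = 0)
  fit <- run_pca(sim$dataset, scale = "uv")
  expect_equal(sum(fit$variance_fraction), 1)
  recon <- fit$scores %*% t(fit$loadings)
  expect_equal(recon, fit$scaled_matrix, tolerance = 1e-8,
               ignore_attr = TRUE)
  fit2 <- run_pca(sim$dataset, scale = "uv")
  expect_identical(fit$scores, fit2$scores)

  # rank-1 data: first component carries all the variance
  s <- outer(1:6, c(1, 2, 3, 4))
  rownames(s) <- paste0("o", 1:6)
  colnames(s) <- paste0("v", 1:4)
  fit3 <- pca_scores_matrix <- run_pca(s, scale = "center")
  expect_equal(fit3$variance_fraction[1], 1)
  # eigen oracle for the first component
  xc <- sweep(s, 2, colMeans(s))
  ev <- eigen(cov(xc))$values
  expect_equal(fit3$variance_fraction,
               ev / sum(ev), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("PLS-DA VIPs satisfy their defining identity", {
  sim <- small_sim(86, n_subject = 16, mv_rate = 0)
  ds <- filter_samples(sim$dataset, function(s) s$class != "QC")
  fit <- run_plsda(ds, n_components = 2)
  expect_equal(mean(fit$vip^2), 1, tolerance = 1e-9)
  expect_error(run_plsda(filter_samples(ds, function(s) s$group == "Case")),
               "two classes")

  # a single perfectly separating variable attains the maximum VIP
  set.seed(86)
  n <- 20
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("v", 1:6)))
  grp <- rep(c("A", "B"), each = n / 2)
  x[, 1] <- ifelse(grp == "A", 3, -3) + rnorm(n, 0, 0.05)
  fit2 <- run_plsda(x, groups = grp, n_components = 2)
  expect_identical(names(which.max(fit2$vip)), "v1")
  expect_gt(max(fit2$vip), 1)
})

test_that("t and wilcoxon p values rank features consistently", {
  sim <- generate_dataset(n_subject = 24, n_qc = 4, n_variable = 60,
                          de_fraction = 0.3, effect_log2 = 1.5, mv_rate = 0,
                          seed = 87)
  ds <- log_transform(sim$dataset)
  pt_ <- extract_variable_info(univariate_test(ds, method = "t"))$p_value
  pw <- extract_variable_info(
    univariate_test(ds, method = "wilcoxon"))$p_value
  keep <- !is.na(pt_) & !is.na(pw)
  expect_gte(cor(-log10(pt_[keep]), -log10(pw[keep]), method = "spearman"),
             0.8)
})

test_that("BH at 5% recovers most planted differential metabolites", {
  sim <- generate_dataset(n_subject = 40, n_qc = 4, n_variable = 200,
                          de_fraction = 0.1, effect_log2 = 1, mv_rate = 0,
                          seed = 88)
  ds <- log_transform(sim$dataset)
  vi <- extract_variable_info(univariate_test(ds))
  called <- vi$variable_id[!is.na(vi$p_value_adjust) &
                             vi$p_value_adjust < 0.05]
  recovery <- mean(sim$truth$de_variable_ids %in% called)
  expect_gte(recovery, 0.8)
})

test_that("the NIPALS PLS-DA agrees with an independent implementation", {
  set.seed(89)
  n <- 24
  x <- matrix(rnorm(n * 12), n, 12,
              dimnames = list(NULL, paste0("v", 1:12)))
  grp <- rep(c("A", "B"), each = n / 2)
  x[, 1:3] <- x[, 1:3] + ifelse(grp == "A", 1.5, -1.5)
  ours <- run_plsda(x, groups = grp, n_components = 2)
  ref <- suppressMessages(mixOmics::plsda(x, factor(grp), ncomp = 2,
                                          scale = TRUE))
  # latent scores span the same directions (sign is arbitrary)
  expect_gt(abs(cor(ours$scores[, 1], ref$variates$X[, 1])), 0.99)
  # both implementations rank the separating variables on top
  ref_vip <- mixOmics::vip(ref)[, 2]
  expect_identical(sort(names(sort(ours$vip, decreasing = TRUE)[1:3])),
                   sort(names(sort(ref_vip, decreasing = TRUE)[1:3])))
})
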