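test_that("noisy-feature flags follow the QC-or-every-group rule", {
  # 5 QC + 4 Case + 4 Control, hand-set missingness
  expr <- matrix(1000, nrow = 4, ncol = 13,
                 dimnames = list(paste0("v", 1:4), paste0("s", 1:13)))
  si <- data.frame(sample_id = paste0("s", 1:13),
                   class = c(rep("QC", 5), rep("Subject", 8)),
                   group = c(rep("QC", 5), rep("A", 4), rep("B", 4)),
                   stringsAsFactors = FALSE)
  vi <- data.frame(variable_id = paste0("v", 1:4), mz = 1:4, rt = 1:4,
                   stringsAsFactors = FALSE)
  expr[2, 1:2] <- NA          # QC freq 0.4 > 0.2 -> flagged
  expr[3, 6:8] <- NA          # A freq 0.75, B freq 0 -> not flagged
  expr[4, 6:12] <- NA         # A freq 1.0, B freq 0.75 -> flagged
  ds <- create_mass_dataset(expr, si, vi)

  out <- flag_noisy_variables(ds)
  expect_identical(extract_variable_info(out)$is_noise,
                   c(FALSE, TRUE, FALSE, TRUE))

  # any-group switch flags v3 too
  out2 <- flag_noisy_variables(ds, any_group = TRUE)
  expect_identical(extract_variable_info(out2)$is_noise,
                   c(FALSE, TRUE, TRUE, TRUE))

  # without QC samples the QC criterion is skipped with a warning
  ds_noqc <- filter_samples(ds, function(s) s$class != "QC")
  expect_warning(out3 <- flag_noisy_variables(ds_noqc), "no QC")
  expect_identical(extract_variable_info(out3)$is_noise,
                   c(FALSE, FALSE, FALSE, TRUE))
})

test_that("noisy-feature flags agree with a brute-force counter", {
  for (seed in 1:25) {
    sim <- small_sim(seed, n_subject = 10, n_qc = 4, n_variable = 15,
                     mv_rate = 0.3)
    ds <- sim$dataset
    out <- flag_noisy_variables(ds)
    expr <- extract_expression_data(ds)
    si <- extract_sample_info(ds)
    oracle <- logical(nrow(expr))
    for (i in seq_len(nrow(expr))) {
      qc_ids <- si$sample_id[si$class == "QC"]
      qc_bad <- mean(is.na(expr[i, qc_ids])) > 0.20
      grp_bad <- TRUE
      for (g in unique(si$group[si$class != "QC"])) {
        ids <- si$sample_id[si$class != "QC" & si$group == g]
        if (mean(is.na(expr[i, ids])) <= 0.50) grp_bad <- FALSE
      }
      oracle[i] <- qc_bad || grp_bad
    }
    expect_identical(extract_variable_info(out)$is_noise, oracle)
  }
})

test_that("constant imputation methods fill exactly as specified", {
  sim <- small_sim(41, mv_rate = 0.2)
  ds <- sim$dataset
  expr <- extract_expression_data(ds)
  na_idx <- which(is.na(expr))

  z <- extract_expression_data(impute(ds, "zero"))
  expect_true(all(z[na_idx] == 0))
  expect_identical(z[-na_idx], expr[-na_idx])

  m <- extract_expression_data(impute(ds, "mean"))
  i <- arrayInd(na_idx[1], dim(expr))[1]
  expect_equal(m[na_idx[1]], mean(expr[i, ], na.rm = TRUE))

  mn <- extract_expression_data(impute(ds, "minimum"))
  expect_equal(mn[na_idx[1]], min(expr[i, ], na.rm = TRUE))

  # idempotence
  once <- impute(ds, "knn", k = 5)
  twice <- impute(once, "knn", k = 5)
  expect_identical(extract_expression_data(once),
                   extract_expression_data(twice))
})

test_that("knn uses a perfect correlate when one exists", {
  expr <- matrix(rlnorm(4 * 8, 10, 0.3), nrow = 4,
                 dimnames = list(paste0("v", 1:4), paste0("s", 1:8)))
  expr[2, ] <- expr[1, ]      # v2 duplicates v1
  expr[1, 3] <- NA
  si <- data.frame(sample_id = paste0("s", 1:8), class = "Subject",
                   group = "Case", stringsAsFactors = FALSE)
  vi <- data.frame(variable_id = paste0("v", 1:4), mz = 1:4, rt = 1:4,
                   stringsAsFactors = FALSE)
  ds <- create_mass_dataset(expr, si, vi)
  out <- extract_expression_data(impute(ds, "knn", k = 1))
  expect_equal(out[1, 3], expr[2, 3])
})

test_that("knn beats mean imputation on correlated data", {
  set.seed(42)
  # correlated block design: groups of variables share a latent profile
  n_var <- 40; n_sample <- 24
  latent <- matrix(rnorm(8 * n_sample, 15, 2), nrow = 8)
  expr <- 2^(latent[rep(1:8, each = 5), ] +
               matrix(rnorm(n_var * n_sample, 0, 0.2), nrow = n_var))
  dimnames(expr) <- list(sprintf("v%02d", 1:n_var),
                         sprintf("s%02d", 1:n_sample))
  mask <- matrix(runif(n_var * n_sample) < 0.1, n_var, n_sample)
  masked <- expr
  masked[mask] <- NA
  si <- data.frame(sample_id = colnames(expr), class = "Subject",
                   group = "Case", stringsAsFactors = FALSE)
  vi <- data.frame(variable_id = rownames(expr), mz = 1:n_var, rt = 1:n_var,
                   stringsAsFactors = FALSE)
  ds <- create_mass_dataset(masked, si, vi)

  rmse <- function(imp) sqrt(mean(((imp[mask] - expr[mask]) / expr[mask])^2))
  rmse_knn <- rmse(extract_expression_data(impute(ds, "knn", k = 5)))
  rmse_mean <- rmse(extract_expression_data(impute(ds, "mean")))
  expect_lt(rmse_knn, rmse_mean)

  # svd completion also recovers structure better than the mean
  rmse_svd <- rmse(extract_expression_data(impute(ds, "svd", rank = 8)))
  expect_lt(rmse_svd, rmse_mean)
})

test_that("impute refuses all-missing variables", {
  sim <- small_sim(43, mv_rate = 0)
  expr <- extract_expression_data(sim$dataset)
  expr[1, ] <- NA
  ds <- create_mass_dataset(expr, extract_sample_info(sim$dataset),
                            extract_variable_info(sim$dataset))
  expect_error(impute(ds, "mean"), "flag_noisy_variables")
})

test_that("sample-wise normalization fixes planted dilution exactly", {
  sim <- small_sim(44, mv_rate = 0)
  ds <- sim$dataset
  expr <- extract_expression_data(ds)
  si <- extract_sample_info(ds)
  qc_ids <- si$sample_id[si$class == "QC"]
  ref <- apply(expr[, qc_ids], 1, median)
  # make one sample exactly 2x the PQN reference
  expr[, "S_001"] <- 2 * ref
  ds <- create_mass_dataset(expr, si, extract_variable_info(ds))
  out <- extract_expression_data(normalize_data(ds, "pqn"))
  expect_equal(unname(out[, "S_001"]), unname(ref), tolerance = 1e-12)

  # total normalization equalizes per-sample sums
  tot <- extract_expression_data(normalize_data(ds, "total"))
  sums <- colSums(tot)
  expect_lt(diff(range(sums)) / mean(sums), 1e-12)

  # normalization preserves the missingness pattern and non-negativity
  ds_na <- small_sim(44, mv_rate = 0.2)$dataset
  out_na <- extract_expression_data(normalize_data(ds_na, "median"))
  expect_identical(is.na(out_na),
                   is.na(extract_expression_data(ds_na)))
  expect_true(all(out_na >= 0, na.rm = TRUE))
})

test_that("LOESS leaves drift-free QC data essentially unchanged", {
  sim <- generate_dataset(n_subject = 16, n_qc = 6, n_variable = 12,
                          drift = "none", mv_rate = 0, seed = 45)
  ds <- sim$dataset
  # constant QC intensities -> correction identically 1
  expr <- extract_expression_data(ds)
  si <- extract_sample_info(ds)
  qc_ids <- si$sample_id[si$class == "QC"]
  expr[, qc_ids] <- rowMeans(expr[, qc_ids])
  ds2 <- create_mass_dataset(expr, si, extract_variable_info(ds))
  out <- extract_expression_data(normalize_data(ds2, "loess_qc"))
  expect_equal(out, extract_expression_data(ds2), tolerance = 1e-9)
})

test_that("QC drift correction repairs a linear 3x decay", {
  sim <- generate_dataset(n_subject = 40, n_qc = 10, n_variable = 40,
                          drift = "linear", mv_rate = 0, seed = 46)
  ds <- sim$dataset
  rsd_before <- median(qc_rsd(ds), na.rm = TRUE)
  for (method in c("loess_qc", "svr_qc")) {
    fixed <- normalize_data(ds, method)
    rsd_after <- median(qc_rsd(fixed), na.rm = TRUE)
    expect_lt(rsd_after, rsd_before)
    expect_lt(rsd_after, 15)
  }
})

test_that("QC-based normalization enforces its preconditions", {
  sim <- generate_dataset(n_subject = 10, n_qc = 5, n_variable = 8,
                          mv_rate = 0, seed = 47)
  ds <- sim$dataset
  few_qc <- filter_samples(ds, function(s)
    s$class != "QC" | s$sample_id %in% c("QC_01", "QC_05"))
  expect_error(normalize_data(few_qc, "loess_qc"), "at least 4 QC")

  si <- extract_sample_info(ds)
  qc <- si[si$class == "QC", ]
  last_qc <- qc$sample_id[which.max(qc$injection_order)]
  nonbracket <- filter_samples(ds, function(s) s$sample_id != last_qc)
  expect_error(normalize_data(nonbracket, "loess_qc"),
               "first and last injections should be QC")
})

test_that("batch integration removes an exact 2x batch shift", {
  sim <- generate_dataset(n_subject = 20, n_qc = 8, n_batch = 2,
                          n_variable = 15, mv_rate = 0, seed = 48)
  ds <- sim$dataset
  si <- extract_sample_info(ds)
  expr <- extract_expression_data(ds)
  expr[, si$batch == 2] <- 2 * expr[, si$batch == 2]
  ds <- create_mass_dataset(expr, si, extract_variable_info(ds))

  out <- extract_expression_data(integrate_batches(ds, "qc_median"))
  for (i in seq_len(nrow(out))) {
    med1 <- median(out[i, si$class == "QC" & si$batch == 1])
    med2 <- median(out[i, si$class == "QC" & si$batch == 2])
    expect_lt(abs(med1 - med2) / med1, 1e-9)
  }

  # single batch: identity transform
  one <- small_sim(48, mv_rate = 0)$dataset
  expect_identical(
    extract_expression_data(integrate_batches(one, "qc_median")),
    extract_expression_data(one))
})

test_that("batch integration shrinks simulated between-batch variance", {
  sim <- generate_dataset(n_subject = 30, n_qc = 10, n_batch = 2,
                          n_variable = 30, batch_shift_sd = 0.5,
                          mv_rate = 0, seed = 49)
  ds <- sim$dataset
  si <- extract_sample_info(ds)
  between_batch_var <- function(expr) {
    v <- vapply(seq_len(nrow(expr)), function(i) {
      means <- vapply(unique(si$batch), function(b) {
        mean(log2(expr[i, si$class == "QC" & si$batch == b]))
      }, numeric(1))
      var(means)
    }, numeric(1))
    mean(v)
  }
  before <- between_batch_var(extract_expression_data(ds))
  after <- between_batch_var(
    extract_expression_data(integrate_batches(ds, "qc_mean")))
  expect_gt(before / after, 5)
})

test_that("every cleaning operation appends exactly one process record", {
  sim <- small_sim(50, mv_rate = 0.1)
  ds <- sim$dataset
  n0 <- length(extract_process_info(ds))
  ds <- flag_noisy_variables(ds)
  ds <- impute(ds, "knn", k = 3)
  ds <- normalize_data(ds, "pqn")
  ds <- integrate_batches(ds, "qc_median")
  expect_length(extract_process_info(ds), n0 + 4)
  ops <- vapply(extract_process_info(ds), function(r) r$function_name,
                character(1))
  expect_identical(ops[-1], c("flag_noisy_variables", "impute",
                              "normalize_data", "integrate_batches"))
})
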