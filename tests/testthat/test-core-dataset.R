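test_that("construction validates, reorders, and records creation", {
  ds <- tiny_dataset()
  expect_s4_class(ds, "MassDataset")
  expect_length(extract_process_info(ds), 1)
  expect_true(validate_mass_dataset(ds))

  # expression given in reverse column order is stored in table order
  expr <- extract_expression_data(ds)
  ds2 <- create_mass_dataset(expr[, rev(colnames(expr))],
                             extract_sample_info(ds),
                             extract_variable_info(ds))
  expect_identical(colnames(extract_expression_data(ds2)),
                   extract_sample_info(ds)$sample_id)
  expect_identical(extract_expression_data(ds2), expr)
})

test_that("construction errors name the offending identifiers", {
  ds <- tiny_dataset()
  expr <- extract_expression_data(ds)
  si <- extract_sample_info(ds)
  vi <- extract_variable_info(ds)

  expect_error(create_mass_dataset(expr, si[-2, ], vi), "s2")
  si_dup <- rbind(si, si[1, ])
  expect_error(create_mass_dataset(expr, si_dup, vi), "duplicate.*s1")
  expr_neg <- expr; expr_neg[1, 1] <- -1
  expect_error(create_mass_dataset(expr_neg, si, vi), "negative")
  expect_error(create_mass_dataset(expr, si, vi[, c("variable_id", "mz")]),
               "rt")
})

test_that("filter_samples synchronizes columns and leaves variables alone", {
  sim <- small_sim(1)
  ds <- sim$dataset
  kept <- filter_samples(ds, function(si) si$class == "QC")
  expect_identical(ncol(extract_expression_data(kept)), 4L)
  expect_identical(nrow(extract_expression_data(kept)),
                   nrow(extract_expression_data(ds)))
  expect_identical(colnames(extract_expression_data(kept)),
                   extract_sample_info(kept)$sample_id)

  # predicate always true: identity plus one process record
  same <- filter_samples(ds, function(si) rep(TRUE, nrow(si)))
  expect_identical(extract_expression_data(same),
                   extract_expression_data(ds))
  expect_length(extract_process_info(same),
                length(extract_process_info(ds)) + 1)

  expect_error(filter_samples(ds, function(si) rep(FALSE, nrow(si))),
               "empty")
})

test_that("filter_variables cascades to annotations and MS2 links", {
  sim <- small_sim(2)
  ds <- sim$dataset
  gen <- generate_ms2_and_database(ds, n_planted = 5, ppm_noise_sd = 0,
                                   rt_noise_sd = 0, seed = 2)
  ds <- attach_ms2(ds, gen$spectra)
  ds <- annotate_dataset(ds, gen$db)
  ann <- extract_annotation_table(ds)
  expect_gt(nrow(ann), 0)

  drop_id <- ann$variable_id[1]
  n_dropped <- sum(ann$variable_id == drop_id)
  ds2 <- filter_variables(ds, function(vi) vi$variable_id != drop_id)
  expect_identical(nrow(extract_annotation_table(ds2)),
                   nrow(ann) - n_dropped)
  links <- vapply(extract_ms2_data(ds2)$spectra,
                  function(s) s$linked_variable_id, character(1))
  expect_false(drop_id %in% links)
  expect_true(validate_mass_dataset(ds2))

  expect_error(filter_variables(ds, function(vi) rep(FALSE, nrow(vi))),
               "empty")
})

test_that("mutate_variable_na_freq matches a counting oracle", {
  sim <- small_sim(3, mv_rate = 0.2)
  ds <- sim$dataset
  si <- extract_sample_info(ds)
  subset <- si$sample_id[1:6]
  ds2 <- mutate_variable_na_freq(ds, sample_subset = subset, label = "six")
  freq <- extract_variable_info(ds2)$na_freq_six
  oracle <- apply(extract_expression_data(ds)[, subset], 1,
                  function(v) sum(is.na(v)) / length(v))
  expect_equal(freq, unname(oracle))
  expect_true(all(freq >= 0 & freq <= 1))
  expect_true("na_freq_six" %in%
                ds2@variable_info_note$field)

  # no missing values anywhere -> all zero
  ds0 <- small_sim(3, mv_rate = 0)$dataset
  ds0 <- mutate_variable_na_freq(ds0, label = "all")
  expect_true(all(extract_variable_info(ds0)$na_freq_all == 0))

  expect_error(mutate_variable_na_freq(ds, sample_subset = "nope"), "nope")
})

test_that("attach_ms2 links by ppm then RT error", {
  expr <- matrix(1:6, nrow = 3,
                 dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  si <- data.frame(sample_id = c("s1", "s2"), class = "Subject",
                   stringsAsFactors = FALSE)
  vi <- data.frame(variable_id = c("a", "b", "c"),
                   mz = c(181.0706, 181.0706 * (1 + 8e-6), 500),
                   rt = c(121, 118, 500), stringsAsFactors = FALSE)
  ds <- create_mass_dataset(expr, si, vi)

  # within both tolerances -> linked to closest-ppm feature
  sp <- ms2_spectrum("q1", 181.0706 * (1 + 5e-6), 120,
                     cbind(c(50, 60), c(10, 20)))
  ds1 <- attach_ms2(ds, ms2_collection(list(sp)), mz_tol_ppm = 25,
                    rt_tol = 30)
  link <- extract_ms2_data(ds1)$spectra[[1]]$linked_variable_id
  expect_identical(link, "b")   # +5 ppm vs a, -3 ppm vs b

  # outside ppm tolerance -> unlinked but retained
  sp2 <- ms2_spectrum("q2", 181.0706 * (1 + 40e-6), 120,
                      cbind(50, 10))
  ds2 <- attach_ms2(ds, ms2_collection(list(sp2)), mz_tol_ppm = 25,
                    rt_tol = 30)
  expect_identical(extract_ms2_data(ds2)$spectra[[1]]$linked_variable_id,
                   NA_character_)

  expect_warning(attach_ms2(ds, ms2_collection(list())), "empty")
})

test_that("merge_datasets concatenates blocks and preserves histories", {
  a <- tiny_dataset()
  b0 <- tiny_dataset()
  # rename b's variables to avoid collisions
  expr <- extract_expression_data(b0)
  rownames(expr) <- paste0("w", 1:3)
  vi <- extract_variable_info(b0)
  vi$variable_id <- paste0("w", 1:3)
  b <- create_mass_dataset(expr, extract_sample_info(b0), vi)

  m <- merge_datasets(a, b, axis = "variable")
  expect_identical(nrow(extract_expression_data(m)), 6L)
  expect_length(extract_process_info(m),
                length(extract_process_info(a)) +
                  length(extract_process_info(b)) + 1)

  expect_error(merge_datasets(a, a, axis = "variable"), "collision")
  expect_error(merge_datasets(a, filter_samples(b, function(s) s$sample_id != "s1"),
                              axis = "variable"), "identical sample_id")
})

test_that("dataset_summary counts every component", {
  sim <- small_sim(4, n_variable = 10, n_subject = 4, n_qc = 4, mv_rate = 0.15)
  ds <- sim$dataset
  s <- dataset_summary(ds)
  expect_identical(s$n_variables, 10L)
  expect_identical(s$n_samples, 8L)
  expect_identical(s$n_process_steps, 1L)
  expect_equal(s$missing_fraction,
               mean(is.na(extract_expression_data(ds))))
  s2 <- dataset_summary(filter_variables(ds, function(v) v$mz > 0))
  expect_identical(s2$n_process_steps, 2L)
})

test_that("replay reproduces a recorded pipeline and rejects unknown ops", {
  sim <- small_sim(5)
  base <- sim$dataset
  out <- mutate_variable_na_freq(base, label = "all")
  out <- filter_variables(out, function(vi) vi$na_freq_all <= 0.3)
  out <- impute(out, "knn", k = 4)

  redo <- replay(extract_process_info(out)[-1], base)
  expect_identical(dataset_diff(redo, out), character(0))

  # empty history is the identity
  expect_identical(dataset_diff(replay(list(), base), base,
                                ignore_time = FALSE), character(0))

  bogus <- process_record("not_an_operation", list(x = 1))
  expect_error(replay(list(bogus), base), "record 1.*not_an_operation")
})

test_that("process records survive parameter normalization round trips", {
  rec <- process_record("impute", list(k = 5L, method = "knn",
                                       flag = TRUE,
                                       nested = list(a = c(1, 2))))
  expect_type(rec$parameters$k, "double")
  expect_error(process_record(""), "non-empty")
  expect_error(process_record("x", list(1)), "named")
  expect_error(process_record("x", list(f = mean)), "numeric, character")
})
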