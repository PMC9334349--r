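make_db <- function(db_type = "in_house", rt = 120, with_ms2 = TRUE) {
  spec <- if (with_ms2) {
    list(ms2_spectrum("C1_lib", 181.0707, rt,
                      cbind(c(55.05, 85.03, 127.04), c(40, 100, 60))))
  } else list()
  compound_database(paste0(db_type, "_db"), db_type, list(
    list(compound_id = "C1", name = "glucose", formula = "C6H12O6",
         exact_mass = 180.06339, rt = rt, ms2 = spec)))
}

test_that("MS1 matching follows the adduct arithmetic", {
  # theoretical [M+H]+ of glucose: 180.06339 + 1.007276 = 181.070666
  expr <- matrix(1:4, nrow = 2,
                 dimnames = list(c("hit", "far"), c("s1", "s2")))
  si <- data.frame(sample_id = c("s1", "s2"), class = "Subject",
                   stringsAsFactors = FALSE)
  vi <- data.frame(variable_id = c("hit", "far"),
                   mz = c(181.07067, 181.07067 * (1 + 40e-6)),
                   rt = c(120, 121), stringsAsFactors = FALSE)
  ds <- create_mass_dataset(expr, si, vi)
  db <- make_db()
  cands <- match_ms1(ds, db, default_adducts("positive"), mz_tol_ppm = 25)
  expect_identical(cands$variable_id, "hit")
  theo <- 180.06339 + 1.007276
  expect_equal(cands$mz_error_ppm, (181.07067 - theo) / theo * 1e6)
  expect_lt(abs(cands$mz_error_ppm), 0.1)
  expect_error(match_ms1(ds, compound_database("empty", "ms1_only", list())),
               "empty")

  # a compound reachable by two adducts yields two candidates
  vi2 <- vi
  vi2$mz <- c(181.07067, 180.06339 + 22.989218)
  ds2 <- create_mass_dataset(expr, si, vi2)
  c2 <- match_ms1(ds2, db)
  expect_identical(sort(c2$adduct), c("[M+H]+", "[M+Na]+"))
})

test_that("RT filtering keeps in-tolerance and RT-less candidates", {
  cands <- data.frame(variable_id = c("a", "b", "c"),
                      mz = rep(181.07, 3), rt = c(130, 165, 150),
                      compound_id = c("C1", "C1", "C2"),
                      compound_name = "x", db_id = "d", adduct = "[M+H]+",
                      mz_error_ppm = 0, stringsAsFactors = FALSE)
  db <- compound_database("d", "in_house", list(
    list(compound_id = "C1", name = "x", formula = NA_character_,
         exact_mass = 180.06339, rt = 120, ms2 = list()),
    list(compound_id = "C2", name = "y", formula = NA_character_,
         exact_mass = 180.06339, rt = NA_real_, ms2 = list())))
  out <- match_rt(cands, db, rt_tol_s = 30)
  expect_identical(out$variable_id, c("a", "c"))   # b is 45 s off
  expect_equal(out$rt_error_s, c(10, NA_real_))
})

test_that("spectral similarity has its boundary values and cosine core", {
  s1 <- ms2_spectrum("a", 200, 100,
                     cbind(c(50, 80, 120), c(100, 50, 25)))
  expect_equal(ms2_similarity(s1, s1), 1)

  s2 <- ms2_spectrum("b", 200, 100, cbind(c(60, 90, 130), c(10, 20, 30)))
  expect_equal(ms2_similarity(s1, s2), 0)

  # partial overlap equals the aligned-vector cosine oracle
  s3 <- ms2_spectrum("c", 200, 100, cbind(c(50, 80, 140), c(80, 60, 40)))
  q <- sqrt(c(100, 50, 25, 0))    # union axis: 50, 80, 120, 140
  l <- sqrt(c(80, 60, 0, 40))
  oracle <- sum(q * l) / sqrt(sum(q^2)) / sqrt(sum(l^2))
  expect_equal(ms2_similarity(s1, s3), oracle, tolerance = 1e-9)

  # monotone in the fragment tolerance sense: jittered copy stays high
  s4 <- ms2_spectrum("d", 200, 100,
                     cbind(c(50.01, 79.99, 120.005), c(100, 50, 25)))
  expect_equal(ms2_similarity(s1, s4), 1, tolerance = 1e-9)
})

test_that("composite scores average the available evidence", {
  cands <- data.frame(mz_error_ppm = c(0, 12.5, 0),
                      rt_error_s = c(0, NA, 15),
                      ms2_similarity = c(1, NA, NA))
  out <- score_annotations(cands, mz_tol_ppm = 25, rt_tol_s = 30)
  expect_equal(out$total_score[1], 1)          # perfect evidence
  expect_equal(out$total_score[2], 0.5)        # mz-only at half tolerance
  # mz perfect (w .25) + rt half (w .25), ms2 absent -> (1*.25+.5*.25)/.5
  expect_equal(out$total_score[3], 0.75)
  expect_true(all(out$total_score >= 0 & out$total_score <= 1))
})

test_that("scores are monotone in each error component", {
  base <- data.frame(mz_error_ppm = 0, rt_error_s = 0, ms2_similarity = 1)
  sweep_scores <- function(col, values) {
    vapply(values, function(v) {
      d <- base; d[[col]] <- v
      score_annotations(d)$total_score
    }, numeric(1))
  }
  expect_true(all(diff(sweep_scores("mz_error_ppm", seq(0, 25, 5))) <= 0))
  expect_true(all(diff(sweep_scores("rt_error_s", seq(0, 30, 5))) <= 0))
  expect_true(all(diff(sweep_scores("ms2_similarity", seq(0, 1, 0.2))) >= 0))
})

test_that("MSI levels follow the database-type rules", {
  evidence <- data.frame(mz_error_ppm = 0, rt_error_s = 2,
                         ms2_similarity = 0.9)
  expect_identical(assign_msi_level(evidence, make_db("in_house"))$msi_level,
                   1L)
  expect_identical(assign_msi_level(evidence, make_db("public_ms2"))$msi_level,
                   2L)
  expect_identical(assign_msi_level(evidence, make_db("ms1_only"))$msi_level,
                   3L)
  # in-house without RT or without a spectral hit degrades to level 3
  no_rt <- evidence; no_rt$rt_error_s <- NA_real_
  expect_identical(assign_msi_level(no_rt, make_db("in_house"))$msi_level, 3L)
  weak <- evidence; weak$ms2_similarity <- 0.2
  expect_identical(assign_msi_level(weak, make_db("in_house"))$msi_level, 3L)
})

test_that("annotate_dataset recovers planted identities and appends", {
  sim <- small_sim(71, n_variable = 30, mv_rate = 0)
  gen <- generate_ms2_and_database(sim$dataset, n_planted = 10,
                                   ppm_noise_sd = 0, rt_noise_sd = 0,
                                   seed = 71)
  ds <- attach_ms2(sim$dataset, gen$spectra)
  ds <- annotate_dataset(ds, gen$db)
  ann <- extract_annotation_table(ds)
  expect_true(all(ann$variable_id %in%
                    extract_variable_info(ds)$variable_id))
  top <- remove_redundant_annotations(ds)
  tt <- extract_annotation_table(top)
  hits <- tt$compound_id[match(names(gen$truth), tt$variable_id)]
  expect_identical(unname(hits), unname(gen$truth))
  expect_true(all(tt$msi_level[tt$variable_id %in% names(gen$truth)] == 1))

  # re-annotating appends rather than overwriting
  again <- annotate_dataset(ds, gen$db)
  expect_identical(nrow(extract_annotation_table(again)), 2L * nrow(ann))
})

test_that("redundancy removal keeps the best candidate per variable", {
  sim <- small_sim(72, n_variable = 5, mv_rate = 0)
  ds <- sim$dataset
  vid <- extract_variable_info(ds)$variable_id[1]
  ds@annotation_table <- data.frame(
    variable_id = vid, compound_id = c("X", "Y", "Z"),
    compound_name = "n", db_id = "d", adduct = "[M+H]+",
    mz_error_ppm = 0, rt_error_s = NA_real_, ms2_similarity = NA_real_,
    total_score = c(0.9, 0.8, 0.7), msi_level = c(3, 3, 3),
    stringsAsFactors = FALSE)
  out <- extract_annotation_table(remove_redundant_annotations(ds))
  expect_identical(nrow(out), 1L)
  expect_identical(out$compound_id, "X")

  # tie on score: the lower MSI level wins
  ds@annotation_table$total_score <- c(0.9, 0.9, 0.7)
  ds@annotation_table$msi_level <- c(2, 1, 3)
  out2 <- extract_annotation_table(remove_redundant_annotations(ds))
  expect_identical(out2$compound_id, "Y")

  # level cutoff drops everything above it
  ds@annotation_table$msi_level <- c(1, 2, 3)
  out3 <- extract_annotation_table(
    remove_redundant_annotations(ds, level_cutoff = 2))
  expect_true(all(out3$msi_level <= 2))
})
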