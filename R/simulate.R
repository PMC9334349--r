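# Seeded synthetic-data generator with known ground truth.
#
# The generator emulates the statistical structure a QC-bracketed
# untargeted LC-MS batch produces after peak picking: log-normal feature
# intensities, pooled-QC replicates injected first, last and every k-th
# position, smooth per-variable signal drift over injection order,
# per-(variable, batch) offsets, intensity-dependent (MNAR-leaning)
# missing values, and a planted set of differential metabolites.

PROTON_MASS <- 1.007276

#' Generate a synthetic MassDataset with known ground truth
#'
#' @param n_subject number of biological subject samples (split evenly
#'   into Case/Control).
#' @param n_qc number of pooled QC samples (>= 4; the first and last
#'   injections are QC, the rest are evenly interleaved).
#' @param n_batch number of acquisition batches (contiguous in injection
#'   order).
#' @param n_variable number of metabolic features.
#' @param drift per-variable intensity drift over injection order:
#'   `"none"`, `"linear"` (log-linear decay to ~1/3 of the starting
#'   response by the last injection) or `"monotone-smooth"` (smoothstep
#'   decay of the same magnitude).
#' @param batch_shift_sd sd (log2 scale) of per-(variable, batch)
#'   offsets; 0 disables batch effects.
#' @param mv_rate target marginal missing-value rate; cells are censored
#'   preferentially at low intensity (MNAR-leaning) but the mechanism is
#'   rank-calibrated so the expected overall rate equals `mv_rate`.
#' @param de_fraction fraction of variables made truly differential
#'   between Case and Control, in `[0, 1]`.
#' @param effect_log2 log2 effect size added to Case samples of
#'   differential variables.
#' @param seed integer seed; the output is a pure function of the
#'   parameters and the seed.
#' @return list with elements `dataset` (a [MassDataset-class]) and
#'   `truth` (seed, per-variable drift coefficients, batch offsets,
#'   differential variable ids with effects, missing-value mask).
#' @export
generate_dataset <- function(n_subject = 52, n_qc = 8, n_batch = 1,
                             n_variable = 200,
                             drift = c("none", "linear", "monotone-smooth"),
                             batch_shift_sd = 0, mv_rate = 0.1,
                             de_fraction = 0.1, effect_log2 = 1,
                             seed = 1) {
  drift <- match.arg(drift)
  if (n_qc < 4) {
    stop("n_qc must be >= 4: QC-based normalization requires bracketing QC injections",
         call. = FALSE)
  }
  if (!is_scalar_number(de_fraction) || de_fraction < 0 || de_fraction > 1) {
    stop("de_fraction must be in [0, 1]", call. = FALSE)
  }
  stopifnot(n_subject >= 2, n_variable >= 2, n_batch >= 1,
            mv_rate >= 0, mv_rate <= 0.5)
  old_seed <- .Random.seed_save()
  on.exit(.Random.seed_restore(old_seed))
  set.seed(as.integer(seed))

  n <- n_subject + n_qc
  # QC injections at the very first and last positions, rest evenly spread
  qc_pos <- unique(round(seq(1, n, length.out = n_qc)))
  while (length(qc_pos) < n_qc) {
    qc_pos <- unique(c(qc_pos, setdiff(seq_len(n), qc_pos)[1]))
  }
  qc_pos <- sort(qc_pos)
  subject_pos <- setdiff(seq_len(n), qc_pos)

  sample_id <- character(n)
  sample_id[qc_pos] <- sprintf("QC_%02d", seq_len(n_qc))
  sample_id[subject_pos] <- sprintf("S_%03d", seq_len(n_subject))
  class <- ifelse(seq_len(n) %in% qc_pos, "QC", "Subject")
  group <- rep("QC", n)
  group[subject_pos] <- sample(rep(c("Case", "Control"),
                                   length.out = n_subject))
  batch <- if (n_batch == 1) rep(1L, n) else
    as.integer(cut(seq_len(n), breaks = n_batch, labels = FALSE))

  variable_id <- sprintf("M%04d", seq_len(n_variable))
  mz <- sort(runif(n_variable, 80, 1000))
  rt <- runif(n_variable, 30, 900)

  mu <- rnorm(n_variable, mean = 15, sd = 2)      # log2 baseline abundance
  sd_bio <- 0.5                                   # biological variation, log2
  sd_ana <- 0.03                                  # analytical noise, log2

  n_de <- round(de_fraction * n_variable)
  de_idx <- if (n_de > 0) sort(sample.int(n_variable, n_de)) else integer(0)
  effects <- setNames(rep(effect_log2, length(de_idx)), variable_id[de_idx])

  log2x <- matrix(rep(mu, n), nrow = n_variable)
  # subjects: biological variation + group effect; QCs: pooled replicates
  bio <- matrix(rnorm(n_variable * n_subject, 0, sd_bio),
                nrow = n_variable)
  log2x[, subject_pos] <- log2x[, subject_pos] + bio
  if (length(de_idx)) {
    case_cols <- which(group == "Case")
    log2x[de_idx, case_cols] <- log2x[de_idx, case_cols] + effect_log2
  }
  log2x <- log2x + matrix(rnorm(n_variable * n, 0, sd_ana), nrow = n_variable)

  drift_coef <- rep(0, n_variable)
  if (drift != "none") {
    drift_coef <- -log2(3) * runif(n_variable, 0.8, 1.2)
    t <- (seq_len(n) - 1) / (n - 1)
    shape <- if (drift == "linear") t else t^2 * (3 - 2 * t)
    log2x <- log2x + outer(drift_coef, shape)
  }

  batch_offsets <- matrix(0, n_variable, n_batch)
  if (batch_shift_sd > 0 && n_batch > 1) {
    batch_offsets <- matrix(rnorm(n_variable * n_batch, 0, batch_shift_sd),
                            n_variable, n_batch)
    log2x <- log2x + batch_offsets[, batch, drop = FALSE]
  }

  x <- 2^log2x
  dimnames(x) <- list(variable_id, sample_id)

  # MNAR-leaning censoring: P(missing) = 2 * mv_rate * (1 - u), where u is
  # the within-variable intensity percentile -> marginal rate = mv_rate.
  mask <- matrix(FALSE, n_variable, n)
  if (mv_rate > 0) {
    for (i in seq_len(n_variable)) {
      u <- (rank(x[i, ], ties.method = "first") - 0.5) / n
      p <- pmin(1, 2 * mv_rate * (1 - u))
      mask[i, ] <- runif(n) < p
    }
    x[mask] <- NA_real_
  }

  sample_info <- data.frame(
    sample_id = sample_id, class = class, group = group,
    batch = as.integer(batch), injection_order = seq_len(n),
    stringsAsFactors = FALSE)
  variable_info <- data.frame(
    variable_id = variable_id, mz = mz, rt = rt, stringsAsFactors = FALSE)

  ds <- local({
    # the generator is pure given (parameters, seed): the creation
    # record's timestamp is seed-derived, not wall clock
    opt <- options(masspipe.log = FALSE,
                   masspipe.fixed_time_base = 946684800 + as.numeric(seed),
                   masspipe.fixed_time_counter = 0)
    on.exit(options(opt))
    create_mass_dataset(x, sample_info, variable_info)
  })
  truth <- list(
    seed = as.integer(seed),
    drift = drift, drift_coefficients = setNames(drift_coef, variable_id),
    batch_offsets = batch_offsets,
    de_variable_ids = variable_id[de_idx],
    effect_log2 = effects,
    mv_rate = mv_rate,
    missing_mask = mask,
    qc_positions = qc_pos)
  list(dataset = ds, truth = truth)
}

# Preserve the caller's RNG state so generators are pure functions of
# their seed and leave the session stream untouched.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate MS2 spectra and a matching compound database with planted
#' identities
#'
#' Selects `n_planted` features of `ds` and creates, for each, a database
#' compound whose exact mass is the feature m/z minus the proton mass
#' (protonated adduct), an RT near the feature's, and a library MS2
#' spectrum; the dataset-side spectrum is a noisy copy (jittered
#' precursor, fragment intensities).  Database mass/RT carry Gaussian
#' noise of `ppm_noise_sd` ppm and `rt_noise_sd` seconds.  Decoy
#' compounds (3 per planted compound) are added with masses at least
#' 50 ppm away from every planted feature.
#'
#' @param ds a [MassDataset-class].
#' @param n_planted number of features given a true identity.
#' @param ppm_noise_sd sd of the mass error between feature and database
#'   compound, in ppm.
#' @param rt_noise_sd sd of the RT error, in seconds.
#' @param seed integer seed.
#' @return list with `spectra` (an [ms2_collection()]), `db` (a
#'   [compound_database()], type `"in_house"`) and `truth` (named
#'   character vector: planted `variable_id` -> true `compound_id`).
#' @export
generate_ms2_and_database <- function(ds, n_planted = 30, ppm_noise_sd = 3,
                                      rt_noise_sd = 5, seed = 1) {
  stopifnot(is(ds, "MassDataset"))
  vi <- ds@variable_info
  if (n_planted > nrow(vi)) {
    stop("n_planted exceeds the number of variables", call. = FALSE)
  }
  old_seed <- .Random.seed_save()
  on.exit(.Random.seed_restore(old_seed))
  set.seed(as.integer(seed))

  planted <- sort(sample.int(nrow(vi), n_planted))
  compounds <- list()
  spectra <- list()
  truth <- character(0)
  for (j in seq_along(planted)) {
    i <- planted[j]
    vid <- vi$variable_id[i]
    cid <- sprintf("CPD%04d", j)
    feature_mz <- vi$mz[i]
    feature_rt <- vi$rt[i]
    db_mass <- feature_mz * (1 + rnorm(1, 0, ppm_noise_sd) * 1e-6) - PROTON_MASS
    db_rt <- feature_rt + rnorm(1, 0, rt_noise_sd)

    n_frag <- sample(6:12, 1)
    frag_mz <- sort(runif(n_frag, 50, max(51, feature_mz - 1)))
    frag_int <- runif(n_frag, 5, 100)
    lib_spec <- ms2_spectrum(
      spectrum_id = paste0(cid, "_lib"),
      precursor_mz = db_mass + PROTON_MASS,
      precursor_rt = db_rt,
      fragments = cbind(frag_mz, frag_int))
    compounds[[length(compounds) + 1L]] <- list(
      compound_id = cid, name = paste0("compound_", j),
      formula = NA_character_, exact_mass = db_mass, rt = db_rt,
      ms2 = list(lib_spec))

    # dataset-side spectrum: noisy copy of the library spectrum
    jitter_int <- frag_int * exp(rnorm(n_frag, 0, 0.1))
    spectra[[length(spectra) + 1L]] <- ms2_spectrum(
      spectrum_id = paste0("query_", vid),
      precursor_mz = feature_mz * (1 + rnorm(1, 0, 1) * 1e-6),
      precursor_rt = feature_rt + rnorm(1, 0, 1),
      fragments = cbind(frag_mz + runif(n_frag, -0.003, 0.003), jitter_int))
    truth[vid] <- cid
  }

  # decoys: >= 50 ppm away from every planted feature mass
  planted_masses <- vi$mz[planted] - PROTON_MASS
  n_decoy <- 3 * n_planted
  made <- 0
  while (made < n_decoy) {
    m <- runif(1, 80, 950)
    if (all(abs((m - planted_masses) / planted_masses) * 1e6 >= 50)) {
      made <- made + 1
      compounds[[length(compounds) + 1L]] <- list(
        compound_id = sprintf("DEC%04d", made),
        name = sprintf("decoy_%d", made), formula = NA_character_,
        exact_mass = m,
        rt = if (runif(1) < 0.5) runif(1, 30, 900) else NA_real_,
        ms2 = list())
    }
  }
  list(spectra = ms2_collection(spectra, source_files = "synthetic"),
       db = compound_database("synthetic_inhouse", "in_house", compounds),
       truth = truth)
}

#' Generate a pathway database with one planted enriched pathway
#'
#' Background pathways draw their members uniformly from
#' `compound_ids`; the designated pathway takes at least 80% of its
#' members from `differential_ids`, so that over-representation analysis
#' of the differential set must rank it first.
#'
#' @param compound_ids universe of compound identifiers.
#' @param differential_ids the truly differential subset.
#' @param n_pathways total number of pathways.
#' @param enriched_pathway_size size of the designated enriched pathway.
#' @param background_size_range size range (inclusive) for background
#'   pathways.
#' @param seed integer seed.
#' @return list with `db` (a `pathway_database`) and `truth`
#'   (`enriched_pathway_id`, its member ids).
#' @export
generate_pathway_db <- function(compound_ids, differential_ids,
                                n_pathways = 20, enriched_pathway_size = 10,
                                background_size_range = c(5, 15), seed = 1) {
  stopifnot(length(compound_ids) >= enriched_pathway_size,
            all(differential_ids %in% compound_ids))
  old_seed <- .Random.seed_save()
  on.exit(.Random.seed_restore(old_seed))
  set.seed(as.integer(seed))

  n_from_de <- min(length(differential_ids),
                   ceiling(0.8 * enriched_pathway_size))
  enriched_members <- c(
    sample(differential_ids, n_from_de),
    sample(setdiff(compound_ids, differential_ids),
           enriched_pathway_size - n_from_de))
  pathways <- list(list(pathway_id = "PW_ENRICHED",
                        name = "planted enriched pathway",
                        compound_ids = sort(enriched_members)))
  for (k in seq_len(n_pathways - 1)) {
    size <- sample(background_size_range[1]:background_size_range[2], 1)
    pathways[[k + 1L]] <- list(
      pathway_id = sprintf("PW_%03d", k),
      name = sprintf("background pathway %d", k),
      compound_ids = sort(sample(compound_ids, size)))
  }
  list(db = pathway_database("synthetic_pathways", pathways),
       truth = list(enriched_pathway_id = "PW_ENRICHED",
                    members = sort(enriched_members)))
}
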