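# Metabolite annotation: MS1 candidate generation, RT filtering, MS2
# spectral similarity, composite scoring, MSI confidence levels,
# redundancy removal and write-back to the dataset.

#' Default adduct rules
#'
#' Relates a neutral exact mass to the observed m/z:
#' `theoretical mz = (exact_mass + mass_shift) / charge`.  The built-in
#' set covers the common singly charged electrospray adducts
#' (`[M+H]+`, `[M+Na]+`, `[M+NH4]+`, `[M-H]-`, `[M+CH3COO]-`); users can
#' supply any data frame with the same columns.
#'
#' @param polarity `"positive"`, `"negative"` or `"both"`.
#' @return data frame with columns `name`, `polarity`, `mass_shift`
#'   (Daltons), `charge`.
#' @export
default_adducts <- function(polarity = c("positive", "negative", "both")) {
  polarity <- match.arg(polarity)
  tab <- data.frame(
    name = c("[M+H]+", "[M+Na]+", "[M+NH4]+", "[M-H]-", "[M+CH3COO]-"),
    polarity = c("positive", "positive", "positive", "negative", "negative"),
    mass_shift = c(1.007276, 22.989218, 18.033823, -1.007276, 59.013851),
    charge = c(1, 1, 1, 1, 1),
    stringsAsFactors = FALSE)
  if (polarity == "both") tab else tab[tab$polarity == polarity, , drop = FALSE]
}

#' MS1 candidate generation by accurate mass
#'
#' Emits one candidate for every (variable, compound, adduct) whose ppm
#' error `(observed - theoretical) / theoretical * 1e6` is within
#' `mz_tol_ppm`.
#'
#' @param ds a [MassDataset-class].
#' @param db a [compound_database()]; must be non-empty.
#' @param adducts adduct rule data frame (see [default_adducts()]).
#' @param mz_tol_ppm mass tolerance in ppm (default 25).
#' @return data frame of candidates with `variable_id`, `compound_id`,
#'   `compound_name`, `db_id`, `adduct`, `mz_error_ppm`, plus feature
#'   `mz`/`rt` carried along for later stages.
#' @export
match_ms1 <- function(ds, db, adducts = default_adducts("positive"),
                      mz_tol_ppm = 25) {
  stopifnot(is(ds, "MassDataset"), inherits(db, "compound_database"),
            is_scalar_number(mz_tol_ppm), mz_tol_ppm > 0)
  if (length(db$compounds) == 0L) {
    stop("compound database '", db$db_id, "' is empty", call. = FALSE)
  }
  if (length(unique(adducts$polarity)) > 1) {
    stop("adduct polarities must be consistent within one search",
         call. = FALSE)
  }
  vi <- ds@variable_info
  out <- list()
  for (cp in db$compounds) {
    for (a in seq_len(nrow(adducts))) {
      theo <- (cp$exact_mass + adducts$mass_shift[a]) / adducts$charge[a]
      ppm <- (vi$mz - theo) / theo * 1e6
      hit <- which(abs(ppm) <= mz_tol_ppm)
      if (length(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          variable_id = vi$variable_id[hit], mz = vi$mz[hit], rt = vi$rt[hit],
          compound_id = cp$compound_id, compound_name = cp$name,
          db_id = db$db_id, adduct = adducts$name[a],
          mz_error_ppm = ppm[hit], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(variable_id = character(0), mz = numeric(0),
                      rt = numeric(0), compound_id = character(0),
                      compound_name = character(0), db_id = character(0),
                      adduct = character(0), mz_error_ppm = numeric(0),
                      stringsAsFactors = FALSE))
  }
  norm_df(do.call(rbind, out))
}

#' Retention-time filtering of MS1 candidates
#'
#' Candidates against compounds with a database RT are kept only when
#' `|feature rt - database rt| <= rt_tol_s`; compounds without RT
#' (RT unavailable in the library) are kept with an absent error, which
#' disables RT evidence downstream.
#'
#' @param candidates output of [match_ms1()].
#' @param db the [compound_database()] searched.
#' @param rt_tol_s RT tolerance in seconds (default 30).
#' @return the filtered candidates with an `rt_error_s` column (`NA`
#'   when the library has no RT).
#' @export
match_rt <- function(candidates, db, rt_tol_s = 30) {
  stopifnot(is.data.frame(candidates), inherits(db, "compound_database"),
            is_scalar_number(rt_tol_s), rt_tol_s > 0)
  if (nrow(candidates) == 0L) {
    candidates$rt_error_s <- numeric(0)
    return(candidates)
  }
  db_rt <- vapply(db$compounds, function(cp) cp$rt %||% NA_real_, numeric(1))
  names(db_rt) <- vapply(db$compounds, `[[`, character(1), "compound_id")
  rt_err <- candidates$rt - db_rt[candidates$compound_id]
  keep <- is.na(rt_err) | abs(rt_err) <= rt_tol_s
  candidates$rt_error_s <- unname(rt_err)
  norm_df(candidates[keep, , drop = FALSE])
}

#' Fragment-spectrum similarity
#'
#' Cosine similarity on square-root intensities: fragments of the two
#' spectra are matched greedily by closest m/z within `frag_tol_da`
#' (each fragment used at most once); the score is the dot product of
#' the matched square-root intensities divided by the norms over all
#' fragments, so identical spectra score 1 and spectra with no shared
#' fragments score 0.  `weight_mz` adds m/z weighting
#' (`w = sqrt(intensity) * mz^weight_mz`), off by default.
#'
#' @param query,library [ms2_spectrum()] objects (non-empty fragment
#'   lists).
#' @param frag_tol_da fragment m/z tolerance in Daltons (default 0.02).
#' @param weight_mz,weight_int exponents of the fragment weight
#'   `mz^weight_mz * intensity^(weight_int/2)`; defaults (0, 1) give the
#'   square-root-intensity cosine.
#' @return similarity in `[0, 1]`.
#' @export
ms2_similarity <- function(query, library, frag_tol_da = 0.02,
                           weight_mz = 0, weight_int = 1) {
  stopifnot(inherits(query, "ms2_spectrum"), inherits(library, "ms2_spectrum"),
            is_scalar_number(frag_tol_da), frag_tol_da > 0)
  qf <- query$fragments
  lf <- library$fragments
  if (nrow(qf) == 0L || nrow(lf) == 0L) {
    stop("spectra must have at least one fragment", call. = FALSE)
  }
  wq <- qf[, "mz"]^weight_mz * qf[, "intensity"]^(weight_int / 2)
  wl <- lf[, "mz"]^weight_mz * lf[, "intensity"]^(weight_int / 2)

  # greedy matching: all cross pairs within tolerance, closest first
  pairs <- which(abs(outer(qf[, "mz"], lf[, "mz"], "-")) <= frag_tol_da,
                 arr.ind = TRUE)
  dot <- 0
  if (nrow(pairs)) {
    d <- abs(qf[pairs[, 1], "mz"] - lf[pairs[, 2], "mz"])
    ord <- order(d)
    used_q <- logical(nrow(qf))
    used_l <- logical(nrow(lf))
    for (p in ord) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      if (!used_q[i] && !used_l[j]) {
        used_q[i] <- TRUE
        used_l[j] <- TRUE
        dot <- dot + wq[i] * wl[j]
      }
    }
  }
  denom <- sqrt(sum(wq^2)) * sqrt(sum(wl^2))
  if (denom == 0) return(0)
  min(1, dot / denom)
}

#' Composite annotation score
#'
#' Linear tolerance-scaled component scores
#' `s_mz = max(0, 1 - |ppm| / mz_tol)`,
#' `s_rt = max(0, 1 - |rt error| / rt_tol)`, `s_ms2 = similarity`,
#' combined as a weighted mean over the evidence that is present (the
#' weight of absent evidence is redistributed), giving a total in
#' `[0, 1]`.
#'
#' @param candidates data frame with `mz_error_ppm` and optionally
#'   `rt_error_s`, `ms2_similarity` columns.
#' @param weights named numeric: weights for `mz`, `rt`, `ms2`.
#' @param mz_tol_ppm,rt_tol_s the tolerances the component scores are
#'   scaled by.
#' @return `candidates` with a `total_score` column.
#' @export
score_annotations <- function(candidates,
                              weights = c(mz = 0.25, rt = 0.25, ms2 = 0.5),
                              mz_tol_ppm = 25, rt_tol_s = 30) {
  stopifnot(is.data.frame(candidates),
            all(c("mz", "rt", "ms2") %in% names(weights)))
  if (nrow(candidates) == 0L) {
    candidates$total_score <- numeric(0)
    return(candidates)
  }
  s_mz <- pmax(0, 1 - abs(candidates$mz_error_ppm) / mz_tol_ppm)
  s_rt <- if ("rt_error_s" %in% names(candidates)) {
    pmax(0, 1 - abs(candidates$rt_error_s) / rt_tol_s)
  } else rep(NA_real_, nrow(candidates))
  s_ms2 <- if ("ms2_similarity" %in% names(candidates)) {
    candidates$ms2_similarity
  } else rep(NA_real_, nrow(candidates))
  comp <- cbind(s_mz, s_rt, s_ms2)
  w <- matrix(rep(c(weights[["mz"]], weights[["rt"]], weights[["ms2"]]),
                  each = nrow(comp)), ncol = 3)
  w[is.na(comp)] <- 0
  comp[is.na(comp)] <- 0
  candidates$total_score <- rowSums(comp * w) / rowSums(w)
  candidates
}

#' Assign MSI confidence levels
#'
#' Level 1: in-house database hit with matched RT and MS2 similarity at
#' or above `ms2_cutoff` (authentic-standard evidence).  Level 2: public
#' MS2 library hit with similarity at or above the cutoff.  Everything
#' else — including MS1-only databases — is level 3 (putative,
#' mass-based).
#'
#' @param candidates scored candidate data frame with `rt_error_s` and
#'   `ms2_similarity` columns.
#' @param db the [compound_database()] searched.
#' @param ms2_cutoff minimal MS2 similarity counting as a spectral match
#'   (default 0.5).
#' @return `candidates` with an integer `msi_level` column.
#' @export
assign_msi_level <- function(candidates, db, ms2_cutoff = 0.5) {
  stopifnot(is.data.frame(candidates), inherits(db, "compound_database"))
  if (nrow(candidates) == 0L) {
    candidates$msi_level <- integer(0)
    return(candidates)
  }
  rt_matched <- !is.na(candidates$rt_error_s %||% rep(NA_real_, nrow(candidates)))
  ms2_hit <- !is.na(candidates$ms2_similarity) &
    candidates$ms2_similarity >= ms2_cutoff
  level <- rep(3L, nrow(candidates))
  if (db$db_type == "in_house") {
    level[rt_matched & ms2_hit] <- 1L
  } else if (db$db_type == "public_ms2") {
    level[ms2_hit] <- 2L
  }
  candidates$msi_level <- level
  candidates
}

#' Annotate the features of a MassDataset against a compound database
#'
#' Runs the full cascade — MS1 matching, RT filtering, MS2 similarity
#' for variables with linked spectra, composite scoring, MSI level
#' assignment — and appends the results to the dataset's
#' `annotation_table` (re-running with another database appends, never
#' overwrites).  The process record stores the matching parameters and
#' the database identity.
#'
#' @param ds a [MassDataset-class].
#' @param db a [compound_database()].
#' @param adducts adduct rules (see [default_adducts()]).
#' @param mz_tol_ppm,rt_tol_s,frag_tol_da matching tolerances.
#' @param ms2_cutoff MSI-level spectral-match cutoff.
#' @param weights composite score weights, see [score_annotations()].
#' @param record append a process record (default `TRUE`).
#' @return the annotated dataset.
#' @export
annotate_dataset <- function(ds, db, adducts = default_adducts("positive"),
                             mz_tol_ppm = 25, rt_tol_s = 30,
                             frag_tol_da = 0.02, ms2_cutoff = 0.5,
                             weights = c(mz = 0.25, rt = 0.25, ms2 = 0.5),
                             record = TRUE) {
  stopifnot(is(ds, "MassDataset"), inherits(db, "compound_database"))
  assert_scalar_flag(record, "record")
  cands <- match_ms1(ds, db, adducts, mz_tol_ppm)
  cands <- match_rt(cands, db, rt_tol_s)

  cands$ms2_similarity <- NA_real_
  if (nrow(cands)) {
    lib_ms2 <- setNames(lapply(db$compounds, `[[`, "ms2"),
                        vapply(db$compounds, `[[`, character(1), "compound_id"))
    for (r in seq_len(nrow(cands))) {
      specs <- spectra_for_variable(ds, cands$variable_id[r])
      libs <- lib_ms2[[cands$compound_id[r]]]
      if (length(specs) && length(libs)) {
        sims <- vapply(specs, function(q) {
          max(vapply(libs, function(l) {
            ms2_similarity(q, l, frag_tol_da = frag_tol_da)
          }, numeric(1)))
        }, numeric(1))
        cands$ms2_similarity[r] <- max(sims)
      }
    }
  }
  cands <- score_annotations(cands, weights, mz_tol_ppm, rt_tol_s)
  cands <- assign_msi_level(cands, db, ms2_cutoff)

  if (nrow(cands)) {
    new_rows <- cands[, c("variable_id", "compound_id", "compound_name",
                          "db_id", "adduct", "mz_error_ppm", "rt_error_s",
                          "ms2_similarity", "total_score", "msi_level")]
    new_rows$msi_level <- as.numeric(new_rows$msi_level)
    ds@annotation_table <- norm_df(rbind(ds@annotation_table, new_rows))
  }
  if (record) {
    ds <- append_record(ds, "annotate_dataset",
                        list(db_id = db$db_id, db_type = db$db_type,
                             mz_tol_ppm = mz_tol_ppm, rt_tol_s = rt_tol_s,
                             frag_tol_da = frag_tol_da,
                             ms2_cutoff = ms2_cutoff,
                             weights = as.list(weights),
                             n_candidates = nrow(cands),
                             resource = db$db_id))
  }
  validObject(ds)
  ds
}

register_operation("annotate_dataset", function(ds, params, resources) {
  db <- resources[[params$db_id]]
  if (is.null(db)) {
    stop("replay: annotate_dataset needs resources[[\"", params$db_id,
         "\"]] (the compound database)", call. = FALSE)
  }
  annotate_dataset(ds, db, mz_tol_ppm = params$mz_tol_ppm %||% 25,
                   rt_tol_s = params$rt_tol_s %||% 30,
                   frag_tol_da = params$frag_tol_da %||% 0.02,
                   ms2_cutoff = params$ms2_cutoff %||% 0.5,
                   weights = if (is.null(params$weights))
                     c(mz = 0.25, rt = 0.25, ms2 = 0.5) else
                     unlist(params$weights))
})

#' Remove redundant annotations
#'
#' `"best_per_variable"` keeps the top-scoring candidate of every
#' variable (ties: lower MSI level number first, then lexicographic
#' `compound_id`).  `level_cutoff` additionally drops candidates whose
#' MSI level exceeds it (e.g. `2` keeps only level 1-2 annotations).
#'
#' @param ds an annotated [MassDataset-class].
#' @param policy redundancy policy (only `"best_per_variable"`).
#' @param level_cutoff optional maximal MSI level to keep.
#' @param record append a process record (default `TRUE`).
#' @return the dataset with a thinned `annotation_table`.
#' @export
remove_redundant_annotations <- function(ds, policy = "best_per_variable",
                                         level_cutoff = NULL,
                                         record = TRUE) {
  stopifnot(is(ds, "MassDataset"), identical(policy, "best_per_variable"))
  assert_scalar_flag(record, "record")
  ann <- ds@annotation_table
  if (!is.null(level_cutoff) && nrow(ann)) {
    ann <- ann[ann$msi_level <= level_cutoff, , drop = FALSE]
  }
  if (nrow(ann)) {
    ord <- order(ann$variable_id, -ann$total_score, ann$msi_level,
                 ann$compound_id)
    ann <- ann[ord, , drop = FALSE]
    ann <- ann[!duplicated(ann$variable_id), , drop = FALSE]
  }
  ds@annotation_table <- norm_df(ann)
  if (record) {
    params <- list(policy = policy)
    if (!is.null(level_cutoff)) params$level_cutoff <- level_cutoff
    ds <- append_record(ds, "remove_redundant_annotations", params)
  }
  validObject(ds)
  ds
}

register_operation("remove_redundant_annotations", function(ds, params, resources) {
  remove_redundant_annotations(ds, policy = params$policy %||% "best_per_variable",
                               level_cutoff = params$level_cutoff)
})
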