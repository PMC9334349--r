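#' Attach MS2 spectra to the features of a MassDataset
#'
#' Each spectrum is assigned to the metabolic feature whose (`mz`, `rt`)
#' lies within both tolerances of the spectrum's precursor.  Among
#' multiple candidate features the one with the smallest absolute ppm
#' error wins, ties broken by smaller absolute RT error, then by
#' `variable_id`.  Spectra without a matching feature are retained
#' unlinked, so a later, looser matching round can pick them up.
#'
#' @param ds a [MassDataset-class].
#' @param spectra an [ms2_collection()].
#' @param mz_tol_ppm precursor m/z tolerance in parts per million.
#' @param rt_tol retention-time tolerance in seconds.
#' @param record append a process record (default `TRUE`).
#' @return the dataset with the collection stored in `ms2_data`.  An
#'   empty collection is a recorded no-op with a warning.
#' @export
attach_ms2 <- function(ds, spectra, mz_tol_ppm = 25, rt_tol = 30,
                       record = TRUE) {
  stopifnot(is(ds, "MassDataset"), inherits(spectra, "ms2_collection"))
  stopifnot(is_scalar_number(mz_tol_ppm), mz_tol_ppm > 0,
            is_scalar_number(rt_tol), rt_tol > 0)
  assert_scalar_flag(record, "record")

  if (length(spectra$spectra) == 0L) {
    warning("attach_ms2: empty spectrum collection, nothing to assign",
            call. = FALSE)
  }
  vi <- ds@variable_info
  linked <- lapply(spectra$spectra, function(s) {
    ppm_err <- (s$precursor_mz - vi$mz) / vi$mz * 1e6
    rt_err <- s$precursor_rt - vi$rt
    ok <- which(abs(ppm_err) <= mz_tol_ppm & abs(rt_err) <= rt_tol)
    if (length(ok)) {
      ord <- order(abs(ppm_err[ok]), abs(rt_err[ok]), vi$variable_id[ok])
      s$linked_variable_id <- vi$variable_id[ok[ord[1]]]
    } else {
      s$linked_variable_id <- NA_character_
    }
    s
  })
  existing_ids <- vapply(ds@ms2_data$spectra, function(s) s$spectrum_id,
                         character(1))
  new_ids <- vapply(linked, function(s) s$spectrum_id, character(1))
  clash <- intersect(existing_ids, new_ids)
  if (length(clash)) {
    stop("spectrum_id already present in dataset: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  ds@ms2_data$spectra <- c(ds@ms2_data$spectra, linked)
  ds@ms2_data$source_files <- union(ds@ms2_data$source_files,
                                    spectra$source_files)
  if (record) {
    ds <- append_record(ds, "attach_ms2",
                        list(mz_tol_ppm = mz_tol_ppm, rt_tol = rt_tol,
                             n_spectra = length(linked),
                             resource = "ms2"))
  }
  validObject(ds)
  ds
}

register_operation("attach_ms2", function(ds, params, resources) {
  col <- resources[["ms2"]]
  if (is.null(col)) {
    stop("replay: attach_ms2 needs resources[[\"ms2\"]] (the spectrum collection)",
         call. = FALSE)
  }
  attach_ms2(ds, col, mz_tol_ppm = params$mz_tol_ppm %||% 25,
             rt_tol = params$rt_tol %||% 30)
})

# Spectra linked to one variable id.
spectra_for_variable <- function(ds, variable_id) {
  Filter(function(s) !is.na(s$linked_variable_id) &&
           s$linked_variable_id == variable_id, ds@ms2_data$spectra)
}
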