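#' The MassDataset container
#'
#' An S4 class holding all components of a processed LC-MS untargeted
#' metabolomics experiment and keeping them synchronized:
#'
#' * `expression_data`: numeric matrix of intensities, rows = variables
#'   (metabolic features), columns = samples. Missing measurements are
#'   `NA`; zeros read from input stay zeros.
#' * `sample_info`: data frame of sample metadata; first column
#'   `sample_id`, identical (content and order) to the matrix column names.
#' * `variable_info`: data frame of variable metadata; first column
#'   `variable_id` (identical to matrix row names), then `mz` (Daltons)
#'   and `rt` (seconds).
#' * `sample_info_note`, `variable_info_note`: data frames
#'   (`field`, `meaning`) documenting every metadata column.
#' * `ms2_data`: list with elements `spectra` (list of `ms2_spectrum`)
#'   and `source_files` (character).
#' * `annotation_table`: data frame of candidate annotations (possibly
#'   empty), every row referencing a current `variable_id`.
#' * `process_info`: ordered list of [process_record()] objects, one per
#'   mutating operation, non-decreasing in time.
#'
#' Use [create_mass_dataset()] to build one; [validate_mass_dataset()]
#' checks all structural invariants.
#'
#' @name MassDataset-class
#' @aliases MassDataset
#' @exportClass MassDataset
setClass(
  "MassDataset",
  representation(
    expression_data = "matrix",
    sample_info = "data.frame",
    variable_info = "data.frame",
    sample_info_note = "data.frame",
    variable_info_note = "data.frame",
    ms2_data = "list",
    annotation_table = "data.frame",
    process_info = "list"
  )
)

empty_annotation_table <- function() {
  data.frame(
    variable_id = character(0), compound_id = character(0),
    compound_name = character(0), db_id = character(0),
    adduct = character(0), mz_error_ppm = numeric(0),
    rt_error_s = numeric(0), ms2_similarity = numeric(0),
    total_score = numeric(0), msi_level = numeric(0),
    stringsAsFactors = FALSE
  )
}

empty_ms2_data <- function() {
  list(spectra = list(), source_files = character(0))
}

#' Build an MS2 spectrum
#'
#' @param spectrum_id unique spectrum identifier.
#' @param precursor_mz precursor (parent ion) m/z in Daltons.
#' @param precursor_rt precursor retention time in seconds.
#' @param fragments two-column numeric matrix (`mz`, `intensity`); at
#'   least one fragment, intensities non-negative. Fragments are stored
#'   sorted ascending by m/z regardless of input order.
#' @param linked_variable_id `variable_id` of the feature this spectrum
#'   was assigned to, or `NA` when unassigned.
#' @return An object of class `ms2_spectrum`.
#' @export
ms2_spectrum <- function(spectrum_id, precursor_mz, precursor_rt,
                         fragments, linked_variable_id = NA_character_) {
  stopifnot(is.character(spectrum_id), length(spectrum_id) == 1L,
            nzchar(spectrum_id))
  stopifnot(is_scalar_number(precursor_mz), precursor_mz > 0)
  stopifnot(is_scalar_number(precursor_rt))
  fragments <- as.matrix(fragments)
  if (nrow(fragments) < 1L || ncol(fragments) != 2L) {
    stop("`fragments` must be a matrix with columns mz, intensity and at least one row",
         call. = FALSE)
  }
  storage.mode(fragments) <- "double"
  colnames(fragments) <- c("mz", "intensity")
  rownames(fragments) <- NULL
  if (any(fragments[, "intensity"] < 0)) {
    stop("fragment intensities must be non-negative", call. = FALSE)
  }
  fragments <- fragments[order(fragments[, "mz"]), , drop = FALSE]
  structure(
    list(spectrum_id = spectrum_id,
         precursor_mz = as.double(precursor_mz),
         precursor_rt = as.double(precursor_rt),
         fragments = fragments,
         linked_variable_id = as.character(linked_variable_id)),
    class = "ms2_spectrum"
  )
}

#' Build an MS2 spectrum collection
#'
#' @param spectra list of [ms2_spectrum()] objects with unique ids.
#' @param source_files character vector of file provenance.
#' @return An object of class `ms2_collection`.
#' @export
ms2_collection <- function(spectra = list(), source_files = character(0)) {
  stopifnot(is.list(spectra))
  ids <- vapply(spectra, function(s) s$spectrum_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate spectrum_id in collection: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(list(spectra = spectra,
                 source_files = as.character(source_files)),
            class = "ms2_collection")
}

#' Validate every structural invariant of a MassDataset
#'
#' Checks identifier agreement between the expression matrix and the two
#' metadata tables, uniqueness of identifiers, completeness of the note
#' tables, validity of MS2 spectrum links and annotation references, and
#' time ordering of the process history.
#'
#' @param ds a [MassDataset-class] object.
#' @return `TRUE` invisibly if valid, otherwise an error listing every
#'   violated invariant.
#' @export
validate_mass_dataset <- function(ds) {
  problems <- mass_dataset_problems(ds)
  if (length(problems)) {
    stop("invalid MassDataset:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  invisible(TRUE)
}

mass_dataset_problems <- function(ds) {
  problems <- character(0)
  expr <- ds@expression_data
  si <- ds@sample_info
  vi <- ds@variable_info

  if (!is.numeric(expr)) problems <- c(problems, "expression matrix is not numeric")
  if (!identical(names(si)[1], "sample_id")) {
    problems <- c(problems, "first column of sample_info must be sample_id")
  }
  if (!identical(names(vi)[1], "variable_id")) {
    problems <- c(problems, "first column of variable_info must be variable_id")
  }
  if (anyDuplicated(si$sample_id)) {
    problems <- c(problems, paste("duplicate sample_id:",
      paste(unique(si$sample_id[duplicated(si$sample_id)]), collapse = ", ")))
  }
  if (anyDuplicated(vi$variable_id)) {
    problems <- c(problems, paste("duplicate variable_id:",
      paste(unique(vi$variable_id[duplicated(vi$variable_id)]), collapse = ", ")))
  }
  if (!identical(colnames(expr), as.character(si$sample_id))) {
    problems <- c(problems,
      "expression column names do not equal sample_info$sample_id in order")
  }
  if (!identical(rownames(expr), as.character(vi$variable_id))) {
    problems <- c(problems,
      "expression row names do not equal variable_info$variable_id in order")
  }
  note_ok <- function(note, tab, side) {
    if (!all(c("field", "meaning") %in% names(note))) {
      return(sprintf("%s_note must have columns field, meaning", side))
    }
    if (!setequal(note$field, names(tab)) || anyDuplicated(note$field)) {
      return(sprintf(
        "%s_note fields must list every %s column exactly once", side, side))
    }
    NULL
  }
  problems <- c(problems,
                note_ok(ds@sample_info_note, si, "sample_info"),
                note_ok(ds@variable_info_note, vi, "variable_info"))

  ms2 <- ds@ms2_data
  if (!all(c("spectra", "source_files") %in% names(ms2))) {
    problems <- c(problems, "ms2_data must have elements spectra, source_files")
  } else {
    ids <- vapply(ms2$spectra, function(s) s$spectrum_id, character(1))
    if (anyDuplicated(ids)) {
      problems <- c(problems, "duplicate spectrum_id in ms2_data")
    }
    links <- vapply(ms2$spectra, function(s) s$linked_variable_id, character(1))
    bad <- links[!is.na(links) & !(links %in% vi$variable_id)]
    if (length(bad)) {
      problems <- c(problems, paste("MS2 spectra linked to absent variable_id:",
                                    paste(unique(bad), collapse = ", ")))
    }
  }

  ann <- ds@annotation_table
  if (nrow(ann)) {
    bad <- setdiff(ann$variable_id, vi$variable_id)
    if (length(bad)) {
      problems <- c(problems, paste("annotation rows reference absent variable_id:",
                                    paste(bad, collapse = ", ")))
    }
  }

  pi <- ds@process_info
  if (length(pi)) {
    if (!all(vapply(pi, inherits, logical(1), "process_record"))) {
      problems <- c(problems, "process_info entries must be process_record objects")
    } else {
      times <- vapply(pi, function(r) as.numeric(r$time), numeric(1))
      if (is.unsorted(times)) {
        problems <- c(problems, "process_info is not non-decreasing in time")
      }
    }
  }
  problems
}

setValidity("MassDataset", function(object) {
  problems <- mass_dataset_problems(object)
  if (length(problems)) problems else TRUE
})

#' Compact printout of a MassDataset
#' @param object a [MassDataset-class] object.
#' @export
setMethod("show", "MassDataset", function(object) {
  s <- dataset_summary(object)
  cat("MassDataset\n")
  cat(sprintf("  variables : %d\n", s$n_variables))
  cat(sprintf("  samples   : %d\n", s$n_samples))
  cat(sprintf("  missing   : %.1f%%\n", 100 * s$missing_fraction))
  cat(sprintf("  MS2       : %d spectra\n", s$n_ms2_spectra))
  cat(sprintf("  annotation: %d rows\n", s$n_annotation_rows))
  cat(sprintf("  history   : %d steps\n", s$n_process_steps))
  invisible(object)
})
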