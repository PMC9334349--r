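#' Lossless on-disk archive of a MassDataset
#'
#' The archive is a directory of plain-text members: the expression
#' matrix and all metadata/note/annotation tables as bit-stable CSV, MS2
#' spectra as MGF under `ms2/`, the process history as
#' `process_info.json` (record times stored verbatim as epoch seconds)
#' and a `tables.json` sidecar with the column schemas.  The round trip
#' `read_archive(write_archive(ds))` reproduces the dataset exactly,
#' missing-value sentinels, spectra and history included — this is the
#' unit of data sharing between collaborators and between CLI steps.
#'
#' @param ds a [MassDataset-class].
#' @param path archive directory (created; existing members overwritten).
#' @return `path`, invisibly.
#' @export
write_archive <- function(ds, path) {
  stopifnot(is(ds, "MassDataset"))
  validate_mass_dataset(ds)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "ms2"), showWarnings = FALSE)

  expr_df <- data.frame(variable_id = rownames(ds@expression_data),
                        as.data.frame(ds@expression_data, check.names = FALSE),
                        check.names = FALSE, stringsAsFactors = FALSE)
  tables <- list(sample_info = ds@sample_info,
                 variable_info = ds@variable_info,
                 sample_info_note = ds@sample_info_note,
                 variable_info_note = ds@variable_info_note,
                 annotation_table = ds@annotation_table)
  write_table_exact(expr_df, file.path(path, "expression.csv"))
  for (nm in names(tables)) {
    write_table_exact(tables[[nm]], file.path(path, paste0(nm, ".csv")))
  }
  meta <- list(
    format = "masspipe_archive",
    version = 1L,
    schemas = lapply(tables, table_schema),
    ms2_source_files = as.list(ds@ms2_data$source_files)
  )
  writeLines(toJSON(meta, auto_unbox = TRUE, digits = I(17), pretty = TRUE),
             file.path(path, "tables.json"))

  write_mgf(ds@ms2_data$spectra, file.path(path, "ms2", "spectra.mgf"))

  records <- lapply(ds@process_info, function(r) {
    list(package_name = r$package_name,
         function_name = r$function_name,
         time_unix = as.numeric(r$time),
         time_iso = format(r$time, "%Y-%m-%dT%H:%M:%OS6%z"),
         parameters = r$parameters)
  })
  writeLines(toJSON(records, auto_unbox = FALSE, digits = I(17), pretty = TRUE,
                    null = "null"),
             file.path(path, "process_info.json"))
  invisible(path)
}

#' @rdname write_archive
#' @return `read_archive()` returns the reconstructed
#'   [MassDataset-class].
#' @export
read_archive <- function(path) {
  member <- function(name) {
    p <- file.path(path, name)
    if (!file.exists(p)) {
      stop("archive is missing member '", name, "'", call. = FALSE)
    }
    p
  }
  meta <- fromJSON(member("tables.json"), simplifyVector = TRUE,
                   simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!identical(meta$format, "masspipe_archive")) {
    stop("not a masspipe archive: ", path, call. = FALSE)
  }
  tabs <- lapply(setNames(nm = names(meta$schemas)), function(nm) {
    read_table_exact(member(paste0(nm, ".csv")), meta$schemas[[nm]])
  })
  expr_raw <- read.csv(member("expression.csv"), colClasses = "character",
                       check.names = FALSE, fileEncoding = "UTF-8")
  expr <- as.matrix(expr_raw[, -1, drop = FALSE])
  expr <- apply(expr, 2, function(v) { v[v == ""] <- NA; as.numeric(v) })
  if (is.null(dim(expr))) expr <- matrix(expr, nrow = nrow(expr_raw))
  rownames(expr) <- expr_raw[[1]]
  colnames(expr) <- names(expr_raw)[-1]

  spectra <- read_mgf(member(file.path("ms2", "spectra.mgf")))

  rec_raw <- fromJSON(member("process_info.json"), simplifyVector = TRUE,
                      simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  process_info <- lapply(rec_raw, function(r) {
    process_record(
      function_name = r$function_name[[1]],
      parameters = r$parameters,
      package_name = r$package_name[[1]],
      time = as.POSIXct(r$time_unix[[1]], origin = "1970-01-01", tz = "UTC"))
  })

  ds <- new("MassDataset",
            expression_data = expr,
            sample_info = tabs$sample_info,
            variable_info = tabs$variable_info,
            sample_info_note = tabs$sample_info_note,
            variable_info_note = tabs$variable_info_note,
            ms2_data = list(spectra = spectra$spectra,
                            source_files = unlist(meta$ms2_source_files) %||%
                              character(0)),
            annotation_table = tabs$annotation_table,
            process_info = process_info)
  validObject(ds)
  ds
}
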