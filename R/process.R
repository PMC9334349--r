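#' Create a processing record
#'
#' One record describes one processing/analysis step applied to a
#' [MassDataset-class]: the package and function that ran, when, and with
#' which parameters.  Records are stored in the `process_info` slot,
#' ordered by time, and carry enough information for [replay()].
#'
#' Parameter values are restricted to numbers, text, booleans and
#' (nested, named) lists thereof, so that the history serializes to JSON
#' and back without loss; numerics are stored as doubles.
#'
#' @param function_name non-empty name of the operation.
#' @param parameters named list of parameters (possibly nested).
#' @param package_name package that provides the operation.
#' @param time time of execution (`POSIXct`).
#' @return An object of class `process_record`.
#' @export
process_record <- function(function_name, parameters = list(),
                           package_name = "masspipe", time = now_time()) {
  if (!is.character(function_name) || length(function_name) != 1L ||
      !nzchar(function_name)) {
    stop("`function_name` must be a non-empty string", call. = FALSE)
  }
  structure(
    list(package_name = package_name,
         function_name = function_name,
         time = as.POSIXct(time),
         parameters = normalize_parameters(parameters)),
    class = "process_record"
  )
}

#' @export
print.process_record <- function(x, ...) {
  cat(sprintf("<process_record> %s::%s @ %s\n", x$package_name,
              x$function_name, format(x$time, "%Y-%m-%d %H:%M:%OS3")))
  for (nm in names(x$parameters)) {
    v <- x$parameters[[nm]]
    txt <- if (is.list(v)) sprintf("<list of %d>", length(v)) else
      if (length(v) > 6) sprintf("<%d values>", length(v)) else
        paste(format(v), collapse = ", ")
    cat(sprintf("  %s: %s\n", nm, txt))
  }
  invisible(x)
}

normalize_parameters <- function(x) {
  if (!is.list(x)) stop("`parameters` must be a list", call. = FALSE)
  if (length(x) && (is.null(names(x)) || any(!nzchar(names(x))))) {
    stop("all parameters must be named", call. = FALSE)
  }
  lapply(x, function(v) {
    if (is.list(v)) return(normalize_parameters(v))
    if (length(v) == 0L) stop("zero-length parameter values are not allowed",
                              call. = FALSE)
    if (is.numeric(v)) return(as.double(unname(v)))
    if (is.character(v) || is.logical(v)) return(unname(v))
    stop("parameter values must be numeric, character, logical or lists thereof",
         call. = FALSE)
  })
}

# Append a record to a dataset and emit the structured log line.
append_record <- function(ds, function_name, parameters = list(),
                          package_name = "masspipe") {
  rec <- process_record(function_name, parameters, package_name)
  ds@process_info <- c(ds@process_info, list(rec))
  log_op(function_name, rec$parameters, dims = dim(ds@expression_data))
  ds
}

# ---------------------------------------------------------------------------
# Operation registry used by replay() and the pipeline runner.  Handlers
# take (ds, parameters, resources) and return the updated dataset.
# ---------------------------------------------------------------------------

#' Re-execute a recorded processing history
#'
#' Runs the operations of `history` in order on `base`, using the stored
#' parameters (filters are replayed from the recorded identifier sets, so
#' no user predicate is needed).  For deterministic steps, and stochastic
#' steps whose seed was recorded, the result equals the dataset that
#' produced the history component by component; record timestamps are the
#' only field allowed to differ.
#'
#' @param history list of [process_record()] objects (a `process_info`
#'   slot).  Creation records are validated and otherwise skipped.
#' @param base the starting [MassDataset-class].
#' @param resources named list of external objects some steps need again
#'   (e.g. a compound database under its `db_id`, an `ms2_collection`
#'   under `"ms2"`).
#' @return the re-derived [MassDataset-class].
#' @export
replay <- function(history, base, resources = list()) {
  stopifnot(is(base, "MassDataset"))
  ds <- base
  for (i in seq_along(history)) {
    rec <- history[[i]]
    if (!inherits(rec, "process_record")) {
      stop("replay: history entry ", i, " is not a process_record", call. = FALSE)
    }
    if (!exists(rec$function_name, envir = op_registry, inherits = FALSE)) {
      stop("replay: record ", i, " has unknown function_name '",
           rec$function_name, "'", call. = FALSE)
    }
    handler <- get(rec$function_name, envir = op_registry)
    ds <- handler(ds, rec$parameters, resources)
  }
  ds
}

# ---------------------------------------------------------------------------
# Component-wise dataset comparison
# ---------------------------------------------------------------------------

#' Compare two MassDataset objects component by component
#'
#' @param a,b datasets to compare.
#' @param ignore_time if `TRUE` (default) the `time` field of process
#'   records is ignored; only order and content matter.  Replay equality
#'   is defined this way.
#' @return character vector of differing component names
#'   (length zero when the datasets are equal).
#' @export
dataset_diff <- function(a, b, ignore_time = TRUE) {
  stopifnot(is(a, "MassDataset"), is(b, "MassDataset"))
  diffs <- character(0)
  if (!identical_numeric_matrix(a@expression_data, b@expression_data)) {
    diffs <- c(diffs, "expression_data")
  }
  if (!identical_df(a@sample_info, b@sample_info)) diffs <- c(diffs, "sample_info")
  if (!identical_df(a@variable_info, b@variable_info)) diffs <- c(diffs, "variable_info")
  if (!identical_df(a@sample_info_note, b@sample_info_note)) {
    diffs <- c(diffs, "sample_info_note")
  }
  if (!identical_df(a@variable_info_note, b@variable_info_note)) {
    diffs <- c(diffs, "variable_info_note")
  }
  if (!identical_ms2(a@ms2_data, b@ms2_data)) diffs <- c(diffs, "ms2_data")
  if (!identical_df(a@annotation_table, b@annotation_table)) {
    diffs <- c(diffs, "annotation_table")
  }
  if (!identical_history(a@process_info, b@process_info, ignore_time)) {
    diffs <- c(diffs, "process_info")
  }
  diffs
}

#' @rdname dataset_diff
#' @return `dataset_identical()` returns a single logical.
#' @export
dataset_identical <- function(a, b, ignore_time = TRUE) {
  length(dataset_diff(a, b, ignore_time = ignore_time)) == 0L
}

identical_numeric_matrix <- function(x, y) {
  storage.mode(x) <- "double"
  storage.mode(y) <- "double"
  identical(dim(x), dim(y)) && identical(dimnames(x), dimnames(y)) &&
    identical(as.vector(x), as.vector(y))
}

identical_df <- function(x, y) {
  x <- norm_df(x); y <- norm_df(y)
  if (!identical(names(x), names(y)) || nrow(x) != nrow(y)) return(FALSE)
  for (j in seq_along(x)) {
    xv <- x[[j]]; yv <- y[[j]]
    if (is.numeric(xv)) xv <- as.double(xv)
    if (is.numeric(yv)) yv <- as.double(yv)
    if (!identical(unname(xv), unname(yv))) return(FALSE)
  }
  TRUE
}

identical_ms2 <- function(x, y) {
  if (!identical(as.character(x$source_files), as.character(y$source_files))) {
    return(FALSE)
  }
  if (length(x$spectra) != length(y$spectra)) return(FALSE)
  for (i in seq_along(x$spectra)) {
    s <- x$spectra[[i]]; t <- y$spectra[[i]]
    if (!identical(s$spectrum_id, t$spectrum_id)) return(FALSE)
    if (!identical(as.double(s$precursor_mz), as.double(t$precursor_mz))) return(FALSE)
    if (!identical(as.double(s$precursor_rt), as.double(t$precursor_rt))) return(FALSE)
    if (!identical(as.character(s$linked_variable_id),
                   as.character(t$linked_variable_id))) return(FALSE)
    if (!identical_numeric_matrix(s$fragments, t$fragments)) return(FALSE)
  }
  TRUE
}

identical_history <- function(x, y, ignore_time = TRUE) {
  if (length(x) != length(y)) return(FALSE)
  for (i in seq_along(x)) {
    a <- x[[i]]; b <- y[[i]]
    if (!identical(a$package_name, b$package_name)) return(FALSE)
    if (!identical(a$function_name, b$function_name)) return(FALSE)
    if (!identical(a$parameters, b$parameters)) return(FALSE)
    if (!ignore_time &&
        !identical(as.numeric(a$time), as.numeric(b$time))) return(FALSE)
  }
  TRUE
}
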