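#' Create a MassDataset from a peak table and metadata
#'
#' Assembles the synchronized container from the three-table contract of
#' untargeted metabolomics peak tables: an intensity matrix (rows =
#' variables, columns = samples), a sample metadata table whose first
#' column is `sample_id`, and a variable metadata table whose first
#' column is `variable_id` followed by `mz` (Daltons) and `rt` (seconds).
#' Identifier sets must agree with the matrix dimnames; the matrix is
#' reordered to follow the metadata tables.  Note tables are
#' auto-generated with a `"from user"` placeholder meaning for every
#' column, and the process history starts with one creation record
#' capturing the table dimensions.
#'
#' @param expression_data numeric matrix (or data frame) of non-negative
#'   intensities with row and column names; `NA` marks missing values.
#' @param sample_info data frame of sample metadata.
#' @param variable_info data frame of variable metadata with `mz` and
#'   `rt` columns.
#' @return a validated [MassDataset-class].
#' @examples
#' expr <- matrix(1:12, nrow = 3,
#'                dimnames = list(paste0("v", 1:3), paste0("s", 1:4)))
#' si <- data.frame(sample_id = paste0("s", 1:4), class = "Subject")
#' vi <- data.frame(variable_id = paste0("v", 1:3),
#'                  mz = c(100.1, 200.2, 300.3), rt = c(30, 60, 90))
#' ds <- create_mass_dataset(expr, si, vi)
#' @export
create_mass_dataset <- function(expression_data, sample_info, variable_info) {
  expression_data <- as.matrix(expression_data)
  storage.mode(expression_data) <- "double"
  sample_info <- norm_df(sample_info)
  variable_info <- norm_df(variable_info)

  if (!identical(names(sample_info)[1], "sample_id")) {
    stop("first column of `sample_info` must be sample_id", call. = FALSE)
  }
  if (!identical(names(variable_info)[1], "variable_id")) {
    stop("first column of `variable_info` must be variable_id", call. = FALSE)
  }
  if (!all(c("mz", "rt") %in% names(variable_info))) {
    stop("`variable_info` must contain mz and rt columns", call. = FALSE)
  }
  sample_info$sample_id <- as.character(sample_info$sample_id)
  variable_info$variable_id <- as.character(variable_info$variable_id)

  dup_s <- unique(sample_info$sample_id[duplicated(sample_info$sample_id)])
  dup_v <- unique(variable_info$variable_id[duplicated(variable_info$variable_id)])
  if (length(dup_s) || length(dup_v)) {
    stop("duplicate identifiers: ",
         paste(c(dup_s, dup_v), collapse = ", "), call. = FALSE)
  }
  id_mismatch <- function(matrix_ids, table_ids, what) {
    missing_in_table <- setdiff(matrix_ids, table_ids)
    missing_in_matrix <- setdiff(table_ids, matrix_ids)
    if (length(missing_in_table) || length(missing_in_matrix)) {
      stop(what, " identifiers do not match expression labels; ",
           "only in expression: {",
           paste(missing_in_table, collapse = ", "), "}; only in table: {",
           paste(missing_in_matrix, collapse = ", "), "}", call. = FALSE)
    }
  }
  id_mismatch(colnames(expression_data), sample_info$sample_id, "sample")
  id_mismatch(rownames(expression_data), variable_info$variable_id, "variable")

  if (any(expression_data < 0, na.rm = TRUE)) {
    stop("expression matrix contains negative intensities", call. = FALSE)
  }
  expression_data <-
    expression_data[variable_info$variable_id, sample_info$sample_id,
                    drop = FALSE]

  ds <- new(
    "MassDataset",
    expression_data = expression_data,
    sample_info = sample_info,
    variable_info = variable_info,
    sample_info_note = data.frame(field = names(sample_info),
                                  meaning = "from user",
                                  stringsAsFactors = FALSE),
    variable_info_note = data.frame(field = names(variable_info),
                                    meaning = "from user",
                                    stringsAsFactors = FALSE),
    ms2_data = empty_ms2_data(),
    annotation_table = empty_annotation_table(),
    process_info = list()
  )
  ds <- append_record(ds, "create_mass_dataset",
                      list(n_variable = nrow(expression_data),
                           n_sample = ncol(expression_data)))
  validObject(ds)
  ds
}

register_operation("create_mass_dataset", function(ds, params, resources) {
  # creation itself is not re-run; the base dataset plays that role
  ds
})

#' Summary counts for a MassDataset
#'
#' @param ds a [MassDataset-class].
#' @return list with `n_samples`, `n_variables`, `n_ms2_spectra`,
#'   `n_annotation_rows`, `n_process_steps` and the overall
#'   `missing_fraction` of the expression matrix.
#' @export
dataset_summary <- function(ds) {
  stopifnot(is(ds, "MassDataset"))
  expr <- ds@expression_data
  list(
    n_samples = ncol(expr),
    n_variables = nrow(expr),
    n_ms2_spectra = length(ds@ms2_data$spectra),
    n_annotation_rows = nrow(ds@annotation_table),
    n_process_steps = length(ds@process_info),
    missing_fraction = if (length(expr)) mean(is.na(expr)) else 0
  )
}

#' @rdname extract_components
#' @name extract_components
#' @title Extract components of a MassDataset
#' @description Plain accessors returning copies of the container
#'   components.
#' @param ds a [MassDataset-class].
#' @return the requested component.
#' @export
extract_expression_data <- function(ds) ds@expression_data

#' @rdname extract_components
#' @export
extract_sample_info <- function(ds) ds@sample_info

#' @rdname extract_components
#' @export
extract_variable_info <- function(ds) ds@variable_info

#' @rdname extract_components
#' @export
extract_annotation_table <- function(ds) ds@annotation_table

#' @rdname extract_components
#' @export
extract_process_info <- function(ds) ds@process_info

#' @rdname extract_components
#' @export
extract_ms2_data <- function(ds) ds@ms2_data

#' Log-transform the expression matrix
#'
#' Applies `log(x + offset)` in the given base to every observed cell;
#' missing cells stay missing.  Metabolomics intensities are approximately
#' log-normal, so parametric tests are usually run after this step.
#'
#' @param ds a [MassDataset-class].
#' @param base logarithm base (default 2).
#' @param offset added before taking logs (default 1, keeps zeros finite).
#' @return the transformed dataset with one appended process record.
#' @export
log_transform <- function(ds, base = 2, offset = 1) {
  stopifnot(is(ds, "MassDataset"), is_scalar_number(base), base > 0,
            is_scalar_number(offset), offset >= 0)
  ds@expression_data <- log(ds@expression_data + offset, base = base)
  ds <- append_record(ds, "log_transform", list(base = base, offset = offset))
  validObject(ds)
  ds
}

register_operation("log_transform", function(ds, params, resources) {
  log_transform(ds, base = params$base %||% 2, offset = params$offset %||% 1)
})
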