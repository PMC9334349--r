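#' Read the three-file peak-table contract into a MassDataset
#'
#' The standard hand-off from peak-picking software: an expression CSV
#' (first column the variable id, remaining columns one per sample), a
#' sample metadata CSV (first column `sample_id`) and a variable metadata
#' CSV (first column `variable_id`, then `mz` in Daltons and `rt` in
#' seconds).
#'
#' @param expr_path,sample_path,variable_path CSV file paths.
#' @param zero_as_missing some exporters write missing measurements as
#'   zero; `TRUE` converts exact zeros to `NA` on read (default `FALSE`,
#'   zeros are kept as zeros).
#' @return a [MassDataset-class] via [create_mass_dataset()].
#' @export
read_peak_table <- function(expr_path, sample_path, variable_path,
                            zero_as_missing = FALSE) {
  assert_scalar_flag(zero_as_missing, "zero_as_missing")
  expr_df <- read.csv(expr_path, check.names = FALSE, stringsAsFactors = FALSE)
  sample_info <- read.csv(sample_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  variable_info <- read.csv(variable_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (!all(c("mz", "rt") %in% names(variable_info))) {
    stop("variable file must contain mz and rt columns (rt in seconds)",
         call. = FALSE)
  }
  ids <- as.character(expr_df[[1]])
  expr_cells <- expr_df[, -1, drop = FALSE]
  for (j in seq_along(expr_cells)) {
    col <- expr_cells[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & col != "")
      if (length(bad)) {
        stop(sprintf(
          "non-numeric intensity in expression file at row %d, column '%s': \"%s\"",
          bad[1], names(expr_cells)[j], col[bad[1]]), call. = FALSE)
      }
      col <- num
    }
    expr_cells[[j]] <- col
  }
  expr <- as.matrix(expr_cells)
  rownames(expr) <- ids
  if (zero_as_missing) {
    expr[!is.na(expr) & expr == 0] <- NA_real_
  }
  create_mass_dataset(expr, sample_info, variable_info)
}

#' Write the three-file peak-table form of a MassDataset
#'
#' @param ds a [MassDataset-class].
#' @param dir output directory (created if needed); writes
#'   `expression.csv`, `sample_info.csv`, `variable_info.csv`.
#' @return `dir`, invisibly.
#' @export
write_peak_table <- function(ds, dir) {
  stopifnot(is(ds, "MassDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  expr_df <- data.frame(variable_id = rownames(ds@expression_data),
                        as.data.frame(ds@expression_data,
                                      check.names = FALSE),
                        check.names = FALSE, stringsAsFactors = FALSE)
  write_table_exact(expr_df, file.path(dir, "expression.csv"))
  write_table_exact(ds@sample_info, file.path(dir, "sample_info.csv"))
  write_table_exact(ds@variable_info, file.path(dir, "variable_info.csv"))
  invisible(dir)
}
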