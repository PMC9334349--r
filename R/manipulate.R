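# Synchronized subsetting and metadata mutation.

# Add (or replace) a column note so the note table always covers every
# metadata column exactly once.
update_note <- function(note, field, meaning) {
  note <- norm_df(note)
  keep <- note$field != field
  rbind(note[keep, , drop = FALSE],
        data.frame(field = field, meaning = meaning,
                   stringsAsFactors = FALSE)) -> out
  norm_df(out)
}

# Core synchronized subset by sample ids (order preserved as given).
subset_samples <- function(ds, keep_ids) {
  ds@sample_info <- norm_df(ds@sample_info[
    match(keep_ids, ds@sample_info$sample_id), , drop = FALSE])
  ds@expression_data <- ds@expression_data[, keep_ids, drop = FALSE]
  # MS2 spectra are tied to features, not samples: keep them (D3).
  ds
}

# Core synchronized subset by variable ids; annotation rows and MS2 links
# for removed variables are dropped.
subset_variables <- function(ds, keep_ids) {
  ds@variable_info <- norm_df(ds@variable_info[
    match(keep_ids, ds@variable_info$variable_id), , drop = FALSE])
  ds@expression_data <- ds@expression_data[keep_ids, , drop = FALSE]
  ann <- ds@annotation_table
  if (nrow(ann)) {
    ds@annotation_table <- norm_df(ann[ann$variable_id %in% keep_ids, ,
                                       drop = FALSE])
  }
  ds@ms2_data$spectra <- lapply(ds@ms2_data$spectra, function(s) {
    if (!is.na(s$linked_variable_id) &&
        !(s$linked_variable_id %in% keep_ids)) {
      s$linked_variable_id <- NA_character_
    }
    s
  })
  ds
}

#' Filter samples of a MassDataset
#'
#' Removes the samples failing `predicate` from the sample metadata and,
#' synchronously, the corresponding expression columns.  The variable
#' side is untouched.  MS2 spectra are tied to features, not samples, so
#' they are kept.
#'
#' @param ds a [MassDataset-class].
#' @param predicate function taking the `sample_info` data frame and
#'   returning one logical per row (`NA` counts as `FALSE`).
#' @param record append a process record (default `TRUE`).  The record
#'   stores the kept sample ids, which [replay()] uses.
#' @return the filtered dataset.  Removing every sample is an error:
#'   empty datasets fail fast rather than propagate silently.
#' @export
filter_samples <- function(ds, predicate, record = TRUE) {
  stopifnot(is(ds, "MassDataset"), is.function(predicate))
  assert_scalar_flag(record, "record")
  keep <- predicate(ds@sample_info)
  if (!is.logical(keep) || length(keep) != nrow(ds@sample_info)) {
    stop("`predicate` must return one logical per sample_info row",
         call. = FALSE)
  }
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) {
    stop("filter_samples would remove every sample; refusing to create an empty dataset",
         call. = FALSE)
  }
  keep_ids <- ds@sample_info$sample_id[keep]
  ds <- subset_samples(ds, keep_ids)
  if (record) {
    ds <- append_record(ds, "filter_samples",
                        list(kept_sample_ids = keep_ids))
  }
  validObject(ds)
  ds
}

register_operation("filter_samples", function(ds, params, resources) {
  ids <- params$kept_sample_ids
  filter_samples(ds, function(si) si$sample_id %in% ids)
})

#' Filter variables of a MassDataset
#'
#' Mirror of [filter_samples()] on the variable axis: removes failing
#' variables from the variable metadata, the expression rows, their
#' annotation rows, and clears MS2 links pointing at them.
#'
#' @inheritParams filter_samples
#' @param predicate function over the `variable_info` data frame
#'   returning one logical per row.
#' @return the filtered dataset; removing every variable is an error.
#' @export
filter_variables <- function(ds, predicate, record = TRUE) {
  stopifnot(is(ds, "MassDataset"), is.function(predicate))
  assert_scalar_flag(record, "record")
  keep <- predicate(ds@variable_info)
  if (!is.logical(keep) || length(keep) != nrow(ds@variable_info)) {
    stop("`predicate` must return one logical per variable_info row",
         call. = FALSE)
  }
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) {
    stop("filter_variables would remove every variable; refusing to create an empty dataset",
         call. = FALSE)
  }
  keep_ids <- ds@variable_info$variable_id[keep]
  ds <- subset_variables(ds, keep_ids)
  if (record) {
    ds <- append_record(ds, "filter_variables",
                        list(kept_variable_ids = keep_ids))
  }
  validObject(ds)
  ds
}

register_operation("filter_variables", function(ds, params, resources) {
  ids <- params$kept_variable_ids
  filter_variables(ds, function(vi) vi$variable_id %in% ids)
})

#' Add per-variable missing-value frequencies to the variable metadata
#'
#' For each variable, the fraction of missing cells over the given sample
#' subset is stored in a new `na_freq_<label>` column (or `na_freq` when
#' `label` is empty), with the note table updated accordingly.
#'
#' @param ds a [MassDataset-class].
#' @param sample_subset character vector of sample ids to count over;
#'   `NULL` means all samples.
#' @param label suffix for the new column, e.g. `"qc"`.
#' @param record append a process record (default `TRUE`).
#' @return the dataset with the new `variable_info` column.
#' @export
mutate_variable_na_freq <- function(ds, sample_subset = NULL, label = "",
                                    record = TRUE) {
  stopifnot(is(ds, "MassDataset"))
  assert_scalar_flag(record, "record")
  if (is.null(sample_subset)) sample_subset <- ds@sample_info$sample_id
  sample_subset <- as.character(sample_subset)
  if (length(sample_subset) == 0L) {
    stop("`sample_subset` must be non-empty", call. = FALSE)
  }
  unknown <- setdiff(sample_subset, ds@sample_info$sample_id)
  if (length(unknown)) {
    stop("unknown sample_id: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  col <- if (nzchar(label)) paste0("na_freq_", label) else "na_freq"
  freq <- rowMeans(is.na(ds@expression_data[, sample_subset, drop = FALSE]))
  ds@variable_info[[col]] <- unname(freq)
  ds@variable_info_note <- update_note(
    ds@variable_info_note, col,
    sprintf("fraction of missing values over %d samples", length(sample_subset)))
  if (record) {
    ds <- append_record(ds, "mutate_variable_na_freq",
                        list(sample_subset = sample_subset, label = label))
  }
  validObject(ds)
  ds
}

register_operation("mutate_variable_na_freq", function(ds, params, resources) {
  mutate_variable_na_freq(ds, sample_subset = params$sample_subset,
                          label = params$label)
})

#' Merge two MassDataset objects
#'
#' Concatenates two datasets along the sample or the variable axis.  The
#' non-growing axis must carry identical identifier sequences and the
#' growing axis must be collision-free.  Metadata tables are concatenated
#' (columns unioned, absent cells `NA`), MS2 spectra and annotation rows
#' are combined, and the merged history is `a`'s records, then `b`'s,
#' then one merge record.
#'
#' @param a,b datasets to merge.
#' @param axis `"sample"` to append `b`'s samples, `"variable"` to append
#'   `b`'s variables.
#' @return the merged dataset.
#' @export
merge_datasets <- function(a, b, axis = c("variable", "sample")) {
  stopifnot(is(a, "MassDataset"), is(b, "MassDataset"))
  axis <- match.arg(axis)
  if (axis == "variable") {
    if (!identical(a@sample_info$sample_id, b@sample_info$sample_id)) {
      stop("axis=\"variable\" requires identical sample_id sequences",
           call. = FALSE)
    }
    clash <- intersect(a@variable_info$variable_id, b@variable_info$variable_id)
    if (length(clash)) {
      stop("variable_id collision: ", paste(clash, collapse = ", "),
           call. = FALSE)
    }
    expr <- rbind(a@expression_data, b@expression_data)
    variable_info <- rbind_union(a@variable_info, b@variable_info)
    sample_info <- a@sample_info
  } else {
    if (!identical(a@variable_info$variable_id, b@variable_info$variable_id)) {
      stop("axis=\"sample\" requires identical variable_id sequences",
           call. = FALSE)
    }
    clash <- intersect(a@sample_info$sample_id, b@sample_info$sample_id)
    if (length(clash)) {
      stop("sample_id collision: ", paste(clash, collapse = ", "),
           call. = FALSE)
    }
    expr <- cbind(a@expression_data, b@expression_data)
    sample_info <- rbind_union(a@sample_info, b@sample_info)
    variable_info <- a@variable_info
  }
  spectra <- c(a@ms2_data$spectra, b@ms2_data$spectra)
  ids <- vapply(spectra, function(s) s$spectrum_id, character(1))
  if (anyDuplicated(ids)) {
    stop("spectrum_id collision: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  out <- new(
    "MassDataset",
    expression_data = expr,
    sample_info = sample_info,
    variable_info = variable_info,
    sample_info_note = note_for(sample_info, a@sample_info_note,
                                b@sample_info_note),
    variable_info_note = note_for(variable_info, a@variable_info_note,
                                  b@variable_info_note),
    ms2_data = list(spectra = spectra,
                    source_files = union(a@ms2_data$source_files,
                                         b@ms2_data$source_files)),
    annotation_table = rbind_union(a@annotation_table, b@annotation_table),
    process_info = list()
  )
  # keep both histories, then stamp the merge itself
  merged_history <- c(a@process_info, b@process_info)
  times <- vapply(merged_history, function(r) as.numeric(r$time), numeric(1))
  out@process_info <- merged_history[order(times)]
  out <- append_record(out, "merge_datasets",
                       list(axis = axis,
                            n_records_a = length(a@process_info),
                            n_records_b = length(b@process_info)))
  validObject(out)
  out
}

rbind_union <- function(x, y) {
  x <- norm_df(x); y <- norm_df(y)
  if (nrow(x) == 0L && nrow(y) == 0L && identical(names(x), names(y))) return(x)
  all_cols <- union(names(x), names(y))
  pad <- function(df) {
    for (nm in setdiff(all_cols, names(df))) df[[nm]] <- NA
    df[, all_cols, drop = FALSE]
  }
  norm_df(rbind(pad(x), pad(y)))
}

note_for <- function(tab, note_a, note_b) {
  pool <- rbind(norm_df(note_a), norm_df(note_b))
  pool <- pool[!duplicated(pool$field), , drop = FALSE]
  out <- data.frame(field = names(tab), stringsAsFactors = FALSE)
  out$meaning <- pool$meaning[match(out$field, pool$field)]
  out$meaning[is.na(out$meaning)] <- "from merge"
  norm_df(out)
}
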