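# Internal helpers shared across modules.

# Wall-clock time for process records.  When option
# `masspipe.fixed_time_base` is set (the pipeline runner sets it from the
# run seed) a deterministic, strictly increasing clock is used instead so
# that two runs of the same pipeline produce byte-identical archives.
now_time <- function() {
  base <- getOption("masspipe.fixed_time_base", NULL)
  if (is.null(base)) {
    return(Sys.time())
  }
  counter <- getOption("masspipe.fixed_time_counter", 0)
  options(masspipe.fixed_time_counter = counter + 1)
  as.POSIXct(as.numeric(base) + counter, origin = "1970-01-01", tz = "UTC")
}

# Drop row names and factor columns so that data frames compare cleanly
# after subsetting and serialization round trips.
norm_df <- function(df) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    if (is.factor(df[[j]])) df[[j]] <- as.character(df[[j]])
  }
  rownames(df) <- NULL
  df
}

# One structured log line per mutating operation, on stderr.
log_op <- function(operation, parameters = list(), dims = NULL) {
  if (!isTRUE(getOption("masspipe.log", TRUE))) {
    return(invisible(NULL))
  }
  par_txt <- if (length(parameters)) {
    paste(vapply(names(parameters), function(nm) {
      v <- parameters[[nm]]
      v_txt <- if (length(v) > 4) paste0("<", length(v), " values>") else
        paste(format(v), collapse = ",")
      paste0(nm, "=", v_txt)
    }, character(1)), collapse = " ")
  } else ""
  dim_txt <- if (is.null(dims)) "" else
    sprintf(" dims=%dx%d", dims[1], dims[2])
  message(sprintf("[masspipe] %s %s%s", operation, par_txt, dim_txt))
  invisible(NULL)
}

# Format a double so that read-back via as.numeric() is bit-exact.
format_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

assert_scalar_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop("`", name, "` must be TRUE or FALSE", call. = FALSE)
  }
  invisible(x)
}
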