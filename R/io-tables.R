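# Bit-stable CSV serialization used by the archive format.
#
# Dialect: comma separated, UTF-8, "." decimal, missing cell encoded as
# the empty string.  Doubles are written with 17 significant digits so
# that as.numeric() reads them back bit-exactly; a JSON sidecar stores
# the column classes so reading needs no type inference.

table_schema <- function(df) {
  list(columns = as.list(names(df)),
       classes = as.list(vapply(df, function(col) {
         if (is.integer(col)) "integer"
         else if (is.numeric(col)) "numeric"
         else if (is.logical(col)) "logical"
         else "character"
       }, character(1))))
}

write_table_exact <- function(df, path) {
  df <- norm_df(df)
  chr <- df
  for (j in seq_along(chr)) {
    col <- chr[[j]]
    chr[[j]] <- if (is.integer(col)) {
      out <- as.character(col); out[is.na(col)] <- ""; out
    } else if (is.numeric(col)) {
      format_num(col)
    } else if (is.logical(col)) {
      out <- as.character(col); out[is.na(col)] <- ""; out
    } else {
      out <- as.character(col); out[is.na(out)] <- ""; out
    }
  }
  write.csv(chr, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

read_table_exact <- function(path, schema) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  fileEncoding = "UTF-8")
  cols <- unlist(schema$columns)
  classes <- unlist(schema$classes)
  if (nrow(raw) == 0L && length(cols) && !identical(names(raw), cols)) {
    raw <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  }
  stopifnot(identical(names(raw), cols))
  for (j in seq_along(raw)) {
    v <- raw[[j]]
    v[v == ""] <- NA
    raw[[j]] <- switch(classes[j],
                       integer = as.integer(v),
                       numeric = as.numeric(v),
                       logical = as.logical(v),
                       as.character(v))
  }
  norm_df(raw)
}
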