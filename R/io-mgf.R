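#' Read an MGF fragment-spectrum file
#'
#' Parses standard Mascot Generic Format: `BEGIN IONS`/`END IONS` blocks
#' with `PEPMASS`, optional `RTINSECONDS` and `TITLE` headers followed by
#' `m/z intensity` peak lines.  Fragments are stored sorted ascending by
#' m/z regardless of file order.  Blocks without `PEPMASS` are skipped;
#' their count is returned in the `n_skipped` attribute and flagged with
#' a warning.
#'
#' @param path MGF file path.
#' @return an [ms2_collection()]; attribute `n_skipped` counts rejected
#'   blocks.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("MGF file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^BEGIN IONS\\s*$", lines)
  ends <- grep("^END IONS\\s*$", lines)
  if (length(starts) != length(ends)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS", call. = FALSE)
  }
  spectra <- list()
  n_skipped <- 0L
  for (b in seq_along(starts)) {
    block <- lines[(starts[b] + 1L):(ends[b] - 1L)]
    block <- block[nzchar(trimws(block))]
    is_kv <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[is_kv], "=", fixed = TRUE)
    keys <- toupper(vapply(kv, `[`, character(1), 1L))
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
    get_val <- function(key) if (key %in% keys) vals[match(key, keys)] else NA_character_

    pepmass <- get_val("PEPMASS")
    if (is.na(pepmass)) {
      n_skipped <- n_skipped + 1L
      next
    }
    precursor_mz <- as.numeric(strsplit(trimws(pepmass), "\\s+")[[1]][1])
    rt <- suppressWarnings(as.numeric(get_val("RTINSECONDS")))
    if (is.na(rt)) rt <- NA_real_
    title <- get_val("TITLE")
    if (is.na(title)) title <- sprintf("spectrum_%d", b)
    linked <- get_val("LINKED_VARIABLE_ID")

    peak_lines <- trimws(block[!is_kv])
    peak_lines <- peak_lines[nzchar(peak_lines)]
    if (!length(peak_lines)) {
      n_skipped <- n_skipped + 1L
      next
    }
    parts <- strsplit(peak_lines, "\\s+")
    frags <- t(vapply(parts, function(p) as.numeric(p[1:2]), numeric(2)))
    if (anyNA(frags)) {
      n_skipped <- n_skipped + 1L
      next
    }
    spectra[[length(spectra) + 1L]] <- ms2_spectrum(
      spectrum_id = title, precursor_mz = precursor_mz,
      precursor_rt = if (is.na(rt)) 0 else rt, fragments = frags,
      linked_variable_id = if (is.na(linked)) NA_character_ else linked)
  }
  if (n_skipped > 0L) {
    warning(sprintf("read_mgf: skipped %d malformed block(s) in %s",
                    n_skipped, path), call. = FALSE)
  }
  out <- ms2_collection(spectra, source_files = basename(path))
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write an MGF fragment-spectrum file
#'
#' @param spectra an [ms2_collection()] or list of [ms2_spectrum()].
#' @param path output path.
#' @param digits significant digits for m/z and intensity; the default 17
#'   round-trips doubles exactly.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path, digits = 17) {
  if (inherits(spectra, "ms2_collection")) spectra <- spectra$spectra
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", s$spectrum_id), con)
    writeLines(paste0("PEPMASS=", fmt(s$precursor_mz)), con)
    writeLines(paste0("RTINSECONDS=", fmt(s$precursor_rt)), con)
    if (!is.na(s$linked_variable_id)) {
      writeLines(paste0("LINKED_VARIABLE_ID=", s$linked_variable_id), con)
    }
    writeLines(paste(fmt(s$fragments[, "mz"]),
                     fmt(s$fragments[, "intensity"])), con)
    writeLines("END IONS", con)
    writeLines("", con)
  }
  invisible(path)
}
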