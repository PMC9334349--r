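#' Compound databases
#'
#' A compound database holds the reference records metabolite annotation
#' matches against: compound identity, exact (neutral, monoisotopic)
#' mass, optionally an experimental retention time, and optionally one or
#' more library MS2 spectra.  The database type determines the best MSI
#' confidence level its hits can reach: an in-house database (authentic
#' standards run on the same platform, with RT) supports level 1, a
#' public MS2 spectral library level 2, and an MS1-only (mass list)
#' database level 3.
#'
#' @param db_id short database identifier.
#' @param db_type one of `"in_house"`, `"public_ms2"`, `"ms1_only"`.
#' @param compounds list of compound records, each a list with
#'   `compound_id`, `name`, `formula` (or `NA`), `exact_mass` (Daltons,
#'   positive), `rt` (seconds or `NA`; `NA` disables RT scoring for the
#'   compound) and `ms2` (possibly empty list of [ms2_spectrum()]).
#' @return an object of class `compound_database`.
#' @export
compound_database <- function(db_id, db_type = c("in_house", "public_ms2",
                                                 "ms1_only"),
                              compounds = list()) {
  db_type <- match.arg(db_type)
  stopifnot(is.character(db_id), length(db_id) == 1L, nzchar(db_id))
  ids <- vapply(compounds, function(cp) cp$compound_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate compound_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  masses <- vapply(compounds, function(cp) cp$exact_mass, numeric(1))
  if (any(!is.finite(masses) | masses <= 0)) {
    stop("every compound needs a positive exact_mass", call. = FALSE)
  }
  structure(list(db_id = db_id, db_type = db_type, compounds = compounds),
            class = "compound_database")
}

#' @export
print.compound_database <- function(x, ...) {
  n_ms2 <- sum(vapply(x$compounds, function(cp) length(cp$ms2) > 0,
                      logical(1)))
  cat(sprintf("<compound_database> %s (%s): %d compounds, %d with MS2\n",
              x$db_id, x$db_type, length(x$compounds), n_ms2))
  invisible(x)
}

#' Read a compound database from an MSP library file
#'
#' MSP records are blocks of `Key: value` headers followed by
#' `Num Peaks: n` and `n` peak lines.  Recognised keys: `Name`,
#' `COMPOUND_ID`, `Formula`, `PRECURSORMZ`, `ExactMass`, `RT`.
#' A record missing both mass fields, or whose peak count disagrees with
#' `Num Peaks`, is rejected; rejected record indices are returned in the
#' `rejected` attribute.  Records sharing a `COMPOUND_ID` are merged into
#' one compound with several library spectra.
#'
#' @param path MSP file path.
#' @param db_id database identifier (default: file name).
#' @param db_type database class, see [compound_database()].
#' @return a `compound_database`; attribute `rejected` lists rejected
#'   record indices.
#' @export
read_msp <- function(path, db_id = basename(path),
                     db_type = c("in_house", "public_ms2", "ms1_only")) {
  db_type <- match.arg(db_type)
  if (!file.exists(path)) stop("MSP file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  # records are separated by blank lines
  blank <- !nzchar(trimws(lines))
  rec_id <- cumsum(c(TRUE, blank[-length(blank)])) * !blank
  records <- split(lines[!blank], rec_id[!blank])

  compounds <- list()
  rejected <- integer(0)
  for (r in seq_along(records)) {
    rec <- records[[r]]
    kv_idx <- grep("^[A-Za-z_][A-Za-z0-9_ ]*:", rec)
    keys <- toupper(trimws(sub(":.*$", "", rec[kv_idx])))
    vals <- trimws(sub("^[^:]*:", "", rec[kv_idx]))
    get_val <- function(key) if (key %in% keys) vals[match(key, keys)] else NA_character_

    name <- get_val("NAME")
    cid <- get_val("COMPOUND_ID")
    if (is.na(cid)) cid <- name
    mass <- suppressWarnings(as.numeric(get_val("EXACTMASS")))
    prec <- suppressWarnings(as.numeric(get_val("PRECURSORMZ")))
    if (is.na(mass) && is.na(prec)) {
      rejected <- c(rejected, r)
      next
    }
    rt <- suppressWarnings(as.numeric(get_val("RT")))
    formula <- get_val("FORMULA")
    n_peaks_txt <- get_val("NUM PEAKS")
    n_peaks <- suppressWarnings(as.integer(n_peaks_txt))

    peak_lines <- trimws(rec[setdiff(seq_along(rec), kv_idx)])
    peak_lines <- peak_lines[nzchar(peak_lines)]
    spectrum <- NULL
    if (!is.na(n_peaks_txt)) {
      if (is.na(n_peaks) || length(peak_lines) != n_peaks) {
        rejected <- c(rejected, r)
        next
      }
      if (n_peaks > 0L) {
        frags <- t(vapply(strsplit(peak_lines, "[\\s;]+", perl = TRUE),
                          function(p) suppressWarnings(as.numeric(p[1:2])),
                          numeric(2)))
        if (anyNA(frags)) {
          rejected <- c(rejected, r)
          next
        }
        spectrum <- ms2_spectrum(
          spectrum_id = sprintf("%s_lib%d", cid, r),
          precursor_mz = if (!is.na(prec)) prec else mass + 1.007276,
          precursor_rt = if (!is.na(rt)) rt else 0,
          fragments = frags)
      }
    }
    if (is.na(mass)) {
      # PRECURSORMZ alone: assume protonated adduct
      mass <- prec - 1.007276
    }
    if (is.na(name) || !nzchar(name)) name <- cid
    if (cid %in% names(compounds)) {
      if (!is.null(spectrum)) {
        compounds[[cid]]$ms2 <- c(compounds[[cid]]$ms2, list(spectrum))
      }
    } else {
      compounds[[cid]] <- list(
        compound_id = cid, name = name,
        formula = if (is.na(formula)) NA_character_ else formula,
        exact_mass = mass, rt = if (is.na(rt)) NA_real_ else rt,
        ms2 = if (is.null(spectrum)) list() else list(spectrum))
    }
  }
  db <- compound_database(db_id, db_type, unname(compounds))
  attr(db, "rejected") <- rejected
  db
}

#' Write a compound database to an MSP library file
#'
#' Inverse of [read_msp()]: one MSP record per library spectrum, plus one
#' peak-less record for compounds without MS2.  Round-trips all supported
#' fields.
#'
#' @param db a [compound_database()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msp <- function(db, path) {
  stopifnot(inherits(db, "compound_database"))
  fmt <- function(x) sprintf("%.17g", x)
  con <- file(path, "w")
  on.exit(close(con))
  write_one <- function(cp, spectrum) {
    writeLines(paste0("Name: ", cp$name), con)
    writeLines(paste0("COMPOUND_ID: ", cp$compound_id), con)
    if (!is.na(cp$formula)) writeLines(paste0("Formula: ", cp$formula), con)
    writeLines(paste0("ExactMass: ", fmt(cp$exact_mass)), con)
    if (!is.na(cp$rt)) writeLines(paste0("RT: ", fmt(cp$rt)), con)
    if (is.null(spectrum)) {
      writeLines("Num Peaks: 0", con)
    } else {
      writeLines(paste0("PRECURSORMZ: ", fmt(spectrum$precursor_mz)), con)
      writeLines(paste0("Num Peaks: ", nrow(spectrum$fragments)), con)
      writeLines(paste(fmt(spectrum$fragments[, "mz"]),
                       fmt(spectrum$fragments[, "intensity"])), con)
    }
    writeLines("", con)
  }
  for (cp in db$compounds) {
    if (length(cp$ms2) == 0L) {
      write_one(cp, NULL)
    } else {
      for (sp in cp$ms2) write_one(cp, sp)
    }
  }
  invisible(path)
}

#' Read an MS1-only compound database from a CSV table
#'
#' Columns: `compound_id`, `name`, `exact_mass`, optional `formula`,
#' optional `rt` (seconds).
#'
#' @param path CSV path.
#' @param db_id database identifier (default: file name).
#' @param db_type database class (default `"ms1_only"`).
#' @return a [compound_database()].
#' @export
read_compound_table <- function(path, db_id = basename(path),
                                db_type = "ms1_only") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("compound_id", "name", "exact_mass") %in% names(df))) {
    stop("compound table needs columns compound_id, name, exact_mass",
         call. = FALSE)
  }
  compounds <- lapply(seq_len(nrow(df)), function(i) {
    list(compound_id = as.character(df$compound_id[i]),
         name = as.character(df$name[i]),
         formula = if ("formula" %in% names(df)) df$formula[i] else NA_character_,
         exact_mass = df$exact_mass[i],
         rt = if ("rt" %in% names(df)) as.numeric(df$rt[i]) else NA_real_,
         ms2 = list())
  })
  compound_database(db_id, db_type, compounds)
}
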