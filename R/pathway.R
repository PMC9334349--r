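# Pathway database container and over-representation analysis.

#' Pathway database
#'
#' A named collection of pathways, each a set of compound identifiers.
#' Enrichment keys on exact `compound_id` agreement between the query
#' (e.g. annotated differential metabolites) and the pathway members, so
#' both must use the same identifier namespace.
#'
#' @param db_name database name.
#' @param pathways list of pathways, each a list with `pathway_id`
#'   (unique), `name`, `compound_ids` (non-empty character vector).
#' @return an object of class `pathway_database`.
#' @export
pathway_database <- function(db_name, pathways = list()) {
  stopifnot(is.character(db_name), length(db_name) == 1L)
  ids <- vapply(pathways, `[[`, character(1), "pathway_id")
  if (anyDuplicated(ids)) {
    stop("duplicate pathway_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  sizes <- vapply(pathways, function(p) length(p$compound_ids), integer(1))
  if (any(sizes == 0L)) {
    stop("pathways with empty compound sets: ",
         paste(ids[sizes == 0L], collapse = ", "), call. = FALSE)
  }
  structure(list(db_name = db_name, pathways = pathways),
            class = "pathway_database")
}

#' @export
print.pathway_database <- function(x, ...) {
  sizes <- vapply(x$pathways, function(p) length(p$compound_ids), integer(1))
  cat(sprintf("<pathway_database> %s: %d pathways (sizes %s)\n", x$db_name,
              length(x$pathways),
              if (length(sizes)) paste0(min(sizes), "-", max(sizes)) else "-"))
  invisible(x)
}

#' Read/write a pathway database as a long-form CSV
#'
#' Columns `pathway_id`, `pathway_name`, `compound_id`; one row per
#' pathway membership.
#'
#' @param path CSV path.
#' @param db_name database name (default: file name).
#' @return [load_pathway_db()] returns a [pathway_database()].
#' @export
load_pathway_db <- function(path, db_name = basename(path)) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("pathway_id", "pathway_name", "compound_id")
  if (!all(need %in% names(df))) {
    stop("pathway CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  split_idx <- split(seq_len(nrow(df)), df$pathway_id)
  # preserve first-appearance order
  split_idx <- split_idx[unique(df$pathway_id)]
  pathways <- lapply(names(split_idx), function(pid) {
    rows <- split_idx[[pid]]
    nms <- unique(df$pathway_name[rows])
    if (length(nms) > 1) {
      stop("pathway_id '", pid, "' has conflicting names", call. = FALSE)
    }
    list(pathway_id = pid, name = nms,
         compound_ids = unique(df$compound_id[rows]))
  })
  pathway_database(db_name, pathways)
}

#' @rdname load_pathway_db
#' @param db a [pathway_database()].
#' @return `write_pathway_db()` returns `path`, invisibly.
#' @export
write_pathway_db <- function(db, path) {
  stopifnot(inherits(db, "pathway_database"))
  rows <- do.call(rbind, lapply(db$pathways, function(p) {
    data.frame(pathway_id = p$pathway_id, pathway_name = p$name,
               compound_id = p$compound_ids, stringsAsFactors = FALSE)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Filter pathways by size within a universe
#'
#' Pathway sizes are computed after intersecting the member sets with
#' `universe` (standard enrichment hygiene: only measurable compounds
#' count).  Pathways outside `[min_size, max_size]` are dropped; member
#' sets themselves are left intact.
#'
#' @param db a [pathway_database()].
#' @param min_size,max_size inclusive size bounds.
#' @param universe compound universe; `NULL` means no intersection.
#' @return the filtered [pathway_database()].
#' @export
filter_pathways <- function(db, min_size = 1, max_size = Inf,
                            universe = NULL) {
  stopifnot(inherits(db, "pathway_database"))
  keep <- vapply(db$pathways, function(p) {
    k <- if (is.null(universe)) length(p$compound_ids) else
      length(intersect(p$compound_ids, universe))
    k >= min_size && k <= max_size
  }, logical(1))
  structure(list(db_name = db$db_name, pathways = db$pathways[keep]),
            class = "pathway_database")
}

#' Upper-tail hypergeometric p value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` pathway members when `n` query compounds are
#' drawn from a universe of `N` compounds of which `K` are in the
#' pathway.  The observed `k` is included in the tail (standard
#' over-representation convention), so `k = 0` gives exactly 1.
#'
#' @param k overlap between query and pathway.
#' @param K pathway size in the universe.
#' @param n query size.
#' @param N universe size.
#' @return p value in `(0, 1]`.
#' @export
hypergeometric_p <- function(k, K, n, N) {
  if (!(is_scalar_number(k) && is_scalar_number(K) && is_scalar_number(n) &&
        is_scalar_number(N))) {
    stop("k, K, n, N must be single numbers", call. = FALSE)
  }
  if (k < 0 || K > N || n > N || k > min(K, n)) {
    stop("require 0 <= k <= min(K, n) and K, n <= N", call. = FALSE)
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Pathway over-representation analysis
#'
#' Tests every pathway with at least one member in the universe for
#' over-representation of the query compound set, by the upper-tail
#' hypergeometric test or the equivalent one-sided Fisher's exact test,
#' with multiple-testing correction across the tested pathways.
#' Query compounds outside the universe are dropped with a warning.
#' Results are invariant to query and universe order.
#'
#' @param query_ids compound ids of interest (e.g. significant
#'   metabolites); non-empty.
#' @param universe_ids the measurable compound universe.
#' @param db a [pathway_database()].
#' @param test `"hypergeometric"` or `"fisher"`.
#' @param adjust correction method for [stats::p.adjust()]
#'   (default `"BH"`).
#' @return data frame sorted ascending by p value: `pathway_id`, `name`,
#'   `overlap` (k), `pathway_size` (K in universe), `query_size` (n),
#'   `universe_size` (N), `p_value`, `p_value_adjust`,
#'   `overlap_compound_ids` (semicolon-joined).
#' @export
enrich_pathways <- function(query_ids, universe_ids, db,
                            test = c("hypergeometric", "fisher"),
                            adjust = "BH") {
  test <- match.arg(test)
  stopifnot(inherits(db, "pathway_database"))
  query_ids <- unique(as.character(query_ids))
  universe_ids <- unique(as.character(universe_ids))
  if (length(query_ids) == 0L) stop("empty query", call. = FALSE)
  outside <- setdiff(query_ids, universe_ids)
  if (length(outside)) {
    warning("query compounds outside the universe were dropped: ",
            paste(head(outside, 10), collapse = ", "), call. = FALSE)
    query_ids <- intersect(query_ids, universe_ids)
    if (length(query_ids) == 0L) {
      stop("no query compounds inside the universe", call. = FALSE)
    }
  }
  query_ids <- sort(query_ids)
  universe_ids <- sort(universe_ids)
  N <- length(universe_ids)
  n <- length(query_ids)
  rows <- lapply(db$pathways, function(p) {
    members <- intersect(p$compound_ids, universe_ids)
    K <- length(members)
    if (K == 0L) return(NULL)
    overlap <- sort(intersect(members, query_ids))
    k <- length(overlap)
    p_val <- if (test == "hypergeometric") {
      hypergeometric_p(k, K, n, N)
    } else {
      tab <- matrix(c(k, n - k, K - k, N - K - (n - k)), nrow = 2)
      fisher.test(tab, alternative = "greater")$p.value
    }
    data.frame(pathway_id = p$pathway_id, name = p$name, overlap = k,
               pathway_size = K, query_size = n, universe_size = N,
               p_value = p_val,
               overlap_compound_ids = paste(overlap, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    stop("no pathway has members in the universe", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_value_adjust <- p.adjust(out$p_value, method = adjust)
  out <- out[order(out$p_value, out$pathway_id),
             c("pathway_id", "name", "overlap", "pathway_size",
               "query_size", "universe_size", "p_value", "p_value_adjust",
               "overlap_compound_ids")]
  norm_df(out)
}
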