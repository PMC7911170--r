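new_feature_matrix <- function(values, basis, normalized = FALSE,
                               n_imputed = 0L) {
  structure(list(values = values, basis = basis,
                 normalized = normalized, n_imputed = as.integer(n_imputed)),
            class = "feature_matrix")
}

#' Assemble per-sequence motif profiles into a feature matrix
#'
#' One row per sequence (input order), one column per motif; columns are
#' grouped by ascending k and lexicographic within k. The frequency basis
#' fills in observed frequencies `P_obs`; the D-ratio basis fills in
#' `D = P_obs / P_exp`, with undefined D values imputed as 0 (the imputation
#' count is recorded on the object and reported with a message).
#'
#' @param records Data frame of records from [read_fasta()] or a generator.
#' @param basis `"frequency"` or `"dratio"`.
#' @param ks Integer vector of motif lengths (D-ratio requires `ks >= 2`).
#' @param kmax Upper bound on k.
#' @return A `feature_matrix`: list with `values` (numeric matrix, rownames
#'   = sequence ids, colnames = motif names), `basis`, `normalized`,
#'   `n_imputed`.
#' @examples
#' recs <- data.frame(id = c("a", "b"), sequence = c("ACGTACGT", "GGGGCCCC"))
#' build_matrix(recs, basis = "frequency", ks = 2)
#' @export
build_matrix <- function(records, basis = c("frequency", "dratio"), ks,
                         kmax = KMAX_DEFAULT) {
  basis <- match.arg(basis)
  check_records(records)
  ks <- sort(unique(as.integer(ks)))
  kmin <- if (basis == "dratio") 2L else 1L
  for (k in ks) check_k(k, kmin = kmin, kmax = kmax)
  if (length(ks) == 0L) abort_motif("'ks' must name at least one motif length")

  cols <- unlist(lapply(ks, enumerate_motifs, kmax = kmax))
  n_imputed <- 0L
  rows <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, , drop = FALSE]
    unlist(lapply(ks, function(k) {
      if (basis == "frequency") {
        profile_sequence(rec, k, kmax = kmax)[[1]]$pobs
      } else {
        suppressWarnings(dratio_profile(rec, k, kmax = kmax)$d)
      }
    }))
  })
  values <- do.call(rbind, rows)
  dimnames(values) <- list(records$id, cols)
  if (anyNA(values)) {
    n_imputed <- sum(is.na(values))
    message(sprintf("imputed %d undefined D-ratio value(s) as 0", n_imputed))
    values[is.na(values)] <- 0
  }
  new_feature_matrix(values, basis = basis, n_imputed = n_imputed)
}

#' Subset a feature matrix by motif names and/or lengths
#'
#' Selection by `names` and `lengths` is the union of the two. Row order and
#' basis are preserved.
#'
#' @param matrix A `feature_matrix`.
#' @param names Optional character vector of motif names to keep.
#' @param lengths Optional integer vector of motif lengths to keep.
#' @return A `feature_matrix` with the selected columns.
#' @export
select_motifs <- function(matrix, names = NULL, lengths = NULL) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (is.null(names) && is.null(lengths)) {
    abort_motif("give at least one of 'names' or 'lengths'")
  }
  cols <- colnames(matrix$values)
  if (!is.null(names)) {
    unknown <- setdiff(names, cols)
    if (length(unknown)) {
      abort_motif(sprintf("unknown motif name(s): %s",
                          paste(unknown, collapse = ", ")), "lookup")
    }
  }
  keep <- cols %in% names | nchar(cols) %in% lengths
  if (!any(keep)) abort_motif("selection matches no columns", "lookup")
  out <- matrix
  out$values <- matrix$values[, keep, drop = FALSE]
  out
}

#' Max-absolute normalization of a feature matrix
#'
#' Divides the entire matrix by its single largest absolute entry, scaling
#' all values into `[-1, 1]` while preserving every ratio between entries.
#' Idempotent; an all-zero matrix is returned unchanged with a warning.
#'
#' @param matrix A `feature_matrix` with finite entries.
#' @return The normalized `feature_matrix` (`normalized = TRUE`).
#' @export
maxabs_normalize <- function(matrix) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (!all(is.finite(matrix$values))) {
    abort_motif("matrix contains non-finite entries", "computation")
  }
  m <- max(abs(matrix$values))
  if (m == 0) {
    warning("all-zero matrix: max-abs normalization is a no-op", call. = FALSE)
    return(matrix)
  }
  out <- matrix
  out$values <- matrix$values / m
  out$normalized <- TRUE
  out
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature matrix: %d sequences x %d motifs (basis = %s%s%s)\n",
              nrow(x$values), ncol(x$values), x$basis,
              if (x$normalized) ", max-abs normalized" else "",
              if (x$n_imputed > 0)
                sprintf(", %d imputed", x$n_imputed) else ""))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' @export
as.matrix.feature_matrix <- function(x, ...) x$values
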