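#' Read a multi-record DNA FASTA file
#'
#' Parses a plain or line-wrapped FASTA file into a data frame of sequence
#' records. Sequence letters are uppercased and `U` is mapped to `T` so that
#' RNA-notated viral genomes load; any character outside the IUPAC
#' nucleotide alphabet (`A C G T R Y S W K M B D H V N`) raises a validation
#' error naming the record and the offending character. Ambiguity letters
#' are accepted here and handled downstream by window skipping (see
#' [count_kmers()]). Duplicate ids and zero-length records produce warnings,
#' not errors.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with one row per record, in file order, and columns
#'   `id` (first whitespace-delimited header token), `description`
#'   (remainder of the header, possibly `""`), `sequence` (uppercase string)
#'   and `length`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 demo", "acgt", ">s2", "GG", "GG"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort_motif(sprintf("FASTA file not found: %s", path), "format")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort_motif(sprintf("not a readable FASTA file (%s): %s",
                          path, conditionMessage(e)), "format")
    }
  )
  if (length(set) == 0L) {
    abort_motif(sprintf("FASTA file contains no records: %s", path), "format")
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  if (any(ids == "")) {
    abort_motif("FASTA record with empty id (bare '>' header)", "format")
  }
  for (i in seq_along(seqs)) {
    bad <- setdiff(unique(strsplit(seqs[[i]], "", fixed = TRUE)[[1]]), IUPAC_DNA)
    if (length(bad) > 0L) {
      abort_motif(sprintf(
        "record '%s' contains non-IUPAC nucleotide character(s): %s",
        ids[[i]], paste(bad, collapse = ", ")), "validation")
    }
  }
  if (anyDuplicated(ids)) {
    warning(sprintf("duplicate FASTA ids: %s",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")),
            call. = FALSE)
  }
  if (any(nchar(seqs) == 0L)) {
    warning(sprintf("zero-length record(s): %s",
                    paste(ids[nchar(seqs) == 0L], collapse = ", ")),
            call. = FALSE)
  }
  data.frame(id = unname(ids), description = unname(desc),
             sequence = unname(seqs), length = nchar(seqs),
             stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' @param records Data frame as returned by [read_fasta()] (columns `id`,
#'   `sequence`, optional `description`).
#' @param path Output file path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  check_records(records)
  con <- file(path, open = "wt")
  on.exit(close(con))
  desc <- records$description %||% rep("", nrow(records))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(desc[[i]])) paste(records$id[[i]], desc[[i]]) else records$id[[i]]
    writeLines(paste0(">", hdr), con)
    s <- records$sequence[[i]]
    if (nchar(s) > 0L) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    }
  }
  invisible(path)
}

check_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L ||
      !all(c("id", "sequence") %in% names(records))) {
    abort_motif("records must be a non-empty data frame with columns 'id' and 'sequence'")
  }
  invisible(records)
}

# RFC-4180-style quoting: quote only fields containing the delimiter,
# a quote, or a newline; embedded quotes doubled.
quote_field <- function(x, delim) {
  needs <- grepl(delim, x, fixed = TRUE) | grepl('"', x, fixed = TRUE) |
    grepl("\n", x, fixed = TRUE)
  x[needs] <- paste0('"', gsub('"', '""', x[needs], fixed = TRUE), '"')
  x
}

#' Write a feature matrix to delimited text
#'
#' Writes a header row (`sequence_id` followed by the motif names) and one
#' row per sequence. Values are rendered with 12 significant digits so the
#' file round-trips through [read_matrix()] to within 1e-9. Ids containing
#' the delimiter are quoted RFC-4180 style.
#'
#' @param matrix A [feature_matrix] object (see [build_matrix()]).
#' @param path Output file path.
#' @param delimiter `","` or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path, delimiter = c(",", "\t")) {
  delimiter <- match.arg(delimiter)
  if (!inherits(matrix, "feature_matrix")) {
    abort_motif("'matrix' must be a feature_matrix")
  }
  v <- matrix$values
  if (nrow(v) < 1L || ncol(v) < 1L) {
    abort_motif("matrix must have at least one row and one column")
  }
  header <- paste(c("sequence_id", quote_field(colnames(v), delimiter)),
                  collapse = delimiter)
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(quote_field(rownames(v)[i], delimiter),
            sprintf("%.12g", v[i, ])), collapse = delimiter)
  }, character(1))
  ok <- tryCatch({ writeLines(c(header, body), path); TRUE },
                 error = function(e) FALSE)
  if (!ok) abort_motif(sprintf("cannot write matrix to %s", path), "computation")
  invisible(path)
}

#' Read a feature matrix written by [write_matrix()]
#'
#' @param path Input file path.
#' @param delimiter `","` or `"\t"`.
#' @param basis Basis to record on the rebuilt object (the file itself does
#'   not store it).
#' @return A [feature_matrix] object.
#' @export
read_matrix <- function(path, delimiter = c(",", "\t"), basis = "frequency") {
  delimiter <- match.arg(delimiter)
  df <- utils::read.table(path, header = TRUE, sep = delimiter, quote = '"',
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- as.character(df[[1]])
  new_feature_matrix(v, basis = basis, normalized = FALSE, n_imputed = 0L)
}

#' Write cluster labels to delimited text
#'
#' Two-column CSV (`sequence_id,cluster_label`) with 0-based integer labels.
#'
#' @param result A `clustering_result` (see [kmeans_cluster()]).
#' @param path Output file path.
#' @param ids Sequence ids, one per label.
#' @return `path`, invisibly.
#' @export
write_labels <- function(result, path, ids = NULL) {
  if (!inherits(result, "clustering_result") || length(result$labels) == 0L) {
    abort_motif("'result' must be a non-empty clustering_result")
  }
  ids <- ids %||% result$ids %||% paste0("row_", seq_along(result$labels))
  if (length(ids) != length(result$labels)) {
    abort_motif("one id required per label")
  }
  writeLines(c("sequence_id,cluster_label",
               paste(quote_field(ids, ","), result$labels, sep = ",")),
             path)
  invisible(path)
}
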