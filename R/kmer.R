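KMAX_DEFAULT <- 5L

#' Enumerate all k-mer motifs
#'
#' All `4^k` strings over `{A,C,G,T}` in lexicographic order (A < C < G < T).
#'
#' @param k Motif length, between 1 and `kmax`.
#' @param kmax Upper bound on k (default 5: beyond that the motif count
#'   grows too fast to be useful as a per-sequence feature set).
#' @return Character vector of length `4^k`.
#' @examples
#' enumerate_motifs(1)
#' head(enumerate_motifs(3))
#' @export
enumerate_motifs <- function(k, kmax = KMAX_DEFAULT) {
  check_k(k, kmin = 1L, kmax = kmax)
  bases <- c("A", "C", "G", "T")
  grids <- rev(lapply(seq_len(k), function(i) bases))
  do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
}

check_k <- function(k, kmin = 1L, kmax = KMAX_DEFAULT) {
  if (length(k) != 1L || !is.numeric(k) || is.na(k) || k != as.integer(k) ||
      k < kmin || k > kmax) {
    abort_motif(sprintf("k must be a single integer in [%d, %d], got %s",
                        kmin, kmax, deparse(k)))
  }
  as.integer(k)
}

# Accept a record row (data frame), a named/unnamed string, or NULL id.
as_sequence <- function(seq) {
  if (is.data.frame(seq)) {
    check_records(seq)
    if (nrow(seq) != 1L) abort_motif("expected a single sequence record")
    return(list(id = seq$id[[1]], sequence = toupper(seq$sequence[[1]])))
  }
  if (is.character(seq) && length(seq) == 1L) {
    return(list(id = names(seq) %||% "seq", sequence = toupper(seq)))
  }
  abort_motif("'seq' must be a single record row or a single character string")
}

#' Count overlapping k-mers in one sequence
#'
#' Slides a window of length `k` along the sequence and counts every window
#' consisting only of `A/C/G/T`; windows containing any other (ambiguity)
#' letter are skipped and excluded from `valid_windows`, so they enter
#' neither the numerator nor the denominator of downstream frequencies.
#' Counting is delegated to [Biostrings::oligonucleotideFrequency()].
#'
#' @param seq A single record row from [read_fasta()] or a character string.
#' @param k Window length.
#' @param kmax Upper bound on k.
#' @return A `kmer_counts` object: list with `k`, `counts` (named integer
#'   vector over all `4^k` motifs, lexicographic order) and `valid_windows`
#'   (= `sum(counts)`, at most `L - k + 1`).
#' @examples
#' count_kmers("ACGTACGT", 2)
#' @export
count_kmers <- function(seq, k, kmax = KMAX_DEFAULT) {
  k <- check_k(k, kmax = kmax)
  s <- as_sequence(seq)
  motifs <- enumerate_motifs(k, kmax = kmax)
  if (nchar(s$sequence) < k) {
    counts <- stats::setNames(integer(length(motifs)), motifs)
  } else {
    counts <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAString(s$sequence), width = k)
    counts <- counts[motifs]   # defensive: fix the column order contract
  }
  structure(list(k = k, counts = counts,
                 valid_windows = sum(counts), id = s$id),
            class = "kmer_counts")
}

#' Observed motif frequencies from a count table
#'
#' `P_obs(m) = count(m) / valid_windows`: each motif's count divided by the
#' total number of counted windows of the same length, so frequencies over a
#' fixed k sum to 1. A table with no valid windows yields an all-zero
#' profile flagged `degenerate`.
#'
#' @param table A `kmer_counts` object from [count_kmers()].
#' @return A `motif_profile` object: list with `k`, `pobs` (named numeric),
#'   `valid_windows`, `degenerate`.
#' @export
observed_frequency <- function(table) {
  if (!inherits(table, "kmer_counts")) {
    abort_motif("'table' must be a kmer_counts object")
  }
  degenerate <- table$valid_windows == 0L
  pobs <- if (degenerate) {
    stats::setNames(numeric(length(table$counts)), names(table$counts))
  } else {
    table$counts / table$valid_windows
  }
  structure(list(k = table$k, pobs = pobs,
                 valid_windows = table$valid_windows,
                 degenerate = degenerate, id = table$id),
            class = "motif_profile")
}

#' Motif frequency profiles of one sequence at several k
#'
#' @param seq A single record row or character string.
#' @param ks Integer vector of motif lengths.
#' @param kmax Upper bound on k.
#' @return Named list mapping each k (as character) to its `motif_profile`.
#' @examples
#' profile_sequence("ACGT", ks = c(1, 2))
#' @export
profile_sequence <- function(seq, ks, kmax = KMAX_DEFAULT) {
  ks <- unique(as.integer(ks))
  out <- lapply(ks, function(k) observed_frequency(count_kmers(seq, k, kmax = kmax)))
  stats::setNames(out, as.character(ks))
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat(sprintf("k-mer counts (k = %d, %d valid windows)\n", x$k, x$valid_windows))
  nz <- x$counts[x$counts > 0]
  if (length(nz)) print(nz) else cat("  all zero\n")
  invisible(x)
}

#' @export
print.motif_profile <- function(x, ...) {
  cat(sprintf("motif profile (k = %d, %d windows%s)\n", x$k, x$valid_windows,
              if (x$degenerate) ", degenerate" else ""))
  nz <- x$pobs[x$pobs > 0]
  if (length(nz)) print(round(nz, 4)) else cat("  all zero\n")
  invisible(x)
}
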