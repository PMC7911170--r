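BASES <- c("A", "C", "G", "T")

check_probs <- function(p, what = "base_probs") {
  if (length(p) != 4L || any(!is.finite(p)) || any(p < 0) ||
      abs(sum(p) - 1) > 1e-9) {
    abort_motif(sprintf("%s must be 4 non-negative numbers summing to 1", what))
  }
  p
}

synth_ids <- function(n, prefix = "synth") {
  sprintf("%s_%04d", prefix, seq_len(n))
}

#' Generate i.i.d. random DNA sequences
#'
#' Every position drawn independently from `base_probs` (order A, C, G, T).
#' The seed is recorded in each record's description for provenance.
#'
#' @param n_sequences Number of sequences.
#' @param length Sequence length.
#' @param base_probs Probability of A, C, G, T at each position.
#' @param seed Integer seed; identical inputs give identical output.
#' @param prefix Id prefix.
#' @return Record data frame as from [read_fasta()].
#' @examples
#' generate_iid(2, 30, seed = 1)
#' @export
generate_iid <- function(n_sequences, length, base_probs = rep(0.25, 4),
                         seed = 0L, prefix = "synth") {
  check_probs(base_probs)
  if (n_sequences < 1L || length < 1L) {
    abort_motif("n_sequences and length must be positive")
  }
  set.seed(seed)
  seqs <- vapply(seq_len(n_sequences), function(i) {
    paste(sample(BASES, length, replace = TRUE, prob = base_probs),
          collapse = "")
  }, character(1))
  data.frame(id = synth_ids(n_sequences, prefix),
             description = sprintf("iid seed=%d", seed),
             sequence = seqs, length = nchar(seqs),
             stringsAsFactors = FALSE)
}

#' Generate sequences from a stationary Markov chain
#'
#' The first `order` positions are drawn uniformly; every later position is
#' drawn from the transition row of its length-`order` context. Rows of
#' `transition_probs` are indexed by context (rownames = context strings in
#' the order of [enumerate_motifs()]`(order)`), columns by next base
#' (A, C, G, T).
#'
#' @param n_sequences Number of sequences.
#' @param length Sequence length (> order).
#' @param order Markov order (>= 1).
#' @param transition_probs `4^order x 4` row-stochastic matrix.
#' @param seed Integer seed.
#' @param prefix Id prefix.
#' @return Record data frame.
#' @examples
#' tp <- matrix(0.25, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
#' generate_markov(1, 50, order = 1, transition_probs = tp, seed = 1)
#' @export
generate_markov <- function(n_sequences, length, order = 1L,
                            transition_probs, seed = 0L, prefix = "synth") {
  order <- as.integer(order)
  if (order < 1L) abort_motif("order must be >= 1")
  ctx <- enumerate_motifs(order)
  tp <- as.matrix(transition_probs)
  if (!all(dim(tp) == c(4^order, 4L))) {
    abort_motif(sprintf("transition_probs must be %d x 4", 4^order))
  }
  if (is.null(rownames(tp))) rownames(tp) <- ctx
  tp <- tp[ctx, , drop = FALSE]
  for (i in seq_len(nrow(tp))) check_probs(tp[i, ], paste("row", rownames(tp)[i]))
  if (length <= order) abort_motif("length must exceed the Markov order")
  set.seed(seed)
  seqs <- vapply(seq_len(n_sequences), function(s) {
    out <- character(length)
    out[seq_len(order)] <- sample(BASES, order, replace = TRUE)
    for (i in (order + 1L):length) {
      context <- paste(out[(i - order):(i - 1L)], collapse = "")
      out[i] <- sample(BASES, 1L, prob = tp[context, ])
    }
    paste(out, collapse = "")
  }, character(1))
  data.frame(id = synth_ids(n_sequences, prefix),
             description = sprintf("markov order=%d seed=%d", order, seed),
             sequence = seqs, length = nchar(seqs),
             stringsAsFactors = FALSE)
}

#' Generate sequences with planted composition clusters
#'
#' `n_per_cluster` i.i.d. sequences per composition; separability of the
#' planted clusters is controlled by the distance between compositions and
#' the sequence length.
#'
#' @param n_per_cluster Sequences per composition.
#' @param compositions List of >= 2 base-probability 4-vectors.
#' @param length Sequence length.
#' @param seed Integer seed.
#' @return List with `records` (data frame, rows grouped by cluster) and
#'   `labels` (0-based true cluster per record).
#' @examples
#' fx <- planted_clusters(5, list(c(.1,.4,.4,.1), c(.4,.1,.1,.4)), 200, seed = 1)
#' table(fx$labels)
#' @export
planted_clusters <- function(n_per_cluster, compositions, length, seed = 0L) {
  if (!is.list(compositions) || base::length(compositions) < 2L) {
    abort_motif("need at least 2 compositions")
  }
  lapply(compositions, check_probs)
  recs <- vector("list", base::length(compositions))
  for (c_i in seq_along(compositions)) {
    recs[[c_i]] <- generate_iid(n_per_cluster, length,
                                base_probs = compositions[[c_i]],
                                seed = seed + c_i - 1L,
                                prefix = sprintf("clust%d", c_i - 1L))
  }
  records <- do.call(rbind, recs)
  labels <- rep(seq_along(compositions) - 1L, each = n_per_cluster)
  list(records = records, labels = labels)
}

#' Demo preset: an HBV-scale synthetic genome set
#'
#' Five base compositions, `n_sequences` total records of length ~3.2 kb
#' (the whole-genome scale of hepatitis B virus), mimicking the shape of a
#' multi-genotype viral genome collection at desk scale.
#'
#' @param n_sequences Total number of sequences (divided evenly over 5
#'   compositions; remainder goes to the last).
#' @param length Sequence length.
#' @param seed Integer seed.
#' @return As [planted_clusters()].
#' @export
hbv_like_demo <- function(n_sequences = 100L, length = 3200L, seed = 0L) {
  comps <- list(c(0.30, 0.20, 0.20, 0.30),
                c(0.20, 0.30, 0.30, 0.20),
                c(0.35, 0.15, 0.25, 0.25),
                c(0.25, 0.25, 0.15, 0.35),
                c(0.15, 0.35, 0.25, 0.25))
  per <- n_sequences %/% 5L
  if (per < 1L) abort_motif("n_sequences must be >= 5")
  fx <- planted_clusters(per, comps, length, seed = seed)
  extra <- n_sequences - per * 5L
  if (extra > 0L) {
    more <- generate_iid(extra, length, base_probs = comps[[5L]],
                         seed = seed + 5L, prefix = "clust4x")
    fx$records <- rbind(fx$records, more)
    fx$labels <- c(fx$labels, rep(4L, extra))
  }
  fx
}
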