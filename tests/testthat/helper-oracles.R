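# Independent oracles, deliberately naive: these re-derive the quantities
# the package computes through a different route.

# quadratic-time counting oracle: compare every window against every motif
oracle_counts <- function(seq, k) {
  motifs <- enumerate_motifs(k)
  L <- nchar(seq)
  if (L < k) {
    return(stats::setNames(integer(length(motifs)), motifs))
  }
  windows <- substring(seq, seq_len(L - k + 1), k:L)
  vapply(motifs, function(m) sum(windows == m), integer(1))
}

# monolithic D-ratio: count the three motif lengths independently, divide
oracle_dratio <- function(seq, motif) {
  k <- nchar(motif)
  pobs_of <- function(m) {
    cts <- oracle_counts(seq, nchar(m))
    tot <- sum(cts)
    if (tot == 0) return(NA_real_)
    cts[[m]] / tot
  }
  pobs <- pobs_of(motif)
  if (k == 2) {
    pexp <- pobs_of(substr(motif, 1, 1)) * pobs_of(substr(motif, 2, 2))
  } else {
    int <- pobs_of(substr(motif, 2, k - 1))
    if (is.na(int) || int == 0) return(NA_real_)
    pexp <- pobs_of(substr(motif, 1, k - 1)) * pobs_of(substr(motif, 2, k)) / int
  }
  if (is.na(pexp) || pexp == 0) return(NA_real_)
  pobs / pexp
}

# Prim's algorithm on a full pairwise-distance matrix; returns the sorted
# MST edge weights
prim_mst_weights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  weights <- numeric(0)
  while (sum(in_tree) < n) {
    sub <- d[in_tree, !in_tree, drop = FALSE]
    w <- min(sub)
    weights <- c(weights, w)
    j <- which(!in_tree)[which(sub == w, arr.ind = TRUE)[1, "col"]]
    in_tree[j] <- TRUE
  }
  sort(weights)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

random_dna <- function(L, seed, probs = rep(0.25, 4)) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = probs),
        collapse = "")
}

write_tmp_fasta <- function(lines) {
  fa <- tempfile(fileext = ".fasta")
  writeLines(lines, fa)
  fa
}

# fixed strictly-positive transition tables for Markov null checks
order1_tp <- function() {
  tp <- rbind(c(0.40, 0.25, 0.20, 0.15),
              c(0.15, 0.40, 0.25, 0.20),
              c(0.20, 0.15, 0.40, 0.25),
              c(0.25, 0.20, 0.15, 0.40))
  dimnames(tp) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  tp
}

order2_tp <- function(seed = 42) {
  set.seed(seed)
  ctx <- enumerate_motifs(2)
  tp <- matrix(stats::runif(64, min = 0.1, max = 0.4), nrow = 16)
  tp <- tp / rowSums(tp)
  dimnames(tp) <- list(ctx, c("A", "C", "G", "T"))
  tp
}
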