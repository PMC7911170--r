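#' Expected motif frequency under the maximal-order Markov model
#'
#' For a motif of length `k >= 3`,
#' `P_exp(m) = P_obs(prefix) * P_obs(suffix) / P_obs(interior)`,
#' where prefix and suffix are the two overlapping `(k-1)`-mers and the
#' interior is their shared `(k-2)`-mer — the `(k-2)`-order Markov
#' expectation (first order for trinucleotides, second order for
#' tetranucleotides, and so on). For dinucleotides the zeroth-order product
#' of the two mononucleotide frequencies is used. All constituent
#' frequencies come from the same sequence's own profiles.
#'
#' @param motif Motif string of length >= 2 over `{A,C,G,T}`.
#' @param profiles Named list of `motif_profile`s covering orders
#'   `k-1` and `k-2` (or order 1 for `k = 2`), as from [profile_sequence()].
#' @return Expected frequency, or `NA` when the interior frequency is zero
#'   (the expectation is then undefined).
#' @examples
#' p <- profile_sequence("TGGGTGGG", ks = 1:4)
#' expected_frequency("TGGG", p)
#' @export
expected_frequency <- function(motif, profiles) {
  k <- nchar(motif)
  if (k < 2L) {
    abort_motif("motif length must be >= 2 (D is identically 1 for single bases)")
  }
  if (!grepl("^[ACGT]+$", motif)) {
    abort_motif(sprintf("motif must be over {A,C,G,T}: %s", motif))
  }
  if (k == 2L) {
    p1 <- get_profile(profiles, 1L)
    a <- p1$pobs[[substr(motif, 1L, 1L)]]
    b <- p1$pobs[[substr(motif, 2L, 2L)]]
    return(a * b)
  }
  pk1 <- get_profile(profiles, k - 1L)
  pk2 <- get_profile(profiles, k - 2L)
  pre <- pk1$pobs[[substr(motif, 1L, k - 1L)]]
  suf <- pk1$pobs[[substr(motif, 2L, k)]]
  int <- pk2$pobs[[substr(motif, 2L, k - 1L)]]
  if (int == 0) return(NA_real_)
  pre * suf / int
}

get_profile <- function(profiles, k) {
  p <- profiles[[as.character(k)]]
  if (is.null(p) || !inherits(p, "motif_profile")) {
    abort_motif(sprintf("profiles must contain a motif_profile for k = %d", k))
  }
  p
}

#' D-ratio (representation) of one motif
#'
#' `D(m) = P_obs(m) / P_exp(m)`. D > 1 marks over-representation relative to
#' the Markov expectation from the motif's constituents, D < 1
#' under-representation. `NA` when the expectation is zero or undefined;
#' 0 when the motif is absent but expected.
#'
#' @inheritParams expected_frequency
#' @return Non-negative number or `NA`.
#' @examples
#' p <- profile_sequence("TGGGTGGG", ks = 1:4)
#' dratio("TGGG", p)  # 72/35
#' @export
dratio <- function(motif, profiles) {
  pexp <- expected_frequency(motif, profiles)
  pobs <- get_profile(profiles, nchar(motif))$pobs[[motif]]
  if (is.na(pexp) || pexp == 0) return(NA_real_)
  pobs / pexp
}

#' D-ratio profile of a sequence over all motifs of one length
#'
#' Computes D for every one of the `4^k` motifs from a single pass over the
#' required profile orders (`k-2`, `k-1`, `k`, or `{1, 2}` when `k = 2`).
#'
#' @param seq A single record row or character string.
#' @param k Motif length, between 2 and `kmax`.
#' @param kmax Upper bound on k.
#' @return A `dratio_profile` object: list with `k`, `d` and `pexp` (named
#'   numeric vectors, `NA` marking undefined entries) and `degenerate`.
#' @examples
#' dp <- dratio_profile("TGGGTGGG", 4)
#' dp$d[["TGGG"]]
#' @export
dratio_profile <- function(seq, k, kmax = KMAX_DEFAULT) {
  k <- check_k(k, kmin = 2L, kmax = kmax)
  orders <- if (k == 2L) c(1L, 2L) else c(k - 2L, k - 1L, k)
  profiles <- profile_sequence(seq, orders, kmax = kmax)
  pk <- get_profile(profiles, k)
  motifs <- names(pk$pobs)
  degenerate <- any(vapply(profiles, function(p) p$degenerate, logical(1)))
  if (degenerate) {
    warning("sequence too short or too ambiguous for D-ratio at k = ", k,
            ": all values undefined", call. = FALSE)
    na <- stats::setNames(rep(NA_real_, length(motifs)), motifs)
    return(structure(list(k = k, d = na, pexp = na, degenerate = TRUE,
                          id = pk$id), class = "dratio_profile"))
  }
  if (k == 2L) {
    p1 <- get_profile(profiles, 1L)$pobs
    pexp <- p1[substr(motifs, 1L, 1L)] * p1[substr(motifs, 2L, 2L)]
  } else {
    pk1 <- get_profile(profiles, k - 1L)$pobs
    pk2 <- get_profile(profiles, k - 2L)$pobs
    int <- pk2[substr(motifs, 2L, k - 1L)]
    pexp <- pk1[substr(motifs, 1L, k - 1L)] * pk1[substr(motifs, 2L, k)] / int
    pexp[int == 0] <- NA_real_
  }
  names(pexp) <- motifs
  d <- pk$pobs / pexp
  d[!is.na(pexp) & pexp == 0] <- NA_real_  # zero expectation: D undefined
  structure(list(k = k, d = d, pexp = pexp, degenerate = FALSE, id = pk$id),
            class = "dratio_profile")
}

#' @export
print.dratio_profile <- function(x, ...) {
  cat(sprintf("D-ratio profile (k = %d%s): %d defined, %d undefined\n",
              x$k, if (x$degenerate) ", degenerate" else "",
              sum(!is.na(x$d)), sum(is.na(x$d))))
  invisible(x)
}
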