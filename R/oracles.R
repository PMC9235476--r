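#' Exhaustively enumerate annotations with given interval lengths
#'
#' Brute-force reference implementation for validating the sampler and the
#' dynamic program on tiny instances: lists every distinct separated
#' annotation on `[0, L)` whose multiset of interval lengths equals
#' `lens_Q`. Intervals are placed left to right, branching over the
#' distinct remaining lengths at each step so duplicate lengths never
#' produce duplicate annotations. Only feasible for tiny search spaces.
#'
#' @param lens_Q Multiset (vector) of interval lengths.
#' @param L Genome length.
#' @param max_count Refuse to enumerate more than this many annotations.
#' @return List with `annotations` (list of two-column matrices of
#'   start/end pairs) and `count`.
#' @examples
#' enumerate_all_annotations(c(1, 1), 10)$count  # 36
#' @export
enumerate_all_annotations <- function(lens_Q, L, max_count = 1e6) {
  lens_Q <- sort(as.numeric(lens_Q))
  n <- length(lens_Q)
  if (n == 0L)
    return(list(annotations = list(matrix(numeric(0), 0L, 2L)), count = 1L))
  # quick size bound: orderings x gap partitions
  U <- L - sum(lens_Q) - n + 1
  if (U < 0) stop("infeasible lens/L combination")
  n_ord <- exp(lgamma(n + 1) - sum(lgamma(table(lens_Q) + 1)))
  if (n_ord * partition_count(U, n + 1) > max_count)
    stop("search space too large to enumerate")
  acc <- list()
  rec <- function(pos, remaining, placed) {
    if (!length(remaining)) {
      acc[[length(acc) + 1L]] <<- matrix(placed, ncol = 2L, byrow = TRUE)
      return(invisible())
    }
    need <- sum(remaining) + length(remaining) - 1
    for (len in unique(remaining)) {
      rest <- remaining[-match(len, remaining)]
      last_start <- L - need  # leaves room for the rest, separated
      s <- pos
      while (s <= last_start && s + len <= L) {
        rec(s + len + 1, rest, c(placed, s, s + len))
        s <- s + 1
      }
    }
  }
  rec(0, lens_Q, numeric(0))
  list(annotations = acc, count = length(acc))
}

#' Exact gold-standard p-value curve by enumeration
#'
#' Counts the overlap statistic over every annotation enumerated by
#' [enumerate_all_annotations()] and returns the exact tail probabilities
#' under the gold-standard null. Testing counterpart of
#' [estimate_pvalue()].
#'
#' @param R Reference [annotation()].
#' @param lens_Q Query interval lengths.
#' @param L Genome length (defaults to `R$L`).
#' @return A [pvalue_curve()] over `k = 0..length(R)`.
#' @export
exact_gold_pvalues <- function(R, lens_Q, L = R$L) {
  stopifnot(inherits(R, "annotation"))
  en <- enumerate_all_annotations(lens_Q, L)
  m <- length(R)
  K <- vapply(en$annotations, function(iv)
    .overlap_count_sorted(R$starts, R$ends, iv[, 1L], iv[, 2L]), 0L)
  pmf <- tabulate(K + 1L, nbins = m + 1L) / en$count
  pvalue_curve(pmf)
}

#' Exact Markov-chain overlap PMF by path enumeration
#'
#' Sums the probability of every binary state sequence of length `L`
#' (position 0 forced to state 0, free end), binning by the number of
#' reference intervals hit. Testing counterpart of [compute_pmf()];
#' limited to `L <= 18` (2^(L-1) paths). Assumes the first reference
#' interval starts at position 1 or later, matching the convention that
#' position 0 is outside any interval.
#'
#' @param R Reference [annotation()].
#' @param L Genome length (defaults to `R$L`).
#' @param params A [markov_params()] object.
#' @return Numeric PMF vector over `K = 0..length(R)`.
#' @export
exact_mc_pmf <- function(R, L = R$L, params) {
  stopifnot(inherits(R, "annotation"), L <= 18, L >= 1)
  m <- length(R)
  if (m > 0L && R$starts[1L] == 0)
    stop("path-enumeration oracle requires the first reference interval ",
         "to start at position >= 1")
  nfree <- L - 1
  if (nfree == 0L) return(c(1, numeric(m)))
  states <- as.matrix(expand.grid(rep(list(0:1), nfree)))
  tm <- matrix(c(params$t00, params$t10, params$t01, params$t11), 2L, 2L)
  # transition from forced state 0 into position 1, then along the path
  prob <- tm[1L, states[, 1L] + 1L]
  if (nfree > 1L) {
    for (step in seq_len(nfree - 1L)) {
      prob <- prob * tm[cbind(states[, step] + 1L, states[, step + 1L] + 1L)]
    }
  }
  K <- integer(nrow(states))
  for (j in seq_len(m)) {
    cols <- seq.int(max(R$starts[j], 1), R$ends[j] - 1)  # positions = columns
    hit <- if (length(cols) == 1L) states[, cols] > 0
           else rowSums(states[, cols]) > 0
    K <- K + hit
  }
  vapply(0:m, function(k) sum(prob[K == k]), 1)
}

#' Minimum achievable overlap by exhaustive search
#'
#' The smallest `K(R, Q')` over all separated annotations `Q'` with
#' interval lengths `lens_Q` on `[0, L)`, found by exhaustive enumeration
#' with early exit at zero. Deciding whether this minimum is zero is the
#' NP-hard core of the gold-standard p-value problem, so this is only
#' feasible on tiny instances.
#'
#' @inheritParams exact_gold_pvalues
#' @return Integer minimum overlap count.
#' @export
min_overlap <- function(R, lens_Q, L = R$L) {
  stopifnot(inherits(R, "annotation"))
  lens_s <- sort(as.numeric(lens_Q))
  n <- length(lens_s)
  if (n == 0L) return(0L)
  U <- L - sum(lens_s) - n + 1
  if (U < 0) stop("infeasible lens/L combination")
  best <- n + 1L
  rs <- R$starts
  re <- R$ends
  rec <- function(pos, remaining, qs, qe) {
    k <- .overlap_count_sorted(rs, re, qs, qe)
    if (k >= best) return(invisible())  # adding intervals cannot decrease K
    if (!length(remaining)) {
      best <<- k
      return(invisible())
    }
    need <- sum(remaining) + length(remaining) - 1
    for (len in unique(remaining)) {
      rest <- remaining[-match(len, remaining)]
      s <- pos
      while (s + need <= L && s + len <= L) {
        rec(s + len + 1, rest, c(qs, s), c(qe, s + len))
        if (best == 0L) return(invisible())
        s <- s + 1
      }
    }
  }
  rec(0, lens_s, numeric(0), numeric(0))
  as.integer(best)
}
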