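#' Number of ordered b-partitions of U
#'
#' Counts ordered tuples of `b` non-negative integers summing to `U`
#' (stars and bars): `choose(U + b - 1, b - 1)`. These index the gap
#' assignments available to the gold-standard sampler.
#'
#' @param U Non-negative integer (free space).
#' @param b Positive integer (number of parts).
#' @return `choose(U + b - 1, b - 1)` as a double (exact for values
#'   representable in 53 bits).
#' @examples
#' partition_count(7, 3)  # 36
#' @export
partition_count <- function(U, b) {
  stopifnot(U >= 0, b >= 1)
  choose(U + b - 1, b - 1)
}

#' Beta-Binomial CDF used by the gold-standard sampler
#'
#' Cumulative distribution of the first part `u1` of a uniformly chosen
#' ordered partition of `U` into `beta + 1` non-negative parts. This is the
#' Beta-Binomial distribution with `U` trials and shape `alpha = 1`,
#' `beta`; in closed form
#' `Pr[u1 <= i] = 1 - ((U-i+beta-1)! U!) / ((U-i-1)! (U+beta)!)`
#' for `i < U` and 1 for `i >= U`. Evaluated in log-gamma space so that
#' genome-scale `U` does not overflow.
#'
#' @param i Integer quantile(s), vectorized.
#' @param U Number of trials (free space), vectorized.
#' @param beta Second shape parameter: the number of remaining gaps after
#'   the current one (`b - 1` where `b` parts remain in total). `beta = 0`
#'   degenerates to a point mass at `U` (a single gap takes all the free
#'   space).
#' @return Probabilities in `[0, 1]`.
#' @export
beta_binomial_cdf <- function(i, U, beta) {
  stopifnot(all(U >= 0), all(beta >= 0), all(i >= 0))
  n <- max(length(i), length(U), length(beta))
  i <- rep_len(as.numeric(i), n)
  U <- rep_len(as.numeric(U), n)
  beta <- rep_len(as.numeric(beta), n)
  out <- numeric(n)
  full <- i >= U
  out[full] <- 1
  if (any(!full)) {
    ii <- i[!full]; uu <- U[!full]; bb <- beta[!full]
    lt <- lgamma(uu - ii + bb) + lgamma(uu + 1) -
      lgamma(uu - ii) - lgamma(uu + bb + 1)
    out[!full] <- 1 - exp(lt)
  }
  pmin(pmax(out, 0), 1)
}

# Vectorized inverse-transform draw of u1 for a batch of partitions, each
# with its own free space U; beta is shared. Smallest i with y <= CDF(i),
# found by binary search on [0, U].
.rbb_inverse <- function(U, beta) {
  y <- stats::runif(length(U))
  lo <- numeric(length(U))
  hi <- as.numeric(U)
  while (any(lo < hi)) {
    mid <- floor((lo + hi) / 2)
    le <- y <= beta_binomial_cdf(mid, U, beta)
    hi <- ifelse(le, mid, hi)
    lo <- ifelse(le, lo, mid + 1)
  }
  lo
}

#' Draw from the sampler's Beta-Binomial distribution
#'
#' Inverse-transform sampling: draws `y` uniform on (0, 1) and returns the
#' smallest `i` with `y <= Pr[u1 <= i]`, located by binary search over
#' `[0, U]` in `O(log U)` CDF evaluations. Uses R's RNG stream; seed with
#' [set.seed()] for reproducibility.
#'
#' @inheritParams beta_binomial_cdf
#' @param n Number of draws.
#' @return Integer draw(s) in `[0, U]`.
#' @export
sample_beta_binomial <- function(U, beta, n = 1L) {
  stopifnot(length(U) == 1L, U >= 0, beta >= 0)
  .rbb_inverse(rep_len(as.numeric(U), n), beta)
}

# Batch core of the gold-standard sampler: returns an (n_gaps = n+1) x
# n_draws matrix of gap lengths whose columns are uniform draws over all
# separated gap assignments for |Q| = n intervals of total weight w on
# [0, L). Gaps are processed left to right; gap i receives a Beta-Binomial
# share of the remaining free space with beta = n - i + 1 remaining gaps.
.sample_gold_gaps <- function(n, w, L, n_draws = 1L) {
  U <- L - w - n + 1
  if (U < 0)
    stop("infeasible: need weight + |Q| - 1 <= L to place a separated annotation")
  gaps <- matrix(rep(c(0, rep(1, max(n - 1, 0)), 0), n_draws),
                 nrow = n + 1L)
  rem <- rep.int(as.numeric(U), n_draws)
  for (i in seq_len(n)) {
    x <- .rbb_inverse(rem, n - i + 1)
    gaps[i, ] <- gaps[i, ] + x
    rem <- rem - x
  }
  gaps[n + 1L, ] <- gaps[n + 1L, ] + rem
  gaps
}

#' Sample an annotation from the gold-standard null
#'
#' Draws uniformly at random from the set of all separated annotations on
#' `[0, L)` whose interval-length multiset equals `lens_Q` (the
#' permutational, "gold-standard" null). The interval order is a uniform
#' permutation of `lens_Q`; the `|Q| + 1` gap lengths are a uniform ordered
#' partition of the free space `L - weight - |Q| + 1`, built by sequential
#' Beta-Binomial inverse-transform draws. Runs in `O(|Q| log L)`.
#'
#' @param lens_Q Multiset (vector) of interval lengths.
#' @param L Genome length.
#' @param chrom Chromosome name for the returned annotation.
#' @return An [annotation()] with `lens()` equal to `lens_Q` (as a
#'   multiset).
#' @examples
#' set.seed(1)
#' sample_gold(c(1, 1, 2), L = 10)
#' @export
sample_gold <- function(lens_Q, L, chrom = "chr1") {
  n <- length(lens_Q)
  if (n == 0L) return(annotation(numeric(0), numeric(0), L, chrom))
  stopifnot(all(lens_Q >= 1))
  ord <- lens_Q[sample.int(n)]
  g <- .sample_gold_gaps(n, sum(lens_Q), L, 1L)[, 1L]
  starts <- cumsum(g[seq_len(n)]) + c(0, cumsum(ord))[seq_len(n)]
  annotation(starts, starts + ord, L, chrom)
}

#' Overlap counts of many gold-standard draws
#'
#' Draws `n_samples` annotations from the gold-standard null with interval
#' lengths `lens_Q` and returns `K(R, draw)` for each. The gap partitions
#' of all draws are advanced gap-by-gap with the Beta-Binomial binary
#' search vectorized across draws, so the cost is `O(|Q| log L)` vector
#' operations in total.
#'
#' @param R Reference [annotation()].
#' @param lens_Q Query interval lengths.
#' @param L Genome length (defaults to `R$L`).
#' @param n_samples Number of draws.
#' @return Integer vector of length `n_samples` of overlap counts.
#' @export
sample_overlap_counts <- function(R, lens_Q, L = R$L, n_samples = 10000L) {
  stopifnot(inherits(R, "annotation"), n_samples >= 1)
  n <- length(lens_Q)
  if (n == 0L) return(integer(n_samples))
  w <- sum(lens_Q)
  g <- .sample_gold_gaps(n, w, L, n_samples)
  distinct <- length(unique(lens_Q)) > 1L
  lcum0 <- c(0, cumsum(lens_Q))[seq_len(n)]
  rs <- R$starts
  re <- R$ends
  K <- integer(n_samples)
  for (d in seq_len(n_samples)) {
    ord <- if (distinct) lens_Q[sample.int(n)] else lens_Q
    starts <- cumsum(g[seq_len(n), d]) +
      (if (distinct) c(0, cumsum(ord))[seq_len(n)] else lcum0)
    K[d] <- .overlap_count_sorted(rs, re, starts, starts + ord)
  }
  K
}

#' Monte-Carlo p-value under the gold-standard null
#'
#' Estimates the enrichment p-value `Pr[K >= K(R, Q)]` by direct sampling:
#' `n_samples` draws from the gold-standard null with the query's interval
#' lengths, each compared against the reference. When no draw reaches the
#' observed overlap, the true p-value can only be bounded: with 95%
#' confidence it is below `3 / n_samples` (the rule of three).
#'
#' @param R Reference [annotation()].
#' @param Q Query [annotation()] on the same chromosome.
#' @param n_samples Number of null draws (default 10000).
#' @return An object of class `"sampling_estimate"`: list with
#'   `k_observed`, `n_samples`, `n_at_least`, `p_hat`, and `p_bound95`
#'   (`3 / n_samples`, meaningful when `n_at_least` is 0, else `NA`).
#' @export
estimate_pvalue <- function(R, Q, n_samples = 10000L) {
  stopifnot(inherits(R, "annotation"), inherits(Q, "annotation"),
            n_samples >= 1)
  k_obs <- overlap_count(R, Q)
  K <- sample_overlap_counts(R, lens(Q), R$L, n_samples)
  n_ge <- sum(K >= k_obs)
  structure(list(k_observed = k_obs,
                 n_samples = as.integer(n_samples),
                 n_at_least = n_ge,
                 p_hat = n_ge / n_samples,
                 p_bound95 = if (n_ge == 0L) 3 / n_samples else NA_real_),
            class = "sampling_estimate")
}

#' @export
print.sampling_estimate <- function(x, ...) {
  cat(sprintf("Gold-standard sampling estimate: K_obs = %d, %d/%d draws >= K_obs\n",
              x$k_observed, x$n_at_least, x$n_samples))
  if (x$n_at_least == 0L)
    cat(sprintf("  p < %.3g with 95%% confidence (rule of three)\n", x$p_bound95))
  else
    cat(sprintf("  p_hat = %.4g\n", x$p_hat))
  invisible(x)
}
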