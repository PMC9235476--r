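#' Gap/length geometry of a reference annotation
#'
#' Extracts the quantities the dynamic program consumes: interval lengths
#' `l_1..l_m` and gap lengths `g_1..g_{m+1}` measured with the convention
#' `e_0 := 1` (position 0 is forced to state 0, so the chain effectively
#' starts at position 1) and `b_{m+1} := L`. Hence
#' `g_j = b_j - e_{j-1}` and `sum(g_1..g_m) + sum(l) + g_{m+1} = L - 1`.
#'
#' If the first reference interval starts at coordinate 0 the convention
#' would give `g_1 = -1`; in that case all coordinates are shifted by +1
#' and the genome length by +1, which preserves every gap and length
#' except the irrelevant leading gap.
#'
#' @param R Reference [annotation()].
#' @param L Genome length (defaults to `R$L`).
#' @return List with `m`, `g` (length `m + 1`), `l` (length `m`).
#' @export
geometry <- function(R, L = R$L) {
  stopifnot(inherits(R, "annotation"))
  starts <- R$starts
  ends <- R$ends
  m <- length(starts)
  if (m > 0L && starts[1L] == 0) {
    starts <- starts + 1
    ends <- ends + 1
    L <- L + 1
  }
  b <- c(starts, L)
  e <- c(1, ends)
  list(m = m, g = b - e, l = ends - starts)
}

#' No-hit step matrix for one reference interval
#'
#' 2x2 matrix whose `(i, i')` entry is the probability of crossing the
#' `j`th reference interval without the chain ever entering state 1 inside
#' it, ending in state `i'`, given state `i` just before the preceding
#' gap: `T^{g_j} %*% Tmod^{l_j}`. Its second column is zero (ending in
#' state 1 at the interval's last base would itself be a hit).
#'
#' @param j Reference interval index, 1-based.
#' @param geom Output of [geometry()].
#' @param params A [markov_params()] object.
#' @return A 2x2 matrix.
#' @export
p_nohit <- function(j, geom, params) {
  stopifnot(j >= 1, j <= geom$m)
  power_T(params, geom$g[j]) %*% power_Tmod(params, geom$l[j])
}

#' Hit step matrix for one reference interval
#'
#' Complement of [p_nohit()]: the probability of crossing the `j`th
#' reference interval with at least one state-1 position inside it,
#' `T^{g_j} %*% (T^{l_j} - Tmod^{l_j})`. Equivalently
#' `T^{g_j + l_j} - p_nohit(j)`. Negative floating-point dust from the
#' subtraction is clipped at zero.
#'
#' @inheritParams p_nohit
#' @return A 2x2 matrix with entries in `[0, 1]`.
#' @export
p_hit <- function(j, geom, params) {
  stopifnot(j >= 1, j <= geom$m)
  D <- power_T(params, geom$l[j]) - power_Tmod(params, geom$l[j])
  if (min(D) < -1e-12)
    stop("internal error: hit-matrix subtraction lost more than 1e-12")
  D[D < 0] <- 0
  power_T(params, geom$g[j]) %*% D
}

#' Exact overlap-count PMF under the Markov-chain null
#'
#' Computes the full probability mass function of `K(R, Q_rand)` — the
#' number of reference intervals hit by a random query — when the query is
#' generated by the two-state Markov chain fitted to `Q` by maximum
#' likelihood. The dynamic program walks the reference intervals left to
#' right; its state is, for every possible hit count `kappa`, the joint
#' probability of that count and the chain state at the current interval's
#' last base. Each of the `O(m^2)` cells costs `O(1)` (2x2 matrix algebra
#' with closed-form matrix powers), so time is `O(m^2 + n)` and memory
#' `O(m)`, independent of the genome length. The sequence after the last
#' reference interval never affects `K` and is not conditioned on.
#'
#' @param R Reference [annotation()] with `m` intervals.
#' @param Q Query [annotation()] used to fit the null (ignored if `params`
#'   is supplied).
#' @param L Genome length (defaults to `R$L`).
#' @param params Optionally, [markov_params()] to use directly instead of
#'   fitting to `Q`.
#' @return Numeric vector `q[1..m+1]` with `q[k + 1] = Pr[K = k]`; sums to
#'   1 within 1e-9. An empty query yields a point mass at 0.
#' @examples
#' R <- annotation(c(6, 14), c(8, 16), L = 22)
#' Q <- annotation(c(1, 10), c(3, 13), L = 22)
#' compute_pmf(R, Q)
#' @export
compute_pmf <- function(R, Q = NULL, L = R$L, params = NULL) {
  stopifnot(inherits(R, "annotation"))
  m <- length(R$starts)
  if (is.null(params)) {
    stopifnot(inherits(Q, "annotation"))
    if (length(Q$starts) == 0L) return(c(1, numeric(m)))
    params <- fit_params(Q, L)
  }
  if (m == 0L) return(1)
  geom <- geometry(R, L)
  # rows kappa = 0..m, columns = chain state (0, 1) at e_j - 1
  P <- matrix(0, m + 1L, 2L)
  P[1L, 1L] <- 1
  for (j in seq_len(m)) {
    A <- p_nohit(j, geom, params)
    B <- p_hit(j, geom, params)
    Pn <- P %*% A
    Pn[-1L, ] <- Pn[-1L, ] + P[-(m + 1L), ] %*% B
    P <- Pn
  }
  q <- rowSums(P)
  q[q < 0] <- 0
  q
}

#' Tail-probability curves from an overlap PMF
#'
#' @param pmf Numeric PMF vector over `K = 0..m` (e.g. from
#'   [compute_pmf()]).
#' @return An object of class `"pvalue_curve"`: list with `p` (enrichment
#'   tails, `p[k + 1] = Pr[K >= k]`, non-increasing with `p[1] = 1`) and
#'   `d` (depletion tails, `d[k + 1] = Pr[K <= k]`).
#' @export
pvalue_curve <- function(pmf) {
  stopifnot(is.numeric(pmf), length(pmf) >= 1)
  structure(list(p = rev(cumsum(rev(pmf))), d = cumsum(pmf)),
            class = "pvalue_curve")
}

#' @export
print.pvalue_curve <- function(x, ...) {
  m <- length(x$p) - 1L
  cat(sprintf("P-value curve over K = 0..%d\n", m))
  show <- seq_len(min(m + 1L, 8L))
  cat("  Pr[K >= k]:", format(signif(x$p[show], 4)),
      if (m + 1L > 8L) "..." else "", "\n")
  invisible(x)
}

#' Critical overlap count at a significance level
#'
#' The smallest `k` whose upper-tail probability `Pr[K >= k]` is at most
#' `alpha`; observed overlaps at or above it are significant. Returns
#' `m + 1` when even `Pr[K >= m]` exceeds `alpha`.
#'
#' @param pmf Numeric PMF vector over `K = 0..m`.
#' @param alpha Significance level in (0, 1).
#' @return Integer critical value in `0..(m + 1)`.
#' @export
critical_value <- function(pmf, alpha = 0.05) {
  stopifnot(alpha > 0, alpha <= 1)
  p <- pmin(rev(cumsum(rev(pmf))), 1)  # cap rounding excess above 1
  k <- which(p <= alpha)
  if (length(k)) k[1L] - 1L else length(pmf)
}

#' Enrichment and depletion p-values at an observed overlap
#'
#' Because the full PMF is available, both tails are exact:
#' `p_enrich = Pr[K >= k_obs]` and `p_deplete = Pr[K <= k_obs]` (their sum
#' is `1 + Pr[K = k_obs]`).
#'
#' @param pmf Numeric PMF vector over `K = 0..m`.
#' @param k_observed Observed overlap count, in `0..m`.
#' @return List with `p_enrich` and `p_deplete`.
#' @export
enrichment_depletion <- function(pmf, k_observed) {
  m <- length(pmf) - 1L
  if (k_observed < 0 || k_observed > m)
    stop("k_observed must be in 0..", m)
  cur <- pvalue_curve(pmf)
  list(p_enrich = cur$p[k_observed + 1L],
       p_deplete = cur$d[k_observed + 1L])
}
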