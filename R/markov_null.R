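#' Fit the two-state Markov-chain null to a query annotation
#'
#' The Markov-chain null hypothesis generates the query by a two-state
#' chain over genome positions, state 0 = outside an interval, state 1 =
#' inside. The maximum-likelihood transition probabilities given an
#' observed query `Q` on a genome of length `L` are
#' `t01 = |Q| / (L - weight(Q) - 1)` and `t10 = |Q| / weight(Q)`, so the
#' expected interval and gap lengths asymptotically match the query's
#' average interval and gap lengths (interval lengths are implicitly
#' geometric).
#'
#' @param Q Query [annotation()] with at least one interval.
#' @param L Genome length (defaults to `Q$L`).
#' @return An object of class `"markov_params"`: list with `t01`, `t10`,
#'   `t00`, `t11`.
#' @examples
#' Q <- annotation(c(10, 50), c(12, 52), L = 100)
#' fit_params(Q)  # t01 = 2/95, t10 = 0.5
#' @export
fit_params <- function(Q, L = Q$L) {
  stopifnot(inherits(Q, "annotation"))
  n <- length(Q$starts)
  if (n == 0L)
    stop("degenerate null: the query annotation is empty ",
         "(the overlap count is deterministically 0)")
  w <- annotation_weight(Q)
  if (L - w - 1 <= n)
    stop("query too dense: maximum-likelihood fit requires ",
         "L - weight(Q) - 1 > |Q| (got L - weight - 1 = ", L - w - 1,
         ", |Q| = ", n, ")")
  markov_params(t01 = n / (L - w - 1), t10 = n / w)
}

#' Construct two-state Markov-chain parameters
#'
#' @param t01 Probability of leaving state 0 (entering an interval).
#' @param t10 Probability of leaving state 1 (ending an interval).
#' @return An object of class `"markov_params"`.
#' @export
markov_params <- function(t01, t10) {
  stopifnot(t01 > 0, t01 < 1, t10 > 0, t10 <= 1)
  structure(list(t01 = t01, t10 = t10, t00 = 1 - t01, t11 = 1 - t10),
            class = "markov_params")
}

#' @export
print.markov_params <- function(x, ...) {
  cat(sprintf("Two-state Markov chain: t01 = %.6g, t10 = %.6g\n", x$t01, x$t10))
  invisible(x)
}

# transition matrix; rows/cols ordered (state 0, state 1)
.T_matrix <- function(params) {
  matrix(c(params$t00, params$t10, params$t01, params$t11), 2L, 2L)
}

.Tmod_matrix <- function(params) {
  matrix(c(params$t00, params$t10, 0, 0), 2L, 2L)
}

.mat_pow_squaring <- function(M, a) {
  out <- diag(2)
  base <- M
  while (a > 0) {
    if (a %% 2 == 1) out <- out %*% base
    a <- a %/% 2
    if (a > 0) base <- base %*% base
  }
  out
}

#' a-step transition matrix of the fitted chain
#'
#' Returns `T^a` for the two-state transition matrix. For large exponents
#' the closed-form eigendecomposition is used: the eigenvalues are 1 and
#' `lambda = t00 - t10 = 1 - t01 - t10`, giving
#' `T^a = P_stat + lambda^a * D` with the stationary projector `P_stat`.
#' For small exponents (`a <= 50`), or when `t00 == t10` (eigenvalue 0),
#' exponentiation by squaring is used instead. `lambda^a` underflowing to 0
#' is the correct stationary limit.
#'
#' @param params A [markov_params()] object.
#' @param a Non-negative integer exponent.
#' @return A 2x2 row-stochastic matrix.
#' @export
power_T <- function(params, a) {
  stopifnot(a >= 0)
  if (a == 0) return(diag(2))
  if (a <= 50 || params$t00 == params$t10)
    return(.mat_pow_squaring(.T_matrix(params), a))
  s <- params$t01 + params$t10
  rho0 <- params$t10 / s
  rho1 <- params$t01 / s
  lam_a <- (params$t00 - params$t10)^a
  matrix(c(rho0 + rho1 * lam_a, rho0 - rho0 * lam_a,
           rho1 - rho1 * lam_a, rho1 + rho0 * lam_a), 2L, 2L)
}

#' a-step matrix of the zero-state-restricted chain
#'
#' `Tmod` is the transition matrix with all transitions into state 1
#' zeroed, so `(Tmod^a)[i, i']` is the probability of taking `a` steps all
#' landing in state 0 (ending in `i'`). In closed form, for `a >= 1`,
#' `Tmod^a = [[t00^a, 0], [t10 * t00^(a-1), 0]]`; `a = 0` gives the
#' identity.
#'
#' @inheritParams power_T
#' @return A 2x2 matrix with zero second column for `a >= 1`.
#' @export
power_Tmod <- function(params, a) {
  stopifnot(a >= 0)
  if (a == 0) return(diag(2))
  t00 <- params$t00
  matrix(c(t00^a, params$t10 * t00^(a - 1), 0, 0), 2L, 2L)
}

#' Unrestricted a-step transition probability
#'
#' Probability of being in state `i_prime` given that `a` positions
#' earlier the state was `i`: entry `(i, i_prime)` of `T^a`.
#'
#' @param i,i_prime States, 0 or 1.
#' @param a Number of steps.
#' @param params A [markov_params()] object.
#' @return A probability.
#' @export
z_any <- function(i, a, i_prime, params) {
  stopifnot(i %in% 0:1, i_prime %in% 0:1)
  power_T(params, a)[i + 1L, i_prime + 1L]
}

#' All-zeros a-step transition probability
#'
#' Probability that the next `a` states are all zero, the last being
#' `i_prime`, given current state `i`: entry `(i, i_prime)` of `Tmod^a`.
#' Zero whenever `i_prime = 1` and `a >= 1`.
#'
#' @inheritParams z_any
#' @return A probability.
#' @export
z_zeros <- function(i, a, i_prime, params) {
  stopifnot(i %in% 0:1, i_prime %in% 0:1)
  power_Tmod(params, a)[i + 1L, i_prime + 1L]
}
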