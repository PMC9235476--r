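#' Combine per-chromosome overlap PMFs
#'
#' Under the per-chromosome null the counts are independent, so the
#' genome-wide overlap count is their sum and its PMF is the sequential
#' convolution of the per-chromosome PMFs. Direct (non-FFT) convolution
#' keeps the result exact to rounding; the total cost over `N`
#' chromosomes with `m` reference intervals each is `O(N m^2)`.
#'
#' @param pmfs List of numeric PMF vectors (each over `K = 0..m_c`).
#' @return Numeric PMF over `K = 0..sum(m_c)`; an empty list gives a point
#'   mass at 0.
#' @export
combine_pmfs <- function(pmfs) {
  stopifnot(is.list(pmfs))
  out <- 1
  for (q in pmfs) {
    stopifnot(is.numeric(q), length(q) >= 1)
    out <- .conv(out, q)
  }
  out
}

.conv <- function(p, q) {
  if (length(q) == 1L) return(p * q)
  if (length(p) == 1L) return(q * p)
  r <- numeric(length(p) + length(q) - 1L)
  iq <- seq_along(q) - 1L
  for (i in seq_along(p)) r[i + iq] <- r[i + iq] + p[i] * q
  r
}

#' Genome-wide overlap significance under the Markov-chain null
#'
#' Orchestrates the per-chromosome analysis: fits the null to each
#' chromosome's query, runs the dynamic program against that chromosome's
#' reference, convolves the per-chromosome PMFs into a genome-wide PMF,
#' and evaluates both tails at the observed total overlap
#' `sum_c K(R_c, Q_c)`. Chromosomes with an empty query contribute a point
#' mass at zero overlaps (their reference intervals cannot be hit);
#' chromosomes with an empty reference contribute nothing.
#'
#' @param multi_R Reference [multi_annotation()].
#' @param multi_Q Query [multi_annotation()] on the same genome table.
#' @param alpha Significance level for the critical value.
#' @param pooled_fit If `TRUE`, fit a single set of transition
#'   probabilities from the query intervals pooled across chromosomes
#'   (total count, weight and genome length) and use it on every
#'   chromosome; by default each chromosome is fitted from its own query.
#' @return List with `per_chrom` (data frame: chrom, m, n, K, t01, t10,
#'   critical value), `pmf` (combined), `k_observed`, `p_enrich`,
#'   `p_deplete`, `critical`, `alpha`.
#' @export
genome_pvalue <- function(multi_R, multi_Q, alpha = 0.05, pooled_fit = FALSE) {
  stopifnot(inherits(multi_R, "multi_annotation"),
            inherits(multi_Q, "multi_annotation"))
  if (!identical(multi_R$genome, multi_Q$genome))
    stop("reference and query use different genome tables")
  genome <- multi_R$genome
  pooled <- NULL
  if (pooled_fit) {
    n_tot <- sum(vapply(multi_Q$annotations, length, 1L))
    w_tot <- sum(vapply(multi_Q$annotations, annotation_weight, 1))
    if (n_tot == 0L)
      stop("pooled fit impossible: all queries are empty")
    L_tot <- sum(genome)
    if (L_tot - w_tot - 1 <= n_tot)
      stop("pooled query too dense for a maximum-likelihood fit")
    pooled <- markov_params(t01 = n_tot / (L_tot - w_tot - 1),
                            t10 = n_tot / w_tot)
  }
  rows <- list()
  pmfs <- list()
  k_tot <- 0L
  for (ch in names(genome)) {
    R_c <- multi_R$annotations[[ch]]
    Q_c <- multi_Q$annotations[[ch]]
    m_c <- length(R_c)
    n_c <- length(Q_c)
    K_c <- overlap_count(R_c, Q_c)
    k_tot <- k_tot + K_c
    if (m_c == 0L) {
      pmf_c <- 1
      par_c <- NULL
    } else if (n_c == 0L && is.null(pooled)) {
      pmf_c <- c(1, numeric(m_c))
      par_c <- NULL
    } else {
      par_c <- if (is.null(pooled)) fit_params(Q_c, genome[[ch]]) else pooled
      pmf_c <- compute_pmf(R_c, L = genome[[ch]], params = par_c)
    }
    pmfs[[ch]] <- pmf_c
    rows[[ch]] <- data.frame(
      chrom = ch, m = m_c, n = n_c, K = K_c,
      t01 = if (is.null(par_c)) NA_real_ else par_c$t01,
      t10 = if (is.null(par_c)) NA_real_ else par_c$t10,
      critical = critical_value(pmf_c, alpha))
  }
  pmf <- combine_pmfs(pmfs)
  tails <- enrichment_depletion(pmf, k_tot)
  list(per_chrom = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       pmf = pmf,
       k_observed = k_tot,
       p_enrich = tails$p_enrich,
       p_deplete = tails$p_deplete,
       critical = critical_value(pmf, alpha),
       alpha = alpha)
}
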