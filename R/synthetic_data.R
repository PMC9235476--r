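#' Specification of a synthetic annotation
#'
#' The simulation design used throughout the package's experiments: a
#' chromosome of length `L` carries `n_intervals` intervals of identical
#' length, placed uniformly at random among all separated arrangements
#' (the gold-standard sampler). *Coverage* is the fraction of the
#' chromosome covered; the common interval length is
#' `floor(coverage * L / n_intervals)`, at least 1.
#'
#' @param L Chromosome length.
#' @param n_intervals Number of intervals.
#' @param coverage Fraction of covered bases, in (0, 1).
#' @return An object of class `"sim_spec"`.
#' @examples
#' sim_spec(1e6, 50, 0.005)  # 50 intervals of length 100
#' @export
sim_spec <- function(L, n_intervals, coverage) {
  stopifnot(L >= 1, n_intervals >= 1, coverage > 0, coverage < 1)
  len <- max(1, floor(coverage * L / n_intervals + 1e-9))
  if (n_intervals * len + n_intervals - 1 > L)
    stop("infeasible spec: ", n_intervals, " separated intervals of length ",
         len, " do not fit on a chromosome of length ", L)
  structure(list(L = L, n_intervals = as.integer(n_intervals),
                 coverage = coverage, interval_length = len),
            class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf("Synthetic annotation spec: L = %s, %d intervals of length %d (coverage %.4g)\n",
              format(x$L, big.mark = ","), x$n_intervals, x$interval_length,
              x$coverage))
  invisible(x)
}

#' Simulate an annotation of fixed-length intervals
#'
#' Draws the interval locations uniformly at random via [sample_gold()].
#'
#' @param spec A [sim_spec()].
#' @param chrom Chromosome name.
#' @return An [annotation()].
#' @export
simulate_annotation <- function(spec, chrom = "chr1") {
  stopifnot(inherits(spec, "sim_spec"))
  sample_gold(rep.int(spec$interval_length, spec$n_intervals), spec$L, chrom)
}

#' Convert a Markov state path to an annotation
#'
#' Each maximal run of 1-states becomes one interval.
#'
#' @param states Vector of 0/1 states over positions `0..L-1`.
#' @param chrom Chromosome name.
#' @return An [annotation()] with `L = length(states)`.
#' @examples
#' states_to_annotation(c(0, 0, 0, 1, 1, 1, 0, 1, 1, 0, 1, 0))
#' # intervals [3,6), [7,9), [10,11)
#' @export
states_to_annotation <- function(states, chrom = "chr1") {
  L <- length(states)
  stopifnot(L >= 1, all(states %in% 0:1))
  r <- rle(as.integer(states))
  ends <- cumsum(r$lengths)
  one <- r$values == 1L
  annotation((ends - r$lengths)[one], ends[one], L, chrom)
}

#' Simulate an annotation from the two-state Markov chain
#'
#' Generates the state path position by position: state 0 forced at
#' position 0, then `L - 1` transitions; contiguous 1-runs become
#' intervals. Implemented by alternating geometric sojourn times (the
#' run-length representation of the chain), so the cost is proportional to
#' the number of runs rather than to `L`.
#'
#' @param L Genome length.
#' @param params A [markov_params()] object.
#' @param chrom Chromosome name.
#' @return An [annotation()].
#' @export
simulate_mc_annotation <- function(L, params, chrom = "chr1") {
  stopifnot(L >= 1)
  # sojourn in state 0 ~ 1 + Geom(t01), in state 1 ~ 1 + Geom(t10);
  # drawn in batches sized to the expected number of runs
  t01 <- params$t01
  t10 <- params$t10
  chunk <- max(16, ceiling(1.2 * L / (1 / t01 + 1 / t10)))
  pos <- 0
  starts <- list()
  ends <- list()
  while (pos < L) {
    g <- 1 + stats::rgeom(chunk, t01)
    run <- 1 + stats::rgeom(chunk, t10)
    s <- pos + cumsum(g) + c(0, cumsum(run))[seq_len(chunk)]
    starts[[length(starts) + 1L]] <- s
    ends[[length(ends) + 1L]] <- s + run
    pos <- s[chunk] + run[chunk]
  }
  s <- unlist(starts)
  e <- unlist(ends)
  keep <- s < L
  annotation(s[keep], pmin(e[keep], L), L, chrom)
}

#' Critical-value experiment on synthetic annotations
#'
#' Replicates the package's simulation protocol: per replicate, draw a
#' fresh reference and query (fixed-length intervals placed uniformly via
#' the gold-standard sampler), then compute the critical overlap count at
#' level `alpha` under (a) the Markov-chain null, exactly, by the dynamic
#' program, and/or (b) the gold-standard null, empirically, as the
#' smallest `k` whose tail fraction over `n_samples` direct draws is at
#' most `alpha`. Means and standard errors are reported over replicates.
#'
#' @param ref_spec,query_spec [sim_spec()] objects sharing the same `L`.
#' @param replicates Number of annotation replicates (default 10).
#' @param n_samples Gold-standard draws per replicate (default 10000).
#' @param alpha Significance level.
#' @param methods Any of `"mcdp"`, `"gold"`.
#' @param seed Optional master seed; replicate `r` reseeds at
#'   `seed + r - 1`.
#' @return An object of class `"experiment_result"`: list with
#'   `replicates` (data frame of per-replicate critical values) and
#'   `summary` (mean and standard error per method), plus the call
#'   parameters.
#' @export
run_experiment <- function(ref_spec, query_spec, replicates = 10L,
                           n_samples = 10000L, alpha = 0.05,
                           methods = c("mcdp", "gold"), seed = NULL) {
  stopifnot(inherits(ref_spec, "sim_spec"), inherits(query_spec, "sim_spec"),
            replicates >= 1)
  if (ref_spec$L != query_spec$L)
    stop("reference and query specs must share the genome length")
  methods <- match.arg(methods, several.ok = TRUE)
  L <- ref_spec$L
  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    if (!is.null(seed)) set.seed(seed + r - 1L)
    R <- simulate_annotation(ref_spec)
    Q <- simulate_annotation(query_spec)
    row <- list(replicate = r)
    if ("mcdp" %in% methods)
      row$mcdp <- critical_value(compute_pmf(R, Q, L), alpha)
    if ("gold" %in% methods) {
      K <- sample_overlap_counts(R, lens(Q), L, n_samples)
      m <- length(R)
      tail_frac <- rev(cumsum(rev(tabulate(K + 1L, nbins = m + 1L)))) / n_samples
      k <- which(tail_frac <= alpha)
      row$gold <- if (length(k)) k[1L] - 1L else m + 1L
    }
    rows[[r]] <- as.data.frame(row)
  }
  reps <- do.call(rbind, rows)
  meths <- setdiff(names(reps), "replicate")
  summ <- data.frame(
    method = meths,
    mean = vapply(meths, function(mm) mean(reps[[mm]]), 1),
    se = vapply(meths, function(mm) stats::sd(reps[[mm]]) / sqrt(nrow(reps)), 1),
    row.names = NULL)
  structure(list(replicates = reps, summary = summ,
                 ref_spec = ref_spec, query_spec = query_spec,
                 n_samples = as.integer(n_samples), alpha = alpha,
                 seed = seed),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Critical-value experiment (alpha = %g, %d replicates)\n",
              x$alpha, nrow(x$replicates)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Divergence measures between two overlap PMFs
#'
#' Compares an analytic PMF against an empirical or alternative one:
#' Kullback-Leibler divergence `KL(p || q)` (summed over bins with
#' `p > 0`, with `q` floored at a pseudo-count so empirical zeros stay
#' finite) and the mean square bias of the upper-tail curves,
#' `mean_k (Pr_p[K >= k] - Pr_q[K >= k])^2`.
#'
#' @param p,q Numeric PMF vectors of equal length.
#' @param floor_q Pseudo-count floor applied to `q` inside the KL sum;
#'   default `1e-5` (i.e. `1 / (10 * 10000)` for the standard number of
#'   sampling draws).
#' @return List with `kl_divergence` and `mean_square_bias`.
#' @export
compare_pmfs <- function(p, q, floor_q = 1e-5) {
  if (length(p) != length(q))
    stop("PMFs must share the same support length")
  pos <- p > 0
  kl <- sum(p[pos] * log(p[pos] / pmax(q[pos], floor_q)))
  tp <- rev(cumsum(rev(p)))
  tq <- rev(cumsum(rev(q)))
  list(kl_divergence = kl, mean_square_bias = mean((tp - tq)^2))
}
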