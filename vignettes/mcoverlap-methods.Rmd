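---
title: "Overlap significance under permutational and Markov-chain nulls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Overlap significance under permutational and Markov-chain nulls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcoverlap)
```

## The problem

Two genome annotations — sets of non-intersecting, *separated* (adjacent
intervals at least one base apart) half-open intervals on a chromosome
`[0, L)` — are compared through the overlap statistic `K(R, Q)`: the number
of intervals of the *reference* `R` that intersect at least one interval of
the *query* `Q`. The p-value problem asks, for every `k`, for
`Pr[K(R, Q_rand) >= k]` when the query is randomized under a null
hypothesis while the reference stays fixed. All coordinates in this package
are 0-based half-open (the BED convention) with no conversion layer; strand
is ignored, since the statistic uses only positions.

Two nulls are implemented.

**Permutational ("gold-standard") null.** `Q_rand` is uniform over all
separated annotations whose interval-length multiset equals `lens(Q)`.
Deciding whether the minimum achievable overlap is zero already encodes a
multiprocessor-scheduling problem (the `min_overlap()` fixture in the test
suite exercises a worked instance of that reduction on a genome of length
22), so exact p-values here are intractable in general; the package instead
samples the null directly.

**Markov-chain null.** `Q_rand` is emitted by a two-state chain over
positions — state 0 outside, state 1 inside an interval — with the
position-0 state fixed at 0 and transition matrix fitted to the observed
query by maximum likelihood:

    t01 = |Q| / (L - weight(Q) - 1),      t10 = |Q| / weight(Q).

The expected interval and gap lengths under this chain asymptotically match
the query's average interval and gap lengths, but interval lengths become
geometric rather than fixed. This relaxation is what buys tractability: the
full PMF of `K` becomes computable exactly in `O(m^2 + n)` time and `O(m)`
memory, independent of `L`.

## The rejection-free sampler

Placing `n = |Q|` intervals with prescribed lengths and separation on
`[0, L)` is equivalent to choosing (i) a uniform permutation of the lengths
and (ii) a uniform ordered partition of the free space
`U = L - weight(Q) - n + 1` into `n + 1` gap shares (the inner gaps get a
baseline of 1). Gap shares are drawn sequentially: with `b` gaps remaining,
the current share of the remaining free space `U'` follows the
Beta-Binomial distribution with `U'` trials and shapes `alpha = 1`,
`beta = b - 1`, whose CDF has the closed form

    Pr[u1 <= i] = 1 - ((U - i + b - 2)! U!) / ((U - i - 1)! (U + b - 1)!),

equal to the exact ratio of partition counts
`S(U, b) = choose(U + b - 1, b - 1)`. Inverse-transform sampling with a
binary search over `[0, U]` gives each draw in `O(log U)` CDF evaluations.

Numerical choices: the CDF is evaluated in log-gamma space, so free space
up to 1e8 and beyond neither overflows nor loses the tail; the uniform `y`
is drawn in (0, 1) and ties resolve to the smallest `i` (the CDF is capped
into `[0, 1]` after exponentiation). Naive alternatives — giving each gap a
uniform share of the remaining space, or a multinomial split — are *not*
uniform over annotations; the test suite keeps two concrete two-interval
counterexample annotations whose probabilities differ by factors of 5 and
40 under those schemes and verifies the implemented sampler makes them
equally likely.

Two simpler schemes are deliberately absent: rejection sampling (useless at
high query coverage) and any importance-sampling correction for small
p-values. When no draw reaches the observed count, the estimate reports the
rule-of-three bound: with `n` samples and zero exceedances, the true
p-value is below `3/n` with 95% confidence.

For Monte-Carlo work the sampler runs in batch: all draws advance one gap
at a time, with the binary search vectorized across draws. The distribution
is identical to the one-draw-at-a-time loop; only the order in which the
RNG stream is consumed differs.

## The dynamic program

Write the reference as gap/length pairs `g_j, l_j` with the convention
`e_0 := 1` (position 0 is forced to state 0) and `b_{m+1} := L`. For each
reference interval `j`, crossing its preceding gap and then the interval
itself without hitting it has probability matrix
`T^{g_j} %*% Tmod^{l_j}`, where `Tmod` zeroes all transitions into state 1;
hitting it is the complement `T^{g_j} %*% (T^{l_j} - Tmod^{l_j})`. The DP
state after interval `j` is, for every possible hit count, the joint
probability of that count and the chain state at the interval's last base;
each interval updates all counts with one no-hit and one hit product. The
implementation keeps a single `(m + 1) x 2` matrix and updates it in place
(the `O(m)` memory contract), with the per-count update vectorized as one
matrix product.

Matrix powers use the closed-form eigendecomposition of the 2x2 chain
(eigenvalues 1 and `t00 - t10`) for exponents above 50 and exponentiation
by squaring below — the crossover matching where the closed form stops
being cheaper — and squaring always when `t00 == t10`, whose zero
eigenvalue would make `0^0` ambiguous at `a = 0`. `lambda^a` underflowing
to zero for large gaps is the correct stationary limit and is allowed
silently. `Tmod^a` has the closed form `[[t00^a, 0], [t10 t00^(a-1), 0]]`;
the `(1,0)` entry is necessarily non-negative, being an entry of a product
of non-negative matrices, and is implemented as such and validated against
iterated products in the tests.

Design choices that were genuinely open:

- **Reference interval at coordinate 0.** The `e_0 = 1` convention would
  give a negative leading gap. All coordinates (and `L`) are then shifted
  by +1, which preserves every gap and length except the leading gap that
  the recurrence treats as ordinary chain steps anyway. The cost is that
  position 0 — forced to state 0 in the unshifted model — becomes a free
  position; only instances whose first reference interval starts at 0 are
  affected, and only through that single position.
- **The chain's final state.** The states after the last reference
  interval cannot change `K`, so the DP simply marginalizes at the last
  interval's end; no renormalization conditions on the genome's final
  position being outside an interval.
- **Floating-point dust.** The subtraction `T^l - Tmod^l` can go a few
  ulps negative; entries are clipped at zero, with an internal guard that
  aborts if the clip ever exceeds 1e-12. All arithmetic is plain double
  precision — the per-step factors are entries of 2x2 stochastic matrices
  and the PMF bins of interest stay far above the underflow threshold in
  the regimes the package targets; bins that do underflow report 0 and the
  tail curves remain valid by construction.
- **Degenerate queries.** An empty query makes the null a point mass at
  zero overlaps (reported as such rather than an error); a query so dense
  that `L - weight(Q) - 1 <= |Q|` has no valid maximum-likelihood fit and
  is rejected with the violated inequality named.

The critical value at level `alpha` is the smallest `k` with
`Pr[K >= k] <= alpha` (`m + 1` if none exists), and because the whole PMF
is available both the enrichment tail `Pr[K >= k_obs]` and the depletion
tail `Pr[K <= k_obs]` are exact.

## Multiple chromosomes

Per-chromosome nulls are independent, so the genome-wide count is a sum of
independent counts and its PMF is the convolution of the per-chromosome
PMFs — implemented directly (not via FFT) to keep the result exact to
rounding; over `N` chromosomes this is the `O(N m^2)` post-processing step.
Transition parameters are fitted per chromosome from that chromosome's
query by default; `pooled_fit = TRUE` fits one parameter set from the
pooled interval count, weight and genome length, for callers who prefer a
genome-wide rate. Chromosomes with a reference but no query contribute a
point mass at zero (their intervals cannot be hit under a null preserving
per-chromosome counts), not an error. Sampled multi-chromosome p-values
draw each chromosome independently and sum the counts, matching that
independence assumption.

## The synthetic generator and what the tests show

`sim_spec(L, n_intervals, coverage)` emulates the simulation design used
throughout: all intervals share one length, `floor(coverage * L /
n_intervals)` with a minimum of 1 (floor rather than round: conservative
coverage; the three standard configurations below divide exactly, so the
choice only matters off-grid), placed uniformly at random by the
gold-standard sampler. `run_experiment()` repeats: draw fresh reference and
query, compute the Markov-chain critical value exactly and/or the
gold-standard one from 10 000 direct samples, and report means with
standard errors; replicate `r` reseeds at `seed + r - 1` so every replicate
is independently reproducible.

The reference simulation conditions are a 1 Mb chromosome with reference
intervals of 100 bp, 10 replicates per configuration, and significance
0.05; the acceptance script runs three configurations (reference 50 or 500
intervals; query 5 x 1000 bp, 50 x 1000 bp, or 500 x 10 bp). In these
regimes the Markov-chain and gold-standard critical values agree to within
about 10%; the known failure mode of the Markov null — a single query
interval expected to span more than one reference interval, where the
geometric length assumption makes the PMF heavy-tailed — lies outside
these configurations and outside what passing tests demonstrate.

What the generator does *not* emulate about real annotations: variable
interval lengths, clustering and mutual exclusion along the genome,
chromosome-specific densities, excluded regions such as centromeres, and
covariates like GC content. Agreement on these synthetic conditions
therefore shows correctness of the algorithms under their stated nulls,
not fidelity of either null to any particular biological process.

Problem sizes in the shipped tests were chosen to keep the default suite
fast while still separating correct from incorrect behaviour: exhaustive
path enumeration up to `L = 16` (2^15 paths) over 100 randomized
instances, exhaustive annotation enumeration up to a few thousand
placements, chi-square uniformity at 1e5 draws, PMF normalization at
`m = 5000` on a 2 Mb chromosome, and the three critical-value
configurations above at full scale (10 replicates, 10 000 samples).

## Divergence diagnostics

`compare_pmfs()` reports `KL(p || q)` with the sum restricted to bins where
`p > 0` and `q` floored at a pseudo-count (default `1e-5`, i.e. one tenth
of a count at the standard 10 000 draws — configurable, since any floor is
a convention) plus the mean square bias of the two upper-tail curves.

## Known limitations

- Interval lengths under the Markov null are geometric; annotations with
  long, regular intervals relative to reference spacing push against this
  assumption (heavy-tailed PMFs, inflated critical values).
- The overlap statistic weighs a 1-base and a 1000-base overlap equally;
  shared-base statistics and minimum-overlap thresholds are different
  measures and out of scope.
- The order-restricted DP of prior work (with its genome-scaling factor)
  and FFT acceleration of the convolution/DP are intentionally not
  implemented.
- `min_overlap()` and the other brute-force references are exponential by
  design and refuse instances beyond tiny sizes; they exist to validate
  the fast paths, not to analyse data.
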