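test_that("geometry extracts gaps and lengths under the e0 = 1 convention", {
  g <- geometry(annotation(c(6, 14), c(8, 16), L = 22))
  expect_identical(g$g, c(5, 6, 6))
  expect_identical(g$l, c(2, 2))

  g1 <- geometry(annotation(1, 2, L = 4))
  expect_identical(g1$g, c(0, 2))
  expect_identical(g1$l, 1)

  g0 <- geometry(annotation(numeric(0), numeric(0), L = 10))
  expect_identical(g0$g, 9)
  expect_length(g0$l, 0L)

  # a reference interval at coordinate 0 triggers the +1 shift
  gs <- geometry(annotation(0, 3, L = 10))
  expect_identical(gs$g, c(0, 7))
  expect_identical(gs$l, 3)

  set.seed(31)
  for (i in 1:10) {
    A <- random_annotation(30, sample(1:4, 1))
    g <- geometry(A)
    expect_equal(sum(g$g) + sum(g$l), 30 - 1)
  }
})

test_that("hit and no-hit step matrices agree with path enumeration", {
  set.seed(32)
  for (i in 1:8) {
    par <- random_params()
    gj <- sample(0:5, 1)
    lj <- sample(1:5, 1)
    geom <- list(m = 1L, g = c(gj, 1), l = lj)
    A <- p_nohit(1, geom, par)
    B <- p_hit(1, geom, par)
    # complementarity and the forced-zero column
    expect_lt(max(abs(A + B - power_T(par, gj + lj))), 1e-12)
    expect_equal(A[, 2L], c(0, 0))
    # explicit enumeration over the g + l steps after the entry state
    steps <- gj + lj
    in_ref <- seq.int(gj + 1, steps)
    for (i0 in 0:1) {
      nohit_or <- enum_path_prob(i0, steps, par,
        keep = function(p) all(p[in_ref] == 0), s_end = 0)
      hit_or <- enum_path_prob(i0, steps, par,
        keep = function(p) any(p[in_ref] == 1))
      expect_equal(A[i0 + 1L, 1L], nohit_or, tolerance = 1e-12)
      expect_equal(sum(B[i0 + 1L, ]), hit_or, tolerance = 1e-12)
    }
  }
})

test_that("the DP reproduces the exhaustive-path PMF on a randomized grid", {
  set.seed(33)
  worst <- 0
  for (case in 1:100) {
    L <- sample(8:16, 1)
    m <- sample(0:3, 1)
    R <- random_annotation(L, m)
    par <- random_params()
    pmf <- compute_pmf(R, L = L, params = par)
    oracle <- exact_mc_pmf(R, L, par)
    worst <- max(worst, max(abs(pmf - oracle)))
  }
  expect_lt(worst, 1e-10)
})

test_that("the DP PMF matches direct Markov-chain simulation", {
  set.seed(34)
  par <- markov_params(0.06, 0.25)
  R <- annotation(c(10, 45, 80), c(20, 55, 90), L = 120)
  pmf <- compute_pmf(R, L = 120, params = par)
  n <- 2e4
  K <- vapply(seq_len(n), function(i)
    overlap_count(R, simulate_mc_annotation(120, par)), 0L)
  emp <- tabulate(K + 1L, nbins = 4L) / n
  se <- sqrt(pmf * (1 - pmf) / n)
  expect_true(all(abs(emp - pmf) <= 4 * se + 1e-9))
})

test_that("PMF normalization and degenerate limits behave", {
  # m = 0 and empty query
  expect_identical(compute_pmf(annotation(numeric(0), numeric(0), 50),
                               annotation(3, 6, L = 50)), 1)
  R <- annotation(c(5, 20), c(10, 30), L = 50)
  expect_identical(compute_pmf(R, annotation(numeric(0), numeric(0), 50)),
                   c(1, 0, 0))
  # a nearly absorbing chain concentrates all mass at zero overlaps
  pmf0 <- compute_pmf(R, L = 50, params = markov_params(1e-12, 0.5))
  expect_gt(pmf0[1], 1 - 1e-9)
  # normalization on a large instance
  set.seed(35)
  Rb <- simulate_annotation(sim_spec(2e6, 5000, 0.25))
  Qb <- simulate_annotation(sim_spec(2e6, 500, 0.05))
  expect_lt(abs(sum(compute_pmf(Rb, Qb)) - 1), 1e-9)
})

test_that("runtime is independent of the genome length", {
  set.seed(36)
  spec_r <- sim_spec(1e8, 50, 5e-5)
  spec_q <- sim_spec(1e8, 50, 5e-4)
  t0 <- proc.time()[["elapsed"]]
  pmf <- compute_pmf(simulate_annotation(spec_r), simulate_annotation(spec_q))
  expect_lt(proc.time()[["elapsed"]] - t0, 10)
  expect_lt(abs(sum(pmf) - 1), 1e-9)
})

test_that("tail curves, critical values and two-sided reporting are coherent", {
  cur <- pvalue_curve(c(0.5, 0.5))
  expect_equal(cur$p, c(1, 0.5))
  expect_equal(cur$d, c(0.5, 1))

  set.seed(37)
  pmf <- prop.table(stats::runif(9))
  cur <- pvalue_curve(pmf)
  expect_equal(cur$p[1], 1)
  expect_true(all(diff(cur$p) <= 1e-12))
  k <- 2:9
  expect_equal(cur$p[k] + cur$d[k - 1L], rep(1, length(k)), tolerance = 1e-12)

  # critical values
  expect_identical(critical_value(c(1, rep(0, 5)), 0.05), 1L)
  expect_identical(critical_value(rep(1 / 20, 20), 0.05), 19L)
  expect_identical(critical_value(rep(1 / 20, 20), 1), 0L)
  expect_identical(critical_value(c(0.5, 0.5), 0.05), 2L)  # unattainable: m + 1

  # enrichment/depletion tails share the observed atom
  ed <- enrichment_depletion(pmf, 3)
  expect_equal(ed$p_enrich + ed$p_deplete, 1 + pmf[4], tolerance = 1e-12)
  expect_equal(enrichment_depletion(pmf, 0)$p_enrich, 1)
  expect_equal(enrichment_depletion(pmf, 8)$p_deplete, 1)
  expect_error(enrichment_depletion(pmf, 9), "0\\.\\.8")
})
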