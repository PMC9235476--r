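test_that("lens and gaps reproduce the textbook example and conservation laws", {
  A <- annotation(c(3, 5, 7), c(4, 6, 9), L = 10)
  expect_identical(lens(A), c(1, 1, 2))
  expect_identical(gaps(A), c(3, 1, 1, 1))
  expect_identical(annotation_weight(A), 4)

  E <- annotation(numeric(0), numeric(0), L = 10)
  expect_length(lens(E), 0L)
  expect_identical(gaps(E), 10)

  set.seed(11)
  for (i in 1:20) {
    A <- random_annotation(L = 40, m = sample(0:6, 1))
    expect_length(gaps(A), length(A) + 1L)
    expect_equal(sum(gaps(A)) + sum(lens(A)), A$L)
    if (length(A) > 1L) expect_true(all(gaps(A)[2:length(A)] >= 1))
  }
})

test_that("annotation constructor enforces the invariants", {
  expect_error(annotation(3, 3, L = 10), "end > start")
  expect_error(annotation(c(3, 2), c(4, 3), L = 10), "sorted")
  expect_error(annotation(c(2, 5), c(5, 8), L = 10), "separated")
  expect_error(annotation(2, 11, L = 10), "contained")
})

test_that("merge_nonseparated unions overlapping and abutting intervals only", {
  m1 <- merge_nonseparated(c(2, 4), c(5, 9), L = 10)
  expect_identical(m1$starts, 2)
  expect_identical(m1$ends, 9)

  m2 <- merge_nonseparated(c(3, 5), c(4, 6), L = 10)
  expect_identical(m2$starts, c(3, 5))  # gap of 1: kept

  m3 <- merge_nonseparated(c(2, 5), c(5, 8), L = 10)  # abutting
  expect_identical(m3$starts, 2)
  expect_identical(m3$ends, 8)

  # coverage preserved on random unsorted input, and idempotent
  set.seed(7)
  for (i in 1:10) {
    L <- 200
    n <- 100
    s <- sample(0:(L - 2), n, replace = TRUE)
    e <- pmin(s + sample(1:5, n, replace = TRUE), L)
    merged <- merge_nonseparated(s, e, L)
    expect_identical(coverage_mask(merged$starts, merged$ends, L),
                     coverage_mask(s, e, L))
    again <- merge_nonseparated(merged$starts, merged$ends, L)
    expect_identical(again$starts, merged$starts)
    expect_identical(again$ends, merged$ends)
  }
})

test_that("merge agrees with the IRanges reduction on random input", {
  skip_if_not_installed("IRanges")
  set.seed(8)
  for (i in 1:10) {
    L <- 500
    s <- sample(0:(L - 10), 50, replace = TRUE)
    e <- s + sample(1:9, 50, replace = TRUE)
    merged <- merge_nonseparated(s, e, L)
    red <- IRanges::reduce(IRanges::IRanges(s + 1, e))  # merges gap-0 too
    expect_identical(merged$starts, as.numeric(IRanges::start(red) - 1))
    expect_identical(merged$ends, as.numeric(IRanges::end(red)))
  }
})

test_that("overlap_count matches per-base mask and IRanges oracles", {
  R <- annotation(0, 5, L = 10)
  expect_identical(overlap_count(R, annotation(4, 6, L = 10)), 1L)
  expect_identical(overlap_count(R, annotation(5, 6, L = 10)), 0L)

  has_iranges <- requireNamespace("IRanges", quietly = TRUE)
  set.seed(9)
  for (i in 1:50) {
    L <- 50
    R <- random_annotation(L, sample(0:4, 1))
    Q <- random_annotation(L, sample(0:4, 1))
    k <- overlap_count(R, Q)
    if (length(R) && length(Q)) {
      expect_identical(k, as.integer(overlap_count_mask(R, Q)))
      if (has_iranges) {
        ir_k <- sum(IRanges::countOverlaps(
          IRanges::IRanges(R$starts + 1, R$ends),
          IRanges::IRanges(Q$starts + 1, Q$ends)) > 0)
        expect_identical(k, as.integer(ir_k))
      }
    } else {
      expect_identical(k, 0L)
    }
  }
})

test_that("overlap_count is monotone under query growth and checks inputs", {
  set.seed(12)
  L <- 60
  R <- random_annotation(L, 4)
  Q_lens <- c(2, 3, 1, 2)
  full <- sample_gold(Q_lens, L)
  ks <- vapply(seq_along(full$starts), function(j) {
    overlap_count(R, annotation(full$starts[1:j], full$ends[1:j], L))
  }, 0L)
  expect_true(all(diff(ks) >= 0))
  expect_error(overlap_count(R, annotation(1, 2, L = 61)), "same chromosome")
})

test_that("BED round trip through merging is exact", {
  genome <- c(chr1 = 10, chr2 = 25)
  bed <- tempfile(fileext = ".bed")
  writeLines(c("# a comment", "track name=demo",
               "chr1 3 4", "chr1 5 6", "chr1 7 9",
               "chr2\t2\t5", "chr2\t5\t8\tname\t0\t+"), bed)
  ma <- read_bed(bed, genome)
  expect_identical(ma$annotations$chr1$starts, c(3, 5, 7))
  expect_identical(ma$annotations$chr1$ends, c(4, 6, 9))
  # abutting chr2 records merged to [2,8)
  expect_identical(ma$annotations$chr2$starts, 2)
  expect_identical(ma$annotations$chr2$ends, 8)

  out <- tempfile(fileext = ".bed")
  write_bed(ma, out)
  ma2 <- read_bed(out, genome)
  expect_equal(ma2$annotations, ma$annotations)
})

test_that("BED reader reports malformed and out-of-range records", {
  genome <- c(chr1 = 10)
  bad <- tempfile()
  writeLines(c("chr1 1 2", "chr1 five 6"), bad)
  expect_error(read_bed(bad, genome), "line 2.*non-integer")
  writeLines("chr1 5 3", bad)
  expect_error(read_bed(bad, genome), "start >= end")
  writeLines("chr1 5 11", bad)
  expect_error(read_bed(bad, genome), "exceeds chromosome length")
  writeLines("chrX 1 2", bad)
  expect_error(read_bed(bad, genome), "absent from the genome table")
  # empty file: empty annotation for every chromosome
  writeLines(character(0), bad)
  ma <- read_bed(bad, c(chr1 = 10, chr2 = 5))
  expect_identical(vapply(ma$annotations, length, 1L), c(chr1 = 0L, chr2 = 0L))
})
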