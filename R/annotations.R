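#' Construct a genome annotation
#'
#' An annotation is a set of non-intersecting, *separated* half-open intervals
#' `[start, end)` on a chromosome of length `L`. Separated means that every
#' gap between adjacent intervals is at least one base; abutting intervals
#' must therefore be merged first (see [merge_nonseparated()]). All
#' coordinates are 0-based half-open, the BED convention.
#'
#' @param starts Integer vector of interval start positions (0-based,
#'   inclusive).
#' @param ends Integer vector of interval end positions (exclusive).
#' @param L Chromosome (genome) length; all intervals must lie in `[0, L)`.
#' @param chrom Chromosome name.
#' @return An object of class `"annotation"`: a list with elements `chrom`,
#'   `L`, `starts`, `ends`.
#' @examples
#' annotation(c(3, 5, 7), c(4, 6, 9), L = 10)
#' @export
annotation <- function(starts, ends, L, chrom = "chr1") {
  starts <- as.numeric(starts)
  ends <- as.numeric(ends)
  if (length(starts) != length(ends))
    stop("'starts' and 'ends' must have equal length")
  if (length(L) != 1L || is.na(L) || L <= 0)
    stop("'L' must be a single positive number")
  L <- as.numeric(L)
  if (length(starts)) {
    if (any(is.na(starts)) || any(is.na(ends)))
      stop("missing coordinates")
    if (any(ends <= starts))
      stop("all intervals must satisfy end > start")
    if (any(starts < 0) || any(ends > L))
      stop("intervals must be contained in [0, L)")
    if (is.unsorted(starts, strictly = TRUE))
      stop("intervals must be sorted by start")
    n <- length(starts)
    if (n > 1L && any(starts[-1L] - ends[-n] < 1))
      stop("annotation is not separated: adjacent intervals must be ",
           "at least 1 base apart (merge first)")
  }
  structure(list(chrom = chrom, L = L, starts = starts, ends = ends),
            class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  n <- length(x$starts)
  cat(sprintf("Annotation on %s (L = %s): %d interval%s, weight %s\n",
              x$chrom, format(x$L, big.mark = ","), n,
              if (n == 1L) "" else "s", format(sum(x$ends - x$starts))))
  if (n) {
    show <- seq_len(min(n, 6L))
    cat(paste0(" [", x$starts[show], ",", x$ends[show], ")",
               collapse = " "), if (n > 6L) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
length.annotation <- function(x) length(x$starts)

#' Interval lengths of an annotation
#'
#' @param A An [annotation()].
#' @return Numeric vector of interval lengths (the multiset `lens(A)`), one
#'   per interval, each at least 1.
#' @examples
#' lens(annotation(c(3, 5, 7), c(4, 6, 9), L = 10))  # 1 1 2
#' @export
lens <- function(A) {
  stopifnot(inherits(A, "annotation"))
  A$ends - A$starts
}

#' Total number of covered bases
#'
#' @param A An [annotation()].
#' @return The weight of `A`: the sum of its interval lengths.
#' @export
annotation_weight <- function(A) {
  stopifnot(inherits(A, "annotation"))
  sum(A$ends - A$starts)
}

#' Gap lengths of an annotation
#'
#' Returns the sequence of gap lengths from the start of the genome to its
#' end: with `n` intervals there are `n + 1` gaps, the inner ones at least 1
#' (separation), and `sum(gaps(A)) + sum(lens(A)) == L`.
#'
#' @param A An [annotation()].
#' @return Numeric vector of `length(A) + 1` gap lengths.
#' @examples
#' gaps(annotation(c(3, 5, 7), c(4, 6, 9), L = 10))  # 3 1 1 1
#' @export
gaps <- function(A) {
  stopifnot(inherits(A, "annotation"))
  c(A$starts, A$L) - c(0, A$ends)
}

#' Merge intersecting or non-separated intervals
#'
#' Unions any pair of input intervals that overlap or abut (gap of zero),
#' producing a valid separated annotation with the same covered positions.
#' Input intervals may be unsorted.
#'
#' @param starts,ends Interval coordinates (0-based half-open), any order.
#' @inheritParams annotation
#' @return An [annotation()].
#' @examples
#' merge_nonseparated(c(2, 5), c(5, 8), L = 10)  # single interval [2,8)
#' @export
merge_nonseparated <- function(starts, ends, L, chrom = "chr1") {
  if (!length(starts)) return(annotation(numeric(0), numeric(0), L, chrom))
  o <- order(starts, ends)
  s <- as.numeric(starts)[o]
  e <- as.numeric(ends)[o]
  n <- length(s)
  cme <- cummax(e)
  # a new run starts where this interval neither overlaps nor abuts all before
  new_run <- c(TRUE, s[-1L] > cme[-n])
  grp <- cumsum(new_run)
  annotation(s[new_run], as.numeric(tapply(e, grp, max)), L, chrom)
}

#' Count reference intervals hit by a query
#'
#' The overlap statistic `K(R, Q)`: the number of intervals of the reference
#' annotation `R` that share at least one base with some interval of the
#' query annotation `Q`. Each reference interval is counted at most once.
#' Computed as a sweep over the two sorted interval lists.
#'
#' @param R Reference [annotation()].
#' @param Q Query [annotation()], on the same chromosome and genome length.
#' @return Integer in `0..length(R)`.
#' @examples
#' R <- annotation(0, 5, L = 10)
#' Q <- annotation(4, 6, L = 10)
#' overlap_count(R, Q)  # 1
#' @export
overlap_count <- function(R, Q) {
  stopifnot(inherits(R, "annotation"), inherits(Q, "annotation"))
  if (R$L != Q$L || !identical(R$chrom, Q$chrom))
    stop("R and Q must be on the same chromosome with equal genome length")
  .overlap_count_sorted(R$starts, R$ends, Q$starts, Q$ends)
}

# core sweep on raw sorted coordinate vectors (query sorted & disjoint)
.overlap_count_sorted <- function(rs, re, qs, qe) {
  if (!length(rs) || !length(qs)) return(0L)
  # first query ending strictly after the reference start is the only
  # candidate with the smallest start; half-open: qe <= rs means no overlap
  idx <- findInterval(rs, qe) + 1L
  ok <- idx <= length(qs)
  sum(ok & qs[idx] < re)
}

#' Read a UCSC-style chromosome sizes file
#'
#' @param path Two-column whitespace-delimited file: chromosome name, length.
#' @return Named numeric vector of chromosome lengths (a genome table).
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, colClasses = c("character", "numeric"),
                           col.names = c("chrom", "length"))
  if (anyDuplicated(tab$chrom)) stop("duplicate chromosome names in ", path)
  if (any(tab$length <= 0)) stop("chromosome lengths must be positive")
  stats::setNames(tab$length, tab$chrom)
}

#' Construct a multi-chromosome annotation
#'
#' @param annotations Named list of [annotation()] objects, one per
#'   chromosome; names must match `genome` and each annotation's `L` must
#'   equal the genome-table entry. Chromosomes of `genome` missing from the
#'   list get empty annotations.
#' @param genome Named vector of chromosome lengths (see
#'   [read_chrom_sizes()]).
#' @return An object of class `"multi_annotation"`.
#' @export
multi_annotation <- function(annotations, genome) {
  if (is.null(names(genome)) || anyDuplicated(names(genome)))
    stop("'genome' must be a uniquely named vector of lengths")
  if (any(genome <= 0)) stop("chromosome lengths must be positive")
  bad <- setdiff(names(annotations), names(genome))
  if (length(bad))
    stop("chromosome(s) not in the genome table: ", paste(bad, collapse = ", "))
  out <- lapply(names(genome), function(chrom) {
    a <- annotations[[chrom]]
    if (is.null(a)) return(annotation(numeric(0), numeric(0), genome[[chrom]], chrom))
    stopifnot(inherits(a, "annotation"))
    if (a$L != genome[[chrom]])
      stop("annotation length for ", chrom, " disagrees with the genome table")
    a
  })
  structure(list(annotations = stats::setNames(out, names(genome)),
                 genome = genome),
            class = "multi_annotation")
}

#' @export
print.multi_annotation <- function(x, ...) {
  n_int <- vapply(x$annotations, length, 1L)
  cat(sprintf("MultiAnnotation: %d chromosome(s), %d interval(s) total\n",
              length(x$genome), sum(n_int)))
  invisible(x)
}

#' Read a BED file into per-chromosome annotations
#'
#' Reads the first three whitespace/tab-delimited columns (chrom, start,
#' end; 0-based half-open), skips `track`, `browser` and `#` lines, merges
#' any intersecting or non-separated intervals per chromosome, and returns
#' one annotation per chromosome of the genome table (empty where the file
#' has no records). Extra BED columns, including strand, are ignored.
#'
#' @param path BED file path.
#' @param genome Named vector of chromosome lengths.
#' @return A [multi_annotation()].
#' @export
read_bed <- function(path, genome) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*$|^track|^browser|^#", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  per <- list()
  if (length(lines)) {
    fields <- strsplit(trimws(lines), "[ \t]+")
    nf <- lengths(fields)
    if (any(nf < 3L))
      stop("BED parse error at line ", lineno[which(nf < 3L)[1L]],
           ": fewer than 3 columns")
    chrom <- vapply(fields, `[[`, "", 1L)
    s_chr <- vapply(fields, `[[`, "", 2L)
    e_chr <- vapply(fields, `[[`, "", 3L)
    bad <- !grepl("^[0-9]+$", s_chr) | !grepl("^[0-9]+$", e_chr)
    if (any(bad))
      stop("BED parse error at line ", lineno[which(bad)[1L]],
           ": non-integer coordinates")
    s <- as.numeric(s_chr)
    e <- as.numeric(e_chr)
    if (any(s >= e))
      stop("BED parse error at line ", lineno[which(s >= e)[1L]],
           ": start >= end")
    unknown <- !(chrom %in% names(genome))
    if (any(unknown))
      stop("line ", lineno[which(unknown)[1L]], ": chromosome '",
           chrom[which(unknown)[1L]], "' absent from the genome table")
    over <- e > genome[chrom]
    if (any(over))
      stop("line ", lineno[which(over)[1L]],
           ": interval end exceeds chromosome length")
    for (ch in unique(chrom)) {
      i <- chrom == ch
      per[[ch]] <- merge_nonseparated(s[i], e[i], genome[[ch]], ch)
    }
  }
  multi_annotation(per, genome)
}

#' Write annotations to a BED file
#'
#' @param x An [annotation()] or [multi_annotation()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  if (inherits(x, "annotation")) x <- list(x)
  else if (inherits(x, "multi_annotation")) x <- x$annotations
  con <- file(path, "w")
  on.exit(close(con))
  for (a in x) {
    if (length(a$starts))
      writeLines(sprintf("%s\t%d\t%d", a$chrom, as.integer(a$starts),
                         as.integer(a$ends)), con)
  }
  invisible(path)
}
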