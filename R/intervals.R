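#' @importFrom rlang abort warn .data
#' @importFrom dplyr %>%
NULL

# Interval tables use the BED convention throughout: `chrom` (character),
# `start` (0-based, inclusive), `end` (exclusive). Zero-length intervals are
# invalid; strand is ignored everywhere.

#' Validate a table of genomic intervals
#'
#' Checks the interval columns of a data frame against the coordinate
#' conventions used throughout the package (0-based half-open, `start < end`,
#' `start >= 0`) and, optionally, against chromosome bounds.
#'
#' @param x A data frame with columns `chrom`, `start`, `end`.
#' @param genome Optional genome layout (see [genome_layout()]); when given,
#'   every interval must lie within its chromosome's length and every
#'   chromosome must be present in the layout.
#' @param arg Name used in error messages.
#'
#' @return `x`, invisibly, as a tibble.
#' @export
#'
#' @examples
#' check_intervals(tibble::tibble(chrom = "chr1", start = 0, end = 100))
check_intervals <- function(x, genome = NULL, arg = "x") {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame of intervals.", arg))
  }
  missing_cols <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "`%s` is missing interval column(s): %s.",
      arg, paste(missing_cols, collapse = ", ")
    ))
  }
  x <- tibble::as_tibble(x)
  if (nrow(x) == 0) {
    return(invisible(x))
  }
  if (anyNA(x$chrom) || anyNA(x$start) || anyNA(x$end)) {
    abort(sprintf("`%s` contains missing values in interval columns.", arg))
  }
  if (any(x$start < 0)) {
    abort(sprintf("`%s` contains intervals with start < 0.", arg))
  }
  if (any(x$start >= x$end)) {
    abort(sprintf(
      "`%s` contains zero- or negative-length intervals (start >= end).", arg
    ))
  }
  if (!is.null(genome)) {
    genome <- as_genome_layout(genome)
    unknown <- setdiff(unique(x$chrom), genome$chrom)
    if (length(unknown) > 0) {
      abort(sprintf(
        "`%s` uses chromosome(s) absent from the genome layout: %s.",
        arg, paste(unknown, collapse = ", ")
      ))
    }
    len <- genome$size[match(x$chrom, genome$chrom)]
    if (any(x$end > len)) {
      abort(sprintf(
        "`%s` contains intervals extending past their chromosome length.", arg
      ))
    }
  }
  invisible(x)
}

#' Construct a genome layout
#'
#' A genome layout records per-chromosome lengths; its total size is the
#' denominator of the enrichment test's background ("a nucleotide not
#' overlapping a peak").
#'
#' @param chrom Character vector of chromosome names, or a data frame with
#'   columns `chrom` and `size`.
#' @param size Integer vector of chromosome lengths in nucleotides.
#'
#' @return A tibble with columns `chrom` and `size`.
#' @export
#'
#' @examples
#' genome_layout(c("chr1", "chr2"), c(2e6, 1e6))
genome_layout <- function(chrom, size = NULL) {
  if (is.data.frame(chrom)) {
    return(as_genome_layout(chrom))
  }
  as_genome_layout(tibble::tibble(chrom = chrom, size = size))
}

as_genome_layout <- function(x) {
  if (!is.data.frame(x) || !all(c("chrom", "size") %in% names(x))) {
    abort("A genome layout needs columns `chrom` and `size`.")
  }
  x <- tibble::as_tibble(x)[c("chrom", "size")]
  x$chrom <- as.character(x$chrom)
  x$size <- as.double(x$size)
  if (anyNA(x$chrom) || anyNA(x$size) || any(x$size <= 0)) {
    abort("Genome layout sizes must be positive and non-missing.")
  }
  if (anyDuplicated(x$chrom)) {
    abort("Genome layout chromosomes must be unique.")
  }
  x
}

#' Total genome size
#'
#' @param genome A genome layout (see [genome_layout()]).
#' @return Total length in nucleotides (sum of chromosome sizes).
#' @export
genome_size <- function(genome) {
  sum(as_genome_layout(genome)$size)
}

# chromosome-name ordering used everywhere: locale-independent radix sort
chrom_order <- function(chrom, start, end, ...) {
  order(chrom, start, end, ..., method = "radix")
}

sort_intervals <- function(x) {
  x[chrom_order(x$chrom, x$start, x$end), , drop = FALSE]
}

# tibble (BED 0-based half-open) -> GRanges (1-based closed)
as_gr <- function(x, seqlevels = NULL) {
  if (is.null(seqlevels)) {
    seqlevels <- sort(unique(as.character(x$chrom)), method = "radix")
  }
  GenomicRanges::GRanges(
    seqnames = factor(as.character(x$chrom), levels = seqlevels),
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

gr_to_tbl <- function(gr) {
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr)
  )
}

#' Pairwise interval overlap predicate
#'
#' Two intervals colocalize when they share at least one nucleotide under
#' half-open semantics: same chromosome, `a$start < b$end` and
#' `b$start < a$end`. Abutting intervals (`a$end == b$start`) do not overlap.
#' This is the colocalization test applied between peaks of different
#' replicates.
#'
#' @param a,b Data frames of intervals; recycled against each other row-wise
#'   (either may have one row).
#'
#' @return Logical vector.
#' @export
#'
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 100, end = 200)
#' b <- tibble::tibble(chrom = "chr1", start = 150, end = 250)
#' intervals_overlap(a, b)
intervals_overlap <- function(a, b) {
  a <- check_intervals(a, arg = "a")
  b <- check_intervals(b, arg = "b")
  if (nrow(a) != nrow(b)) {
    if (nrow(a) == 1) {
      a <- a[rep(1, nrow(b)), , drop = FALSE]
    } else if (nrow(b) == 1) {
      b <- b[rep(1, nrow(a)), , drop = FALSE]
    } else {
      abort("`a` and `b` must have the same number of rows (or one row).")
    }
  }
  a$chrom == b$chrom & a$start < b$end & b$start < a$end
}

#' Build an overlap index over a set of intervals
#'
#' Preprocesses intervals into a structure supporting repeated overlap queries
#' via [query_overlaps()]. Input order is retained so query results can report
#' the original row (`rank`).
#'
#' @param x Data frame of intervals.
#' @return An object of class `overlap_index`.
#' @export
overlap_index <- function(x) {
  x <- check_intervals(x)
  structure(
    list(intervals = tibble::as_tibble(x), gr = as_gr(x)),
    class = "overlap_index"
  )
}

#' @export
print.overlap_index <- function(x, ...) {
  cat(sprintf("<overlap_index: %d intervals>\n", nrow(x$intervals)))
  invisible(x)
}

#' Query an overlap index
#'
#' Returns the stored intervals overlapping each query interval (at least one
#' shared nucleotide), in deterministic (start, end, input-rank) order within
#' each query.
#'
#' @param index An [overlap_index()].
#' @param query Data frame of query intervals.
#'
#' @return A tibble with the matching stored rows plus `query` (query row
#'   number) and `rank` (stored row number).
#' @export
query_overlaps <- function(index, query) {
  stopifnot(inherits(index, "overlap_index"))
  query <- check_intervals(query, arg = "query")
  stored <- index$intervals
  if (nrow(query) == 0 || nrow(stored) == 0) {
    out <- stored[0, , drop = FALSE]
    out$query <- integer(0)
    out$rank <- integer(0)
    return(out)
  }
  lev <- sort(
    union(unique(as.character(stored$chrom)),
          unique(as.character(query$chrom))),
    method = "radix"
  )
  qgr <- as_gr(query, seqlevels = lev)
  sgr <- as_gr(stored, seqlevels = lev)
  hits <- GenomicRanges::findOverlaps(qgr, sgr)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  out <- stored[si, , drop = FALSE]
  out$query <- qi
  out$rank <- si
  ord <- order(out$query, out$start, out$end, out$rank, method = "radix")
  out[ord, , drop = FALSE]
}

#' Merge intervals into their coverage union
#'
#' Collapses a set of intervals into the minimal sorted set of disjoint
#' intervals covering the same nucleotides. Overlapping and abutting inputs
#' are merged (coverage semantics: adjacency leaves no gap even though
#' abutting intervals share no nucleotide).
#'
#' @param x Data frame of intervals.
#' @return A tibble of disjoint intervals sorted by (chrom, start).
#' @export
#'
#' @examples
#' coverage_union(tibble::tibble(
#'   chrom = "chr1", start = c(0, 5), end = c(10, 20)
#' ))
coverage_union <- function(x) {
  x <- check_intervals(x)
  if (nrow(x) == 0) {
    return(tibble::tibble(
      chrom = character(0), start = double(0), end = double(0)
    ))
  }
  gr_to_tbl(GenomicRanges::reduce(as_gr(x)))
}

#' Total nucleotides covered by a set of intervals
#'
#' @param x Data frame of intervals (need not be disjoint).
#' @return Number of distinct nucleotides covered.
#' @export
coverage_bp <- function(x) {
  m <- coverage_union(x)
  sum(m$end - m$start)
}

#' Nucleotides covered by both of two interval sets
#'
#' Counts positions lying in the coverage union of `a` and in that of `b`.
#' Symmetric; `intersect_bp(a, a)` equals `coverage_bp(a)`.
#'
#' @param a,b Data frames of intervals.
#' @return Number of shared nucleotides.
#' @export
intersect_bp <- function(a, b) {
  a <- check_intervals(a, arg = "a")
  b <- check_intervals(b, arg = "b")
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(0)
  }
  lev <- sort(
    union(unique(as.character(a$chrom)), unique(as.character(b$chrom))),
    method = "radix"
  )
  ga <- GenomicRanges::reduce(as_gr(a, seqlevels = lev))
  gb <- GenomicRanges::reduce(as_gr(b, seqlevels = lev))
  sum(GenomicRanges::width(GenomicRanges::intersect(ga, gb)))
}
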