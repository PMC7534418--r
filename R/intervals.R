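#' Construct a table of genomic intervals
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end`
#' and `strand`, using the package-wide 0-based half-open convention:
#' `start` is the first base of the feature, `end` is one past the last,
#' and `end - start` is the length.
#'
#' @param chrom Chromosome names (non-empty character).
#' @param start 0-based inclusive start positions.
#' @param end 0-based exclusive end positions (`end > start`).
#' @param strand `"+"`, `"-"` or `"."` (unstranded).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`.
#' @examples
#' genomic_intervals("chr1", 0, 100)
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

#' Validate an interval table
#'
#' Checks the invariants of the internal interval representation:
#' non-empty chromosome names, `0 <= start < end`, strand in `+`/`-`/`.`.
#'
#' @param x Data frame with columns `chrom`, `start`, `end` (and
#'   optionally `strand`).
#' @return `x`, invisibly; stops on violation.
#' @export
validate_intervals <- function(x) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  if (any(!nzchar(x$chrom)) || anyNA(x$chrom))
    stop("interval with empty chromosome name")
  if (anyNA(x$start) || anyNA(x$end))
    stop("interval with missing coordinate")
  if (any(x$start < 0)) stop("interval with negative start")
  if (any(x$end <= x$start)) stop("interval with end <= start (zero/negative length)")
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  invisible(x)
}

## merge overlapping/adjacent intervals per chromosome; strand is dropped
merge_intervals <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  parts <- split(x, x$chrom)
  out <- lapply(names(parts), function(ch) {
    p <- parts[[ch]]
    ir <- IRanges::reduce(IRanges::IRanges(start = p$start + 1, end = p$end))
    data.frame(chrom = ch, start = IRanges::start(ir) - 1,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Build a coverage index for fast covered-base queries
#'
#' Merges a feature set per chromosome and precomputes prefix sums of
#' merged-interval lengths, so that the number of feature-covered bases in
#' any query window is an O(log n) lookup.  This is the workhorse behind
#' [window_coverage()] and the permutation machinery, where the same
#' repeat annotation is queried against hundreds of thousands of windows.
#'
#' @param features Interval table (see [genomic_intervals()]).
#' @return An object of class `coverage_index`.
#' @export
coverage_index <- function(features) {
  m <- merge_intervals(features)
  idx <- lapply(split(m, m$chrom), function(p) {
    p <- p[order(p$start), , drop = FALSE]
    list(start = p$start, end = p$end,
         cum = c(0, cumsum(p$end - p$start)))
  })
  structure(list(chroms = idx), class = "coverage_index")
}

## covered bases of [start, end) on one chromosome; start/end may be vectors
covered_bases <- function(index, chrom, start, end) {
  stopifnot(inherits(index, "coverage_index"))
  p <- index$chroms[[chrom]]
  if (is.null(p)) return(numeric(length(start)))
  n <- length(p$start)
  ## total covered in [0, x): full intervals before + partial overlap
  cum_at <- function(x) {
    i <- findInterval(x, p$start)             # intervals with start < x (starts are sorted, x not equal? x==start -> includes)
    full <- p$cum[pmax(i, 0) + 1]
    ## interval i may extend past x; subtract the uncovered tail
    adj <- ifelse(i >= 1, pmax(0, p$end[pmax(i, 1)] - pmax(x, p$start[pmax(i, 1)])), 0)
    full - adj
  }
  cum_at(end) - cum_at(start)
}

## pairwise overlap in bases between two single intervals (same chrom assumed
## checked by caller); vectorized
overlap_bases <- function(start1, end1, start2, end2) {
  pmax(0, pmin(end1, end2) - pmax(start1, start2))
}

#' Fraction of one interval covered by another
#'
#' Encompassment of `a` by `b`: overlapping bases divided by the length of
#' `a`.  Intervals on different chromosomes have encompassment 0.
#'
#' @param a,b Single-row interval tables (or lists with `chrom`, `start`,
#'   `end`).
#' @return Fraction in `[0, 1]`.
#' @examples
#' a <- genomic_intervals("chr1", 100, 200)
#' b <- genomic_intervals("chr1", 0, 1000)
#' encompassment_fraction(a, b)  # 1
#' @export
encompassment_fraction <- function(a, b) {
  if (a$chrom[1] != b$chrom[1]) return(0)
  overlap_bases(a$start[1], a$end[1], b$start[1], b$end[1]) /
    (a$end[1] - a$start[1])
}
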