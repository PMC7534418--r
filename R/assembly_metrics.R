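#' Split a scaffold sequence into contig lengths at gap runs
#'
#' Contigs are the maximal non-gap segments between N-runs of length
#' `>= min_gap_len`; shorter N-runs stay inside their contig.
#'
#' @param sequence A single nucleotide string.
#' @param min_gap_len Minimum N-run length that splits (default 10).
#' @return Numeric vector of contig lengths (possibly empty).
#' @examples
#' split_into_contigs(paste0("AAAA", strrep("N", 100), "CCC"))  # 4 3
#' @export
split_into_contigs <- function(sequence, min_gap_len = 10L) {
  stopifnot(min_gap_len >= 1)
  gaps <- find_assembly_gaps(sequence, min_len = min_gap_len)
  L <- nchar(sequence)
  bounds <- c(0, as.vector(rbind(gaps$start, gaps$end)), L)
  starts <- bounds[seq(1, length(bounds), 2)]
  ends <- bounds[seq(2, length(bounds), 2)]
  len <- ends - starts
  len[len > 0]
}

#' NX length statistic of a set of contig lengths
#'
#' The smallest length `L` such that contigs of length `>= L` together
#' cover at least `x` percent of the total; `nx(lengths, 50)` is the
#' familiar N50.
#'
#' @param lengths Non-empty numeric vector of lengths.
#' @param x Percentage in `(0, 100]`.
#' @return The NX length.
#' @examples
#' nx(c(1, 1, 1, 1, 1, 5), 50)  # 5
#' @export
nx <- function(lengths, x = 50) {
  stopifnot(length(lengths) > 0, x > 0, x <= 100)
  s <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(s)
  s[which(cum >= x / 100 * sum(s))[1]]
}

#' Fraction of softmasked (lowercase) bases in a sequence
#'
#' @param sequence Non-empty nucleotide string.
#' @param exclude_n If `TRUE`, N bases are removed from the denominator;
#'   the default keeps them, matching a "percent of assembly bases"
#'   reading.
#' @return Fraction in `[0, 1]`.
#' @examples
#' masked_fraction("acgtACGT")  # 0.5
#' @export
masked_fraction <- function(sequence, exclude_n = FALSE) {
  stopifnot(length(sequence) == 1, nchar(sequence) > 0)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  lower <- sum(chars %in% letters)
  denom <- if (exclude_n) sum(!chars %in% c("N", "n")) else length(chars)
  if (denom == 0) stop("no countable bases")
  lower / denom
}

#' Per-sequence and total assembly summary statistics
#'
#' For each sequence: total length, contig count and contig N50 after
#' splitting at N-runs of `>= min_gap_len`, gap count, and softmasked
#' fraction.  A final `All` row aggregates every column (N50 over the
#' pooled contig set; masked fraction length-weighted).
#'
#' @param genome Named character vector of sequences.
#' @param min_gap_len Gap-splitting threshold (default 10).
#' @return Data frame with columns `name`, `total_length`, `contig_count`,
#'   `contig_n50`, `gap_count`, `masked_fraction`; last row is `All`.
#' @export
summarize_assembly <- function(genome, min_gap_len = 10L) {
  stopifnot(length(genome) > 0, !is.null(names(genome)))
  per <- lapply(names(genome), function(nm) {
    s <- genome[[nm]]
    contigs <- split_into_contigs(s, min_gap_len)
    gaps <- find_assembly_gaps(s, min_gap_len)
    data.frame(name = nm, total_length = nchar(s),
               contig_count = length(contigs),
               contig_n50 = if (length(contigs)) nx(contigs, 50) else NA_real_,
               gap_count = nrow(gaps),
               masked_fraction = masked_fraction(s),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, per)
  all_contigs <- unlist(lapply(genome, split_into_contigs, min_gap_len))
  totals <- data.frame(
    name = "All", total_length = sum(rows$total_length),
    contig_count = sum(rows$contig_count),
    contig_n50 = if (length(all_contigs)) nx(all_contigs, 50) else NA_real_,
    gap_count = sum(rows$gap_count),
    masked_fraction = sum(rows$masked_fraction * rows$total_length) /
      sum(rows$total_length),
    stringsAsFactors = FALSE)
  out <- rbind(rows, totals)
  rownames(out) <- NULL
  out
}
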