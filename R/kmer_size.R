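#' Locate the error/signal threshold in a k-mer spectrum
#'
#' Sequencing errors create a spike of low-multiplicity k-mers; genuine
#' genomic k-mers pile up around the coverage depth.  The threshold is the
#' multiplicity of the first local minimum of counts scanning upward from
#' m = 1; everything below it is treated as error mass.  Peak detection
#' runs on raw counts by default; an optional centered moving-average
#' window smooths the spectrum first.
#'
#' @param hist A [kmer_histogram()].
#' @param smooth Moving-average window width (0 = off, the default).
#' @return The threshold multiplicity (scalar).
#' @examples
#' h <- kmer_histogram(1:5, c(100, 10, 50, 80, 50))
#' find_error_threshold(h)  # 2
#' @export
find_error_threshold <- function(hist, smooth = 0L) {
  stopifnot(inherits(hist, "kmer_histogram"), nrow(hist) > 0)
  cnt <- hist$count
  if (smooth > 1) {
    k <- as.integer(smooth)
    cnt <- stats::filter(cnt, rep(1 / k, k), sides = 2)
    cnt[is.na(cnt)] <- hist$count[is.na(cnt)]
    cnt <- as.numeric(cnt)
  }
  n <- length(cnt)
  if (n == 1) return(hist$multiplicity[1])  # no error spike resolvable
  ## first i with cnt[i] <= both neighbours and some later bin rises above it
  for (i in seq_len(n - 1)) {
    if (i > 1 && cnt[i] <= cnt[i - 1] && cnt[i] <= cnt[i + 1]) {
      if (max(cnt[(i + 1):n]) > cnt[i]) return(hist$multiplicity[i])
    }
    if (i == 1 && n >= 2 && cnt[2] > cnt[1]) return(hist$multiplicity[1])
  }
  stop("no coverage peak: histogram has no local minimum followed by a peak")
}

#' Estimate haploid genome size from a k-mer histogram
#'
#' Peak-based estimator: after discarding error mass below the threshold
#' from [find_error_threshold()], the homozygous coverage peak is the
#' multiplicity with the largest count, and
#' `genome_size = sum(m * count_m, m >= threshold) / peak`.
#' This deliberately fits no heterozygous-peak mixture; the metadata of
#' the returned object records that simplification.
#'
#' @param hist A [kmer_histogram()].
#' @param smooth Moving-average window for peak detection (default off).
#' @param threshold Explicit error threshold; overrides
#'   [find_error_threshold()] when the spectrum's error valley is not
#'   detectable (e.g. sparse bins).
#' @return List of class `genome_size_estimate` with `genome_size`,
#'   `error_threshold`, `hom_peak`, `included_kmer_mass`, `k`, `model`.
#' @examples
#' h <- kmer_histogram(c(1, 20), c(1e6, 1000))
#' estimate_genome_size(h, threshold = 2)$genome_size  # 1000
#' @export
estimate_genome_size <- function(hist, smooth = 0L, threshold = NULL) {
  thr <- if (is.null(threshold)) find_error_threshold(hist, smooth = smooth)
         else threshold
  keep <- hist$multiplicity >= thr
  m <- hist$multiplicity[keep]
  cnt <- hist$count[keep]
  peak <- m[which.max(cnt)]
  mass <- sum(m * cnt)
  structure(list(genome_size = mass / peak,
                 error_threshold = thr,
                 hom_peak = peak,
                 included_kmer_mass = mass,
                 k = attr(hist, "k"),
                 model = "haploid-peak (no heterozygous mixture fit)"),
            class = "genome_size_estimate")
}

#' @export
print.genome_size_estimate <- function(x, ...) {
  cat(sprintf(
    "Genome size estimate: %.0f bp\n  coverage peak: %gx  error threshold: m >= %g\n  included k-mer mass: %.0f (k = %d)\n  model: %s\n",
    x$genome_size, x$hom_peak, x$error_threshold, x$included_kmer_mass,
    x$k, x$model))
  invisible(x)
}
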