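#' Structural-variant curation thresholds
#'
#' Defaults encode the curation chain: precise (split-read resolved)
#' breakpoints, length strictly under 5 Mb, FILTER `PASS`, median mapping
#' quality strictly greater than zero, and at least five supporting
#' paired-end reads.
#'
#' @param max_length Exclusive length ceiling in bases (default 5e6).
#' @param min_pe Inclusive minimum paired-end support (default 5).
#' @param require_precise Require the PRECISE flag (default `TRUE`).
#' @param require_pass Require FILTER == PASS (default `TRUE`).
#' @param min_mapq_exclusive Exclusive mapping-quality floor (default 0).
#' @param pe_plus_sr Count PE+SR rather than PE alone against `min_pe`
#'   (default `FALSE`; "paired-reads" names the paired-end evidence
#'   class).
#' @return List of class `sv_filter_config`.
#' @export
sv_filter_config <- function(max_length = 5e6, min_pe = 5L,
                             require_precise = TRUE, require_pass = TRUE,
                             min_mapq_exclusive = 0L, pe_plus_sr = FALSE) {
  stopifnot(max_length >= 0, min_pe >= 0, min_mapq_exclusive >= 0)
  structure(list(max_length = max_length, min_pe = min_pe,
                 require_precise = require_precise,
                 require_pass = require_pass,
                 min_mapq_exclusive = min_mapq_exclusive,
                 pe_plus_sr = pe_plus_sr),
            class = "sv_filter_config")
}

#' Structural-variant length
#'
#' `end - pos` on the 1-based VCF fields, for all variant types.
#' Zero-length records (pos == end) are legal but degenerate.
#'
#' @param records Record table of an [sv_set()] (or the set itself).
#' @return Numeric vector of lengths.
#' @export
sv_length <- function(records) {
  if (inherits(records, "sv_set")) records <- records$records
  records$end - records$pos
}

#' Apply the curation filter chain to SV records
#'
#' @param records Record table or [sv_set()].
#' @param config An [sv_filter_config()].
#' @return Data frame with `id`, `pass` (logical) and `reasons`
#'   (comma-joined violated-rule labels, empty when passing).  A record
#'   that is PRECISE but has `sr == 0` (or vice versa) triggers a warning,
#'   since the two encodings of split-read resolution disagree.
#' @export
passes_filters <- function(records, config = sv_filter_config()) {
  if (inherits(records, "sv_set")) records <- records$records
  stopifnot(inherits(config, "sv_filter_config"))
  len <- records$end - records$pos
  pe_val <- if (config$pe_plus_sr) records$pe + records$sr else records$pe
  checks <- list(
    precise = if (config$require_precise) records$precise else TRUE,
    max_length = len < config$max_length,
    filter_pass = if (config$require_pass) records$filter == "PASS" else TRUE,
    mapq = records$mapq > config$min_mapq_exclusive,
    min_pe = pe_val >= config$min_pe)
  mat <- do.call(cbind, checks)
  if (any(records$precise != (records$sr > 0)))
    warning("PRECISE flag and split-read count disagree for ",
            sum(records$precise != (records$sr > 0)), " record(s)")
  reasons <- apply(mat, 1, function(r)
    paste(names(checks)[!r], collapse = ","))
  data.frame(id = records$id, pass = rowSums(!mat) == 0,
             reasons = reasons, stringsAsFactors = FALSE)
}

#' Minor allele frequency from diploid genotype calls
#'
#' Alternate-allele frequency over called genotypes (missing excluded),
#' folded to the minor allele: `MAF = min(f_alt, 1 - f_alt)`.
#'
#' @param genotypes Character vector or matrix of `"0/0"`, `"0/1"`,
#'   `"1/1"`, `NA`.  A matrix is processed row-wise.
#' @return For a vector: list with `maf` and `called`.  For a matrix: a
#'   data frame with one row per variant.
#' @examples
#' minor_allele_frequency(c("0/1", "0/1", rep("0/0", 8)))$maf  # 0.1
#' @export
minor_allele_frequency <- function(genotypes) {
  one <- function(g) {
    called <- sum(!is.na(g))
    if (called == 0) stop("all genotypes missing")
    alt <- sum(g == "0/1", na.rm = TRUE) + 2 * sum(g == "1/1", na.rm = TRUE)
    f <- alt / (2 * called)
    list(maf = min(f, 1 - f), called = called)
  }
  if (is.matrix(genotypes)) {
    res <- apply(genotypes, 1, one)
    data.frame(maf = vapply(res, `[[`, 0, "maf"),
               called = vapply(res, `[[`, 0, "called"))
  } else one(genotypes)
}

#' Population summary of curated structural variants
#'
#' Applies the filter chain, computes per-variant minor allele
#' frequencies over the sample panel, and summarizes per variant type:
#' count, median length (midpoint convention for even sets), and count
#' with MAF at or above the threshold.
#'
#' @param sv An [sv_set()].
#' @param config An [sv_filter_config()].
#' @param maf_threshold Inclusive MAF threshold (default 0.01).
#' @return List of class `population_sv_summary` with `per_type` (data
#'   frame `sv_type`, `n`, `median_length`, `n_maf`), `per_variant`
#'   (curated records with `length`, `maf`, `called`), and `filter`
#'   (the [passes_filters()] table over all input records).
#' @export
summarize_population <- function(sv, config = sv_filter_config(),
                                 maf_threshold = 0.01) {
  stopifnot(inherits(sv, "sv_set"))
  flt <- passes_filters(sv$records, config)
  keep <- flt$pass
  rec <- sv$records[keep, , drop = FALSE]
  per_variant <- rec
  if (nrow(rec)) {
    per_variant$length <- sv_length(rec)
    mafs <- minor_allele_frequency(sv$genotypes[keep, , drop = FALSE])
    per_variant$maf <- mafs$maf
    per_variant$called <- mafs$called
  } else {
    per_variant$length <- numeric(); per_variant$maf <- numeric()
    per_variant$called <- numeric()
  }
  per_type <- do.call(rbind, lapply(SV_TYPES, function(t) {
    s <- per_variant[per_variant$sv_type == t, , drop = FALSE]
    data.frame(sv_type = t, n = nrow(s),
               median_length = if (nrow(s)) median(s$length) else NA_real_,
               n_maf = sum(s$maf >= maf_threshold),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_type = per_type, per_variant = per_variant,
                 filter = flt, maf_threshold = maf_threshold),
            class = "population_sv_summary")
}

#' Histogram overlap between deletion lengths and TE lengths
#'
#' Bins both samples on a shared grid `[0, range_max)`, normalizes each
#' histogram to sum 1, and reports the overlap coefficient
#' `sum(pmin(p, q))` — 1 for identical distributions, 0 for disjoint
#' support.  Defaults follow the small-deletion (< 10 kb) comparison
#' against retrotransposon length distributions: 500-bp bins over 10 kb.
#'
#' @param del_lengths Deletion lengths in bases (non-empty).
#' @param te_lengths TE lengths in bases (non-empty).
#' @param bin_width Bin width in bases (default 500).
#' @param range_max Upper bound of the shared grid (default 10000);
#'   lengths at or above it are dropped before normalization.
#' @return List with `overlap`, `breaks`, `del_density`, `te_density`.
#' @export
deletion_te_length_overlap <- function(del_lengths, te_lengths,
                                       bin_width = 500, range_max = 10000) {
  stopifnot(length(del_lengths) > 0, length(te_lengths) > 0, bin_width >= 1)
  breaks <- seq(0, range_max, by = bin_width)
  if (tail(breaks, 1) < range_max) breaks <- c(breaks, range_max)
  binned <- function(x) {
    x <- x[x >= 0 & x < range_max]
    if (length(x) == 0) stop("no lengths inside [0, range_max)")
    h <- tabulate(findInterval(x, breaks), nbins = length(breaks) - 1)
    h / sum(h)
  }
  p <- binned(del_lengths); q <- binned(te_lengths)
  list(overlap = sum(pmin(p, q)), breaks = breaks,
       del_density = p, te_density = q)
}
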