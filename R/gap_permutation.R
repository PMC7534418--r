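#' Flanking windows at a fixed distance from gap boundaries
#'
#' For each gap, the left window `[start - d, start)` and right window
#' `[end, end + d)`.  Windows that would extend past a chromosome end are
#' discarded outright (not truncated), so every retained window has
#' exactly width `d` and observed and permuted statistics average windows
#' of identical width.
#'
#' @param gaps Gap interval table (`chrom`, `start`, `end`).
#' @param distance Window width `d` in bases (>= 1).
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @return Interval table of flank windows (possibly empty).
#' @examples
#' flank_windows(data.frame(chrom = "c", start = 100, end = 200),
#'               50, c(c = 10000))
#' @export
flank_windows <- function(gaps, distance, chrom_lengths) {
  stopifnot(distance >= 1)
  L <- chrom_lengths[gaps$chrom]
  left <- data.frame(chrom = gaps$chrom, start = gaps$start - distance,
                     end = gaps$start, stringsAsFactors = FALSE)
  right <- data.frame(chrom = gaps$chrom, start = gaps$end,
                      end = gaps$end + distance, stringsAsFactors = FALSE)
  left <- left[left$start >= 0, , drop = FALSE]
  right <- right[right$end <= L[right$chrom], , drop = FALSE]
  out <- rbind(left, right)
  rownames(out) <- NULL
  out
}

## GC fraction of windows, N excluded from the denominator
window_gc <- function(windows, genome) {
  vapply(seq_len(nrow(windows)), function(i) {
    s <- substr(genome[[windows$chrom[i]]],
                windows$start[i] + 1, windows$end[i])
    chars <- toupper(strsplit(s, "", fixed = TRUE)[[1]])
    gc <- sum(chars %in% c("G", "C"))
    acgt <- sum(chars %in% c("A", "C", "G", "T"))
    if (acgt == 0) NA_real_ else gc / acgt
  }, 0)
}

#' Mean flank statistic at one distance
#'
#' `repeat_fraction`: per-window fraction of bases covered by a repeat;
#' `gc_fraction`: per-window (G+C)/(A+C+G+T), Ns excluded from the
#' denominator.  The statistic is the unweighted mean over all flank
#' windows (both flanks of every gap contribute as separate windows).
#'
#' @param gaps Gap interval table.
#' @param distance Flank width in bases.
#' @param statistic `"repeat_fraction"` or `"gc_fraction"`.
#' @param chrom_lengths Named chromosome lengths.
#' @param repeats Repeat interval table (required for `repeat_fraction`);
#'   a precomputed [coverage_index()] is also accepted.
#' @param genome Named sequence vector (required for `gc_fraction`).
#' @return Scalar mean statistic.
#' @export
mean_flank_statistic <- function(gaps, distance,
                                 statistic = c("repeat_fraction", "gc_fraction"),
                                 chrom_lengths, repeats = NULL, genome = NULL) {
  statistic <- match.arg(statistic)
  w <- flank_windows(gaps, distance, chrom_lengths)
  if (nrow(w) == 0) stop("no valid flank windows at distance ", distance)
  if (statistic == "repeat_fraction") {
    if (is.null(repeats)) stop("repeat_fraction needs repeats")
    idx <- if (inherits(repeats, "coverage_index")) repeats
           else coverage_index(repeats)
    vals <- unlist(lapply(split(seq_len(nrow(w)), w$chrom), function(ii)
      covered_bases(idx, w$chrom[ii[1]], w$start[ii], w$end[ii]) /
        (w$end[ii] - w$start[ii])))
    mean(vals)
  } else {
    if (is.null(genome)) stop("gc_fraction needs the genome sequence")
    mean(window_gc(w, genome), na.rm = TRUE)
  }
}

#' Randomly re-place gaps on the chromosomes
#'
#' Each gap keeps its length and is placed uniformly: chromosome chosen
#' with probability proportional to length, offset uniform over the
#' feasible range.  Placed gaps must not overlap each other (re-drawn on
#' collision up to `max_tries` per gap); they may overlap the original
#' gap positions.
#'
#' @param gaps Gap interval table.
#' @param chrom_lengths Named chromosome lengths.
#' @param max_tries Redraws allowed per gap before giving up.
#' @return Gap table of identical length multiset.
#' @export
shuffle_gaps <- function(gaps, chrom_lengths, max_tries = 1000L) {
  n <- nrow(gaps)
  lens <- gaps$end - gaps$start
  chroms <- names(chrom_lengths)
  placed_ch <- character(n); placed_s <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      ch <- sample(chroms, 1, prob = as.numeric(chrom_lengths))
      room <- chrom_lengths[[ch]] - lens[i]
      if (room < 0) next
      s <- floor(runif(1, 0, room + 1))
      prev <- which(placed_ch[seq_len(i - 1)] == ch)
      if (!any(placed_s[prev] < s + lens[i] &
               placed_s[prev] + lens[prev] > s)) {
        placed_ch[i] <- ch; placed_s[i] <- s; ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place shuffled gap after ", max_tries, " tries")
  }
  data.frame(chrom = placed_ch, start = placed_s, end = placed_s + lens,
             stringsAsFactors = FALSE)
}

#' Permutation test for sequence content at gap flanks
#'
#' Compares the observed mean flank statistic against the distribution
#' obtained by randomly re-placing the gaps `n_perm` times and
#' recomputing the identical statistic.  The p-value is the proportion of
#' permuted means strictly greater than the observed mean (ties do not
#' count); `p = 0` therefore means "less than `1/n_perm`".
#'
#' @param gaps Gap interval table (non-empty).
#' @param chrom_lengths Named chromosome lengths.
#' @param repeats Repeat table (needed for `repeat_fraction`).
#' @param genome Named sequence vector (needed for `gc_fraction`).
#' @param n_perm Number of permutations (default 1000).
#' @param distances Flank widths in bases (default 50, 100, 500, 1000,
#'   1500).
#' @param statistics Statistics to evaluate (default both available given
#'   the inputs supplied).
#' @param seed Integer seed for the permutation stream.
#' @return Data frame with one row per distance x statistic: `distance`,
#'   `statistic`, `observed`, `p_value`, `zero_variance` (flag for a
#'   degenerate constant permutation distribution).  The full permuted
#'   distributions are attached as attribute `permuted` (a named list).
#' @export
permutation_test <- function(gaps, chrom_lengths, repeats = NULL,
                             genome = NULL, n_perm = 1000L,
                             distances = c(50, 100, 500, 1000, 1500),
                             statistics = NULL, seed = 1L) {
  stopifnot(nrow(gaps) > 0, n_perm >= 1, all(distances > 0))
  if (is.null(statistics))
    statistics <- c(if (!is.null(repeats)) "repeat_fraction",
                    if (!is.null(genome)) "gc_fraction")
  if (length(statistics) == 0) stop("no statistic computable from inputs")
  idx <- if (!is.null(repeats)) {
    if (inherits(repeats, "coverage_index")) repeats else coverage_index(repeats)
  } else NULL
  set.seed(seed)
  shuffles <- lapply(seq_len(n_perm), function(i)
    shuffle_gaps(gaps, chrom_lengths))
  rows <- list(); perms <- list()
  for (d in distances) {
    for (st in statistics) {
      obs <- mean_flank_statistic(gaps, d, st, chrom_lengths,
                                  repeats = idx, genome = genome)
      pv <- vapply(shuffles, function(g)
        mean_flank_statistic(g, d, st, chrom_lengths,
                             repeats = idx, genome = genome), 0)
      key <- paste0(st, "_d", d)
      perms[[key]] <- pv
      rows[[key]] <- data.frame(
        distance = d, statistic = st, observed = obs,
        p_value = mean(pv > obs),
        zero_variance = length(unique(pv)) == 1,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "permuted") <- perms
  out
}
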