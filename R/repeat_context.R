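#' Classify repeats by genic context and strand concordance
#'
#' A repeat is genic when it overlaps a gene span by at least one base
#' (introns and UTRs count; set `exons_only` for the stricter mode).
#' Genic, stranded repeats get a strand relation (`same`/`different`)
#' relative to the overlapping gene; when several genes overlap, the
#' leftmost by coordinate wins and the `multi_gene` flag records the tie.
#'
#' @param repeats Repeat table (see [read_repeat_table()]).
#' @param genes Gene span table ([gene_spans()]) or list of
#'   [gene_model()] objects.
#' @param exons_only If `TRUE`, overlap is computed against exons rather
#'   than gene spans (requires gene models, not spans).
#' @return `repeats` with added columns `context` (`genic`/`non-genic`),
#'   `strand_relation` (`same`/`different`/`unstranded`) and `multi_gene`.
#' @export
classify_repeats <- function(repeats, genes, exons_only = FALSE) {
  if (is.list(genes) && !is.data.frame(genes)) {
    spans <- if (exons_only) exon_spans(genes) else gene_spans(genes)
  } else {
    if (exons_only) stop("exons_only requires gene models, not spans")
    spans <- genes
  }
  n <- nrow(repeats)
  context <- rep("non-genic", n)
  relation <- rep("unstranded", n)
  multi <- rep(FALSE, n)
  for (ch in unique(repeats$chrom)) {
    ri <- which(repeats$chrom == ch)
    gs <- spans[spans$chrom == ch, , drop = FALSE]
    if (nrow(gs) == 0) next
    gs <- gs[order(gs$start), , drop = FALSE]
    for (i in ri) {
      hit <- which(gs$start < repeats$end[i] & gs$end > repeats$start[i])
      if (length(hit) == 0) next
      context[i] <- "genic"
      multi[i] <- length(hit) > 1
      g <- gs[hit[1], ]
      if (repeats$strand[i] %in% c("+", "-") && g$strand %in% c("+", "-"))
        relation[i] <- if (repeats$strand[i] == g$strand) "same" else "different"
    }
  }
  repeats$context <- context
  repeats$strand_relation <- relation
  repeats$multi_gene <- multi
  repeats
}

## exon intervals of a gene-model list, one row per exon
exon_spans <- function(genes) {
  out <- lapply(genes, function(g) {
    ex <- do.call(rbind, lapply(g$transcripts, function(t) t$exons))
    data.frame(chrom = g$span$chrom, start = ex$start, end = ex$end,
               strand = g$span$strand, gene_id = g$gene_id,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Repeat composition by class within genic and non-genic space
#'
#' For every repeat class: element counts and within-context shares, the
#' non-genic vs genic fold difference of shares, and the same:different
#' strand ratio among genic stranded elements.
#'
#' @param repeats Repeat table.
#' @param genes Gene spans or gene models (see [classify_repeats()]).
#' @param weight `"count"` (each element counts once, the default) or
#'   `"bases"` (elements weighted by length).
#' @return List of class `context_composition` with a per-class data frame
#'   (`class`, `genic_n`, `nongenic_n`, `genic_share`, `nongenic_share`,
#'   `fold_nongenic_vs_genic`, `strand_same`, `strand_different`,
#'   `strand_ratio`) and context totals.
#' @export
context_composition <- function(repeats, genes, weight = c("count", "bases")) {
  weight <- match.arg(weight)
  stopifnot(nrow(repeats) > 0)
  cl <- classify_repeats(repeats, genes)
  w <- if (weight == "bases") cl$end - cl$start else rep(1, nrow(cl))
  classes <- sort(unique(cl$class))
  genic_tot <- sum(w[cl$context == "genic"])
  nongenic_tot <- sum(w[cl$context == "non-genic"])
  per <- lapply(classes, function(k) {
    sel <- cl$class == k
    gn <- sum(w[sel & cl$context == "genic"])
    ng <- sum(w[sel & cl$context == "non-genic"])
    gshare <- if (genic_tot > 0) gn / genic_tot else NA_real_
    nshare <- if (nongenic_tot > 0) ng / nongenic_tot else NA_real_
    same <- sum(sel & cl$strand_relation == "same")
    diff <- sum(sel & cl$strand_relation == "different")
    data.frame(class = k, genic_n = gn, nongenic_n = ng,
               genic_share = gshare, nongenic_share = nshare,
               fold_nongenic_vs_genic =
                 if (!is.na(gshare) && !is.na(nshare) && gshare > 0)
                   nshare / gshare else NA_real_,
               strand_same = same, strand_different = diff,
               strand_ratio = if (diff > 0) same / diff else NA_real_,
               stringsAsFactors = FALSE)
  })
  structure(list(by_class = do.call(rbind, per),
                 genic_total = genic_tot, nongenic_total = nongenic_tot,
                 weight = weight,
                 empty_context = c(genic = genic_tot == 0,
                                   nongenic = nongenic_tot == 0)),
            class = "context_composition")
}

#' Count ratio between two repeat classes
#'
#' @param repeats Repeat table.
#' @param class_a,class_b Class labels (matched against `class`, or
#'   against `class/family` when the label contains a slash).
#' @return List with `ratio` (count_a / count_b), `counts`, and `label`
#'   (nearest-integer `"n:1"` rendering).
#' @examples
#' r <- data.frame(chrom = "c", start = 0:3 * 10, end = 0:3 * 10 + 5,
#'                 class = c("LTR", "LTR", "LTR", "LINE"),
#'                 family = c("Gypsy", "Gypsy", "Gypsy", ""),
#'                 strand = "+")
#' class_count_ratio(r, "LTR", "LINE")$label  # "3:1"
#' @export
class_count_ratio <- function(repeats, class_a, class_b) {
  key <- function(lbl) {
    if (grepl("/", lbl, fixed = TRUE)) {
      parts <- strsplit(lbl, "/", fixed = TRUE)[[1]]
      repeats$class == parts[1] & repeats$family == parts[2]
    } else repeats$class == lbl
  }
  a <- sum(key(class_a)); b <- sum(key(class_b))
  if (b == 0) stop("class ", class_b, " absent (zero denominator)")
  list(ratio = a / b, counts = c(a = a, b = b),
       label = paste0(round(a / b), ":1"))
}

#' Covered fraction of non-overlapping genome windows
#'
#' Tiles each chromosome with non-overlapping windows and reports, per
#' window, the fraction of bases covered by at least one feature.  The
#' final partial window is normalized by its own width.
#'
#' @param features Interval table.
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param window Window size in bases (>= 1).
#' @return Data frame `chrom`, `start`, `end`, `covered_fraction`.
#' @export
window_coverage <- function(features, chrom_lengths, window) {
  stopifnot(window >= 1, !is.null(names(chrom_lengths)))
  idx <- coverage_index(features)
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq(0, L - 1, by = window)
    ends <- pmin(starts + window, L)
    data.frame(chrom = ch, start = starts, end = ends,
               covered_fraction =
                 covered_bases(idx, ch, starts, ends) / (ends - starts),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
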