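#' Drop gene models with weak evidence support (AED threshold)
#'
#' A gene survives iff its best-supported isoform has
#' `AED <= max_aed`; models with AED strictly greater than the threshold
#' across all isoforms are removed.
#'
#' @param genes List of [gene_model()] objects.
#' @param max_aed Inclusive AED ceiling (default 0.5).
#' @return Surviving subset of `genes`.
#' @export
filter_by_aed <- function(genes, max_aed = 0.5) {
  keep <- vapply(genes, function(g)
    min(vapply(g$transcripts, `[[`, 0, "aed")) <= max_aed, TRUE)
  genes[keep]
}

#' Select the primary (best-supported) isoform of a gene
#'
#' The transcript with the minimum AED; ties broken by greater exonic
#' length, then lexicographically smaller id.
#'
#' @param gene A [gene_model()].
#' @return The primary [transcript()].
#' @export
select_primary <- function(gene) {
  txs <- gene$transcripts
  aed <- vapply(txs, `[[`, 0, "aed")
  len <- vapply(txs, transcript_length, 0)
  ids <- vapply(txs, `[[`, "", "id")
  o <- order(aed, -len, ids)
  txs[[o[1]]]
}

#' Gene expression as the sum of isoform TPMs
#'
#' @param expr TPM matrix (transcripts x samples, see [read_tpm_table()]).
#' @param gene A [gene_model()].
#' @return Named numeric vector: per-sample gene TPM.
#' @export
gene_tpm <- function(expr, gene) {
  ids <- vapply(gene$transcripts, `[[`, "", "id")
  missing <- setdiff(ids, rownames(expr))
  if (length(missing))
    stop("isoform absent from expression table: ", missing[1])
  colSums(expr[ids, , drop = FALSE])
}

#' Final curation of a gene set
#'
#' After AED filtration and primary-isoform selection, a gene is removed
#' iff (a) its primary transcript is shorter than `min_length` bases, or
#' (b) it is a single-exon primary model in a focal-species-specific,
#' single-copy orthogroup (or in no orthogroup at all, an equally
#' species-specific singleton) that either lacks expression support
#' (merged-sample gene TPM `< tpm_threshold`) or is mostly encompassed
#' (`> encompass_threshold` of its span) by another candidate gene.
#' Encompassment is evaluated against all other genes that survive the
#' length rule, so the outcome is order-independent and the filter is
#' idempotent.
#'
#' @param genes List of [gene_model()] objects (post-AED filtration).
#' @param orthogroups Orthogroup table (`orthogroup`, `species`,
#'   `gene_id`; see [read_orthogroups()]).
#' @param expr TPM matrix over all isoforms.
#' @param focal_species Name of the focal species in `orthogroups`.
#' @param min_length Strict primary-transcript length floor (default 50).
#' @param tpm_threshold Expression-support cutoff (default 1; a gene at
#'   exactly the threshold is not removed, since removal needs TPM
#'   strictly below it).
#' @param encompass_threshold Strict coverage fraction above which a gene
#'   counts as encompassed (default 0.9).
#' @param length_mode `"exonic"` (primary-transcript exonic length, the
#'   default) or `"span"` (gene-span length) for the `min_length` rule.
#' @return Data frame of class `filter_report`: `gene_id`, `kept`
#'   (logical), `rule` (`""`, `"min_length"`,
#'   `"specific_og_unsupported"`, `"specific_og_encompassed"`), plus
#'   per-gene `tpm` and `max_encompassment` diagnostics.
#' @export
apply_final_filter <- function(genes, orthogroups, expr, focal_species,
                               min_length = 50, tpm_threshold = 1,
                               encompass_threshold = 0.9,
                               length_mode = c("exonic", "span")) {
  length_mode <- match.arg(length_mode)
  n <- length(genes)
  ids <- vapply(genes, `[[`, "", "gene_id")
  primaries <- lapply(genes, select_primary)
  plen <- if (length_mode == "exonic")
    vapply(primaries, transcript_length, 0)
  else vapply(genes, function(g) g$span$end - g$span$start, 0)
  single_exon <- vapply(primaries, function(t) nrow(t$exons) == 1, TRUE)

  ## focal-specific single-copy orthogroup per gene
  og_of <- setNames(orthogroups$orthogroup, orthogroups$gene_id)
  og_size <- table(orthogroups$orthogroup)
  og_species <- tapply(orthogroups$species, orthogroups$orthogroup,
                       function(s) unique(s))
  specific_single <- vapply(ids, function(g) {
    og <- og_of[g]
    if (is.na(og)) return(TRUE)  # unassigned gene = de facto specific singleton
    identical(as.character(og_species[[og]]), focal_species) &&
      og_size[[og]] == 1
  }, TRUE)

  tpm <- vapply(seq_len(n), function(i) sum(gene_tpm(expr, genes[[i]])), 0)

  fails_length <- plen < min_length
  ## encompassment candidates: genes surviving the length rule
  cand <- which(!fails_length)
  spans <- gene_spans(genes)
  max_enc <- rep(0, n)
  check <- which(single_exon & specific_single & !fails_length &
                   tpm >= tpm_threshold)
  for (i in check) {
    same <- cand[cand != i & spans$chrom[cand] == spans$chrom[i]]
    if (length(same))
      max_enc[i] <- max(overlap_bases(spans$start[i], spans$end[i],
                                      spans$start[same], spans$end[same])) /
        (spans$end[i] - spans$start[i])
  }
  ## diagnostics for all single-exon specific genes
  rule <- rep("", n)
  rule[fails_length] <- "min_length"
  weak <- !fails_length & single_exon & specific_single & tpm < tpm_threshold
  rule[weak] <- "specific_og_unsupported"
  enc <- !fails_length & single_exon & specific_single &
    tpm >= tpm_threshold & max_enc > encompass_threshold
  rule[enc] <- "specific_og_encompassed"
  out <- data.frame(gene_id = ids, kept = rule == "", rule = rule,
                    tpm = tpm, max_encompassment = max_enc,
                    stringsAsFactors = FALSE)
  class(out) <- c("filter_report", "data.frame")
  out
}
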