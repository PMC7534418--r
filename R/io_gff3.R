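#' Construct a transcript (gene isoform)
#'
#' @param id Transcript identifier.
#' @param gene_id Parent gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"`, `"-"` or `"."`.
#' @param exons Data frame with `start`, `end` (0-based half-open),
#'   non-overlapping; sorted internally.
#' @param aed Annotation Edit Distance in `[0, 1]` (0 = perfect evidence
#'   agreement).
#' @return List of class `transcript`.
#' @export
transcript <- function(id, gene_id, chrom, strand, exons, aed) {
  stopifnot(is.data.frame(exons), nrow(exons) >= 1)
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  if (any(exons$end <= exons$start)) stop("exon with end <= start")
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)]))
    stop("overlapping exons in transcript ", id)
  if (is.na(aed) || aed < 0 || aed > 1)
    stop("AED outside [0,1] for transcript ", id)
  structure(list(id = id, gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, aed = as.numeric(aed)),
            class = "transcript")
}

#' Total exonic length of a transcript
#' @param tx A [transcript()].
#' @return Length in bases.
#' @export
transcript_length <- function(tx) sum(tx$exons$end - tx$exons$start)

#' Construct a gene model with one or more isoforms
#'
#' The gene span is the union (bounding interval) of all isoform spans.
#'
#' @param gene_id Gene identifier.
#' @param transcripts List of [transcript()] objects on one
#'   chromosome/strand.
#' @return List of class `gene_model` with `span` (interval table row).
#' @export
gene_model <- function(gene_id, transcripts) {
  stopifnot(length(transcripts) >= 1)
  chroms <- unique(vapply(transcripts, `[[`, "", "chrom"))
  strands <- unique(vapply(transcripts, `[[`, "", "strand"))
  if (length(chroms) != 1 || length(strands) != 1)
    stop("isoforms of gene ", gene_id, " disagree on chromosome/strand")
  start <- min(vapply(transcripts, function(t) min(t$exons$start), 0))
  end <- max(vapply(transcripts, function(t) max(t$exons$end), 0))
  structure(list(gene_id = gene_id,
                 span = genomic_intervals(chroms, start, end, strands),
                 transcripts = transcripts),
            class = "gene_model")
}

#' Gene spans of a gene-model list as one interval table
#' @param genes List of [gene_model()] objects.
#' @return Interval table with one row per gene; row `gene_id` column added.
#' @export
gene_spans <- function(genes) {
  if (length(genes) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      strand = character(), gene_id = character()))
  out <- do.call(rbind, lapply(genes, `[[`, "span"))
  out$gene_id <- vapply(genes, `[[`, "", "gene_id")
  rownames(out) <- NULL
  out
}

parse_gff3_attrs <- function(s) {
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  setNames(vapply(kv, function(p) if (length(p) >= 2) p[2] else "", ""),
           vapply(kv, `[[`, "", 1))
}

#' Read a MAKER-style gene annotation GFF3
#'
#' Consumes the gene/mRNA/exon hierarchy with an `AED` attribute on each
#' mRNA, the dialect MAKER emits.  Coordinates are converted from GFF3
#' 1-based closed to the internal 0-based half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @return List of [gene_model()] objects, in file order of genes.
#' @export
read_gene_gff3 <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) return(list())
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 9)) stop("malformed GFF3 line (expected 9 columns)")
  typ <- vapply(f, `[[`, "", 3)
  keep <- typ %in% c("gene", "mRNA", "exon")
  f <- f[keep]; typ <- typ[keep]
  attrs <- lapply(f, function(x) parse_gff3_attrs(x[9]))
  chrom <- vapply(f, `[[`, "", 1)
  start0 <- as.numeric(vapply(f, `[[`, "", 4)) - 1
  end0 <- as.numeric(vapply(f, `[[`, "", 5))
  strand <- vapply(f, `[[`, "", 7)

  gene_rows <- which(typ == "gene")
  gene_ids <- vapply(attrs[gene_rows], function(a) a[["ID"]], "")
  mrna_rows <- which(typ == "mRNA")
  exon_rows <- which(typ == "exon")

  mrna_parent <- vapply(attrs[mrna_rows], function(a) a[["Parent"]], "")
  if (any(!mrna_parent %in% gene_ids))
    stop("orphan mRNA (Parent gene not in file): ",
         mrna_parent[!mrna_parent %in% gene_ids][1])
  mrna_ids <- vapply(attrs[mrna_rows], function(a) a[["ID"]], "")
  aed <- vapply(attrs[mrna_rows], function(a) {
    v <- suppressWarnings(as.numeric(a[["AED"]]))
    if (is.na(v)) stop("mRNA without parseable AED attribute")
    v
  }, 0)
  if (any(aed < 0 | aed > 1)) stop("AED outside [0,1]")

  exon_parent <- vapply(attrs[exon_rows], function(a) a[["Parent"]], "")
  if (any(!exon_parent %in% mrna_ids))
    stop("orphan exon (Parent mRNA not in file)")

  genes <- lapply(seq_along(gene_rows), function(gi) {
    gid <- gene_ids[gi]
    mi <- which(mrna_parent == gid)
    if (length(mi) == 0) stop("gene without mRNA: ", gid)
    txs <- lapply(mi, function(j) {
      tid <- mrna_ids[j]
      ei <- exon_rows[exon_parent == tid]
      if (length(ei) == 0) stop("mRNA without exons: ", tid)
      ex <- data.frame(start = start0[ei], end = end0[ei])
      mr <- mrna_rows[j]
      if (min(ex$start) < start0[mr] || max(ex$end) > end0[mr])
        stop("exon outside mRNA span in transcript ", tid)
      transcript(tid, gid, chrom[mr], strand[mr], ex, aed[j])
    })
    gene_model(gid, txs)
  })
  genes
}

#' Write gene models as MAKER-style GFF3
#'
#' Inverse of [read_gene_gff3()]: emits gene/mRNA/exon rows with `AED`
#' attributes, converting back to 1-based closed coordinates.
#'
#' @param genes List of [gene_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_gff3 <- function(genes, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("##gff-version 3", con, sep = "\n")
  fmt <- function(chrom, src, type, s0, e0, strand, attr)
    paste(chrom, src, type, s0 + 1, e0, ".", strand, ".", attr, sep = "\t")
  for (g in genes) {
    sp <- g$span
    writeLines(fmt(sp$chrom, "foxtail", "gene", sp$start, sp$end, sp$strand,
                   paste0("ID=", g$gene_id)), con, sep = "\n")
    for (tx in g$transcripts) {
      writeLines(fmt(tx$chrom, "foxtail", "mRNA", min(tx$exons$start),
                     max(tx$exons$end), tx$strand,
                     sprintf("ID=%s;Parent=%s;AED=%s", tx$id, g$gene_id,
                             format(tx$aed, trim = TRUE))), con, sep = "\n")
      for (i in seq_len(nrow(tx$exons)))
        writeLines(fmt(tx$chrom, "foxtail", "exon", tx$exons$start[i],
                       tx$exons$end[i], tx$strand,
                       sprintf("ID=%s.exon%d;Parent=%s", tx$id, i, tx$id)),
                   con, sep = "\n")
    }
  }
  invisible(path)
}
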