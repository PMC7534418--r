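#' Construct a k-mer multiplicity histogram
#'
#' @param multiplicity Strictly increasing integer multiplicities (>= 1).
#' @param count Non-negative k-mer counts.
#' @param k K-mer length (default 21).
#' @return Data frame of class `kmer_histogram` with attribute `k`.
#' @export
kmer_histogram <- function(multiplicity, count, k = 21L) {
  stopifnot(length(multiplicity) == length(count))
  if (any(multiplicity < 1) || any(multiplicity != round(multiplicity)))
    stop("multiplicities must be integers >= 1")
  if (anyDuplicated(multiplicity)) stop("duplicate multiplicity")
  if (is.unsorted(multiplicity, strictly = TRUE))
    stop("multiplicities must be strictly increasing")
  if (any(count < 0)) stop("negative count")
  structure(data.frame(multiplicity = as.numeric(multiplicity),
                       count = as.numeric(count)),
            k = as.integer(k), class = c("kmer_histogram", "data.frame"))
}

#' Read a two-column k-mer histogram file
#'
#' Whitespace-delimited `multiplicity count` pairs, as written by k-mer
#' counters such as Jellyfish.
#'
#' @param path Path to the histogram file.
#' @param k K-mer length the histogram was computed with (default 21).
#' @return A [kmer_histogram()].
#' @export
read_kmer_histogram <- function(path, k = 21L) {
  stopifnot(file.exists(path))
  toks <- scan(path, what = character(), quiet = TRUE)
  if (length(toks) %% 2 != 0) stop("odd token count in histogram file")
  vals <- suppressWarnings(as.numeric(toks))
  if (anyNA(vals)) stop("non-integer token in histogram file: ",
                        toks[is.na(vals)][1])
  m <- vals[seq(1, length(vals), 2)]
  cnt <- vals[seq(2, length(vals), 2)]
  o <- order(m)
  kmer_histogram(m[o], cnt[o], k = k)
}

#' Write a k-mer histogram
#' @param hist A [kmer_histogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kmer_histogram <- function(hist, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(format(hist$multiplicity, scientific = FALSE, trim = TRUE),
                   format(hist$count, scientific = FALSE, trim = TRUE)),
             con, sep = "\n")
  invisible(path)
}

#' Read a BED-like repeat annotation table
#'
#' Tab-delimited `chrom start end class/family strand`, with 0-based
#' half-open coordinates (BED convention).  The label is split on the
#' first `/` into repeat class and family; labels without a slash get an
#' empty family.  Strand `.` is allowed.
#'
#' @param path Path to the table.
#' @return Data frame with columns `chrom`, `start`, `end`, `class`,
#'   `family`, `strand`.
#' @export
read_repeat_table <- function(path) {
  stopifnot(file.exists(path))
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "label", "strand"),
                   colClasses = c("character", "numeric", "numeric",
                                  "character", "character"))
  if (nrow(df) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), class = character(),
                      family = character(), strand = character()))
  if (any(df$start >= df$end)) stop("repeat with start >= end")
  if (!all(df$strand %in% c("+", "-", ".")))
    stop("malformed strand in repeat table")
  slash <- regexpr("/", df$label, fixed = TRUE)
  df$class <- ifelse(slash > 0, substr(df$label, 1, slash - 1), df$label)
  df$family <- ifelse(slash > 0, substring(df$label, slash + 1), "")
  if (any(!nzchar(df$class))) stop("repeat with empty class")
  df[, c("chrom", "start", "end", "class", "family", "strand")]
}

#' Write a repeat annotation table
#' @param repeats Data frame as returned by [read_repeat_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeat_table <- function(repeats, path) {
  label <- ifelse(nzchar(repeats$family),
                  paste0(repeats$class, "/", repeats$family), repeats$class)
  con <- file(path, "wb")
  on.exit(close(con))
  if (nrow(repeats))
    writeLines(paste(repeats$chrom,
                     format(repeats$start, scientific = FALSE, trim = TRUE),
                     format(repeats$end, scientific = FALSE, trim = TRUE),
                     label, repeats$strand, sep = "\t"), con, sep = "\n")
  invisible(path)
}

#' Read a transcript-level TPM expression table
#'
#' TSV with a `transcript_id` column followed by one numeric column per
#' sample.  A complete quantification should have per-sample totals near
#' one million TPM; deviations produce a warning only, since subset
#' tables are legitimate inputs.
#'
#' @param path Path to the table.
#' @return Numeric matrix, rows = transcripts, columns = samples.
#' @export
read_tpm_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  stopifnot(names(df)[1] == "transcript_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$transcript_id
  if (any(m < 0)) stop("negative TPM")
  tot <- colSums(m)
  off <- abs(tot - 1e6) / 1e6 > 0.05
  if (any(off) && all(tot > 0))
    warning("per-sample TPM totals far from 1e6 (partial table?)")
  m
}

#' Write a TPM table
#' @param tpm Numeric matrix with transcript rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tpm_table <- function(tpm, path) {
  df <- data.frame(transcript_id = rownames(tpm), tpm, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an orthogroup membership table
#'
#' TSV with columns `orthogroup`, `species`, `gene_id` (one row per gene).
#'
#' @param path Path to the table.
#' @return Data frame with those columns.
#' @export
read_orthogroups <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = "character")
  stopifnot(all(c("orthogroup", "species", "gene_id") %in% names(df)))
  df
}

#' Read a duplication-event table
#'
#' TSV with columns `node`, `orthogroup`, `support` (0-1) and `gene_ids`
#' (comma-separated), one row per inferred gene-family duplication event
#' on the species tree.
#'
#' @param path Path to the table.
#' @return Data frame with `gene_ids` kept as comma-joined text.
#' @export
read_duplications <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c(node = "character",
                                  orthogroup = "character",
                                  support = "character",
                                  gene_ids = "character"))
  stopifnot(all(c("node", "orthogroup", "support", "gene_ids") %in% names(df)))
  sup <- suppressWarnings(as.numeric(df$support))
  if (anyNA(sup) && nrow(df) > 0) stop("malformed support value")
  df$support <- sup
  df
}

#' Read a gene-to-term annotation map
#'
#' TSV with columns `gene_id`, `term`; one row per assignment.
#'
#' @param path Path to the table.
#' @return Data frame with those columns.
#' @export
read_annotation_map <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, colClasses = "character")
  stopifnot(all(c("gene_id", "term") %in% names(df)))
  df
}
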