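IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Read a (possibly softmasked) FASTA file
#'
#' Softmasking is lowercase encoding of repeat bases, so case is preserved
#' exactly.  Record names must be unique, records must be non-empty, and
#' every character must be an IUPAC nucleotide code (either case).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences, case intact.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (length(seqs) == 0) return(setNames(character(), character()))
  if (anyDuplicated(names(seqs)))
    stop("duplicate FASTA record name: ",
         names(seqs)[duplicated(names(seqs))][1])
  if (any(!nzchar(seqs))) stop("empty FASTA record")
  bad <- vapply(seqs, function(s) {
    chars <- unique(strsplit(toupper(s), "", fixed = TRUE)[[1]])
    any(!chars %in% IUPAC_CHARS)
  }, logical(1))
  if (any(bad))
    stop("non-nucleotide character in record: ", names(seqs)[bad][1])
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in bases (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(length(names(seqs)) == length(seqs), width >= 1)
  con <- file(path, "wb")  # binary: byte-stable across platforms
  on.exit(close(con))
  for (nm in names(seqs)) {
    s <- seqs[[nm]]
    n <- nchar(s)
    starts <- seq(1L, n, by = width)
    lines <- substring(s, starts, pmin(starts + width - 1L, n))
    writeLines(c(paste0(">", nm), lines), con, sep = "\n")
  }
  invisible(path)
}

#' Find assembly gaps (maximal N runs) in one sequence
#'
#' Assembly gaps between adjacent contigs are represented as runs of the
#' ambiguity base N (conventionally 100 Ns per unspanned junction).  Only
#' N counts as gap material — other ambiguity codes do not — and case is
#' ignored.
#'
#' @param sequence A single nucleotide string.
#' @param min_len Minimum run length to report (default 10, the census
#'   threshold for "large" gaps).
#' @return Interval table of gaps (0-based half-open), sorted by start.
#' @examples
#' find_assembly_gaps(paste0("ACGT", strrep("N", 100), "ACGT"))
#' @export
find_assembly_gaps <- function(sequence, min_len = 10L) {
  stopifnot(length(sequence) == 1, min_len >= 1)
  m <- gregexpr("[Nn]+", sequence)[[1]]
  if (m[1] == -1)
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  len <- attr(m, "match.length")
  keep <- len >= min_len
  data.frame(chrom = rep(NA_character_, sum(keep)),
             start = as.numeric(m[keep]) - 1,
             end = as.numeric(m[keep]) - 1 + len[keep],
             stringsAsFactors = FALSE)
}

#' Find assembly gaps across a whole genome
#'
#' @param genome Named character vector of sequences (see [read_fasta()]).
#' @param min_len Minimum N-run length.
#' @return Interval table with `chrom` filled in, sorted.
#' @export
find_genome_gaps <- function(genome, min_len = 10L) {
  out <- lapply(names(genome), function(nm) {
    g <- find_assembly_gaps(genome[[nm]], min_len)
    g$chrom <- rep(nm, nrow(g))
    g
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(), end = numeric())
  out[order(out$chrom, out$start), , drop = FALSE]
}
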