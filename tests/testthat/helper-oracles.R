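# Independent brute-force oracles. These deliberately share no code with
# the package internals they check.

## NX by scanning every candidate length
oracle_nx <- function(lengths, x) {
  cands <- sort(unique(lengths), decreasing = TRUE)
  total <- sum(lengths)
  for (L in cands) {
    if (sum(lengths[lengths >= L]) >= x / 100 * total) return(L)
  }
  min(lengths)
}

## covered bases of [start, end) by per-base counting
oracle_covered <- function(features, chrom, start, end) {
  if (end <= start) return(0)
  bases <- rep(FALSE, end - start)
  f <- features[features$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(f))) {
    lo <- max(f$start[i], start); hi <- min(f$end[i], end)
    if (hi > lo) bases[(lo - start + 1):(hi - start)] <- TRUE
  }
  sum(bases)
}

## contig lengths by per-base scanning
oracle_contigs <- function(sequence, min_gap_len) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  is_n <- chars %in% c("N", "n")
  r <- rle(is_n)
  ## merge N runs shorter than min_gap_len into neighbours
  r$values[r$values & r$lengths < min_gap_len] <- FALSE
  r2 <- rle(inverse.rle(r))
  r2$lengths[!r2$values]
}

## genic / strand-relation call by all-pairs comparison
oracle_classify <- function(rp, genes) {
  hits <- which(genes$chrom == rp$chrom &
                  genes$start < rp$end & genes$end > rp$start)
  if (length(hits) == 0)
    return(list(context = "non-genic", relation = "unstranded"))
  hits <- hits[order(genes$start[hits])]
  g <- genes[hits[1], ]
  rel <- if (rp$strand %in% c("+", "-") && g$strand %in% c("+", "-")) {
    if (rp$strand == g$strand) "same" else "different"
  } else "unstranded"
  list(context = "genic", relation = rel)
}

## exact hypergeometric upper tail by combinatorial enumeration
oracle_hyper <- function(k, K, n, N) {
  js <- k:min(n, K)
  if (length(js) == 0 || k > min(n, K)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

## independent re-statement of the SV curation rules
oracle_sv_pass <- function(rec) {
  rec$precise &
    (rec$end - rec$pos) < 5e6 &
    rec$filter == "PASS" &
    rec$mapq > 0 &
    rec$pe >= 5
}

## GC fraction by per-character counting
oracle_gc <- function(s) {
  chars <- toupper(strsplit(s, "", fixed = TRUE)[[1]])
  sum(chars %in% c("G", "C")) / sum(chars %in% c("A", "C", "G", "T"))
}

## random interval sets for fuzzing
random_intervals <- function(n, chroms = c("c1", "c2"), max_pos = 1000,
                             stranded = TRUE) {
  s <- sample.int(max_pos - 2, n, replace = TRUE)
  len <- sample.int(50, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = s, end = pmin(s + len, max_pos),
             strand = if (stranded) sample(c("+", "-"), n, replace = TRUE)
                      else ".",
             stringsAsFactors = FALSE)
}

## minimal gene-model builders for fixtures
mk_tx <- function(id, gid, chrom, strand, exon_mat, aed)
  transcript(id, gid, chrom, strand,
             data.frame(start = exon_mat[, 1], end = exon_mat[, 2]), aed)

mk_gene <- function(gid, chrom, strand, exon_mat, aed = 0.1, n_tx = 1)
  gene_model(gid, lapply(seq_len(n_tx), function(i)
    mk_tx(paste0(gid, ".", i), gid, chrom, strand, exon_mat, aed)))
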