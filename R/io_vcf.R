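SV_TYPES <- c("DEL", "DUP", "INV")

#' Construct a structural-variant call set
#'
#' A call set bundles a record table with a genotype matrix over a sample
#' panel.  Records keep the VCF 1-based `pos`/`end` convention (Delly
#' dialect), so the variant length is simply `end - pos`
#' ([sv_length()]).
#'
#' @param records Data frame with columns `id`, `sv_type` (DEL/DUP/INV),
#'   `chrom`, `pos`, `end`, `precise` (logical), `pe`, `sr`, `mapq`
#'   (non-negative integers), `filter` (PASS or a failure label).
#' @param genotypes Character matrix, rows = records, columns = samples;
#'   entries `"0/0"`, `"0/1"`, `"1/1"` or `NA` (missing).
#' @return List of class `sv_set` with elements `records`, `genotypes`,
#'   `samples`.
#' @export
sv_set <- function(records, genotypes) {
  need <- c("id", "sv_type", "chrom", "pos", "end", "precise", "pe", "sr",
            "mapq", "filter")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  if (!all(records$sv_type %in% SV_TYPES))
    stop("unknown SVTYPE: ",
         records$sv_type[!records$sv_type %in% SV_TYPES][1])
  if (any(records$end < records$pos)) stop("SV with end < pos")
  if (any(records$pe < 0 | records$sr < 0 | records$mapq < 0))
    stop("negative evidence field")
  stopifnot(is.matrix(genotypes), nrow(genotypes) == nrow(records))
  ok <- genotypes %in% c("0/0", "0/1", "1/1") | is.na(genotypes)
  if (!all(ok)) stop("invalid genotype string: ", genotypes[!ok][1])
  structure(list(records = records, genotypes = genotypes,
                 samples = colnames(genotypes)),
            class = "sv_set")
}

parse_info <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  has_eq <- grepl("=", parts, fixed = TRUE)
  kv <- strsplit(parts[has_eq], "=", fixed = TRUE)
  vals <- setNames(vapply(kv, `[[`, "", 2), vapply(kv, `[[`, "", 1))
  flags <- parts[!has_eq]
  list(values = vals, flags = flags)
}

info_num <- function(info, key, id) {
  if (!key %in% names(info$values))
    stop("record ", id, " missing INFO key ", key)
  v <- suppressWarnings(as.numeric(info$values[[key]]))
  if (is.na(v)) stop("record ", id, ": non-numeric INFO ", key)
  v
}

#' Read a Delly-dialect structural-variant VCF
#'
#' Requires INFO keys `SVTYPE`, `END`, `PE`, `SR`, `MAPQ` and a
#' `PRECISE`/`IMPRECISE` flag, and `GT` first in FORMAT.  Unknown INFO
#' keys are ignored.  `./.` genotypes map to missing.
#'
#' @param path Path to an uncompressed VCF 4.x file.
#' @return An [sv_set()].
#' @export
read_sv_vcf <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1) stop("VCF without #CHROM header line")
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  samples <- if (length(cols) > 9) cols[10:length(cols)] else character()
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  n <- length(body)
  gt <- matrix(NA_character_, nrow = n, ncol = length(samples),
               dimnames = list(NULL, samples))
  rec <- vector("list", n)
  for (i in seq_len(n)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(cols))
      stop("line ", i, ": ", length(f) - 9, " sample fields for ",
           length(samples), " samples")
    info <- parse_info(f[8])
    if (!"SVTYPE" %in% names(info$values))
      stop("record ", f[3], " missing INFO key SVTYPE")
    svt <- info$values[["SVTYPE"]]
    if (!svt %in% SV_TYPES) stop("unknown SVTYPE: ", svt)
    rec[[i]] <- data.frame(
      id = f[3], sv_type = svt, chrom = f[1], pos = as.numeric(f[2]),
      end = info_num(info, "END", f[3]),
      precise = "PRECISE" %in% info$flags,
      pe = info_num(info, "PE", f[3]), sr = info_num(info, "SR", f[3]),
      mapq = info_num(info, "MAPQ", f[3]), filter = f[7],
      stringsAsFactors = FALSE)
    if (length(samples)) {
      fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
      gt_i <- match("GT", fmt)
      if (is.na(gt_i)) stop("FORMAT without GT")
      calls <- vapply(strsplit(f[10:length(f)], ":", fixed = TRUE),
                      `[[`, "", gt_i)
      calls[calls %in% c("./.", ".")] <- NA_character_
      gt[i, ] <- calls
    }
  }
  sv_set(do.call(rbind, rec), gt)
}

#' Write a structural-variant call set as VCF
#'
#' @param sv An [sv_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(sv, path) {
  stopifnot(inherits(sv, "sv_set"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=PE,Number=1,Type=Integer,Description=\"Paired-end support\">",
    "##INFO=<ID=SR,Number=1,Type=Integer,Description=\"Split-read support\">",
    "##INFO=<ID=MAPQ,Number=1,Type=Integer,Description=\"Median mapping quality\">",
    "##INFO=<ID=PRECISE,Number=0,Type=Flag,Description=\"Precise structural variant\">",
    "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"Imprecise structural variant\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sv$samples), collapse = "\t")), con, sep = "\n")
  r <- sv$records
  for (i in seq_len(nrow(r))) {
    info <- sprintf("%s;SVTYPE=%s;END=%d;PE=%d;SR=%d;MAPQ=%d",
                    if (r$precise[i]) "PRECISE" else "IMPRECISE",
                    r$sv_type[i], as.integer(r$end[i]), as.integer(r$pe[i]),
                    as.integer(r$sr[i]), as.integer(r$mapq[i]))
    calls <- sv$genotypes[i, ]
    calls[is.na(calls)] <- "./."
    writeLines(paste(c(r$chrom[i], as.integer(r$pos[i]), r$id[i], "N",
                       paste0("<", r$sv_type[i], ">"), ".", r$filter[i],
                       info, "GT", calls), collapse = "\t"), con, sep = "\n")
  }
  invisible(path)
}
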