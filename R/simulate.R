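#' Simulation configuration
#'
#' One configuration object drives every generator, and all randomness
#' flows from its single `seed`.  Defaults describe a desk-scale world:
#' two 200-kb chromosomes, twenty 100-N assembly gaps, LTR repeat
#' families with bimodal log-normal length mixtures peaking near 3/13 kb
#' (copia-like) and 3/8 kb (gypsy-like), a 235-sample diversity panel
#' with Hardy-Weinberg genotypes, and curated-scale structural-variant
#' counts (150 deletions, 186 duplications, 85 inversions) plus records
#' deliberately violating exactly one curation rule each.
#'
#' @param seed Integer master seed.
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param background_gc Background GC fraction.
#' @param gap_count,gap_length Number and length (bases) of N-run gaps.
#' @param repeat_families List of families; each a list with `label`
#'   (`class/family`), `count`, and `mixture` — a list of
#'   `c(weight, mean, sdlog)` log-normal components (`mean` in bases is
#'   the component median; `sdlog` is the log-scale sd).
#' @param gene_count Number of gene models.
#' @param gene_length_mean,gene_length_sdlog Log-normal gene-span length.
#' @param exon_rate Mean additional exons per gene (exon count is
#'   `1 + Poisson(exon_rate)`).
#' @param aed_shape1,aed_shape2 Beta parameters for transcript AEDs.
#' @param repeat_genic_bias Fold preference for placing repeats inside
#'   gene spans (1 = no bias).
#' @param gap_flank_enrichment Fold preference for placing repeats within
#'   `gap_flank_width` of a gap (1 = no enrichment, the null world).
#' @param gap_flank_width Width of the gap-flank attraction zone (bases).
#' @param sample_count Samples in the SV diversity panel.
#' @param sv_counts Named vector: clean records per type.
#' @param sv_fail_each Records per type per curation rule that violate
#'   exactly that rule.
#' @param af_shape1,af_shape2 Beta parameters of the variant
#'   allele-frequency distribution (a stand-in; the real panel's
#'   frequency spectrum is unknown).
#' @param dup_length_median,inv_length_median Log-normal medians for
#'   duplication/inversion lengths (deletion lengths come from the TE
#'   mixtures).
#' @param n_orthogroups,species Number of orthogroups and species names
#'   (first is the focal species).
#' @param planted_node Node id carrying the planted duplication burst.
#' @param n_dup_events Duplication events at the planted node.
#' @param low_support_fraction Fraction of duplication events drawn with
#'   support below 0.90.
#' @param enriched_term,effect_size Planted term and its fold enrichment
#'   among genes duplicated at the planted node (1 = null).
#' @param n_terms Number of background annotation terms.
#' @param base_term_freq Baseline per-term annotation frequency.
#' @param repeats_avoid_gaps If `TRUE` (default) repeats are never placed
#'   across gap runs, which keeps the masked-base bookkeeping exact; set
#'   `FALSE` for the null world in which repeat placement is strictly
#'   independent of gap placement (required for permutation-test
#'   calibration, since annotation-free gap bodies otherwise depress
#'   observed flank coverage relative to shuffled gaps).
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    chrom_lengths = c(chr1 = 200000, chr2 = 200000),
    background_gc = 0.46,
    gap_count = 20L, gap_length = 100L,
    repeat_families = list(
      list(label = "LTR/Copia", count = 5L,
           mixture = list(c(0.5, 3000, 0.15), c(0.5, 13000, 0.15))),
      list(label = "LTR/Gypsy", count = 15L,
           mixture = list(c(0.5, 3000, 0.15), c(0.5, 8000, 0.15))),
      list(label = "LINE/L1", count = 10L,
           mixture = list(c(1, 1000, 0.3))),
      list(label = "DNA/MULE-MuDR", count = 15L,
           mixture = list(c(1, 500, 0.3))),
      list(label = "RC/Helitron", count = 10L,
           mixture = list(c(1, 1000, 0.3)))),
    gene_count = 60L,
    gene_length_mean = 2400, gene_length_sdlog = 0.4,
    exon_rate = 3,
    aed_shape1 = 1, aed_shape2 = 4,
    repeat_genic_bias = 1,
    gap_flank_enrichment = 1, gap_flank_width = 1500,
    sample_count = 235L,
    sv_counts = c(DEL = 150L, DUP = 186L, INV = 85L),
    sv_fail_each = 2L,
    af_shape1 = 0.5, af_shape2 = 5,
    dup_length_median = 2120, inv_length_median = 20000,
    n_orthogroups = 400L,
    species = c("focal", "grassA", "grassB"),
    planted_node = "setaria_ancestor",
    n_dup_events = 60L,
    low_support_fraction = 0.2,
    enriched_term = "TERM_planted", effect_size = 1,
    n_terms = 20L, base_term_freq = 0.05,
    repeats_avoid_gaps = TRUE) {
  cfg <- as.list(environment())
  stopifnot(cfg$gap_count >= 0, cfg$gene_count >= 0, cfg$sample_count >= 1,
            cfg$background_gc >= 0, cfg$background_gc <= 1,
            length(cfg$species) >= 2)
  for (fam in cfg$repeat_families) {
    w <- vapply(fam$mixture, `[[`, 0, 1)
    if (abs(sum(w) - 1) > 1e-9) stop("mixture weights must sum to 1")
  }
  structure(cfg, class = "simulation_config")
}

random_sequence <- function(n, gc) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

draw_mixture_lengths <- function(n, mixture) {
  if (n == 0) return(numeric())
  w <- vapply(mixture, `[[`, 0, 1)
  comp <- sample(seq_along(mixture), n, replace = TRUE, prob = w)
  round(vapply(seq_len(n), function(i) {
    m <- mixture[[comp[i]]]
    rlnorm(1, meanlog = log(m[2]), sdlog = m[3])
  }, 0))
}

## rejection-sample non-overlapping placements; `occupied` is a data frame
## of blocked intervals; optional attraction zones with probability p_zone
place_features <- function(lengths, chrom_lengths, occupied,
                           zones = NULL, p_zone = 0, max_tries = 2000L) {
  chroms <- names(chrom_lengths)
  out <- data.frame(chrom = character(), start = numeric(), end = numeric())
  blocked <- occupied
  for (len in lengths) {
    done <- FALSE
    for (try in seq_len(max_tries)) {
      in_zone <- !is.null(zones) && nrow(zones) > 0 && runif(1) < p_zone
      if (in_zone) {
        z <- zones[sample.int(nrow(zones), 1), ]
        ch <- z$chrom
        ## any start that makes the element overlap the zone by >= 1 base
        s <- floor(runif(1, max(1, z$start - len + 1), z$end))
      } else {
        ch <- sample(chroms, 1, prob = as.numeric(chrom_lengths))
        room <- chrom_lengths[[ch]] - len
        if (room < 1) next
        s <- floor(runif(1, 1, room))
      }
      e <- s + len
      if (e > chrom_lengths[[ch]] - 1) next
      b <- blocked[blocked$chrom == ch, , drop = FALSE]
      if (nrow(b) == 0 || !any(b$start < e & b$end > s)) {
        out <- rbind(out, data.frame(chrom = ch, start = s, end = e,
                                     stringsAsFactors = FALSE))
        blocked <- rbind(blocked,
                         data.frame(chrom = ch, start = s, end = e,
                                    stringsAsFactors = FALSE))
        done <- TRUE
        break
      }
    }
    if (!done) stop("infeasible feature placement after ", max_tries,
                    " tries (genome too crowded)")
  }
  out
}

#' Simulate a softmasked genome with repeats, genes and assembly gaps
#'
#' Generates, deterministically from `config$seed`: background sequence
#' at the configured GC; `gap_count` runs of `gap_length` Ns; repeat
#' elements drawn from the configured family length mixtures, placed
#' non-overlapping (optionally biased into gene spans and/or gap flanks)
#' and softmasked in the sequence; and non-overlapping gene models with
#' exon structure and AED scores.  Ground truth is returned alongside so
#' tests can compare recovered statistics with planted values exactly.
#'
#' @param config A [simulation_config()].
#' @param dir Optional output directory; when given, writes `genome.fa`,
#'   `repeats.tsv`, `genes.gff3`, `gaps.bed` via the package writers.
#' @return List with `genome` (named character), `gaps`, `repeats`,
#'   `genes` (list of [gene_model()]), and `truth` (masked base count
#'   etc.).
#' @export
simulate_genome <- function(config = simulation_config(), dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cl <- config$chrom_lengths
  genome <- setNames(
    vapply(cl, function(L) random_sequence(L, config$background_gc), ""),
    names(cl))

  empty <- data.frame(chrom = character(), start = numeric(), end = numeric())
  ## gaps first: they are hard boundaries for everything else
  gaps <- if (config$gap_count > 0)
    place_features(rep(config$gap_length, config$gap_count), cl, empty)
  else empty
  gaps <- gaps[order(gaps$chrom, gaps$start), , drop = FALSE]
  rownames(gaps) <- NULL

  ## genes next (non-overlapping with each other and with gaps)
  gene_lengths <- round(rlnorm(config$gene_count,
                               log(config$gene_length_mean),
                               config$gene_length_sdlog))
  gene_lengths <- pmax(gene_lengths, 150)
  gene_pos <- place_features(gene_lengths, cl, gaps)
  genes <- lapply(seq_len(config$gene_count), function(i) {
    gid <- sprintf("gene%04d", i)
    strand <- sample(c("+", "-"), 1)
    n_ex <- 1 + rpois(1, config$exon_rate)
    s <- gene_pos$start[i]; e <- gene_pos$end[i]
    len <- e - s
    n_ex <- min(n_ex, max(1, floor(len / 120)))
    ## cut the span into n_ex exons separated by introns
    cuts <- sort(sample(seq_len(len - 1), 2 * n_ex - 2))
    bounds <- c(0, cuts, len)
    ex_all <- data.frame(start = s + bounds[seq(1, length(bounds), 2)],
                         end = s + bounds[seq(2, length(bounds), 2)])
    ex_all <- ex_all[ex_all$end > ex_all$start, , drop = FALSE]
    aed1 <- rbeta(1, config$aed_shape1, config$aed_shape2)
    txs <- list(transcript(paste0(gid, ".1"), gid, gene_pos$chrom[i],
                           strand, ex_all, aed1))
    if (runif(1) < 0.3 && nrow(ex_all) > 1) {  # second, worse isoform
      keep <- sort(sample(nrow(ex_all), nrow(ex_all) - 1))
      txs <- c(txs, list(transcript(paste0(gid, ".2"), gid,
                                    gene_pos$chrom[i], strand,
                                    ex_all[keep, , drop = FALSE],
                                    min(1, aed1 + runif(1, 0.05, 0.3)))))
    }
    gene_model(gid, txs)
  })

  ## repeats: biased into gap flanks and/or gene spans when configured
  flank_zones <- if (config$gap_flank_enrichment > 1 && nrow(gaps) > 0) {
    fz <- flank_windows(gaps, config$gap_flank_width, cl)
    fz
  } else NULL
  gene_zone <- if (config$repeat_genic_bias != 1 && length(genes) > 0)
    gene_spans(genes)[, c("chrom", "start", "end")] else NULL
  zone_frac <- function(z) sum(z$end - z$start) / sum(cl)
  if (!is.null(flank_zones)) {
    f <- zone_frac(flank_zones)
    p_zone <- config$gap_flank_enrichment * f /
      (config$gap_flank_enrichment * f + (1 - f))
    zones <- flank_zones
  } else if (!is.null(gene_zone)) {
    f <- zone_frac(gene_zone)
    p_zone <- config$repeat_genic_bias * f /
      (config$repeat_genic_bias * f + (1 - f))
    zones <- gene_zone
  } else {
    p_zone <- 0; zones <- NULL
  }
  rep_list <- list()
  ## repeats avoid each other; gaps too unless the null world asks for
  ## placement independent of gaps (genes may always overlap repeats)
  occupied <- if (config$repeats_avoid_gaps) gaps else empty
  for (fam in config$repeat_families) {
    lens <- draw_mixture_lengths(fam$count, fam$mixture)
    lens <- pmin(lens, min(cl) - 2)  # keep placeable
    pos <- place_features(lens, cl, occupied, zones = zones, p_zone = p_zone)
    occupied <- rbind(occupied, pos)
    slash <- regexpr("/", fam$label, fixed = TRUE)
    pos$class <- if (slash > 0) substr(fam$label, 1, slash - 1) else fam$label
    pos$family <- if (slash > 0) substring(fam$label, slash + 1) else ""
    pos$strand <- sample(c("+", "-"), nrow(pos), replace = TRUE)
    rep_list[[fam$label]] <- pos
  }
  repeats <- do.call(rbind, rep_list)
  if (is.null(repeats))
    repeats <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), class = character(),
                          family = character(), strand = character())
  rownames(repeats) <- NULL

  ## mutate the sequence: softmask repeats, hard-write N gaps
  for (ch in names(genome)) {
    s <- genome[[ch]]
    r <- repeats[repeats$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(r)))
      substr(s, r$start[i] + 1, r$end[i]) <-
        tolower(substr(s, r$start[i] + 1, r$end[i]))
    g <- gaps[gaps$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(g)))
      substr(s, g$start[i] + 1, g$end[i]) <-
        strrep("N", g$end[i] - g$start[i])
    genome[[ch]] <- s
  }

  gap_overlap <- if (nrow(gaps) && nrow(repeats)) {
    gidx <- coverage_index(gaps)
    sum(vapply(seq_len(nrow(repeats)), function(i)
      covered_bases(gidx, repeats$chrom[i], repeats$start[i],
                    repeats$end[i]), 0))
  } else 0
  truth <- list(masked_bases = sum(repeats$end - repeats$start) - gap_overlap,
                genome_length = sum(cl),
                gap_count = nrow(gaps))
  out <- list(genome = genome, gaps = gaps, repeats = repeats,
              genes = genes, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(genome, file.path(dir, "genome.fa"))
    write_repeat_table(repeats, file.path(dir, "repeats.tsv"))
    write_gene_gff3(genes, file.path(dir, "genes.gff3"))
    write.table(gaps, file.path(dir, "gaps.bed"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  out
}

#' Simulate a k-mer multiplicity histogram
#'
#' Genomic k-mers draw their multiplicity from Poisson(coverage); error
#' k-mers (one per erroneous base times k, approximately unique) draw
#' from a geometric concentrated at multiplicity 1-2.
#'
#' @param genome_size Haploid genome size in bases.
#' @param coverage Mean sequencing depth.
#' @param error_rate Per-base error rate in `[0, 1)`.
#' @param seed Integer seed.
#' @param k K-mer length (default 21).
#' @return A [kmer_histogram()].
#' @export
simulate_kmer_histogram <- function(genome_size, coverage, error_rate = 0,
                                    seed = 1L, k = 21L) {
  stopifnot(coverage > 0, error_rate >= 0, error_rate < 1)
  set.seed(seed)
  mult <- rpois(genome_size, coverage)
  mult <- mult[mult > 0]
  if (error_rate > 0) {
    n_err <- round(genome_size * coverage * error_rate * k)
    mult <- c(mult, 1 + rgeom(n_err, 0.9))
  }
  h <- tabulate(mult)
  keep <- which(h > 0)
  kmer_histogram(keep, h[keep], k = k)
}

hw_genotypes <- function(freq, n_samples) {
  g <- rbinom(n_samples, 2, freq)
  c("0/0", "0/1", "1/1")[g + 1]
}

#' Simulate a population structural-variant call set
#'
#' Clean records carry PRECISE split-read-supported breakpoints, PASS
#' filters, positive mapping quality and at least five paired reads;
#' designated records violate exactly one curation rule each (length of
#' exactly 5 Mb, fewer than five paired reads, IMPRECISE with zero split
#' reads, zero mapping quality, non-PASS filter), so filter logic is
#' attributable.  Genotypes are drawn per variant at its allele frequency
#' under Hardy-Weinberg; deletion lengths come from the configured TE
#' length mixtures.
#'
#' @param config A [simulation_config()].
#' @param dir Optional output directory (writes `svs.vcf`,
#'   `sv_truth.tsv`).
#' @return List with `sv` (an [sv_set()]) and `truth` (data frame `id`,
#'   `sv_type`, `length`, `allele_freq`, `fate` — `"pass"` or the rule
#'   violated).
#' @export
simulate_sv_population <- function(config = simulation_config(), dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  cl <- config$chrom_lengths
  samples <- sprintf("acc%03d", seq_len(config$sample_count))
  rules <- c("pass", "max_length", "min_pe", "precise", "mapq",
             "filter_pass")
  te_mix <- do.call(c, lapply(
    config$repeat_families[vapply(config$repeat_families, function(f)
      grepl("^LTR/", f$label), TRUE)], `[[`, "mixture"))
  te_mix <- lapply(te_mix, function(m) c(m[1] / 2, m[2], m[3]))  # renormalize

  rec <- list(); gt <- list(); truth <- list()
  idx <- 0
  for (typ in names(config$sv_counts)) {
    n_clean <- config$sv_counts[[typ]]
    fates <- c(rep("pass", n_clean),
               rep(setdiff(rules, "pass"), each = config$sv_fail_each))
    for (fate in fates) {
      idx <- idx + 1
      len <- switch(typ,
        DEL = max(50, draw_mixture_lengths(1, te_mix)),
        DUP = max(50, round(rlnorm(1, log(config$dup_length_median), 0.5))),
        INV = max(50, round(rlnorm(1, log(config$inv_length_median), 0.5))))
      if (fate == "max_length") len <- 5e6
      ch <- sample(names(cl), 1, prob = as.numeric(cl))
      pos <- floor(runif(1, 1, max(2, cl[[ch]] - min(len, cl[[ch]] - 2))))
      freq <- rbeta(1, config$af_shape1, config$af_shape2)
      rec[[idx]] <- data.frame(
        id = sprintf("%s%05d", typ, idx), sv_type = typ, chrom = ch,
        pos = pos, end = pos + len,
        precise = fate != "precise",
        pe = if (fate == "min_pe") sample(0:4, 1) else 5 + rpois(1, 10),
        sr = if (fate == "precise") 0 else 1 + rpois(1, 5),
        mapq = if (fate == "mapq") 0 else 20 + rpois(1, 20),
        filter = if (fate == "filter_pass") "LowQual" else "PASS",
        stringsAsFactors = FALSE)
      gt[[idx]] <- hw_genotypes(freq, config$sample_count)
      truth[[idx]] <- data.frame(id = rec[[idx]]$id, sv_type = typ,
                                 length = len, allele_freq = freq,
                                 fate = fate, stringsAsFactors = FALSE)
    }
  }
  gtm <- do.call(rbind, gt)
  colnames(gtm) <- samples
  sv <- sv_set(do.call(rbind, rec), gtm)
  truth <- do.call(rbind, truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_sv_vcf(sv, file.path(dir, "svs.vcf"))
    write.table(truth, file.path(dir, "sv_truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(sv = sv, truth = truth)
}

#' Simulate orthogroup, duplication and annotation tables
#'
#' Plants `n_dup_events` duplication events at `planted_node` (a
#' configurable fraction drawn with clade support below 0.90) and
#' annotates genes duplicated there with the enriched term at
#' `effect_size` times the baseline frequency; `effect_size = 1` is the
#' null world used for calibration.
#'
#' @param config A [simulation_config()].
#' @param focal_gene_ids Optional focal-species gene ids to use (e.g.
#'   from [simulate_genome()]); generated when omitted.
#' @param dir Optional output directory (writes `orthogroups.tsv`,
#'   `duplications.tsv`, `annotations.tsv`).
#' @return List with `orthogroups`, `duplications`, `annotations`
#'   (data frames as read by the corresponding readers), `focal_genes`,
#'   and `truth` (planted node, term, study genes).
#' @export
simulate_orthogroups <- function(config = simulation_config(),
                                 focal_gene_ids = NULL, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 2L)
  n_og <- config$n_orthogroups
  species <- config$species
  focal <- species[1]
  per_og_focal <- 1 + rpois(n_og, 1)
  if (is.null(focal_gene_ids)) {
    focal_gene_ids <- sprintf("%s_g%05d", focal, seq_len(sum(per_og_focal)))
  } else {
    per_og_focal <- pmin(per_og_focal, 3)
    while (sum(per_og_focal) > length(focal_gene_ids))
      per_og_focal[which.max(per_og_focal)] <-
        per_og_focal[which.max(per_og_focal)] - 1
    if (sum(per_og_focal) < length(focal_gene_ids))
      per_og_focal[1] <- per_og_focal[1] +
        length(focal_gene_ids) - sum(per_og_focal)
  }
  og_ids <- sprintf("OG%05d", seq_len(n_og))
  assign_og <- rep(og_ids, per_og_focal)
  rows <- data.frame(orthogroup = assign_og, species = focal,
                     gene_id = focal_gene_ids, stringsAsFactors = FALSE)
  for (sp in species[-1]) {
    n_sp <- rpois(n_og, 1.2)
    keep <- n_sp > 0
    rows <- rbind(rows, data.frame(
      orthogroup = rep(og_ids[keep], n_sp[keep]),
      species = sp,
      gene_id = sprintf("%s_g%05d", sp, seq_len(sum(n_sp))),
      stringsAsFactors = FALSE))
  }

  ## duplication events: planted node + background nodes
  multi <- og_ids[per_og_focal >= 2]
  if (length(multi) == 0) multi <- og_ids[per_og_focal >= 1]
  mk_events <- function(node, n, prefix) {
    if (n == 0) return(NULL)
    ogs <- sample(multi, n, replace = TRUE)
    do.call(rbind, lapply(seq_len(n), function(i) {
      members <- rows$gene_id[rows$orthogroup == ogs[i] &
                                rows$species == focal]
      g <- sample(members, min(2, length(members)))
      low <- runif(1) < config$low_support_fraction
      data.frame(node = node, orthogroup = ogs[i],
                 support = if (low) round(runif(1, 0.5, 0.89), 3)
                           else round(runif(1, 0.9, 1), 3),
                 gene_ids = paste(g, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  }
  dups <- rbind(mk_events(config$planted_node, config$n_dup_events, "p"),
                mk_events("background_node", max(5, config$n_dup_events %/% 3),
                          "b"))

  ## annotations: background terms everywhere, planted term enriched in
  ## the genes duplicated (with support) at the planted node
  parsed <- parse_duplications(dups, 0.90)
  study <- node_duplicated_genes(parsed, config$planted_node)
  terms <- sprintf("TERM_%02d", seq_len(config$n_terms))
  ann <- list()
  for (t in terms) {
    f <- config$base_term_freq
    hit <- focal_gene_ids[runif(length(focal_gene_ids)) < f]
    if (length(hit))
      ann[[t]] <- data.frame(gene_id = hit, term = t,
                             stringsAsFactors = FALSE)
  }
  p_study <- min(1, config$effect_size * config$base_term_freq)
  in_study <- focal_gene_ids %in% study
  p_vec <- ifelse(in_study, p_study, config$base_term_freq)
  hit <- focal_gene_ids[runif(length(focal_gene_ids)) < p_vec]
  if (length(hit))
    ann[[config$enriched_term]] <-
      data.frame(gene_id = hit, term = config$enriched_term,
                 stringsAsFactors = FALSE)
  annotations <- do.call(rbind, ann)
  rownames(annotations) <- NULL

  out <- list(orthogroups = rows, duplications = dups,
              annotations = annotations, focal_genes = focal_gene_ids,
              truth = list(planted_node = config$planted_node,
                           enriched_term = config$enriched_term,
                           study_genes = study))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write.table(rows, file.path(dir, "orthogroups.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(dups, file.path(dir, "duplications.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(annotations, file.path(dir, "annotations.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}

#' Simulate a transcript-level TPM table for a gene set
#'
#' Log-normal raw abundances per transcript and sample, normalized so
#' every sample sums to one million TPM.
#'
#' @param genes List of [gene_model()] objects.
#' @param n_samples Number of samples (default 3).
#' @param seed Integer seed.
#' @param silent_fraction Fraction of transcripts forced to ~0 abundance.
#' @return TPM matrix (transcripts x samples).
#' @export
simulate_expression <- function(genes, n_samples = 3L, seed = 1L,
                                silent_fraction = 0.1) {
  set.seed(seed + 3L)
  ids <- unlist(lapply(genes, function(g)
    vapply(g$transcripts, `[[`, "", "id")))
  raw <- matrix(rlnorm(length(ids) * n_samples, 3, 1.5),
                nrow = length(ids),
                dimnames = list(ids, sprintf("sample%d", seq_len(n_samples))))
  silent <- runif(length(ids)) < silent_fraction
  raw[silent, ] <- raw[silent, ] * 1e-4
  sweep(raw, 2, colSums(raw), "/") * 1e6
}
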