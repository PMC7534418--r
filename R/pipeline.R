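#' Read a flat key-value pipeline configuration file
#'
#' Lines of the form `key = value` (`#` comments and blank lines
#' ignored).  Unknown keys are errors — fail fast beats silently ignored
#' typos.  Recognized keys: `fasta`, `repeats`, `genes`, `vcf`,
#' `histogram`, `tpm`, `orthogroups`, `duplications`, `annotations`
#' (input paths); `out_dir`; `seed`; `min_gap_len`, `n_perm`,
#' `distances` (comma-separated), `maf_threshold`, `min_support`,
#' `alpha`, `focal_species`, `simulate` (`true`/`false`).
#'
#' @param path Path to the config file.
#' @return Named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  known <- c("fasta", "repeats", "genes", "vcf", "histogram", "tpm",
             "orthogroups", "duplications", "annotations", "out_dir",
             "seed", "min_gap_len", "n_perm", "distances", "maf_threshold",
             "min_support", "alpha", "focal_species", "simulate")
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  if (any(lengths(kv) != 2)) stop("malformed config line")
  keys <- vapply(kv, `[[`, "", 1)
  if (any(!keys %in% known))
    stop("unknown config key: ", keys[!keys %in% known][1])
  cfg <- setNames(lapply(kv, `[[`, 2), keys)
  structure(cfg, class = "pipeline_config")
}

num_or <- function(cfg, key, default) {
  if (is.null(cfg[[key]])) default else as.numeric(cfg[[key]])
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage on the configured inputs (or on freshly
#' simulated ones when `simulate = true`): genome-size estimation,
#' assembly summary, repeat context composition, gap-flank permutation
#' tests, structural-variant curation and population summary, gene-set
#' filtration, and duplication-set enrichment.  Each stage writes a TSV
#' under `out_dir` and contributes to a combined JSON report; a stage
#' failure aborts with the stage named, retaining earlier outputs.
#'
#' @param config A `pipeline_config` (see [read_pipeline_config()]) or a
#'   named list with the same keys.
#' @return Invisibly, the combined report (named list), also written to
#'   `out_dir/report.json`.
#' @export
run_pipeline <- function(config) {
  out_dir <- if (is.null(config$out_dir)) "foxtail_out" else config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(num_or(config, "seed", 1))
  report <- list(seed = seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  simulate <- identical(tolower(config$simulate %||% "false"), "true")
  if (simulate) {
    sim_dir <- file.path(out_dir, "simulated")
    scfg <- simulation_config(seed = seed)
    stage("simulate", {
      g <- simulate_genome(scfg, dir = sim_dir)
      simulate_sv_population(scfg, dir = sim_dir)
      simulate_orthogroups(
        scfg, focal_gene_ids = vapply(g$genes, `[[`, "", "gene_id"),
        dir = sim_dir)
      tpm <- simulate_expression(g$genes, seed = seed)
      write_tpm_table(tpm, file.path(sim_dir, "tpm.tsv"))
      h <- simulate_kmer_histogram(5e5, 25, 0.01, seed = seed)
      write_kmer_histogram(h, file.path(sim_dir, "kmers.hist"))
    })
    config$fasta <- file.path(sim_dir, "genome.fa")
    config$repeats <- file.path(sim_dir, "repeats.tsv")
    config$genes <- file.path(sim_dir, "genes.gff3")
    config$vcf <- file.path(sim_dir, "svs.vcf")
    config$histogram <- file.path(sim_dir, "kmers.hist")
    config$tpm <- file.path(sim_dir, "tpm.tsv")
    config$orthogroups <- file.path(sim_dir, "orthogroups.tsv")
    config$duplications <- file.path(sim_dir, "duplications.tsv")
    config$annotations <- file.path(sim_dir, "annotations.tsv")
    if (is.null(config$focal_species)) config$focal_species <- "focal"
  }
  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  if (!is.null(config$histogram)) {
    est <- stage("kmer-size", {
      h <- read_kmer_histogram(config$histogram)
      estimate_genome_size(h)
    })
    tsv(data.frame(genome_size = est$genome_size,
                   error_threshold = est$error_threshold,
                   hom_peak = est$hom_peak,
                   included_kmer_mass = est$included_kmer_mass,
                   model = est$model), "kmer_size.tsv")
    report$genome_size_estimate <- est$genome_size
  }

  genome <- NULL
  if (!is.null(config$fasta)) {
    genome <- stage("read-fasta", read_fasta(config$fasta))
    summ <- stage("asm-stats",
                  summarize_assembly(genome,
                                     num_or(config, "min_gap_len", 10)))
    tsv(summ, "assembly_summary.tsv")
    tot <- summ[summ$name == "All", ]
    report$assembly <- list(total_length = tot$total_length,
                            contig_count = tot$contig_count,
                            contig_n50 = tot$contig_n50,
                            gap_count = tot$gap_count,
                            masked_fraction = tot$masked_fraction)
  }

  repeats <- if (!is.null(config$repeats))
    stage("read-repeats", read_repeat_table(config$repeats)) else NULL
  genes <- if (!is.null(config$genes))
    stage("read-genes", read_gene_gff3(config$genes)) else NULL

  if (!is.null(repeats) && !is.null(genes)) {
    comp <- stage("repeat-context", context_composition(repeats, genes))
    tsv(comp$by_class, "repeat_context.tsv")
    report$repeat_context <- list(genic_total = comp$genic_total,
                                  nongenic_total = comp$nongenic_total)
  }

  if (!is.null(genome) && !is.null(repeats)) {
    perm <- stage("gap-perm", {
      gaps <- find_genome_gaps(genome, num_or(config, "min_gap_len", 10))
      if (nrow(gaps) == 0) NULL
      else permutation_test(
        gaps, setNames(nchar(genome), names(genome)),
        repeats = repeats, genome = genome,
        n_perm = as.integer(num_or(config, "n_perm", 1000)),
        distances = if (!is.null(config$distances))
          as.numeric(strsplit(config$distances, ",")[[1]])
        else c(50, 100, 500, 1000, 1500),
        seed = seed)
    })
    if (!is.null(perm)) {
      tsv(perm, "gap_permutation.tsv")
      report$gap_permutation <- setNames(
        as.list(perm$p_value), paste0(perm$statistic, "_d", perm$distance))
    }
  }

  if (!is.null(config$vcf)) {
    svsum <- stage("sv-pop", {
      sv <- read_sv_vcf(config$vcf)
      summarize_population(sv, sv_filter_config(),
                           num_or(config, "maf_threshold", 0.01))
    })
    tsv(svsum$per_type, "sv_summary.tsv")
    tsv(svsum$per_variant, "sv_curated.tsv")
    report$sv <- setNames(as.list(svsum$per_type$n), svsum$per_type$sv_type)
    report$sv_maf <- setNames(as.list(svsum$per_type$n_maf),
                              svsum$per_type$sv_type)
  }

  if (!is.null(genes) && !is.null(config$tpm) &&
      !is.null(config$orthogroups)) {
    filt <- stage("gene-filter", {
      expr <- read_tpm_table(config$tpm)
      og <- read_orthogroups(config$orthogroups)
      surv <- filter_by_aed(genes, 0.5)
      apply_final_filter(surv, og, expr,
                         config$focal_species %||% "focal")
    })
    tsv(filt, "gene_filter.tsv")
    report$genes_kept <- sum(filt$kept)
    report$genes_removed <- sum(!filt$kept)
  }

  if (!is.null(config$duplications) && !is.null(config$annotations) &&
      !is.null(config$orthogroups)) {
    enr <- stage("enrich", {
      dups <- read_duplications(config$duplications)
      ann <- read_annotation_map(config$annotations)
      og <- read_orthogroups(config$orthogroups)
      parsed <- parse_duplications(dups,
                                   num_or(config, "min_support", 0.90))
      tsv(parsed$per_node, "duplications_per_node.tsv")
      node <- parsed$per_node$node[which.max(parsed$per_node$n_events)]
      study <- node_duplicated_genes(parsed, node)
      pop <- og$gene_id[og$species == (config$focal_species %||% "focal")]
      res <- enrich(intersect(study, pop), ann, pop,
                    num_or(config, "alpha", 0.05))
      list(node = node, res = res)
    })
    tsv(enr$res, "enrichment.tsv")
    report$enrichment <- list(node = enr$node,
                              n_significant = sum(enr$res$significant))
  }

  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  writeLines(json, file.path(out_dir, "report.json"))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Subcommands: `simulate`, `kmer-size`, `asm-stats`, `repeat-context`,
#' `gap-perm`, `sv-pop`, `gene-filter`, `enrich`, `run-all`.  Every
#' subcommand is a thin wrapper over [run_pipeline()] with the matching
#' subset of config keys; `run-all --config FILE` runs the whole chain.
#' Invoke via `Rscript -e 'foxtail::foxtail_cli()' -- <subcommand>
#' key=value ...` or the installed `exec/foxtail` script.
#'
#' @param args Character vector of arguments (defaults to the command
#'   line).
#' @return Exit status 0 on success (invisibly).
#' @export
foxtail_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: foxtail <subcommand> key=value ...",
    "subcommands: simulate kmer-size asm-stats repeat-context gap-perm",
    "             sv-pop gene-filter enrich run-all",
    "common keys: out_dir=DIR seed=N; run-all also accepts config=FILE",
    sep = "\n")
  if (length(args) == 0) stop(usage, call. = FALSE)
  sub <- args[1]
  kv <- strsplit(args[-1], "=", fixed = TRUE)
  if (any(lengths(kv) < 2)) stop("arguments must be key=value\n", usage)
  opts <- setNames(lapply(kv, function(p) paste(p[-1], collapse = "=")),
                   vapply(kv, `[[`, "", 1))
  cfg <- if (!is.null(opts$config))
    c(read_pipeline_config(opts$config), opts[names(opts) != "config"])
  else opts
  keep_keys <- switch(sub,
    "simulate" = { cfg$simulate <- "true"; TRUE },
    "kmer-size" = "histogram",
    "asm-stats" = "fasta",
    "repeat-context" = c("repeats", "genes"),
    "gap-perm" = c("fasta", "repeats", "n_perm", "distances"),
    "sv-pop" = c("vcf", "maf_threshold"),
    "gene-filter" = c("genes", "tpm", "orthogroups", "focal_species"),
    "enrich" = c("duplications", "annotations", "orthogroups",
                 "min_support", "alpha", "focal_species"),
    "run-all" = TRUE,
    stop("unknown subcommand: ", sub, "\n", usage))
  if (!isTRUE(keep_keys))
    cfg <- cfg[names(cfg) %in% c(keep_keys, "out_dir", "seed",
                                 "min_gap_len", "simulate")]
  run_pipeline(cfg)
  invisible(0L)
}
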