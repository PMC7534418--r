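#' Filter and group gene-family duplication events by tree node
#'
#' Keeps events with clade support at or above the threshold (inclusive)
#' and groups them by species-tree node.
#'
#' @param dups Duplication table (`node`, `orthogroup`, `support`,
#'   `gene_ids` comma-joined; see [read_duplications()]).
#' @param min_support Inclusive support threshold (default 0.90).
#' @return List with `events` (the surviving rows, `gene_ids` split into
#'   list-column `genes`) and `per_node` (data frame `node`, `n_events`).
#' @export
parse_duplications <- function(dups, min_support = 0.90) {
  if (nrow(dups) && (anyNA(dups$support) ||
                     any(dups$support < 0 | dups$support > 1)))
    stop("malformed support value (outside [0,1] or non-numeric)")
  keep <- dups[dups$support >= min_support, , drop = FALSE]
  keep$genes <- strsplit(keep$gene_ids, ",", fixed = TRUE)
  tab <- table(keep$node)
  counts <- data.frame(node = names(tab),
                       n_events = as.integer(tab),
                       stringsAsFactors = FALSE)
  list(events = keep, per_node = counts)
}

#' All genes duplicated at one species-tree node
#'
#' @param parsed Result of [parse_duplications()].
#' @param node Node identifier.
#' @return Character vector of unique gene ids.
#' @export
node_duplicated_genes <- function(parsed, node) {
  ev <- parsed$events[parsed$events$node == node, , drop = FALSE]
  unique(unlist(ev$genes))
}

#' Exact hypergeometric upper-tail probability
#'
#' `P(X >= k)` when drawing `n` genes without replacement from a
#' population of `N` genes of which `K` carry the annotation.
#'
#' @param k Observed annotated genes in the study set.
#' @param K Annotated genes in the population.
#' @param n Study-set size.
#' @param N Population size.
#' @return Probability in `[0, 1]`.
#' @examples
#' hypergeometric_upper(4, 5, 4, 10)  # 1/42
#' @export
hypergeometric_upper <- function(k, K, n, N) {
  stopifnot(k >= 0, k <= n, n <= N, K <= N, K >= 0)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment with enforced monotonicity, capped at 1;
#' returned in the input order.
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values))
    stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  if (m == 0) return(numeric())
  o <- order(p_values)
  q <- p_values[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(o)]
}

#' Functional-term enrichment of a gene set
#'
#' One hypergeometric upper-tail test per term present in the study set,
#' against a fixed population (background), with Benjamini-Hochberg
#' correction across all tested terms.
#'
#' @param study_genes Character vector of study gene ids (subset of the
#'   population).
#' @param annotation_map Data frame `gene_id`, `term`.
#' @param population_genes Character vector of background gene ids.
#' @param alpha Significance level on the adjusted q (default 0.05).
#' @return Data frame sorted by `q`: `term`, `k` (study hits), `n`
#'   (study size), `K` (population hits), `N` (population size), `p`,
#'   `q`, `significant` (`q < alpha`).
#' @export
enrich <- function(study_genes, annotation_map, population_genes,
                   alpha = 0.05) {
  study_genes <- unique(study_genes)
  population_genes <- unique(population_genes)
  outside <- setdiff(study_genes, population_genes)
  if (length(outside))
    stop("study gene absent from population: ", outside[1])
  ann <- annotation_map[annotation_map$gene_id %in% population_genes, ,
                        drop = FALSE]
  ann <- unique(ann[, c("gene_id", "term")])
  N <- length(population_genes)
  n <- length(study_genes)
  study_ann <- ann[ann$gene_id %in% study_genes, , drop = FALSE]
  terms <- sort(unique(study_ann$term))
  if (length(terms) == 0)
    return(data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric(),
                      q = numeric(), significant = logical()))
  K_all <- table(ann$term)
  k_all <- table(study_ann$term)
  res <- data.frame(
    term = terms,
    k = as.integer(k_all[terms]),
    n = n,
    K = as.integer(K_all[terms]),
    N = N, stringsAsFactors = FALSE)
  res$p <- mapply(hypergeometric_upper, res$k, res$K, res$n, res$N)
  res$q <- bh_adjust(res$p)
  res$significant <- res$q < alpha
  res[order(res$q, res$p, res$term), , drop = FALSE]
}
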