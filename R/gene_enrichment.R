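#' Per-gene enrichment scores
#'
#' For each panel gene, the read share is normalised by the gene's footprint
#' share of the panel:
#' `score(g) = (reads_g / total_reads) / (footprint_g / total_footprint)`.
#' A score of 1 means the gene captured exactly its footprint-proportional
#' share of reads; applied to cfChIP samples it estimates gene activity, and
#' the identical formula applied to size-selected samples gives the
#' size-selection enrichment. Genes with zero reads score 0. Fragments without
#' a gene assignment are ignored.
#'
#' @param fragments Gene-assigned fragment tibble.
#' @param panel Gene-panel tibble (`gene_id`, `footprint_bp`).
#' @return Enrichment tibble: `gene_id`, `read_count`, `score`, `rank`
#'   (1 = lowest score; ties broken by gene_id order).
#' @export
gene_enrichment_scores <- function(fragments, panel) {
  gidx <- factor(fragments$gene_id, levels = panel$gene_id)
  counts <- tabulate(gidx, nbins = nrow(panel))
  total <- sum(counts)
  if (total == 0L) stop("no gene-assigned reads")
  footprint_share <- panel$footprint_bp / sum(panel$footprint_bp)
  score <- (counts / total) / footprint_share
  ord <- order(score, panel$gene_id)
  rank <- integer(nrow(panel))
  rank[ord] <- seq_len(nrow(panel))
  tibble(
    gene_id = panel$gene_id,
    read_count = counts,
    score = score,
    rank = rank
  )
}

#' Select high- and low-enrichment gene sets
#'
#' The `k` most enriched genes are called highly expressed and the `k` least
#' enriched lowly expressed (default k = 15). Ties are broken by stable
#' gene_id order, with a warning when a tie spans a set boundary.
#'
#' @param table Enrichment tibble from [gene_enrichment_scores()].
#' @param k Set size (default 15).
#' @return List with character vectors `high` and `low` (disjoint).
#' @export
select_high_low <- function(table, k = 15) {
  if (k == 0) return(list(high = character(), low = character()))
  if (nrow(table) < 2 * k) stop("need at least 2k genes")
  ord <- order(table$score, table$gene_id)
  sorted <- table[ord, , drop = FALSE]
  low <- sorted$gene_id[seq_len(k)]
  high <- sorted$gene_id[seq(nrow(sorted) - k + 1L, nrow(sorted))]
  n <- nrow(sorted)
  if (sorted$score[k] == sorted$score[k + 1L] ||
      sorted$score[n - k + 1L] == sorted$score[n - k]) {
    warning("tied scores span a high/low set boundary; gene_id order used")
  }
  list(high = high, low = low)
}

#' Assign enrichment quantiles
#'
#' Splits the ranked genes into `n_quantiles` contiguous groups with sizes
#' differing by at most one, Q1 holding the least enriched genes and the top
#' quantile the most enriched. When sizes cannot be equal, the larger groups
#' are placed at the top ranks (e.g. 197 genes in 10 quantiles gives
#' Q1-Q3 of 19 and Q4-Q10 of 20). Genes named in `inactive` are labelled
#' `"inactive"` first and excluded from the ranking (validation-style
#' grouping where an external expression source defines zero-activity genes).
#'
#' @param table Enrichment tibble from [gene_enrichment_scores()].
#' @param n_quantiles Number of quantile groups (default 10).
#' @param inactive Optional character vector of gene_ids to label inactive.
#' @return The table with a `quantile` column (factor, ordered
#'   `inactive < Q1 < ... < Qn`).
#' @export
assign_quantiles <- function(table, n_quantiles = 10, inactive = NULL) {
  is_inactive <- table$gene_id %in% inactive
  n <- sum(!is_inactive)
  if (n < n_quantiles) stop("fewer rankable genes than quantiles")
  base <- n %/% n_quantiles
  rem <- n %% n_quantiles
  sizes <- c(rep(base, n_quantiles - rem), rep(base + 1L, rem))
  qlabels <- paste0("Q", seq_len(n_quantiles))
  per_rank <- rep(qlabels, times = sizes)
  active <- table[!is_inactive, , drop = FALSE]
  ord <- order(active$score, active$gene_id)
  qa <- character(nrow(active))
  qa[ord] <- per_rank
  quantile <- rep("inactive", nrow(table))
  quantile[!is_inactive] <- qa
  table$quantile <- factor(quantile, levels = c(
    if (any(is_inactive)) "inactive", qlabels))
  table
}

#' Cross-assay Spearman correlation of gene enrichment
#'
#' Spearman rank correlation of per-gene enrichment scores between two assays
#' (e.g. cfChIP vs in-vitro size selection) over the genes present in both
#' tables.
#'
#' @param table_a,table_b Enrichment tibbles (`gene_id`, `score`).
#' @return List with `estimate` (Spearman r), `p_value`, `n_genes`.
#' @export
cross_assay_correlation <- function(table_a, table_b) {
  shared <- intersect(table_a$gene_id, table_b$gene_id)
  if (length(shared) < 3L) stop("fewer than 3 shared genes")
  sa <- table_a$score[match(shared, table_a$gene_id)]
  sb <- table_b$score[match(shared, table_b$gene_id)]
  st <- suppressWarnings(
    stats::cor.test(sa, sb, method = "spearman", exact = FALSE))
  list(estimate = unname(st$estimate), p_value = st$p.value,
       n_genes = length(shared))
}
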