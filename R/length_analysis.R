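#' Short-fragment fraction
#'
#' Fraction of fragments strictly shorter than `cutoff` bp. The 150 bp default
#' follows the short-cfDNA convention; a fragment of exactly `cutoff` bp is
#' not short.
#'
#' @param fragments Fragment tibble (non-empty).
#' @param cutoff Length cutoff in bp (default 150).
#' @param label Optional label (sample or gene-set) stored on the result.
#' @return List with `label`, `cutoff`, `n_total`, `n_short`, `fraction`.
#' @export
short_fraction <- function(fragments, cutoff = 150, label = NULL) {
  if (nrow(fragments) == 0L) stop("no fragments")
  n_short <- sum(fragments$length < cutoff)
  list(
    label = if (is.null(label)) unique(fragments$sample_id)[1] else label,
    cutoff = cutoff, n_total = nrow(fragments), n_short = n_short,
    fraction = n_short / nrow(fragments)
  )
}

#' Fragment-length density
#'
#' Normalised per-bin density of fragment lengths over left-closed
#' right-open bins of width `bin_bp` covering the observed range; densities
#' sum to 1.
#'
#' @param fragments Fragment tibble (non-empty).
#' @param bin_bp Bin width in bp (>= 1).
#' @return Tibble with `bin_lo`, `bin_hi`, `n`, `density`.
#' @export
length_density <- function(fragments, bin_bp = 1L) {
  if (nrow(fragments) == 0L) stop("no fragments")
  stopifnot(bin_bp >= 1L)
  len <- fragments$length
  lo <- (min(len) %/% bin_bp) * bin_bp
  hi <- (max(len) %/% bin_bp + 1L) * bin_bp
  edges <- seq(lo, hi, by = bin_bp)
  idx <- findInterval(len, edges, rightmost.closed = FALSE)
  n <- tabulate(idx, nbins = length(edges) - 1L)
  tibble(
    bin_lo = edges[-length(edges)],
    bin_hi = edges[-1L],
    n = n,
    density = n / sum(n)
  )
}

#' In-silico size-selection bins with mutant/WT enrichment
#'
#' Counts mutant and wild-type fragments in 10 bp bins from 50 to 400 bp and
#' reports, per bin, the mutant/WT ratio normalised to the overall mutant/WT
#' ratio of the combined in-range pool. `relative_ratio > 1` flags mutant
#' enrichment in a bin, `< 1` WT enrichment. Bins with no WT fragments have an
#' undefined ratio and are flagged rather than imputed; `pseudocount = 0.5`
#' enables a continuity-corrected ratio instead. Fragments outside [50, 400)
#' are ignored and counted.
#'
#' @param mut_fragments,wt_fragments Fragment tibbles (non-empty).
#' @param pseudocount 0 (default, no smoothing) or a positive continuity
#'   correction added to all four counts of a bin's ratio.
#' @return Tibble with `bin_lo`, `bin_hi`, `n_mut`, `n_wt`, `relative_ratio`,
#'   `undefined`; attributes `n_out_of_range_mut` / `n_out_of_range_wt`.
#' @export
insilico_size_bins <- function(mut_fragments, wt_fragments, pseudocount = 0) {
  if (nrow(mut_fragments) == 0L) stop("no mutant fragments")
  if (nrow(wt_fragments) == 0L) stop("no WT fragments")
  edges <- seq(50L, 400L, by = 10L)
  bin_counts <- function(len) {
    inr <- len >= 50L & len < 400L
    idx <- findInterval(len[inr], edges, rightmost.closed = FALSE)
    list(n = tabulate(idx, nbins = 35L), out = sum(!inr))
  }
  mc <- bin_counts(mut_fragments$length)
  wc <- bin_counts(wt_fragments$length)
  n_mut_tot <- sum(mc$n)
  n_wt_tot <- sum(wc$n)
  if (n_wt_tot == 0L) stop("no WT fragments in [50, 400)")
  if (n_mut_tot == 0L) stop("no mutant fragments in [50, 400)")
  overall <- n_mut_tot / n_wt_tot
  if (pseudocount > 0) {
    rel <- ((mc$n + pseudocount) / (wc$n + pseudocount)) /
      ((n_mut_tot + pseudocount) / (n_wt_tot + pseudocount))
    undefined <- rep(FALSE, 35L)
  } else {
    rel <- ifelse(wc$n > 0L, (mc$n / wc$n) / overall, NA_real_)
    undefined <- wc$n == 0L
  }
  out <- tibble(
    bin_lo = edges[-36L], bin_hi = edges[-1L],
    n_mut = mc$n, n_wt = wc$n,
    relative_ratio = rel, undefined = undefined
  )
  attr(out, "n_out_of_range_mut") <- mc$out
  attr(out, "n_out_of_range_wt") <- wc$out
  out
}

#' Length-cutoff sweep against a per-gene reference score
#'
#' For each length cutoff, computes the per-gene short-fragment fraction from
#' gene-assigned fragments and its Spearman correlation with a per-gene
#' reference enrichment score (e.g. cfChIP enrichment), mirroring the in-silico
#' size-selection cutoff analysis. Genes with zero fragments are excluded and
#' counted.
#'
#' @param fragments Gene-assigned fragment tibble.
#' @param reference_scores Named numeric vector of per-gene scores, or an
#'   enrichment table with `gene_id` and `score` columns.
#' @param cutoffs Integer vector of length cutoffs in bp.
#' @return Tibble with `cutoff`, `spearman_r`, `p_value`, `n_genes`,
#'   `n_genes_excluded`.
#' @export
cutoff_sweep <- function(fragments, reference_scores,
                         cutoffs = seq(100L, 400L, by = 10L)) {
  if (is.data.frame(reference_scores)) {
    reference_scores <- stats::setNames(reference_scores$score,
                                        reference_scores$gene_id)
  }
  frag <- fragments[!is.na(fragments$gene_id), , drop = FALSE]
  genes <- intersect(names(reference_scores), unique(frag$gene_id))
  n_excluded <- length(reference_scores) - length(genes)
  if (length(genes) < 3L) stop("fewer than 3 genes with fragments and scores")
  gidx <- factor(frag$gene_id, levels = genes)
  inuse <- !is.na(gidx)
  gidx <- gidx[inuse]
  len <- frag$length[inuse]
  totals <- tabulate(gidx, nbins = length(genes))
  ref <- reference_scores[genes]
  rows <- lapply(cutoffs, function(ct) {
    shorts <- tabulate(gidx[len < ct], nbins = length(genes))
    fr <- shorts / totals
    st <- suppressWarnings(
      stats::cor.test(fr, ref, method = "spearman", exact = FALSE))
    tibble(cutoff = ct, spearman_r = unname(st$estimate),
           p_value = st$p.value, n_genes = length(genes),
           n_genes_excluded = n_excluded)
  })
  dplyr::bind_rows(rows)
}
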