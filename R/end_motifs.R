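#' The 64-motif universe
#'
#' All 4^3 = 64 DNA 3-mers in lexicographic order. Every motif-frequency
#' vector in the package is indexed by this fixed universe, so unobserved
#' motifs are retained with zero frequency and all tests and overlap
#' statistics share a constant universe.
#'
#' @return Character vector of length 64.
#' @export
all_motifs <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(third = b, second = b, first = b, stringsAsFactors = FALSE)
  paste0(g$first, g$second, g$third)
}

#' Per-sample fragment end motif frequencies
#'
#' Both ends of every motif-complete fragment contribute one count each; the
#' 64 frequencies are normalised by the total number of counted ends
#' (`n_ends` = 2 x motif-complete fragments). Fragments missing either motif
#' are excluded and counted.
#'
#' @param fragments Fragment tibble.
#' @param sample_id Optional label stored on the result (defaults to the
#'   single sample id present, or `"pooled"`).
#' @return An object of class `motif_freq`: a list with `freq` (named numeric,
#'   64 entries summing to 1), `n_ends`, `n_excluded`, `sample_id`.
#' @export
motif_frequencies <- function(fragments, sample_id = NULL) {
  complete <- !is.na(fragments$motif_up) & !is.na(fragments$motif_down)
  n_excluded <- sum(!complete)
  if (sum(complete) == 0L) stop("no motif-complete fragments")
  universe <- all_motifs()
  ends <- factor(c(fragments$motif_up[complete], fragments$motif_down[complete]),
                 levels = universe)
  if (anyNA(ends)) stop("motifs outside the ACGT 3-mer universe")
  counts <- tabulate(ends, nbins = 64L)
  if (is.null(sample_id)) {
    sids <- unique(fragments$sample_id[complete])
    sample_id <- if (length(sids) == 1L) sids else "pooled"
  }
  structure(
    list(freq = stats::setNames(counts / sum(counts), universe),
         n_ends = sum(counts), n_excluded = n_excluded,
         sample_id = sample_id),
    class = "motif_freq"
  )
}

#' @export
print.motif_freq <- function(x, ...) {
  cat("<motif_freq> sample:", x$sample_id, " ends:", x$n_ends, "\n")
  top <- sort(x$freq, decreasing = TRUE)[1:5]
  cat("top motifs:", paste(sprintf("%s=%.4f", names(top), top), collapse = " "), "\n")
  invisible(x)
}

#' Motif-frequency matrix for a multi-sample fragment table
#'
#' @param fragments Fragment tibble covering one or more samples.
#' @return Numeric matrix, one row per sample (rownames = sample ids), 64
#'   columns in [all_motifs()] order; rows sum to 1. Row attribute `n_ends`
#'   carries the per-sample end counts.
#' @export
motif_frequency_matrix <- function(fragments) {
  sids <- unique(fragments$sample_id)
  vecs <- lapply(sids, function(s) {
    motif_frequencies(fragments[fragments$sample_id == s, , drop = FALSE], s)
  })
  as_motif_matrix(vecs)
}

as_motif_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 64L)
    if (is.null(colnames(x))) colnames(x) <- all_motifs()
    return(x)
  }
  if (inherits(x, "motif_freq")) x <- list(x)
  m <- do.call(rbind, lapply(x, function(v) v$freq))
  rownames(m) <- vapply(x, function(v) v$sample_id, character(1))
  attr(m, "n_ends") <- vapply(x, function(v) v$n_ends, numeric(1))
  m
}

#' Differential fragment end motif analysis
#'
#' Per-motif two-sided t-tests between two groups of motif-frequency vectors
#' (paired across matched subjects, or unpaired Welch), with
#' Benjamini-Hochberg adjustment across exactly the 64 motif tests. Motifs
#' with `q_value` below threshold flag significance; `direction` records which
#' group the motif is enriched in. Zero-variance motifs (all paired
#' differences identical, or both groups constant) are reported with p = 1 and
#' `degenerate = TRUE` so the BH step stays well defined.
#'
#' @param vectors_a,vectors_b Lists of `motif_freq` objects, or numeric
#'   matrices (samples x 64).
#' @param paired Paired tests across matched rows (requires equal group sizes
#'   in matched order).
#' @return A 64-row tibble: `motif`, `mean_a`, `mean_b`, `mean_diff`
#'   (`mean_a - mean_b`; paired: mean of per-pair differences), `statistic`,
#'   `p_value`, `q_value`, `direction`, `degenerate`.
#' @export
differential_motifs <- function(vectors_a, vectors_b, paired = FALSE) {
  a <- as_motif_matrix(vectors_a)
  b <- as_motif_matrix(vectors_b)
  if (paired && nrow(a) != nrow(b)) {
    stop("paired mode requires equal, matched group sizes")
  }
  if (min(nrow(a), nrow(b)) < 3L) stop("need at least 3 samples (pairs) per group")
  universe <- all_motifs()
  res <- lapply(seq_len(64L), function(i) {
    xa <- a[, i]
    xb <- b[, i]
    degenerate <- if (paired) stats::sd(xa - xb) == 0 else
      (stats::sd(xa) == 0 && stats::sd(xb) == 0)
    if (degenerate) {
      list(stat = NA_real_, p = 1, deg = TRUE)
    } else {
      tt <- stats::t.test(xa, xb, paired = paired)
      list(stat = unname(tt$statistic), p = tt$p.value, deg = FALSE)
    }
  })
  mean_diff <- colMeans(a) - colMeans(b)
  p <- vapply(res, `[[`, numeric(1), "p")
  tibble(
    motif = universe,
    mean_a = unname(colMeans(a)),
    mean_b = unname(colMeans(b)),
    mean_diff = unname(mean_diff),
    statistic = vapply(res, `[[`, numeric(1), "stat"),
    p_value = p,
    q_value = stats::p.adjust(p, method = "BH"),
    direction = ifelse(mean_diff > 0, "A_enriched",
                       ifelse(mean_diff < 0, "B_enriched", "none")),
    degenerate = vapply(res, `[[`, logical(1), "deg")
  )
}

#' Select a motif set from a differential table
#'
#' Motifs significant at `q_value < q_threshold` with the requested direction
#' of mean difference. A threshold of 1 (or more) disables the q filter, so
#' the 64 motifs are partitioned purely by direction sign.
#'
#' @param table Output of [differential_motifs()].
#' @param direction `"A_enriched"` or `"B_enriched"`.
#' @param q_threshold Significance threshold on the BH-adjusted q value.
#' @param label Optional set label stored as an attribute.
#' @return Character vector of motifs (possibly empty).
#' @export
define_motif_set <- function(table, direction = c("A_enriched", "B_enriched"),
                             q_threshold = 0.05, label = NULL) {
  direction <- match.arg(direction)
  sig <- if (q_threshold >= 1) TRUE else table$q_value < q_threshold
  out <- table$motif[sig & table$direction == direction]
  if (!is.null(label)) attr(out, "label") <- label
  out
}

#' G+C content of a motif set
#'
#' @param motifs Character vector of 3-mers.
#' @return List with `per_motif` (named numeric, (#G + #C)/3 per motif) and
#'   `mean_gc` (set mean).
#' @export
gc_content <- function(motifs) {
  if (length(motifs) == 0L) stop("empty motif set")
  gc <- vapply(strsplit(toupper(motifs), ""), function(b) mean(b %in% c("G", "C")),
               numeric(1))
  names(gc) <- motifs
  list(per_motif = gc, mean_gc = mean(gc))
}

#' Compare the G+C content of two motif sets
#'
#' Wilcoxon rank-sum test on the per-motif G+C fractions of the two sets.
#'
#' @param set_a,set_b Character vectors of 3-mers.
#' @return List with `statistic`, `p_value`, `mean_gc_a`, `mean_gc_b`.
#' @export
compare_gc_content <- function(set_a, set_b) {
  ga <- gc_content(set_a)
  gb <- gc_content(set_b)
  wt <- suppressWarnings(stats::wilcox.test(ga$per_motif, gb$per_motif))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       mean_gc_a = ga$mean_gc, mean_gc_b = gb$mean_gc)
}

#' Hypergeometric overlap test between two motif sets
#'
#' Upper-tail hypergeometric probability of observing at least the seen
#' overlap when `|set_b|` motifs are drawn without replacement from a universe
#' of `universe_size` motifs of which `|set_a|` are "successes":
#' p = P(X >= overlap).
#'
#' @param set_a,set_b Character vectors (subsets of the universe).
#' @param universe_size Universe size (default 64).
#' @return List with `overlap`, `p_value`, `size_a`, `size_b`.
#' @export
motif_set_overlap <- function(set_a, set_b, universe_size = 64) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (length(set_a) > universe_size || length(set_b) > universe_size) {
    stop("set size exceeds universe")
  }
  k <- length(intersect(set_a, set_b))
  p <- stats::phyper(k - 1, length(set_a), universe_size - length(set_a),
                     length(set_b), lower.tail = FALSE)
  list(overlap = k, p_value = p, size_a = length(set_a), size_b = length(set_b))
}

#' 2-D embedding of motif-frequency vectors
#'
#' UMAP (uwot) on the 64-dimensional motif-frequency vectors, for
#' cluster-structure plots of samples or gene sets. Deterministic for a fixed
#' seed. Degenerate inputs (all vectors identical) yield constant coordinates
#' rather than an error. No numerical acceptance is attached to the
#' embedding; it is plotting plumbing.
#'
#' @param vectors List of `motif_freq` objects or a samples x 64 matrix.
#' @param seed Integer seed.
#' @param n_neighbors,min_dist UMAP hyperparameters (defaults 5 and 0.1).
#' @return Tibble with `sample_id`, `umap1`, `umap2`.
#' @export
embed_samples <- function(vectors, seed = 42L, n_neighbors = 5, min_dist = 0.1) {
  m <- as_motif_matrix(vectors)
  if (nrow(m) < 4L) stop("need at least 4 vectors to embed")
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(m)))
  coords <- tryCatch({
    withr_seed <- function(expr) { # local RNG scope
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      expr
    }
    withr_seed(uwot::umap(m, n_neighbors = min(n_neighbors, nrow(m) - 1L),
                          min_dist = min_dist, n_threads = 1, n_sgd_threads = 1))
  }, error = function(e) matrix(0, nrow(m), 2L))
  tibble(sample_id = ids, umap1 = coords[, 1L], umap2 = coords[, 2L])
}
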