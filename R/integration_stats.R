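#' Stamp subject ids onto a fragment table
#'
#' @param fragments Fragment tibble.
#' @param manifest Manifest tibble (`sample_id`, `subject_id`, ...).
#' @return The fragment tibble with a `subject_id` column.
#' @export
add_subject_ids <- function(fragments, manifest) {
  fragments$subject_id <- manifest$subject_id[
    match(fragments$sample_id, manifest$sample_id)]
  fragments
}

#' Per-subject, per-quantile fragmentation metrics
#'
#' Builds a subjects x quantile-groups matrix of one of three fragment-level
#' metrics, computed from each subject's fragments grouped by that subject's
#' own gene-quantile assignment (quantiles are subject-specific):
#' `short_fraction` (fraction with length < cutoff), `motif_fraction`
#' (fraction of motif-complete fragments whose ends satisfy `match_rule`
#' against `motif_set`) and `combined_fraction` (fraction of motif-complete
#' fragments that are both short and motif-matching, so
#' `combined <= min(short, motif)` cell-wise). Empty cells are `NA` with a
#' warning.
#'
#' @param fragments Gene-assigned fragment tibble with a `subject_id` column
#'   (see [add_subject_ids()]).
#' @param quantiles Tibble `subject_id`, `gene_id`, `quantile` (factor with
#'   ordered levels) giving each subject's gene grouping.
#' @param metric `"short_fraction"`, `"motif_fraction"` or
#'   `"combined_fraction"`.
#' @param cutoff Length cutoff in bp (default 150).
#' @param motif_set Character vector of motifs (required for motif/combined).
#' @param match_rule `"any_end"` (default): a fragment matches when either
#'   terminal motif is in the set; `"both_ends"`: both must be.
#' @return Numeric matrix (rownames subjects, colnames quantile groups) with
#'   attribute `metric`.
#' @export
quantile_metric <- function(fragments, quantiles,
                            metric = c("short_fraction", "motif_fraction",
                                       "combined_fraction"),
                            cutoff = 150, motif_set = NULL,
                            match_rule = c("any_end", "both_ends")) {
  metric <- match.arg(metric)
  match_rule <- match.arg(match_rule)
  if (metric != "short_fraction" && is.null(motif_set)) {
    stop("motif_set is required for metric '", metric, "'")
  }
  if (is.null(fragments$subject_id)) stop("fragments need a subject_id column")
  stopifnot(is.factor(quantiles$quantile))
  glabels <- levels(quantiles$quantile)
  subjects <- sort(unique(quantiles$subject_id))
  genes <- unique(quantiles$gene_id)

  # integer lookup subject x gene -> quantile index (quantiles are
  # subject-specific)
  qmat <- matrix(NA_integer_, length(subjects), length(genes),
                 dimnames = list(subjects, genes))
  qmat[cbind(match(quantiles$subject_id, subjects),
             match(quantiles$gene_id, genes))] <-
    as.integer(quantiles$quantile)
  si <- match(fragments$subject_id, subjects)
  gi <- match(fragments$gene_id, genes)
  ok <- !is.na(si) & !is.na(gi)
  frag_qi <- rep(NA_integer_, nrow(fragments))
  frag_qi[ok] <- qmat[cbind(si[ok], gi[ok])]
  keep <- !is.na(frag_qi)
  if (metric != "short_fraction") {
    keep <- keep & !is.na(fragments$motif_up) & !is.na(fragments$motif_down)
  }
  frag <- fragments[keep, , drop = FALSE]
  cell <- (si[keep] - 1L) * length(glabels) + frag_qi[keep]

  hit <- switch(metric,
    short_fraction = frag$length < cutoff,
    motif_fraction = motif_match(frag, motif_set, match_rule),
    combined_fraction = frag$length < cutoff &
      motif_match(frag, motif_set, match_rule)
  )
  ncell <- length(subjects) * length(glabels)
  num <- tabulate(cell[hit], nbins = ncell)
  den <- tabulate(cell, nbins = ncell)
  m <- matrix(num / den, nrow = length(subjects), ncol = length(glabels),
              byrow = TRUE, dimnames = list(subjects, glabels))
  m[is.nan(m)] <- NA_real_
  if (anyNA(m)) warning("empty subject x quantile cells set to NA")
  attr(m, "metric") <- metric
  m
}

motif_match <- function(frag, motif_set, match_rule) {
  up <- frag$motif_up %in% motif_set
  dn <- frag$motif_down %in% motif_set
  if (match_rule == "any_end") up | dn else up & dn
}

#' Per-subject, per-quantile mean enrichment
#'
#' Companion to [quantile_metric()] for enrichment-score metrics (e.g.
#' size-selection enrichment): the cell value is the mean per-gene score over
#' the genes of that subject's quantile.
#'
#' @param tables Named list of enrichment tibbles, one per subject.
#' @param quantiles Tibble `subject_id`, `gene_id`, `quantile`.
#' @return Numeric matrix (subjects x groups), attribute
#'   `metric = "sizesel_enrichment"`.
#' @export
quantile_enrichment <- function(tables, quantiles) {
  stopifnot(is.factor(quantiles$quantile))
  glabels <- levels(quantiles$quantile)
  subjects <- sort(names(tables))
  m <- matrix(NA_real_, length(subjects), length(glabels),
              dimnames = list(subjects, glabels))
  for (s in subjects) {
    tab <- tables[[s]]
    q <- quantiles[quantiles$subject_id == s, , drop = FALSE]
    sc <- tab$score[match(q$gene_id, tab$gene_id)]
    mm <- tapply(sc, q$quantile, mean)
    m[s, names(mm)] <- as.numeric(mm)
  }
  attr(m, "metric") <- "sizesel_enrichment"
  m
}

#' Normalise a quantile-metric matrix to a reference group
#'
#' Per subject, the percent change of each group relative to the reference
#' group, `(value / reference - 1) * 100` (so the reference column is exactly
#' 0 for every subject), summarised per group by the median and IQR across
#' subjects (type-7 quartiles). Subjects whose reference value is 0 or
#' missing are flagged and excluded from the summaries. `method = "ratio"`
#' reports `value / reference * 100` instead.
#'
#' @param matrix Subjects x groups matrix from [quantile_metric()] or
#'   [quantile_enrichment()].
#' @param reference Reference group label (default `"Q1"`).
#' @param method `"percent_change"` (default) or `"ratio"`.
#' @return List with `normalized` (subjects x groups), `summary` (tibble:
#'   group, median, iqr_lo, iqr_hi, n), `excluded_subjects`, `reference`.
#' @export
normalize_to_reference <- function(matrix, reference = "Q1",
                                   method = c("percent_change", "ratio")) {
  method <- match.arg(method)
  if (!reference %in% colnames(matrix)) {
    stop("reference group not in matrix: ", reference)
  }
  ref <- matrix[, reference]
  bad <- is.na(ref) | ref == 0
  norm <- sweep(matrix, 1L, ref, "/")
  norm <- if (method == "percent_change") (norm - 1) * 100 else norm * 100
  norm[bad, ] <- NA_real_
  kept <- norm[!bad, , drop = FALSE]
  summary <- tibble(
    group = colnames(matrix),
    median = unname(apply(kept, 2L, stats::median, na.rm = TRUE)),
    iqr_lo = unname(apply(kept, 2L, stats::quantile, probs = 0.25,
                          na.rm = TRUE, names = FALSE)),
    iqr_hi = unname(apply(kept, 2L, stats::quantile, probs = 0.75,
                          na.rm = TRUE, names = FALSE)),
    n = unname(apply(kept, 2L, function(x) sum(!is.na(x))))
  )
  list(normalized = norm, summary = summary,
       excluded_subjects = rownames(matrix)[bad], reference = reference)
}

#' Friedman test across quantiles with conditional post-hoc paired t-tests
#'
#' Friedman's rank ANOVA over the ordered quantile groups with subjects as
#' blocks (subjects with any missing cell are dropped and counted). If and
#' only if the Friedman p-value is below `alpha`, each non-reference group is
#' compared to the reference with an unadjusted two-sided paired t-test
#' (multiplicity correction is deliberately not applied to these post-hoc
#' tests; FDR control is reserved for the 64-motif analyses).
#'
#' @param matrix Subjects x groups metric matrix.
#' @param reference Reference group (default `"Q1"`).
#' @param alpha Gate for the post-hoc tests (default 0.05).
#' @return List with `statistic`, `df`, `p_value`, `n_subjects`,
#'   `n_dropped`, and `posthoc` (tibble group/statistic/p_value/degenerate,
#'   or `NULL` when not gated in).
#' @export
friedman_quantile_test <- function(matrix, reference = "Q1", alpha = 0.05) {
  complete <- stats::complete.cases(matrix)
  m <- matrix[complete, , drop = FALSE]
  if (nrow(m) < 3L || ncol(m) < 3L) {
    stop("need at least 3 complete subjects and 3 groups")
  }
  ft <- stats::friedman.test(m)
  # every block completely tied: the tie-corrected statistic is 0/0; the
  # rank evidence is null, so report statistic 0, p = 1
  if (is.nan(ft$statistic)) {
    ft$statistic[] <- 0
    ft$p.value <- 1
  }
  posthoc <- NULL
  if (ft$p.value < alpha) {
    others <- setdiff(colnames(m), reference)
    rows <- lapply(others, function(gcol) {
      gt <- group_comparison_tests(m[, gcol], m[, reference], paired = TRUE)
      tibble(group = gcol, statistic = gt$statistic, p_value = gt$p_value,
             degenerate = gt$degenerate)
    })
    posthoc <- dplyr::bind_rows(rows)
  }
  list(statistic = unname(ft$statistic), df = unname(ft$parameter),
       p_value = ft$p.value, n_subjects = nrow(m),
       n_dropped = sum(!complete), posthoc = posthoc)
}

#' Two-group t-test with degenerate-input guards
#'
#' Two-sided t-test, paired or unpaired; unpaired tests use the Welch
#' unequal-variance form. Zero-variance inputs are flagged instead of
#' erroring: identical groups give p = 1, a nonzero constant difference gives
#' p = NA (the t statistic is unbounded), both with `degenerate = TRUE`.
#'
#' @param values_a,values_b Numeric vectors (paired: equal length, matched
#'   order).
#' @param paired Paired test (default `FALSE`).
#' @return List with `statistic`, `df`, `p_value`, `mean_diff`, `degenerate`.
#' @export
group_comparison_tests <- function(values_a, values_b, paired = FALSE) {
  if (paired) {
    stopifnot(length(values_a) == length(values_b))
    if (length(values_a) < 2L) stop("need at least 2 pairs")
    d <- values_a - values_b
    if (stats::sd(d) == 0) {
      return(list(statistic = NA_real_, df = NA_real_,
                  p_value = if (mean(d) == 0) 1 else NA_real_,
                  mean_diff = mean(d), degenerate = TRUE))
    }
    tt <- stats::t.test(values_a, values_b, paired = TRUE)
  } else {
    if (min(length(values_a), length(values_b)) < 2L) {
      stop("need at least 2 values per group")
    }
    if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
      eq <- mean(values_a) == mean(values_b)
      return(list(statistic = NA_real_, df = NA_real_,
                  p_value = if (eq) 1 else NA_real_,
                  mean_diff = mean(values_a) - mean(values_b),
                  degenerate = TRUE))
    }
    tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
  }
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       mean_diff = if (paired) mean(values_a - values_b)
                   else mean(values_a) - mean(values_b),
       degenerate = FALSE)
}
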