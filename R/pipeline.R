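#' Per-subject gene-activity quantile assignments from cfChIP samples
#'
#' For each subject with a cfChIP sample, scores genes with
#' [gene_enrichment_scores()] on that sample and splits them into
#' subject-specific quantiles with [assign_quantiles()].
#'
#' @param fragments Gene-assigned fragment tibble (all samples).
#' @param manifest Manifest tibble.
#' @param panel Gene-panel tibble.
#' @param n_quantiles Number of quantiles (default 10).
#' @return List with `tables` (named list of per-subject enrichment tibbles)
#'   and `quantiles` (tibble `subject_id`, `gene_id`, `quantile`).
#' @export
subject_quantiles <- function(fragments, manifest, panel, n_quantiles = 10) {
  chip <- manifest[manifest$assay == "cfchip", , drop = FALSE]
  if (nrow(chip) == 0L) stop("no cfchip samples in manifest")
  tables <- list()
  qrows <- list()
  for (i in seq_len(nrow(chip))) {
    subj <- chip$subject_id[i]
    tab <- gene_enrichment_scores(
      fragments[fragments$sample_id == chip$sample_id[i], , drop = FALSE],
      panel)
    tabq <- assign_quantiles(tab, n_quantiles = n_quantiles)
    tables[[subj]] <- tabq
    qrows[[subj]] <- tibble(subject_id = subj, gene_id = tabq$gene_id,
                            quantile = tabq$quantile)
  }
  list(tables = tables, quantiles = dplyr::bind_rows(qrows))
}

#' Full fragmentomics analysis of a cohort
#'
#' Runs the integrated analysis on a cohort (simulated or loaded from disk):
#' per-subject cfChIP gene-activity quantiles; paired differential end-motif
#' analysis (cfChIP vs input) defining the cfChIP and input motif sets;
#' per-quantile short-fraction, motif-fraction and combined metrics on input
#' cfDNA with Q1-normalisation and the Friedman + paired-t inference scheme;
#' size-selection enrichment per quantile, its differential motifs, the
#' hypergeometric motif-set overlap and the per-subject cfChIP/size-selection
#' Spearman correlations; nucleosome core/linker end fractions for high- vs
#' low-expression gene sets; mutant/WT in-silico size bins and length-shift
#' estimate; and the cancer vs healthy short-fraction comparison.
#'
#' @param cohort List with `fragments`, `panel`, `manifest`, optional `track`
#'   (a `synthetic_cohort` works as-is).
#' @param cutoff Short-fragment cutoff in bp (default 150).
#' @param n_quantiles Number of gene-activity quantiles (default 10).
#' @param k_highlow Size of the high/low gene sets (default 15).
#' @param q_threshold q-value threshold for motif sets (default 0.05).
#' @param motif_set Optional externally supplied motif set for the
#'   motif/combined quantile metrics; by default the cfChIP motif set derived
#'   from the paired differential analysis is used.
#' @param match_rule Fragment-level motif membership rule (default
#'   `"any_end"`).
#' @param embed Also compute the UMAP embedding of sample motif vectors
#'   (default `FALSE`).
#' @param seed Seed for the embedding.
#' @return A nested results list; see the methods vignette for a walkthrough.
#' @export
analyze_cohort <- function(cohort, cutoff = 150, n_quantiles = 10,
                           k_highlow = 15, q_threshold = 0.05,
                           motif_set = NULL, match_rule = "any_end",
                           embed = FALSE, seed = 1L) {
  frags <- add_subject_ids(cohort$fragments, cohort$manifest)
  man <- cohort$manifest
  res <- list(settings = list(cutoff = cutoff, n_quantiles = n_quantiles,
                              k_highlow = k_highlow, q_threshold = q_threshold,
                              match_rule = match_rule))

  sidx <- split(seq_len(nrow(frags)), frags$sample_id)
  sample_frags <- function(sid) frags[sidx[[sid]], , drop = FALSE]

  sq <- subject_quantiles(frags, man, cohort$panel, n_quantiles)
  res$chip_tables <- sq$tables
  res$quantiles <- sq$quantiles
  cancer_subjects <- sort(names(sq$tables))

  sample_of <- function(subj, assay) {
    man$sample_id[man$subject_id == subj & man$assay == assay][1]
  }
  vec_matrix <- function(assay) {
    rows <- lapply(cancer_subjects, function(s) {
      motif_frequencies(sample_frags(sample_of(s, assay)), s)$freq
    })
    m <- do.call(rbind, rows)
    rownames(m) <- cancer_subjects
    m
  }

  input_mat <- vec_matrix("input")
  chip_mat <- vec_matrix("cfchip")
  res$diff_chip <- differential_motifs(chip_mat, input_mat, paired = TRUE)
  res$cfchip_motifs <- define_motif_set(res$diff_chip, "A_enriched",
                                        q_threshold, label = "cfchip_motifs")
  res$input_motifs <- define_motif_set(res$diff_chip, "B_enriched",
                                       q_threshold, label = "input_motifs")
  used_set <- if (is.null(motif_set)) res$cfchip_motifs else motif_set
  res$motif_set_used <- used_set

  input_ids <- man$sample_id[man$assay == "input" &
                               man$subject_id %in% cancer_subjects]
  input_frags <- frags[frags$sample_id %in% input_ids, , drop = FALSE]

  res$metrics <- list()
  res$metrics$short_fraction <- quantile_metric(
    input_frags, sq$quantiles, "short_fraction", cutoff = cutoff)
  if (length(used_set) > 0L) {
    res$metrics$motif_fraction <- quantile_metric(
      input_frags, sq$quantiles, "motif_fraction", cutoff = cutoff,
      motif_set = used_set, match_rule = match_rule)
    res$metrics$combined_fraction <- quantile_metric(
      input_frags, sq$quantiles, "combined_fraction", cutoff = cutoff,
      motif_set = used_set, match_rule = match_rule)
  }

  res$normalized <- lapply(res$metrics, normalize_to_reference, reference = "Q1")
  res$friedman <- lapply(res$metrics, friedman_quantile_test, reference = "Q1")

  ss <- man[man$assay == "size_selected", , drop = FALSE]
  if (nrow(ss) >= 3L) {
    ss_subjects <- intersect(cancer_subjects, ss$subject_id)
    ss_tables <- lapply(stats::setNames(ss_subjects, ss_subjects), function(s) {
      gene_enrichment_scores(
        sample_frags(sample_of(s, "size_selected")),
        cohort$panel)
    })
    res$sizesel_tables <- ss_tables
    qe <- quantile_enrichment(ss_tables,
                              sq$quantiles[sq$quantiles$subject_id %in% ss_subjects, ])
    res$metrics$sizesel_enrichment <- qe
    res$normalized$sizesel_enrichment <- normalize_to_reference(qe, "Q1")
    res$friedman$sizesel_enrichment <- friedman_quantile_test(qe, "Q1")
    res$cross_assay <- vapply(ss_subjects, function(s) {
      cross_assay_correlation(res$chip_tables[[s]], ss_tables[[s]])$estimate
    }, numeric(1))
    ss_mat <- do.call(rbind, lapply(ss_subjects, function(s) {
      motif_frequencies(
        sample_frags(sample_of(s, "size_selected")),
        s)$freq
    }))
    rownames(ss_mat) <- ss_subjects
    res$diff_sizesel <- differential_motifs(
      ss_mat, input_mat[ss_subjects, , drop = FALSE], paired = TRUE)
    res$sizesel_motifs <- define_motif_set(res$diff_sizesel, "A_enriched",
                                           q_threshold, label = "sizesel_motifs")
    res$motif_overlap <- motif_set_overlap(res$cfchip_motifs,
                                           res$sizesel_motifs)
  }

  if (!is.null(cohort$track) && nrow(cohort$track) > 0L) {
    clf <- lapply(cancer_subjects, function(s) {
      tab <- res$chip_tables[[s]]
      hl <- select_high_low(tab, k_highlow)
      sfr <- sample_frags(sample_of(s, "input"))
      fr_h <- core_linker_fraction(end_dyad_distances(
        sfr[sfr$gene_id %in% hl$high, , drop = FALSE], cohort$track, "high"))
      fr_l <- core_linker_fraction(end_dyad_distances(
        sfr[sfr$gene_id %in% hl$low, , drop = FALSE], cohort$track, "low"))
      c(high = fr_h$fraction, low = fr_l$fraction)
    })
    clm <- do.call(rbind, clf)
    rownames(clm) <- cancer_subjects
    res$core_linker <- list(
      fractions = clm,
      test = group_comparison_tests(clm[, "high"], clm[, "low"], paired = TRUE))
  }

  mut <- input_frags[!is.na(input_frags$allele) & input_frags$allele == "MUT", ]
  wt <- input_frags[!is.na(input_frags$allele) & input_frags$allele == "WT", ]
  if (nrow(mut) > 0L && nrow(wt) > 0L) {
    res$mutation <- list(
      bins = insilico_size_bins(mut, wt),
      delta_hat = mean(mut$length) - mean(wt$length),
      n_mut = nrow(mut), n_wt = nrow(wt)
    )
  }

  healthy_ids <- man$sample_id[man$assay == "input" & man$group == "healthy"]
  if (length(healthy_ids) >= 2L && length(input_ids) >= 2L) {
    sf_of <- function(ids) vapply(ids, function(sid) {
      short_fraction(sample_frags(sid),
                     cutoff)$fraction
    }, numeric(1))
    res$cancer_vs_healthy <- group_comparison_tests(
      sf_of(input_ids), sf_of(healthy_ids), paired = FALSE)
  }

  if (embed) {
    both <- rbind(input_mat, chip_mat)
    rownames(both) <- c(paste0(cancer_subjects, "_input"),
                        paste0(cancer_subjects, "_cfchip"))
    res$embedding <- embed_samples(both, seed = seed)
  }
  res
}

#' Run the full pipeline from a configuration
#'
#' Orchestrates simulate (optional) -> filter -> gene assignment -> the
#' integrated analysis of [analyze_cohort()], optionally writing tidy result
#' tables and a JSON summary. `config` is either a [simulation_config()]
#' (synthetic run) or a list of input paths with required fields `fragments`,
#' `manifest` and `panel` (optional `track`); a missing field aborts with an
#' error naming it.
#'
#' @param config A `simulation_config` or a named list of file paths.
#' @param outdir Optional output directory for result tables and
#'   `summary.json`.
#' @param ... Passed to [analyze_cohort()].
#' @return List with `cohort` and `results` (invisible when writing).
#' @export
run_pipeline <- function(config, outdir = NULL, ...) {
  if (inherits(config, "simulation_config")) {
    cohort <- simulate_cohort(config)
  } else {
    for (field in c("fragments", "manifest", "panel")) {
      if (is.null(config[[field]])) {
        stop("pipeline config is missing required field '", field, "'")
      }
    }
    manifest <- as_tibble(utils::read.table(config$manifest, sep = "\t",
                                            header = TRUE,
                                            stringsAsFactors = FALSE))
    panel <- read_gene_panel(config$panel)
    frags <- read_fragments(config$fragments, "bed_like")
    frags <- filter_fragments(frags)$fragments
    if (all(is.na(frags$gene_id))) frags <- assign_genes(frags, panel)
    track <- if (!is.null(config$track)) read_nucleosome_track(config$track)
             else NULL
    cohort <- list(fragments = frags, panel = panel, manifest = manifest,
                   track = track)
  }
  results <- analyze_cohort(cohort, ...)
  if (!is.null(outdir)) {
    write_pipeline_outputs(results, outdir)
    return(invisible(list(cohort = cohort, results = results)))
  }
  list(cohort = cohort, results = results)
}

write_pipeline_outputs <- function(results, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, name) {
    utils::write.table(as.data.frame(df), file.path(outdir, name),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wtsv(results$diff_chip, "differential_motifs_cfchip_vs_input.tsv")
  if (!is.null(results$diff_sizesel)) {
    wtsv(results$diff_sizesel, "differential_motifs_sizesel_vs_input.tsv")
  }
  for (metric in names(results$normalized)) {
    wtsv(results$normalized[[metric]]$summary,
         paste0("quantile_summary_", metric, ".tsv"))
  }
  writeLines(results$cfchip_motifs, file.path(outdir, "cfchip_motifs.txt"))
  writeLines(results$input_motifs, file.path(outdir, "input_motifs.txt"))
  if (!is.null(results$sizesel_motifs)) {
    writeLines(results$sizesel_motifs, file.path(outdir, "sizesel_motifs.txt"))
  }
  if (!is.null(results$mutation)) wtsv(results$mutation$bins, "mutant_wt_bins.tsv")
  jsonlite::write_json(pipeline_summary(results),
                       file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Flat numeric summary of a pipeline run
#'
#' @param results Output of [analyze_cohort()].
#' @return Named list of headline numbers (JSON-serialisable).
#' @export
pipeline_summary <- function(results) {
  q10 <- function(metric) {
    nr <- results$normalized[[metric]]
    if (is.null(nr)) return(NULL)
    top <- nr$summary[nrow(nr$summary), ]
    list(median = top$median, iqr_lo = top$iqr_lo, iqr_hi = top$iqr_hi)
  }
  out <- list(
    n_subjects = length(results$chip_tables),
    cutoff = results$settings$cutoff,
    n_cfchip_motifs = length(results$cfchip_motifs),
    n_input_motifs = length(results$input_motifs),
    q10_short_fraction = q10("short_fraction"),
    q10_motif_fraction = q10("motif_fraction"),
    q10_combined_fraction = q10("combined_fraction"),
    q10_sizesel_enrichment = q10("sizesel_enrichment"),
    friedman_p = lapply(results$friedman, `[[`, "p_value")
  )
  if (!is.null(results$cross_assay)) {
    out$spearman_range <- range(results$cross_assay)
    out$spearman_median <- stats::median(results$cross_assay)
  }
  if (!is.null(results$motif_overlap)) {
    out$motif_overlap <- results$motif_overlap$overlap
    out$motif_overlap_p <- results$motif_overlap$p_value
  }
  if (!is.null(results$mutation)) out$delta_mut_hat <- results$mutation$delta_hat
  if (!is.null(results$core_linker)) {
    out$core_linker_p <- results$core_linker$test$p_value
  }
  if (!is.null(results$cancer_vs_healthy)) {
    out$cancer_vs_healthy_p <- results$cancer_vs_healthy$p_value
  }
  out
}
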