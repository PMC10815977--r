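# One quantile-analysis run on a planted (or null) cohort of 12 cancer
# subjects at 1e5 fragments/sample: subject-specific cfChIP deciles, then the
# per-quantile short/motif/combined metrics and size-selection enrichment
# with Q1 normalisation and Friedman tests. The motif metrics use the planted
# active-motif set; recovery of the set itself is exercised separately via
# simulate_motif_pairs().
cohort_quantile_run <- function(seed, null = FALSE) {
  cfg <- if (null) {
    simulation_config(seed = seed, n_cancer = 12L, n_healthy = 0L,
                      w_slope = 0, motif_boost = 0)
  } else {
    simulation_config(seed = seed, n_cancer = 12L, n_healthy = 0L)
  }
  coh <- simulate_cohort(cfg)
  frags <- add_subject_ids(coh$fragments, coh$manifest)
  sq <- suppressWarnings(subject_quantiles(frags, coh$manifest, coh$panel))
  inp <- frags[grepl("_input$", frags$sample_id), , drop = FALSE]

  short <- quantile_metric(inp, sq$quantiles, "short_fraction")
  out <- list(friedman_short_p = friedman_quantile_test(short, "Q1")$p_value)
  q10_median <- function(m) {
    s <- normalize_to_reference(m, "Q1")$summary
    s$median[nrow(s)]
  }
  out$q10_short <- q10_median(short)
  if (null) return(out)

  set <- coh$truth$active_motifs
  motif <- quantile_metric(inp, sq$quantiles, "motif_fraction",
                           motif_set = set)
  comb <- quantile_metric(inp, sq$quantiles, "combined_fraction",
                          motif_set = set)
  ss_ids <- coh$manifest[coh$manifest$assay == "size_selected", ]
  ss_tables <- lapply(stats::setNames(ss_ids$sample_id, ss_ids$subject_id),
                      function(sid) {
    gene_enrichment_scores(frags[frags$sample_id == sid, , drop = FALSE],
                           coh$panel)
  })
  sizesel <- quantile_enrichment(ss_tables, sq$quantiles)

  out$q10_motif <- q10_median(motif)
  out$q10_combined <- q10_median(comb)
  out$q10_sizesel <- q10_median(sizesel)
  out$friedman_motif_p <- friedman_quantile_test(motif, "Q1")$p_value
  out$friedman_combined_p <- friedman_quantile_test(comb, "Q1")$p_value
  out$friedman_sizesel_p <- friedman_quantile_test(sizesel, "Q1")$p_value
  out
}
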