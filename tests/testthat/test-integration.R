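toy_quantiles <- function(subjects = c("S1", "S2", "S3"), n_genes = 6L,
                          n_q = 3L) {
  genes <- sprintf("G%02d", seq_len(n_genes))
  qlab <- paste0("Q", seq_len(n_q))
  dplyr::bind_rows(lapply(subjects, function(s) {
    tibble::tibble(subject_id = s, gene_id = genes,
                   quantile = factor(rep(qlab, each = n_genes / n_q),
                                     levels = qlab))
  }))
}

toy_fragments <- function(subject, gene, length, up = "AAA", down = "AAA") {
  f <- fragment_table(chrom = "chr1", start = 0L, end = as.integer(length),
                      sample_id = paste0(subject, "_input"),
                      motif_up = up, motif_down = down, gene_id = gene)
  f$subject_id <- subject
  f
}

test_that("quantile metrics apply the length and motif rules per cell", {
  q <- toy_quantiles(subjects = c("S1", "S2", "S3"), n_genes = 6L, n_q = 3L)
  set <- c("CCG", "GGC")
  frags <- dplyr::bind_rows(
    toy_fragments("S1", "G01", 140, up = "CCG", down = "AAA"), # short + motif
    toy_fragments("S1", "G01", 160, up = "CCG", down = "GGC"), # motif only
    toy_fragments("S1", "G01", 140, up = "AAA", down = "TTT"), # short only
    toy_fragments("S1", "G03", 140, up = "CCG", down = "CCG"),
    toy_fragments("S1", "G05", 170, up = "AAA", down = "AAA"),
    toy_fragments("S2", "G01", 120, up = "GGC", down = "GGC"),
    toy_fragments("S2", "G03", 200, up = "AAA", down = "AAA"),
    toy_fragments("S2", "G05", 100, up = "CCG", down = "AAA"),
    toy_fragments("S3", "G01", 149, up = "AAA", down = "GGC"),
    toy_fragments("S3", "G03", 151, up = "AAA", down = "AAA"),
    toy_fragments("S3", "G05", 150, up = "GGC", down = "AAA")
  )
  short <- quantile_metric(frags, q, "short_fraction")
  motif <- quantile_metric(frags, q, "motif_fraction", motif_set = set)
  comb <- quantile_metric(frags, q, "combined_fraction", motif_set = set)

  # S1 Q1 = gene G01/G02: lengths 140,160,140 -> short 2/3
  expect_equal(short["S1", "Q1"], 2 / 3)
  # any_end motif matches: rows 1,2 -> 2/3
  expect_equal(motif["S1", "Q1"], 2 / 3)
  # combined: only row 1 (140 & motif) -> 1/3; 160 bp match does not count
  expect_equal(comb["S1", "Q1"], 1 / 3)
  # strict cutoff: 150 bp is not short (S3 Q3), 149 bp is (S3 Q1)
  expect_equal(short["S3", "Q3"], 0)
  expect_equal(short["S3", "Q1"], 1)
  # intersection bound holds cell-wise
  expect_true(all(comb <= pmin(short, motif) + 1e-12, na.rm = TRUE))

  both <- quantile_metric(frags, q, "motif_fraction", motif_set = set,
                          match_rule = "both_ends")
  expect_equal(both["S1", "Q1"], 1 / 3) # only the (CCG,GGC) fragment
  expect_error(quantile_metric(frags, q, "motif_fraction"), "motif_set")
})

test_that("combined fraction never exceeds its components on simulated data", {
  coh <- small_cohort()
  frags <- add_subject_ids(coh$fragments, coh$manifest)
  sq <- subject_quantiles(frags, coh$manifest, coh$panel)
  inp <- frags[grepl("_input$", frags$sample_id) & !is.na(frags$subject_id), ]
  set <- coh$truth$active_motifs
  short <- quantile_metric(inp, sq$quantiles, "short_fraction")
  motif <- quantile_metric(inp, sq$quantiles, "motif_fraction", motif_set = set)
  comb <- quantile_metric(inp, sq$quantiles, "combined_fraction",
                          motif_set = set)
  expect_true(all(comb <= pmin(short, motif) + 1e-12, na.rm = TRUE))
})

test_that("reference normalisation gives zero at the reference and known medians", {
  m <- rbind(S1 = c(Q1 = 0.10, Q2 = 0.11, Q3 = 0.12),
             S2 = c(0.20, 0.22, 0.24),
             S3 = c(0.10, 0.12, 0.13))
  norm <- normalize_to_reference(m, "Q1")
  expect_true(all(norm$normalized[, "Q1"] == 0))
  expect_equal(unname(norm$normalized["S1", "Q3"]), 20, tolerance = 1e-9)
  # median/IQR across subjects with type-7 quartiles: {10,20,30} -> 20 [15,25]
  m2 <- rbind(S1 = c(Q1 = 0.10, Q2 = 0.11),
              S2 = c(0.10, 0.12),
              S3 = c(0.10, 0.13))
  s <- normalize_to_reference(m2, "Q1")$summary
  expect_equal(s$median[s$group == "Q2"], 20)
  expect_equal(s$iqr_lo[s$group == "Q2"], 15)
  expect_equal(s$iqr_hi[s$group == "Q2"], 25)

  flat <- rbind(S1 = c(Q1 = 0.2, Q2 = 0.2), S2 = c(0.3, 0.3))
  expect_true(all(normalize_to_reference(flat, "Q1")$normalized == 0))

  mz <- rbind(S1 = c(Q1 = 0, Q2 = 0.1), S2 = c(Q1 = 0.1, Q2 = 0.2))
  nz <- normalize_to_reference(mz, "Q1")
  expect_equal(nz$excluded_subjects, "S1")
  expect_equal(nz$summary$n[2], 1L)

  ratio <- normalize_to_reference(m, "Q1", method = "ratio")
  expect_equal(unname(ratio$normalized["S1", "Q3"]), 120, tolerance = 1e-9)
})

test_that("Friedman test matches the rank formula and gates the post-hoc", {
  # perfect within-subject ordering, n = k = 3: rank sums (3, 6, 9),
  # statistic 12/(3*3*4) * (9 + 36 + 81) - 3*3*4 = 6
  m <- rbind(S1 = c(Q1 = 1, Q2 = 2, Q3 = 3),
             S2 = c(1, 2, 3), S3 = c(1, 2, 3))
  ft <- friedman_quantile_test(m, "Q1", alpha = 1)
  expect_equal(ft$statistic, 6)
  expect_equal(ft$df, 2)

  # identical columns: zero statistic, p = 1, no post-hoc at alpha 0.05
  flat <- rbind(S1 = c(Q1 = 2, Q2 = 2, Q3 = 2), S2 = c(5, 5, 5),
                S3 = c(1, 1, 1))
  ff <- friedman_quantile_test(flat, "Q1")
  expect_equal(ff$statistic, 0)
  expect_equal(ff$p_value, 1)
  expect_null(ff$posthoc)

  # brute-force oracle on random continuous matrices (no ties a.s.)
  set.seed(47)
  for (i in 1:1000) {
    r <- matrix(runif(20), 5, 4,
                dimnames = list(paste0("S", 1:5), paste0("Q", 1:4)))
    expect_equal(unname(stats::friedman.test(r)$statistic), friedman_brute(r),
                 tolerance = 1e-10)
  }

  # a strong planted trend triggers Q2..Q10-style post-hoc tests
  set.seed(48)
  trend <- matrix(rep(1:4, each = 6), 6, 4) + rnorm(24, 0, 0.1)
  dimnames(trend) <- list(paste0("S", 1:6), paste0("Q", 1:4))
  ft2 <- friedman_quantile_test(trend, "Q1")
  expect_lt(ft2$p_value, 0.05)
  expect_equal(nrow(ft2$posthoc), 3L)
  expect_true(all(ft2$posthoc$p_value < 0.05))

  expect_error(friedman_quantile_test(m[1:2, ]), "at least 3")
})

test_that("group comparisons guard degenerate inputs and match known values", {
  same <- group_comparison_tests(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)

  const_shift <- group_comparison_tests(c(2, 3, 4), c(1, 2, 3), paired = TRUE)
  expect_true(const_shift$degenerate)
  expect_true(is.na(const_shift$p_value))

  flat2 <- group_comparison_tests(c(1, 1, 1), c(1, 1), paired = FALSE)
  expect_true(flat2$degenerate)
  expect_equal(flat2$p_value, 1)

  # classic paired example: R's sleep data, t = -4.0621, p = 0.002833
  with(stats::setNames(split(sleep$extra, sleep$group), c("g1", "g2")), {
    res <- group_comparison_tests(g1, g2, paired = TRUE)
    expect_equal(res$statistic, -4.0621, tolerance = 1e-4)
    expect_equal(res$p_value, 0.002833, tolerance = 1e-4)
  })

  # Welch unpaired agrees with stats::t.test
  set.seed(50)
  a <- rnorm(10)
  b <- rnorm(12, 1)
  res <- group_comparison_tests(a, b)
  ref <- stats::t.test(a, b)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
})
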