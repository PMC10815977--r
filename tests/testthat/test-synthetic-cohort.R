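test_that("the same seed reproduces the cohort exactly", {
  cfg <- simulation_config(seed = 77L, n_cancer = 2L, n_healthy = 1L,
                           fragments_per_sample = 5000L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$fragments, b$fragments)
  expect_identical(a$track, b$track)
  expect_identical(as.character(a$reference), as.character(b$reference))
  c <- simulate_cohort(simulation_config(seed = 78L, n_cancer = 2L,
                                         n_healthy = 1L,
                                         fragments_per_sample = 5000L))
  expect_false(identical(a$fragments, c$fragments))
})

test_that("config validation rejects broken probability models", {
  bad <- stats::setNames(rep(1 / 60, 64), all_motifs())
  expect_error(simulation_config(motif_baseline = bad), "sum to 1")
  expect_error(simulation_config(maf = 1.5), "maf")
  expect_error(simulation_config(activity = rep(2, 197)), "activity")
  expect_error(simulation_config(n_genes = 5, activity = rep(0.5, 4)),
               "activity")
})

test_that("size-selected samples are exactly the in-window input fragments", {
  coh <- small_cohort()
  w <- coh$truth$config$sizesel_window
  ss <- coh$fragments[coh$fragments$sample_id == "C02_sizesel", ]
  expect_true(all(ss$length >= w[1] & ss$length <= w[2]))
  inp <- coh$fragments[coh$fragments$sample_id == "C02_input", ]
  inw <- inp[inp$length >= w[1] & inp$length <= w[2], ]
  expect_equal(nrow(ss), nrow(inw))
  expect_equal(ss$start, inw$start)
})

test_that("manifest structure matches the cohort design", {
  coh <- small_cohort()
  man <- coh$manifest
  expect_equal(sum(man$assay == "input"), 7L)       # 5 cancer + 2 healthy
  expect_equal(sum(man$assay == "cfchip"), 5L)      # cancer only
  expect_equal(sum(man$assay == "size_selected"), 5L)
  expect_false(anyDuplicated(man[, c("subject_id", "assay")]) > 0)
  expect_true(all(is.na(man$mutation_status[man$group == "healthy"])))
})

test_that("closed-form expected short fractions match the stated mixtures", {
  cfg <- simulation_config(seed = 1, n_genes = 4L,
                           activity = c(0, 0, 1, 1),
                           w0 = 0, w_slope = 0)
  em <- truth_expected_metrics(list(activity = stats::setNames(
    cfg$activity, sprintf("G%03d", 1:4)), config = cfg),
    continuity = FALSE, n_quantiles = 2)
  # short weight 0 -> Phi((150-167)/10)
  expect_equal(unique(em$per_gene$expected_short_fraction),
               stats::pnorm((150 - 167) / 10), tolerance = 1e-12)
  expect_equal(unique(round(em$per_gene$expected_short_fraction, 4)), 0.0446)

  cfg1 <- simulation_config(seed = 1, n_genes = 4L,
                            activity = c(0, 0, 1, 1),
                            w0 = 1, w_slope = 0)
  em1 <- truth_expected_metrics(list(activity = stats::setNames(
    cfg1$activity, sprintf("G%03d", 1:4)), config = cfg1),
    continuity = FALSE, n_quantiles = 2)
  # short weight 1 -> Phi((150-130)/15)
  expect_equal(unique(round(em1$per_gene$expected_short_fraction, 4)), 0.9088)

  # no boost -> active-motif end fraction equals the baseline set mass
  cfg0 <- simulation_config(seed = 1, motif_boost = 0)
  em0 <- truth_expected_metrics(list(activity = stats::setNames(
    runif(197), sprintf("G%03d", 1:197)), config = cfg0))
  expect_equal(unique(em0$per_gene$expected_motif_end_fraction), 8 / 64,
               tolerance = 1e-12)
})

test_that("empirical short fractions converge to the planted expectation", {
  cfg <- simulation_config(seed = 202L, n_cancer = 1L, n_healthy = 0L,
                           fragments_per_sample = 50000L, maf = 0)
  coh <- simulate_cohort(cfg)
  em <- truth_expected_metrics(coh)
  inp <- coh$fragments[coh$fragments$sample_id == "C01_input", ]
  # per-sample expectation: genes drawn uniformly (equal footprints)
  expected <- mean(em$per_gene$expected_short_fraction)
  observed <- short_fraction(inp)$fraction
  se <- sqrt(expected * (1 - expected) / nrow(inp))
  expect_lt(abs(observed - expected), 3 * se)

  # active-motif end fraction likewise
  p_end <- mean(em$per_gene$expected_motif_end_fraction)
  ends <- c(inp$motif_up, inp$motif_down)
  obs_end <- mean(ends %in% coh$truth$active_motifs)
  se_end <- sqrt(p_end * (1 - p_end) / length(ends))
  expect_lt(abs(obs_end - p_end), 3 * se_end)
})

test_that("cfChIP sampling is enriched for high-activity genes", {
  coh <- small_cohort()
  chip <- coh$fragments[grepl("_cfchip$", coh$fragments$sample_id), ]
  share <- table(factor(chip$gene_id, levels = coh$panel$gene_id))
  rho <- cor(as.numeric(share), coh$truth$activity[coh$panel$gene_id],
             method = "spearman")
  expect_gte(rho, 0.8)
})

test_that("mutant fragments recover the planted length shift", {
  cfg <- simulation_config(seed = 303L, n_cancer = 1L, n_healthy = 0L,
                           fragments_per_sample = 100000L)
  coh <- simulate_cohort(cfg)
  inp <- coh$fragments[coh$fragments$sample_id == "C01_input", ]
  mut <- inp[inp$allele == "MUT", ]
  wt <- inp[inp$allele == "WT", ]
  expect_gt(nrow(mut), 0.05 * nrow(inp))
  delta_hat <- mean(mut$length) - mean(wt$length)
  expect_lt(abs(delta_hat - cfg$delta_mut), 2)
})

test_that("simulated motif pairs live on the 64-simplex", {
  pairs <- simulate_motif_pairs(n_pairs = 5, seed = 2)
  expect_equal(unname(rowSums(pairs$a)), rep(1, 5), tolerance = 1e-9)
  expect_equal(unname(rowSums(pairs$b)), rep(1, 5), tolerance = 1e-9)
  expect_true(all(pairs$a >= 0) && all(pairs$b >= 0))
})

test_that("motif injection makes reference annotation reproduce the table", {
  ref <- tiny_reference(seed = 31L, len = 2000L)
  starts <- seq(10L, 1800L, by = 120L)
  set.seed(19)
  frags <- fragment_table(
    chrom = "chr1", start = starts, end = starts + 100L,
    motif_up = sample(all_motifs(), length(starts), replace = TRUE),
    motif_down = sample(all_motifs(), length(starts), replace = TRUE)
  )
  ref2 <- inject_end_motifs(ref, frags)
  ann <- annotate_motifs(fragment_table(chrom = "chr1", start = frags$start,
                                        end = frags$end), ref2)
  expect_equal(ann$motif_up, frags$motif_up)
  expect_equal(ann$motif_down, frags$motif_down)

  clash <- fragment_table(chrom = "chr1", start = c(0L, 1L), end = c(60L, 61L),
                          motif_up = c("AAA", "CCC"),
                          motif_down = c("GGG", "TTT"))
  expect_error(inject_end_motifs(ref, clash), "collide")
})

test_that("cohorts round-trip through the on-disk formats", {
  cfg <- simulation_config(seed = 88L, n_cancer = 2L, n_healthy = 1L,
                           fragments_per_sample = 2000L)
  coh <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  frags <- read_fragments(file.path(dir, "fragments.tsv"))
  expect_equal(nrow(frags), nrow(coh$fragments))
  expect_equal(frags$motif_up, coh$fragments$motif_up)
  panel <- read_gene_panel(file.path(dir, "panel.bed"))
  expect_equal(as.data.frame(panel), as.data.frame(coh$panel))
  track <- read_nucleosome_track(file.path(dir, "dyads.bed"))
  expect_equal(as.data.frame(track), as.data.frame(coh$track))
  ref <- Biostrings::readDNAStringSet(file.path(dir, "reference.fa"))
  expect_equal(as.character(ref[[1]]), as.character(coh$reference[[1]]))
})
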