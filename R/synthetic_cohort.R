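#' Simulation configuration
#'
#' Parameters of the synthetic cfDNA cohort generator. The generator plants
#' the statistical structure the downstream analysis assumes: a per-gene
#' latent activity in [0, 1]; a fragment-length mixture with a mononucleosomal
#' mode and an activity-dependent sub-150 bp component; an activity-dependent
#' GC-rich end-motif boost; mutation spike-ins with shorter mutant fragments;
#' a phased nucleosome dyad track with activity-dependent cleavage bias;
#' cfChIP sampling weighted by activity; and an in-vitro-like 95-152 bp
#' size-selection window.
#'
#' Fragment lengths are drawn as `N(mu, sd)` from the mixture (short-component
#' weight `w(g) = w0 + w_slope * activity(g)`, truncated to [0, 1]), rounded
#' to integer bp and truncated to `length_range`. Mutant fragments (planted at
#' `maf` in cancer samples) have both component means shifted by `delta_mut`.
#' End motifs are drawn from a baseline 64-simplex with the mass of
#' `active_motifs` multiplied by `1 + motif_boost * activity(g)` (then
#' renormalised). Fragment ends are placed by rejection sampling with
#' acceptance weight `1 + core_boost * activity(g)` for ends within 75 bp of
#' the nearest dyad (negative `core_boost` gives linker-biased cleavage).
#'
#' @param seed Master integer seed; all randomness flows from it through
#'   named substreams.
#' @param n_cancer,n_healthy Subject counts (defaults 12 and 7).
#' @param n_genes Panel size (default 197).
#' @param gene_length_bp Per-gene targeted footprint (default 1005 bp, giving
#'   a ~198 kb panel at 197 genes).
#' @param gene_gap_bp Spacing between genes on the synthetic chromosome.
#' @param fragments_per_sample Fragments drawn per sample (default 1e5).
#' @param activity Optional per-gene activity vector in [0, 1]; drawn
#'   uniformly from the seed when `NULL`.
#' @param mu_mono,sd_mono Mononucleosomal length component (167, 10).
#' @param mu_short,sd_short Short length component (130, 15).
#' @param w0,w_slope Short-component weight intercept and activity slope.
#' @param motif_baseline Baseline motif simplex (default uniform over 64).
#' @param active_motifs The boosted "active" motif set (default the eight
#'   G/C-only 3-mers).
#' @param motif_boost Multiplicative boost at activity 1 (default 0.15).
#' @param maf Planted mutant allele fraction in cancer samples (default 0.1).
#' @param delta_mut Mutant length shift in bp (default -20).
#' @param dyad_spacing,dyad_jitter_sd Nucleosome grid spacing and jitter.
#' @param core_boost Activity-scaled cleavage acceptance bias toward the
#'   nucleosome core (default 1; negative values bias toward the linker).
#' @param cfchip_eps Floor added to activity for cfChIP gene sampling weights.
#' @param sizesel_window In-silico analogue of the in-vitro size-selection
#'   window, bp (default c(95, 152)).
#' @param length_range Fragment length truncation range, bp (default
#'   c(50, 400), the in-silico bin domain).
#' @return A `simulation_config` list (validated).
#' @export
simulation_config <- function(seed = 1L, n_cancer = 12L, n_healthy = 7L,
                              n_genes = 197L, gene_length_bp = 1005L,
                              gene_gap_bp = 500L,
                              fragments_per_sample = 100000L,
                              activity = NULL,
                              mu_mono = 167, sd_mono = 10,
                              mu_short = 130, sd_short = 15,
                              w0 = 0.15, w_slope = 0.05,
                              motif_baseline = NULL,
                              active_motifs = NULL,
                              motif_boost = 0.15,
                              maf = 0.1, delta_mut = -20,
                              dyad_spacing = 190L, dyad_jitter_sd = 5,
                              core_boost = 1,
                              cfchip_eps = 0.02,
                              sizesel_window = c(95L, 152L),
                              length_range = c(50L, 400L)) {
  universe <- all_motifs()
  if (is.null(motif_baseline)) {
    motif_baseline <- stats::setNames(rep(1 / 64, 64), universe)
  }
  if (is.null(active_motifs)) {
    gc_only <- universe[!grepl("[AT]", universe)]
    active_motifs <- gc_only
  }
  cfg <- list(
    seed = as.integer(seed), n_cancer = as.integer(n_cancer),
    n_healthy = as.integer(n_healthy), n_genes = as.integer(n_genes),
    gene_length_bp = as.integer(gene_length_bp),
    gene_gap_bp = as.integer(gene_gap_bp),
    fragments_per_sample = as.integer(fragments_per_sample),
    activity = activity,
    mu_mono = mu_mono, sd_mono = sd_mono,
    mu_short = mu_short, sd_short = sd_short,
    w0 = w0, w_slope = w_slope,
    motif_baseline = motif_baseline, active_motifs = active_motifs,
    motif_boost = motif_boost, maf = maf, delta_mut = delta_mut,
    dyad_spacing = as.integer(dyad_spacing), dyad_jitter_sd = dyad_jitter_sd,
    core_boost = core_boost, cfchip_eps = cfchip_eps,
    sizesel_window = as.integer(sizesel_window),
    length_range = as.integer(length_range)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  if (abs(sum(cfg$motif_baseline) - 1) > 1e-9) {
    stop("motif_baseline must sum to 1")
  }
  if (any(cfg$motif_baseline < 0)) stop("motif_baseline must be non-negative")
  if (!all(cfg$active_motifs %in% all_motifs())) {
    stop("active_motifs must be 3-mers over ACGT")
  }
  if (cfg$n_cancer < 0 || cfg$n_healthy < 0 || cfg$fragments_per_sample < 1) {
    stop("subject and fragment counts must be non-negative")
  }
  if (cfg$maf < 0 || cfg$maf > 1) stop("maf must be in [0, 1]")
  if (!is.null(cfg$activity) &&
      (length(cfg$activity) != cfg$n_genes ||
       any(cfg$activity < 0 | cfg$activity > 1))) {
    stop("activity must be length n_genes with values in [0, 1]")
  }
  invisible(cfg)
}

substream_seeds <- function(seed, streams) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  stats::setNames(sample.int(2147483646L, length(streams)), streams)
}

#' Simulate a synthetic cfDNA cohort
#'
#' Generates, from a single seed, a gene panel, a phased nucleosome dyad
#' track, an i.i.d.-uniform reference sequence, a sample manifest and
#' fragment-level records: an input cfDNA sample per subject; for each cancer
#' subject additionally a cfChIP sample (genes drawn proportional to planted
#' activity) and a size-selected sample (that subject's input fragments
#' restricted to the size-selection window). Mutant fragments are planted at
#' the configured MAF in cancer samples with lengths shifted by `delta_mut`.
#' The fragment table's motif columns are drawn from the motif model and are
#' authoritative; the emitted reference exercises coordinate and FASTA
#' plumbing (see [inject_end_motifs()] for reconciling the two on small
#' layouts).
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_cohort` list: `fragments` (all samples, one tibble),
#'   `panel`, `track`, `manifest`, `reference` (DNAStringSet), `truth`
#'   (planted activity, active motif set, MAF, delta_mut, config echo).
#' @export
simulate_cohort <- function(config) {
  cfg <- config
  validate_simulation_config(cfg)
  seeds <- substream_seeds(cfg$seed, c("activity", "reference", "track", "samples"))

  pitch <- cfg$gene_length_bp + cfg$gene_gap_bp
  gene_start <- cfg$gene_gap_bp + (seq_len(cfg$n_genes) - 1L) * pitch
  panel <- tibble(
    gene_id = sprintf("G%03d", seq_len(cfg$n_genes)),
    chrom = "chr1",
    start = gene_start,
    end = gene_start + cfg$gene_length_bp,
    footprint_bp = cfg$gene_length_bp
  )

  set.seed(seeds[["activity"]])
  activity <- if (is.null(cfg$activity)) stats::runif(cfg$n_genes) else cfg$activity

  chrom_len <- cfg$gene_gap_bp + cfg$n_genes * pitch
  set.seed(seeds[["reference"]])
  reference <- Biostrings::DNAStringSet(paste(
    sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE), collapse = ""))
  names(reference) <- "chr1"

  set.seed(seeds[["track"]])
  offs <- seq(cfg$dyad_spacing %/% 2L, cfg$gene_length_bp - 1L,
              by = cfg$dyad_spacing)
  dyads <- rep(gene_start, each = length(offs)) + rep(offs, cfg$n_genes)
  dyads <- dyads + as.integer(round(stats::rnorm(length(dyads), 0, cfg$dyad_jitter_sd)))
  dyads <- pmin(pmax(dyads, rep(gene_start, each = length(offs))),
                rep(gene_start + cfg$gene_length_bp - 1L, each = length(offs)))
  track <- nucleosome_track("chr1", dyads)

  subjects <- c(
    if (cfg$n_cancer > 0) sprintf("C%02d", seq_len(cfg$n_cancer)),
    if (cfg$n_healthy > 0) sprintf("H%02d", seq_len(cfg$n_healthy))
  )
  groups <- c(rep("cancer", cfg$n_cancer), rep("healthy", cfg$n_healthy))

  input_weights <- panel$footprint_bp / sum(panel$footprint_bp)
  cfchip_weights <- (activity + cfg$cfchip_eps) * input_weights
  cfchip_weights <- cfchip_weights / sum(cfchip_weights)

  frag_list <- list()
  manifest_rows <- list()
  sample_seed <- seeds[["samples"]]
  for (i in seq_along(subjects)) {
    subj <- subjects[i]
    cancer <- groups[i] == "cancer"
    maf <- if (cancer) cfg$maf else 0
    sid_in <- paste0(subj, "_input")
    set.seed((sample_seed + i * 131L) %% 2147483647L)
    inp <- simulate_sample(cfg, activity, panel, track, input_weights,
                           n = cfg$fragments_per_sample, sid = sid_in, maf = maf)
    frag_list[[sid_in]] <- inp
    manifest_rows[[sid_in]] <- tibble(
      sample_id = sid_in, subject_id = subj, group = groups[i], assay = "input",
      mutation_status = if (cancer) ifelse(maf > 0, "positive", "negative")
                        else NA_character_)
    if (cancer) {
      sid_ch <- paste0(subj, "_cfchip")
      set.seed((sample_seed + i * 131L + 7L) %% 2147483647L)
      chip <- simulate_sample(cfg, activity, panel, track, cfchip_weights,
                              n = cfg$fragments_per_sample, sid = sid_ch,
                              maf = maf)
      frag_list[[sid_ch]] <- chip
      manifest_rows[[sid_ch]] <- tibble(
        sample_id = sid_ch, subject_id = subj, group = "cancer",
        assay = "cfchip",
        mutation_status = ifelse(maf > 0, "positive", "negative"))

      sid_ss <- paste0(subj, "_sizesel")
      ss <- inp[inp$length >= cfg$sizesel_window[1L] &
                inp$length <= cfg$sizesel_window[2L], , drop = FALSE]
      ss$sample_id <- sid_ss
      frag_list[[sid_ss]] <- ss
      manifest_rows[[sid_ss]] <- tibble(
        sample_id = sid_ss, subject_id = subj, group = "cancer",
        assay = "size_selected",
        mutation_status = ifelse(maf > 0, "positive", "negative"))
    }
  }

  structure(list(
    fragments = dplyr::bind_rows(frag_list),
    panel = panel,
    track = track,
    manifest = dplyr::bind_rows(manifest_rows),
    reference = reference,
    truth = list(
      activity = stats::setNames(activity, panel$gene_id),
      active_motifs = cfg$active_motifs,
      maf = cfg$maf, delta_mut = cfg$delta_mut,
      config = cfg
    )
  ), class = "synthetic_cohort")
}

# inverse-CDF categorical sampler, O(n log k)
sample_categorical <- function(n, prob) {
  cums <- cumsum(prob) / sum(prob)
  findInterval(stats::runif(n), cums) + 1L
}

# draw one sample's fragments (gene, allele, length, placement, motifs)
simulate_sample <- function(cfg, activity, panel, track, gene_weights, n, sid,
                            maf) {
  g <- sample_categorical(n, gene_weights)
  a <- activity[g]
  mut <- stats::runif(n) < maf
  w <- pmin(pmax(cfg$w0 + cfg$w_slope * a, 0), 1)
  is_short <- stats::runif(n) < w
  mu <- cfg$mu_mono + is_short * (cfg$mu_short - cfg$mu_mono) +
    mut * cfg$delta_mut
  sdv <- cfg$sd_mono + is_short * (cfg$sd_short - cfg$sd_mono)
  len <- as.integer(round(stats::rnorm(n, mu, sdv)))
  len <- pmin(pmax(len, cfg$length_range[1L]), cfg$length_range[2L])

  start <- place_fragments(cfg, panel, track, g, a, len)

  motif_up <- draw_motifs(cfg, a)
  motif_down <- draw_motifs(cfg, a)

  fragment_table(
    chrom = "chr1", start = start, end = start + len,
    strand = sample(c("+", "-"), n, replace = TRUE),
    sample_id = sid,
    motif_up = motif_up, motif_down = motif_down,
    allele = if (maf > 0) ifelse(mut, "MUT", "WT") else NA_character_,
    gene_id = panel$gene_id[g]
  )
}

# rejection-sample fragment starts inside each gene with a cleavage-bias
# acceptance weight per end: 1 + core_boost * activity within 75 bp of the
# nearest dyad, 1 otherwise
place_fragments <- function(cfg, panel, track, g, a, len, max_rounds = 30L) {
  n <- length(g)
  gs <- panel$start[g]
  span <- cfg$gene_length_bp - len + 1L
  pos <- sort(track$pos)
  end_weight <- function(x, act) {
    i <- findInterval(x, pos)
    lo <- pmax(i, 1L)
    hi <- pmin(i + 1L, length(pos))
    d <- pmin(abs(x - pos[lo]), abs(x - pos[hi]))
    1 + (d <= 75L) * cfg$core_boost * act
  }
  start <- integer(n)
  todo <- seq_len(n)
  wmax <- pmax(1, 1 + cfg$core_boost * a)^2
  for (round in seq_len(max_rounds)) {
    if (length(todo) == 0L) break
    cand <- gs[todo] + as.integer(floor(stats::runif(length(todo)) * span[todo]))
    wt <- end_weight(cand, a[todo]) * end_weight(cand + len[todo], a[todo])
    acc <- stats::runif(length(todo)) < wt / wmax[todo]
    start[todo[acc]] <- cand[acc]
    todo <- todo[!acc]
  }
  if (length(todo) > 0L) { # residual: accept unconditionally (bias negligible)
    start[todo] <- gs[todo] +
      as.integer(floor(stats::runif(length(todo)) * span[todo]))
  }
  start
}

# motif draw for one end of every fragment: two-stratum sampling (active set
# vs rest), exact for any baseline simplex under the multiplicative boost
draw_motifs <- function(cfg, a) {
  universe <- all_motifs()
  active <- universe %in% cfg$active_motifs
  mass_active <- sum(cfg$motif_baseline[active])
  p_active <- mass_active * (1 + cfg$motif_boost * a) /
    (1 + mass_active * cfg$motif_boost * a)
  in_active <- stats::runif(length(a)) < p_active
  out <- character(length(a))
  n_act <- sum(in_active)
  if (n_act > 0L) {
    out[in_active] <- universe[active][
      sample_categorical(n_act, cfg$motif_baseline[active])]
  }
  if (n_act < length(a)) {
    out[!in_active] <- universe[!active][
      sample_categorical(length(a) - n_act, cfg$motif_baseline[!active])]
  }
  out
}

#' Closed-form expected metrics for a planted cohort
#'
#' Expectations under the generative mixture, used as oracle targets in
#' recovery tests. The expected short fraction of a gene with activity `a` is
#' the mixture-weighted normal CDF at the cutoff,
#' `w Phi((c* - mu_short)/sd_short) + (1 - w) Phi((c* - mu_mono)/sd_mono)`
#' with `w = w0 + w_slope a`. Because generated lengths are rounded to
#' integer bp, the exact cutoff for the strict `length < c` rule is
#' `c* = c - 0.5` (`continuity = TRUE`, the default); `continuity = FALSE`
#' evaluates the plain CDF at `c`. Expected active-motif end fraction is the
#' boosted active-set mass; the fragment-level any-end fraction is
#' `1 - (1 - p)^2` and the expected combined fraction is the product of the
#' short and any-end fractions (lengths and motifs are independent given the
#' gene).
#'
#' @param truth `truth` element of a [simulate_cohort()] result (or a whole
#'   `synthetic_cohort`).
#' @param cutoff Short-fragment cutoff (default 150).
#' @param n_quantiles Number of activity quantiles (default 10).
#' @param continuity Apply the half-integer rounding correction (default
#'   `TRUE`).
#' @return List with `per_gene` (tibble: gene_id, activity, quantile,
#'   expected_short_fraction, expected_motif_end_fraction,
#'   expected_motif_fragment_fraction, expected_combined_fraction) and
#'   `per_quantile` (tibble of quantile means).
#' @export
truth_expected_metrics <- function(truth, cutoff = 150, n_quantiles = 10,
                                   continuity = TRUE) {
  if (inherits(truth, "synthetic_cohort")) truth <- truth$truth
  cfg <- truth$config
  a <- truth$activity
  cstar <- if (continuity) cutoff - 0.5 else cutoff
  w <- pmin(pmax(cfg$w0 + cfg$w_slope * a, 0), 1)
  sf <- w * stats::pnorm(cstar, cfg$mu_short, cfg$sd_short) +
    (1 - w) * stats::pnorm(cstar, cfg$mu_mono, cfg$sd_mono)
  universe <- all_motifs()
  active <- universe %in% cfg$active_motifs
  mass_active <- sum(cfg$motif_baseline[active])
  p_end <- mass_active * (1 + cfg$motif_boost * a) /
    (1 + mass_active * cfg$motif_boost * a)
  p_frag <- 1 - (1 - p_end)^2
  per_gene <- tibble(
    gene_id = names(a), activity = unname(a),
    expected_short_fraction = unname(sf),
    expected_motif_end_fraction = unname(p_end),
    expected_motif_fragment_fraction = unname(p_frag),
    expected_combined_fraction = unname(sf * p_frag)
  )
  ranked <- tibble(gene_id = names(a), score = unname(a))
  ranked <- assign_quantiles(
    gene_enrichment_scores_like(ranked), n_quantiles = n_quantiles)
  per_gene$quantile <- ranked$quantile[match(per_gene$gene_id, ranked$gene_id)]
  per_quantile <- per_gene %>%
    group_by(.data$quantile) %>%
    summarise(
      expected_short_fraction = mean(.data$expected_short_fraction),
      expected_motif_end_fraction = mean(.data$expected_motif_end_fraction),
      expected_motif_fragment_fraction = mean(.data$expected_motif_fragment_fraction),
      expected_combined_fraction = mean(.data$expected_combined_fraction),
      .groups = "drop")
  list(per_gene = per_gene, per_quantile = per_quantile)
}

# minimal enrichment-like table from a plain score vector (internal)
gene_enrichment_scores_like <- function(df) {
  ord <- order(df$score, df$gene_id)
  rank <- integer(nrow(df))
  rank[ord] <- seq_len(nrow(df))
  tibble(gene_id = df$gene_id, read_count = NA_integer_,
         score = df$score, rank = rank)
}

#' Simulate paired motif-frequency vectors with planted shifts
#'
#' Direct generator for differential-FEM recovery tests: `n_pairs` paired
#' samples whose group-B vectors have `shift` added to a designated motif
#' subset before renormalisation, with i.i.d. Gaussian per-motif noise in
#' both groups. Because every vector is renormalised to the 64-simplex, the
#' unshifted motifs acquire a small systematic negative difference in B; they
#' are therefore not false positives in the shifted (B-enriched) direction.
#'
#' @param n_pairs Number of matched pairs (default 12).
#' @param shift_motifs Motifs to shift (default the first 10 of
#'   [all_motifs()]).
#' @param shift Added frequency before renormalisation (default 0.01).
#' @param noise_sd Per-motif, per-sample Gaussian noise sd (default 0.001).
#' @param baseline Baseline simplex (default uniform).
#' @param seed Integer seed.
#' @return List with matrices `a` and `b` (`n_pairs` x 64) and `shifted`.
#' @export
simulate_motif_pairs <- function(n_pairs = 12, shift_motifs = all_motifs()[1:10],
                                 shift = 0.01, noise_sd = 0.001,
                                 baseline = NULL, seed = 1L) {
  universe <- all_motifs()
  if (is.null(baseline)) baseline <- stats::setNames(rep(1 / 64, 64), universe)
  stopifnot(all(shift_motifs %in% universe))
  set.seed(seed)
  draw <- function(base) {
    m <- matrix(rep(base, each = n_pairs), n_pairs, 64) +
      stats::rnorm(n_pairs * 64, 0, noise_sd)
    m[m < 0] <- 0
    m <- m / rowSums(m)
    colnames(m) <- universe
    rownames(m) <- paste0("P", seq_len(n_pairs))
    m
  }
  shifted_base <- baseline
  shifted_base[shift_motifs] <- shifted_base[shift_motifs] + shift
  list(a = draw(baseline), b = draw(shifted_base), shifted = shift_motifs)
}

#' Inject fragment end motifs into a reference sequence
#'
#' Overwrites the terminal 3-mers of each fragment in the reference so that
#' [annotate_motifs()] reproduces the fragment table's motif columns exactly,
#' leaving the flanking reference unmodified. Only valid when no two
#' replacement windows collide (fragment termini must not overlap), which
#' restricts it to small, sparse layouts; it errors otherwise.
#'
#' @param reference Named [Biostrings::DNAStringSet].
#' @param fragments Fragment tibble with motif columns set.
#' @param revcomp_downstream Must match the convention used at annotation
#'   time (default `TRUE`).
#' @return The modified DNAStringSet.
#' @export
inject_end_motifs <- function(reference, fragments, revcomp_downstream = TRUE) {
  for (chr in unique(fragments$chrom)) {
    frag <- fragments[fragments$chrom == chr, , drop = FALSE]
    at <- IRanges::IRanges(
      start = c(frag$start + 1L, frag$end - 2L), width = 3L)
    if (!IRanges::isDisjoint(at)) {
      stop("fragment termini collide on ", chr, "; cannot inject motifs")
    }
    down <- if (revcomp_downstream) revcomp_3mer(frag$motif_down) else frag$motif_down
    value <- Biostrings::DNAStringSet(c(frag$motif_up, down))
    reference[[chr]] <- Biostrings::replaceAt(reference[[chr]], at, value)
  }
  reference
}

#' Write a synthetic cohort to disk
#'
#' Emits the fragment table TSV, panel BED, dyad-track BED, reference FASTA,
#' manifest TSV and a machine-readable key-value truth file.
#'
#' @param cohort A `synthetic_cohort`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_fragments(cohort$fragments, file.path(outdir, "fragments.tsv"))
  write_gene_panel(cohort$panel, file.path(outdir, "panel.bed"))
  write_nucleosome_track(cohort$track, file.path(outdir, "dyads.bed"))
  Biostrings::writeXStringSet(cohort$reference, file.path(outdir, "reference.fa"))
  utils::write.table(as.data.frame(cohort$manifest),
                     file.path(outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  kv <- c(
    paste0("maf\t", truth$maf),
    paste0("delta_mut\t", truth$delta_mut),
    paste0("active_motifs\t", paste(truth$active_motifs, collapse = ",")),
    paste0("activity.", names(truth$activity), "\t", truth$activity)
  )
  writeLines(kv, file.path(outdir, "truth.tsv"))
  invisible(outdir)
}
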