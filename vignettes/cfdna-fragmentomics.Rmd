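---
title: "Linking cfDNA fragmentation to gene activity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking cfDNA fragmentation to gene activity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cffrag)
```

## The scientific question

Plasma cell-free DNA (cfDNA) is released largely as nucleosome-protected
fragments with a mononucleosomal mode near 167 bp. Two fragmentomic features
carry information about the tissue and chromatin state of origin: the
fragment length distribution (actively transcribed, open chromatin yields
shorter fragments) and the 3-mer *fragment end motifs* (FEMs) left by the
nucleases that cleave chromatin. `cffrag` implements an integrated analysis
that ties both features to gene activity measured in the same plasma sample
by H3K36me3 cfChIP-seq (chromatin immunoprecipitation of histone-bound cfDNA,
enriching fragments from actively transcribed gene bodies), over a targeted
CAPP-seq panel of 197 genes (~198 kb).

The pipeline, mirroring the analysis stages of the study design it
implements:

1. **Fragment model** — BED-convention (0-based half-open) fragment records
   with two end motifs read 5'→3' *into* the fragment at each terminus;
   quality filters (length ≥ 1 bp, no N in a terminus); gene assignment by
   largest overlap.
2. **Gene activity** — per-gene cfChIP enrichment
   `score(g) = (reads_g/total) / (footprint_g/total footprint)`, per-subject
   deciles Q1 (least active) to Q10 (most active), and 15-gene high/low sets.
3. **Length analysis** — short-fragment fraction (strict `< 150` bp),
   in-silico size selection in 10 bp bins over [50, 400) with mutant/WT
   ratios normalised to the pool ratio, and a cutoff sweep correlating
   per-gene short fractions with enrichment scores.
4. **End motifs** — 64-component frequency vectors counting both ends,
   paired differential t-tests with Benjamini–Hochberg adjustment across
   exactly the 64 tests, motif-set definition at q < 0.05, GC content,
   upper-tail hypergeometric set-overlap tests, and UMAP embedding.
5. **Nucleosome footprint** — signed end-to-dyad distances for fragments
   overlapping a dyad, core (|d| ≤ 75 bp) vs linker (75 < |d| ≤ 95 bp) end
   classification and their ratio.
6. **Integration** — per-subject × per-quantile matrices of short, motif and
   combined (short **and** motif) fractions, percent change relative to Q1,
   Friedman rank ANOVA across quantiles with subjects as blocks, and
   conditional unadjusted paired t-tests of each quantile against Q1.

## Statistical conventions

* **"Short" is strict.** A fragment of exactly 150 bp is not short; the
  cutoff is a parameter everywhere it appears.
* **Quantile sizes.** `n` ranked genes in `k` quantiles gives sizes
  differing by at most one, with the larger groups at the top ranks: 197
  genes → Q1–Q3 of 19 and Q4–Q10 of 20. The placement of the remainder is a
  documented tie-break; it does not affect monotonicity analyses.
* **Normalisation is percent change**, `(value/Q1 − 1) × 100`, so the
  reference column is identically zero; a ratio mode is available. Group
  summaries use the median and type-7 (linear interpolation) quartiles.
* **Inference scheme.** Friedman's ANOVA gates the post-hoc paired t-tests
  (run only when p < 0.05) and those post-hoc tests are deliberately
  unadjusted; FDR control applies only to the 64 motif tests. Unpaired
  comparisons use the Welch form. Degenerate inputs (zero variance) are
  flagged, never silently converted to NaN: identical groups give p = 1 so
  BH stays well defined.
* **Motif orientation.** The downstream-end motif is the reverse complement
  of the plus-strand terminal 3-mer, i.e. both motifs read 5'→3' into the
  fragment — the prevailing convention in the cfDNA end-motif literature.
  `revcomp_downstream = FALSE` disables this for sensitivity analysis. A
  strand-symmetry test (reverse-complementing the genome and mirroring the
  coordinates swaps the two motifs of every fragment) pins the convention.
* **Bin edges.** Size-selection bins are left-closed right-open,
  [50,60) … [390,400). Bins with no WT fragments are reported as undefined
  rather than imputed; an optional +0.5 continuity correction exists but
  transparency is the default.
* **Overlap ties.** A fragment overlapping two genes goes to the larger
  overlap, lexicographic gene id on exact ties — fragments are never double
  counted.
* **Core boundary.** |d| = 75 bp belongs to the core. The linker is
  (75, 95] by absolute value; ends beyond 95 bp are counted but excluded
  from the core/linker ratio. Classification by |d| is equivalent to signed
  classification for these symmetric windows.

## The synthetic cohort generator

The study's plasma data are not public, so the package ships a generator
whose defaults *are* the study conditions: 12 cancer and 7 healthy subjects,
197 genes × 1005 bp (≈ 198 kb), 1e5 fragments per sample, and for each
cancer subject an input, a cfChIP (genes sampled proportional to activity)
and a size-selected sample (input restricted to the 95–152 bp window that
the in-vitro protocol sequences).

Planted structure, with defaults chosen once to sit at the magnitudes the
study reports rather than at convenient extremes:

* **Lengths**: mixture of N(167, 10) (mononucleosomal) and N(130, 15)
  (short), short weight `w(g) = 0.15 + 0.05·activity(g)`. This yields a Q10
  vs Q1 short-fraction increase of ≈ 20%, the scale of the reported effect.
  Lengths are rounded to integer bp and truncated to [50, 400], the
  in-silico bin domain.
* **Motifs**: uniform baseline over the 64 3-mers with the mass of the eight
  G/C-only motifs multiplied by `1 + 0.15·activity(g)` — a GC-rich,
  activity-linked end-motif signature giving a Q10 motif-fraction increase
  of ≈ 11%. Because lengths and motifs are independent given the gene, the
  combined (short ∧ motif) metric multiplies the two relative effects, which
  is exactly the "combination beats either alone" structure the integrated
  analysis is designed to detect.
* **Mutations**: each cancer-sample fragment is mutant with probability
  0.1 (the planted MAF), with both length-component means shifted by
  −20 bp.
* **Nucleosomes**: dyads on a 190 bp grid per gene with 5 bp Gaussian
  jitter; fragment ends are rejection-sampled with acceptance weight
  `1 + core_boost·activity` within 75 bp of the nearest dyad. The default
  `core_boost = 1` makes cleavage in active genes more core-concentrated
  (the direction of the core/linker contrast between high- and
  low-expression genes); a negative value produces linker-biased cleavage
  for profile analyses.
* **Determinism**: a single master seed feeds named substreams (activity,
  reference, track, per-sample draws), so identical seeds give bit-identical
  cohorts and individual stages are independently reproducible.

`truth_expected_metrics()` returns the closed-form expectations under this
model (mixture-weighted normal CDFs, boosted simplex masses). Because
generated lengths are rounded to integers, the exact expectation for the
strict `< c` rule evaluates the CDF at `c − 0.5`; `continuity = FALSE` gives
the plain CDF form for analytic reference.

What the generator deliberately does **not** emulate: sequencing error, GC
amplification bias, capture efficiency, subclonal structure, positional
mutation hotspots, or any coupling between fragment length and end motif
beyond their shared dependence on gene activity. Passing recovery tests on
these cohorts therefore demonstrates that the pipeline measures what it
claims under its own model assumptions — not that real plasma data will show
effects of the same size. In particular, the differential-motif contrast
between size-selected and unselected synthetic samples is weak by
construction (selection recruits motifs only through the activity link), so
the motif-set overlap analysis is exercised at the published set sizes
rather than re-derived from synthetic data.

## Design choices on genuinely open points

* **"NGS coverage of that particular gene"** in the enrichment formula is
  read as the gene's targeted footprint within the panel; footprints are an
  explicit panel column so alternative normalisations are one column away.
  An optional input-normalised score (cfChIP/input) is available but off by
  default.
* **Mutant/WT bin normalisation** uses the mutant/WT *ratio* of the pooled
  in-range sample; normalising to the allele fraction instead differs by a
  monotone transform and does not change enrichment directions.
* **Fragment-level motif membership** defaults to `any_end` (either
  terminus in the set); `both_ends` is available. The quantile-metric
  property runs use the planted active-motif set so that metric behaviour is
  tested separately from motif-set recovery, which has its own well-powered
  recovery test via `simulate_motif_pairs()`.
* **Raw frequencies** are tested (no variance-stabilising transform); with
  n = 12 pairs and multinomial noise at 2 × 1e5 ends this is the more
  conservative choice.
* **Embedding** hyperparameters (5 neighbours, min_dist 0.1) are fixed in
  the interface; no numerical acceptance is attached to the embedding.

## Problem sizes and runtime

Property tests run 20-seed batches of 12-subject cohorts at 1e5 fragments
per sample — large enough that per-cell binomial noise (~0.004 on a
fraction) sits well below the planted effects, small enough for a laptop
CPU. Oracle tests (hypergeometric enumeration, brute-force BH step-up,
all-pairs nearest dyad, rank-form Friedman statistic) run on deliberately
tiny instances where exhaustive computation is exact.

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 7)
cohort <- simulate_cohort(cfg)
results <- analyze_cohort(cohort, motif_set = cohort$truth$active_motifs)

# Q10 percent change vs Q1, median [IQR] across subjects
results$normalized$combined_fraction$summary

# Friedman gate + per-quantile paired t-tests
results$friedman$short_fraction

# hypergeometric overlap between two motif sets
motif_set_overlap(results$cfchip_motifs, results$sizesel_motifs)
```

## Known limitations

* Alignment input supports coordinate-sorted paired-end BAM semantics via
  Rsamtools; exotic flags (secondary/supplementary pairings) are not
  modelled — input is assumed position-deduplicated upstream.
* The generator's reference FASTA is i.i.d. uniform sequence; fragment motif
  columns are drawn from the motif model and are authoritative. At cohort
  depth, fragment termini collide, so the reference cannot encode every
  fragment's motifs; `inject_end_motifs()` reconciles the two on sparse
  layouts and is used to round-trip the annotation convention in tests.
* Healthy subjects receive input samples only (cfChIP yield failure is the
  in-study norm), so the quantile analyses run on the cancer arm; the
  `inactive`-group variant of `assign_quantiles()` supports external
  expression-defined groupings for validation-style analyses.
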