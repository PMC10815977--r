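# cffrag — cell-free DNA fragmentomics of gene activity

`cffrag` is an R package for analysing how plasma cell-free DNA (cfDNA)
fragmentation reflects gene activity. It is built for liquid-biopsy
researchers who have fragment-level cfDNA data (BED-like tables or
paired-end alignments) over a targeted gene panel, together with a measure
of per-gene activity from the same plasma — typically H3K36me3 cfChIP-seq
enrichment — and who want to ask: *do active genes shed shorter fragments,
with distinct fragment end motifs, cleaved differently around nucleosomes,
and does combining those signals sharpen the association?*

## What it computes

For a panel of genes with per-subject activity deciles Q1 (least active) …
Q10 (most active):

* **Gene activity**: per-gene cfChIP enrichment
  `score(g) = (reads_g / total reads) / (footprint_g / total footprint)`,
  per-subject deciles, and 15-gene high/low expression sets.
* **Fragment lengths**: short-fragment fractions (strict `< 150` bp),
  length densities, in-silico size selection in 10 bp bins over [50, 400)
  with per-bin mutant/WT ratios normalised to the pooled ratio, and
  cutoff-sweep Spearman correlations against enrichment.
* **Fragment end motifs (FEMs)**: 64-component 3-mer frequency vectors
  counting both fragment ends, paired differential t-tests with
  Benjamini–Hochberg FDR across the 64 motifs, motif sets at q < 0.05, GC
  content, upper-tail hypergeometric set-overlap tests
  (`P(X >= overlap)`), and UMAP embedding of samples.
* **Nucleosome footprint**: signed fragment-end distances to the nearest
  dyad, core (|d| ≤ 75 bp) vs linker (75 < |d| ≤ 95 bp) end counts and
  their ratio.
* **Integration**: per-subject × per-quantile matrices of short, motif and
  combined (short **and** motif) fragment fractions, percent change vs Q1,
  Friedman rank ANOVA across quantiles (subjects as blocks) gating
  unadjusted paired t-tests of each quantile against Q1.

A seed-deterministic synthetic cohort generator (`simulate_cohort()`)
plants all of these effects — an activity-dependent short-fragment mixture,
a GC-rich activity-linked motif boost, mutant spike-ins with shorter
fragments, a phased dyad track with activity-dependent cleavage bias and a
95–152 bp size-selection window — so the entire pipeline is testable
without access to patient data.

## Worked example

```r
library(cffrag)

cfg <- simulation_config(seed = 1)        # 12 cancer + 7 healthy subjects
cohort <- simulate_cohort(cfg)            # fragments, panel, dyads, manifest
results <- analyze_cohort(cohort, motif_set = cohort$truth$active_motifs)

results$normalized$combined_fraction$summary
#> # A tibble: 10 × 5
#>    group median iqr_lo iqr_hi     n
#>    <chr>  <dbl>  <dbl>  <dbl> <int>
#>  1 Q1      0      0      0       12
#>  2 Q2      6.11  -2.54   8.14    12
#>  ...
#> 10 Q10    31.1   27.4   33.7     12

results$friedman$short_fraction$p_value
#> [1] 4.682871e-18

motif_set_overlap(all_motifs()[1:24], all_motifs()[c(1:12, 30:32)])
#> $overlap
#> [1] 12
#> $p_value
#> [1] 0.0001801905
#> $size_a
#> [1] 24
#> $size_b
#> [1] 15
```

Reading: the median subject shows a **31.1%** increase in the fraction of
fragments that are both short (< 150 bp) and carry active-set end motifs in
the most active gene decile relative to the least active one — larger than
the short-fraction (18.1%) or motif-fraction (9.4%) increases alone; the
Friedman test confirms the monotone trend across deciles. The overlap call
shows that observing 12 shared motifs between a 24-motif and a 15-motif set
drawn from the 64-motif universe has upper-tail hypergeometric
p = 0.00018.

## Package layout

* `R/fragments.R` — fragment records, readers/writers, filters, motif
  annotation from a reference, gene assignment
* `R/synthetic_cohort.R` — cohort simulator and closed-form truth
* `R/length_analysis.R` — short fractions, densities, size-selection bins,
  cutoff sweep
* `R/end_motifs.R` — motif frequencies, differential tests, motif sets,
  overlap statistics, embedding
* `R/gene_enrichment.R` — enrichment scores, high/low sets, quantiles,
  cross-assay correlation
* `R/nucleosome_footprint.R` — dyad distances, core/linker fractions,
  profiles
* `R/integration_stats.R`, `R/pipeline.R` — quantile metrics,
  normalisation, Friedman scheme, orchestration

The methods vignette (`vignettes/cfdna-fragmentomics.Rmd`) documents the
model, the statistical conventions, the generator's assumptions and the
design decisions in detail.
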