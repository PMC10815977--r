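test_that("fragment tables round-trip through the TSV dialect bit-exactly", {
  frags <- fragment_table(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(100L, 250L, 0L), end = c(267L, 380L, 150L),
    strand = c("+", "-", "+"), sample_id = "S1",
    motif_up = c("ACG", NA, "TTT"), motif_down = c("GGC", NA, "AAA"),
    allele = c("WT", "MUT", NA), gene_id = c("G001", NA, "G002")
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fragments(frags, path)
  back <- read_fragments(path)
  expect_equal(as.data.frame(back), as.data.frame(frags))
})

test_that("bed-like reader handles headers, short rows, and bad input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend", "chr1\t10\t177", "chr1\t30\t60"), path)
  frags <- read_fragments(path, sample_id = "X")
  expect_equal(nrow(frags), 2L)
  expect_equal(frags$length, c(167L, 30L))
  expect_true(all(frags$sample_id == "X"))

  writeLines(c("chr1\t10\t177", "chr1\tten\t60"), path)
  expect_error(read_fragments(path), "line 2")

  writeLines(character(), path)
  expect_warning(empty <- read_fragments(path), "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("alignment input yields one fragment per properly paired template", {
  skip_if_not_installed("Rsamtools")
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:1000",
    # proper pair: fragment [99, 266) -> length 167
    "r1\t99\tchr1\t100\t60\t50M\t=\t317\t167\t*\t*",
    "r1\t147\tchr1\t317\t60\t50M\t=\t100\t-167\t*\t*",
    # unpaired read: skipped
    "r2\t0\tchr1\t500\t60\t50M\t*\t0\t0\t*\t*"
  ), sam)
  bam <- Rsamtools::asBam(sam, withr::local_tempfile(), overwrite = TRUE)
  frags <- suppressMessages(read_fragments(bam, format = "alignment",
                                           sample_id = "S1"))
  expect_equal(nrow(frags), 1L)
  expect_equal(frags$start, 99L)
  expect_equal(frags$end, 266L)
  expect_equal(frags$length, 167L)
})

test_that("filters drop zero-length fragments and N-containing termini", {
  frags <- fragment_table(
    chrom = "chr1", start = c(0L, 10L, 20L, 30L),
    end = c(0L, 110L, 187L, 130L),
    motif_up = c(NA, "ANG", "ACG", NA),
    motif_down = c(NA, "CCC", "TTT", NA)
  )
  out <- filter_fragments(frags)
  expect_equal(nrow(out$fragments), 2L)
  expect_equal(out$report$n[out$report$reason == "nonpositive_length"], 1L)
  expect_equal(out$report$n[out$report$reason == "n_in_terminus"], 1L)
  # survivors obey the motif/length contract
  surv <- out$fragments
  expect_true(all(surv$length == surv$end - surv$start & surv$length >= 1L))
  expect_true(all(is.na(surv$motif_up) | grepl("^[ACGT]{3}$", surv$motif_up)))

  clean <- filter_fragments(out$fragments)
  expect_identical(clean$fragments, out$fragments)
  expect_equal(sum(clean$report$n[clean$report$reason != "kept"]), 0L)
})

test_that("motif annotation reads 5'->3' into the fragment from both ends", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "AAACGTTT", chr2 = "ACGT"))
  frags <- fragment_table(chrom = c("chr1", "chr2"), start = c(0L, 0L),
                          end = c(8L, 4L))
  ann <- annotate_motifs(frags, ref)
  expect_equal(ann$motif_up, c("AAA", "ACG"))
  # downstream end: reverse complement of the plus-strand terminal 3-mer
  expect_equal(ann$motif_down, c("AAA", "ACG"))
  plus <- annotate_motifs(frags, ref, revcomp_downstream = FALSE)
  expect_equal(plus$motif_down, c("TTT", "CGT"))

  tiny <- fragment_table(chrom = "chr1", start = 2L, end = 4L)
  ann2 <- annotate_motifs(tiny, ref)
  expect_true(is.na(ann2$motif_up) && is.na(ann2$motif_down))
  expect_equal(attr(ann2, "n_too_short"), 1L)

  off <- fragment_table(chrom = "chr2", start = 1L, end = 9L)
  expect_error(annotate_motifs(off, ref), "outside")
})

test_that("motif pairs are strand-symmetric under genome reverse complement", {
  ref <- tiny_reference()
  len <- length(ref[[1L]])
  set.seed(11)
  start <- sample.int(len - 200L, 150L)
  frags <- fragment_table(chrom = "chr1", start = start,
                          end = start + sample(50:180, 150L, replace = TRUE))
  fwd <- annotate_motifs(frags, ref)
  rc <- Biostrings::DNAStringSet(Biostrings::reverseComplement(ref[[1L]]))
  names(rc) <- "chr1"
  mirrored <- fragment_table(chrom = "chr1", start = len - frags$end,
                             end = len - frags$start)
  rev <- annotate_motifs(mirrored, rc)
  # mirroring swaps the two ends but preserves each motif pair
  expect_setequal(paste(fwd$motif_up, fwd$motif_down),
                  paste(rev$motif_down, rev$motif_up))
  expect_equal(sort(paste(fwd$motif_up, fwd$motif_down)),
               sort(paste(rev$motif_down, rev$motif_up)))
})

test_that("gene assignment picks the largest overlap with stable tie-break", {
  panel <- tibble::tibble(
    gene_id = c("GA", "GB", "GC"), chrom = "chr1",
    start = c(100L, 290L, 600L), end = c(300L, 500L, 700L),
    footprint_bp = c(200L, 210L, 100L)
  )
  frags <- fragment_table(
    chrom = "chr1",
    start = c(150L, 900L, 250L, 240L),
    end = c(250L, 1000L, 450L, 340L)
  )
  out <- assign_genes(frags, panel)
  expect_equal(out$gene_id[1], "GA")          # fully inside GA
  expect_true(is.na(out$gene_id[2]))          # outside all genes
  expect_equal(out$gene_id[3], "GB")          # 50 bp in GA vs 160 bp in GB
  expect_equal(out$gene_id[4], "GA")          # 60/60 tie -> lexicographic
})

test_that("panel and dyad-track BED files round-trip", {
  panel <- tibble::tibble(gene_id = c("G1", "G2"), chrom = "chr1",
                          start = c(0L, 500L), end = c(200L, 900L),
                          footprint_bp = c(200L, 400L))
  pbed <- withr::local_tempfile(fileext = ".bed")
  write_gene_panel(panel, pbed)
  expect_equal(as.data.frame(read_gene_panel(pbed)), as.data.frame(panel))

  track <- nucleosome_track(c("chr1", "chr1", "chr2"), c(500L, 100L, 7L))
  tbed <- withr::local_tempfile(fileext = ".bed")
  write_nucleosome_track(track, tbed)
  expect_equal(as.data.frame(read_nucleosome_track(tbed)),
               as.data.frame(track))
  # sorted strictly increasing per chromosome
  expect_equal(track$pos[track$chrom == "chr1"], c(100L, 500L))
})
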