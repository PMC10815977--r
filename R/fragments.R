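#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% arrange group_by summarise mutate filter select left_join n
#' @importFrom rlang .data
NULL

FRAGMENT_COLUMNS <- c(
  "chrom", "start", "end", "strand", "sample_id",
  "motif_up", "motif_down", "allele", "gene_id"
)

#' Build a fragment table
#'
#' A fragment table is a tibble with one row per sequenced cfDNA fragment and
#' columns `chrom`, `start`, `end` (0-based half-open, BED convention),
#' `strand`, `sample_id`, `motif_up`, `motif_down` (3-mers read 5'->3' into the
#' fragment from each terminus, `NA` when unknown), `allele` (`"WT"`, `"MUT"`
#' or `NA`) and `gene_id` (`NA` when unassigned). A `length` column
#' (`end - start`) is always present and kept consistent.
#'
#' @param chrom Chromosome names.
#' @param start 0-based inclusive start positions.
#' @param end 0-based exclusive end positions.
#' @param strand `"+"` or `"-"` (recycled).
#' @param sample_id Sample identifier (recycled).
#' @param motif_up,motif_down Optional terminal 3-mers.
#' @param allele Optional `"WT"`/`"MUT"` labels.
#' @param gene_id Optional gene assignments.
#' @return A fragment tibble.
#' @export
fragment_table <- function(chrom, start, end, strand = "+", sample_id = "S1",
                           motif_up = NA_character_, motif_down = NA_character_,
                           allele = NA_character_, gene_id = NA_character_) {
  out <- tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    sample_id = as.character(sample_id),
    motif_up = as.character(motif_up),
    motif_down = as.character(motif_down),
    allele = as.character(allele),
    gene_id = as.character(gene_id)
  )
  out$length <- out$end - out$start
  out
}

empty_fragment_table <- function() {
  fragment_table(character(), integer(), integer(), character(), character(),
                 character(), character(), character(), character())
}

#' Read a fragment table
#'
#' Reads fragment-level records either from the package's tab-separated
#' fragment-table dialect (`format = "bed_like"`; columns
#' chrom, start, end, strand, sample_id, motif_up, motif_down, allele, gene_id,
#' with `.` for missing values and an optional header line; files with only the
#' first columns are accepted, missing columns are filled with `NA`) or from a
#' coordinate-sorted paired-end alignment file (`format = "alignment"`, BAM
#' semantics via Rsamtools). In alignment mode one record is emitted per
#' properly paired template, spanning the outer coordinates of the pair;
#' 1-based alignment starts are converted to 0-based half-open coordinates.
#' Unpaired reads are skipped and counted in the `skipped_unpaired` attribute.
#'
#' @param path Input file.
#' @param format `"bed_like"` or `"alignment"`.
#' @param sample_id Sample id to stamp on records; defaults to the file name
#'   (bed_like input keeps an explicit sample_id column if present).
#' @return A fragment tibble.
#' @export
read_fragments <- function(path, format = c("bed_like", "alignment"),
                           sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  default_sid <- if (is.null(sample_id)) {
    sub("\\.(tsv|bed|txt|bam|sam)(\\.gz)?$", "", basename(path))
  } else {
    sample_id
  }
  if (format == "bed_like") {
    read_fragments_bedlike(path, default_sid, !is.null(sample_id))
  } else {
    read_fragments_alignment(path, default_sid)
  }
}

read_fragments_bedlike <- function(path, sid, force_sid) {
  lines <- readLines(path)
  if (length(lines) > 0L) lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty fragment file: ", path)
    return(empty_fragment_table())
  }
  header_offset <- 0L
  first <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (grepl("^#", first[[1L]]) || identical(tolower(first[[1L]]), "chrom")) {
    lines <- lines[-1L]
    header_offset <- 1L
    if (length(lines) == 0L) {
      warning("empty fragment file: ", path)
      return(empty_fragment_table())
    }
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("unparseable line ", which(nf < 3L)[1L] + header_offset,
         " in ", path, ": fewer than 3 fields")
  }
  get_col <- function(i) {
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else ".", character(1))
  }
  start_chr <- get_col(2L)
  end_chr <- get_col(3L)
  start <- suppressWarnings(as.integer(start_chr))
  end <- suppressWarnings(as.integer(end_chr))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    stop("unparseable line ", bad[1L] + header_offset, " in ", path,
         ": non-integer coordinates")
  }
  dotna <- function(x) ifelse(x == ".", NA_character_, x)
  sid_col <- dotna(get_col(5L))
  if (force_sid) sid_col <- rep(sid, length(sid_col))
  sid_col[is.na(sid_col)] <- sid
  fragment_table(
    chrom = get_col(1L), start = start, end = end,
    strand = ifelse(get_col(4L) %in% c("+", "-"), get_col(4L), "+"),
    sample_id = sid_col,
    motif_up = dotna(get_col(6L)), motif_down = dotna(get_col(7L)),
    allele = dotna(get_col(8L)), gene_id = dotna(get_col(9L))
  )
}

read_fragments_alignment <- function(path, sid) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("alignment input requires the Rsamtools package")
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "isize", "flag"),
    flag = Rsamtools::scanBamFlag(isPaired = TRUE, isUnmappedQuery = FALSE)
  )
  res <- Rsamtools::scanBam(path, param = param)[[1L]]
  n_all <- length(res$pos)
  # keep the leftmost mate of each properly paired template: positive isize
  proper <- bitwAnd(res$flag, 2L) > 0L
  keep <- proper & !is.na(res$isize) & res$isize > 0L & !is.na(res$pos)
  n_skipped <- sum(!proper | is.na(res$isize))
  out <- fragment_table(
    chrom = as.character(res$rname[keep]),
    start = res$pos[keep] - 1L,
    end = res$pos[keep] - 1L + res$isize[keep],
    strand = ifelse(bitwAnd(res$flag[keep], 16L) > 0L, "-", "+"),
    sample_id = sid
  )
  if (n_skipped > 0L) {
    message(n_skipped, " of ", n_all, " reads skipped (not properly paired)")
  }
  attr(out, "skipped_unpaired") <- n_skipped
  out
}

#' Write a fragment table
#'
#' Tab-separated, `.` for missing, column order chrom, start, end, strand,
#' sample_id, motif_up, motif_down, allele, gene_id (a BED3+-compatible
#' prefix). Read back bit-exactly by [read_fragments()].
#'
#' @param fragments Fragment tibble.
#' @param path Output file.
#' @param header Write a header line (default `TRUE`).
#' @export
write_fragments <- function(fragments, path, header = TRUE) {
  df <- as.data.frame(fragments[, FRAGMENT_COLUMNS])
  for (col in FRAGMENT_COLUMNS) {
    v <- as.character(df[[col]])
    v[is.na(v)] <- "."
    df[[col]] <- v
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

#' Quality-filter fragments
#'
#' Removes records with no usable length (`end <= start`, i.e. length < 1 bp)
#' and records whose terminal motifs contain `N` or other non-ACGT characters.
#' The N-rule is applied only to records that carry motifs; records with
#' missing motifs are retained (they are excluded later from motif analyses
#' only). Never errors: an empty result is legal.
#'
#' @param fragments Fragment tibble.
#' @return A list with `fragments` (survivors) and `report`, a tibble of
#'   removal counts by reason (`nonpositive_length`, `n_in_terminus`, `kept`).
#' @export
filter_fragments <- function(fragments) {
  len_ok <- !is.na(fragments$length) & fragments$length >= 1L
  motif_bad <- function(m) !is.na(m) & !grepl("^[ACGTacgt]{3}$", m)
  bad_motif <- motif_bad(fragments$motif_up) | motif_bad(fragments$motif_down)
  removed_len <- sum(!len_ok)
  removed_n <- sum(len_ok & bad_motif)
  keep <- len_ok & !bad_motif
  list(
    fragments = fragments[keep, , drop = FALSE],
    report = tibble(
      reason = c("nonpositive_length", "n_in_terminus", "kept"),
      n = c(removed_len, removed_n, sum(keep))
    )
  )
}

revcomp_3mer <- function(x) {
  rc <- chartr("ACGTacgt", "TGCAtgca", x)
  out <- paste0(substring(rc, 3L, 3L), substring(rc, 2L, 2L), substring(rc, 1L, 1L))
  out[is.na(x)] <- NA_character_
  out
}

#' Annotate terminal 3-mer end motifs from a reference sequence
#'
#' Both motifs are read 5'->3' *into* the fragment from each end: `motif_up` is
#' the plus-strand reference 3-mer at `[start, start+3)`; `motif_down` is the
#' reverse complement of the plus-strand 3-mer at `[end-3, end)`. This is the
#' prevailing convention in the cfDNA end-motif literature; set
#' `revcomp_downstream = FALSE` to keep the plus-strand downstream 3-mer
#' instead (sensitivity analysis). Bases are uppercased. Fragments shorter
#' than 3 bp get `NA` motifs and are counted in the `n_too_short` attribute.
#'
#' @param fragments Fragment tibble.
#' @param reference A named [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param revcomp_downstream Reverse-complement the downstream-end 3-mer
#'   (default `TRUE`).
#' @return The fragment tibble with `motif_up`/`motif_down` filled in.
#' @export
annotate_motifs <- function(fragments, reference, revcomp_downstream = TRUE) {
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  motif_up <- rep(NA_character_, nrow(fragments))
  motif_down <- rep(NA_character_, nrow(fragments))
  ok <- fragments$length >= 3L
  for (chr in unique(fragments$chrom)) {
    if (!chr %in% names(reference)) {
      stop("chromosome not in reference: ", chr)
    }
    idx <- which(fragments$chrom == chr & ok)
    if (length(idx) == 0L) next
    seq <- reference[[chr]]
    if (any(fragments$start[idx] < 0L) || any(fragments$end[idx] > length(seq))) {
      stop("fragment coordinates outside reference on ", chr)
    }
    up <- as.character(Biostrings::extractAt(
      seq, IRanges::IRanges(fragments$start[idx] + 1L, width = 3L)))
    dn <- as.character(Biostrings::extractAt(
      seq, IRanges::IRanges(fragments$end[idx] - 2L, width = 3L)))
    motif_up[idx] <- toupper(up)
    motif_down[idx] <- if (revcomp_downstream) revcomp_3mer(toupper(dn)) else toupper(dn)
  }
  fragments$motif_up <- motif_up
  fragments$motif_down <- motif_down
  attr(fragments, "n_too_short") <- sum(!ok)
  fragments
}

#' Read a gene panel from BED
#'
#' BED4(+1) dialect: chrom, start, end, gene_id and an optional fifth column
#' giving the targeted footprint in bp (defaults to the interval width).
#'
#' @param path BED file.
#' @return A gene-panel tibble with columns `gene_id`, `chrom`, `start`,
#'   `end`, `footprint_bp`.
#' @export
read_gene_panel <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  panel <- tibble(
    gene_id = as.character(df[[4L]]),
    chrom = as.character(df[[1L]]),
    start = as.integer(df[[2L]]),
    end = as.integer(df[[3L]]),
    footprint_bp = if (ncol(df) >= 5L) as.integer(df[[5L]]) else
      as.integer(df[[3L]]) - as.integer(df[[2L]])
  )
  validate_gene_panel(panel)
  panel
}

validate_gene_panel <- function(panel) {
  if (anyDuplicated(panel$gene_id)) stop("gene_ids must be unique")
  if (any(panel$footprint_bp <= 0L)) stop("footprint_bp must be > 0")
  invisible(panel)
}

#' Write a gene panel to BED
#' @param panel Gene-panel tibble.
#' @param path Output BED file.
#' @export
write_gene_panel <- function(panel, path) {
  utils::write.table(
    data.frame(panel$chrom, panel$start, panel$end, panel$gene_id,
               panel$footprint_bp),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

panel_granges <- function(panel) {
  GenomicRanges::GRanges(
    seqnames = panel$chrom,
    ranges = IRanges::IRanges(start = panel$start + 1L, end = panel$end),
    gene_id = panel$gene_id
  )
}

#' Assign fragments to panel genes
#'
#' Each fragment overlapping exactly one panel gene receives that `gene_id`;
#' non-overlapping fragments get `NA`. A fragment overlapping several genes is
#' assigned to the gene with the larger overlap, with ties broken by the
#' lexicographically smaller `gene_id`, so fragments are never double-counted.
#'
#' @param fragments Fragment tibble.
#' @param panel Gene-panel tibble.
#' @return The fragment tibble with `gene_id` filled in.
#' @export
assign_genes <- function(fragments, panel) {
  if (nrow(fragments) == 0L) return(fragments)
  frag_gr <- GenomicRanges::GRanges(
    seqnames = fragments$chrom,
    ranges = IRanges::IRanges(start = fragments$start + 1L,
                              end = pmax(fragments$end, fragments$start + 1L))
  )
  pan_gr <- panel_granges(panel)
  hits <- GenomicRanges::findOverlaps(frag_gr, pan_gr)
  gene_id <- rep(NA_character_, nrow(fragments))
  if (length(hits) > 0L) {
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(frag_gr)[q], IRanges::ranges(pan_gr)[s]))
    gid <- panel$gene_id[s]
    ord <- order(q, -ov, gid)
    first <- !duplicated(q[ord])
    gene_id[q[ord][first]] <- gid[ord][first]
  }
  fragments$gene_id <- gene_id
  fragments
}

#' Read a nucleosome dyad track from BED
#'
#' Point positions: rows may be zero-width (`start == end`) or 1 bp intervals;
#' the dyad is taken at `start`. Positions are sorted and de-duplicated per
#' chromosome.
#'
#' @param path BED file.
#' @return A tibble with columns `chrom`, `pos` (0-based dyad positions).
#' @export
read_nucleosome_track <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  nucleosome_track(chrom = as.character(df[[1L]]), pos = as.integer(df[[2L]]))
}

#' Build a nucleosome dyad track
#' @param chrom Chromosome names.
#' @param pos 0-based dyad positions.
#' @return A sorted, de-duplicated tibble with columns `chrom`, `pos`.
#' @export
nucleosome_track <- function(chrom, pos) {
  out <- tibble(chrom = as.character(chrom), pos = as.integer(pos))
  out <- out[!duplicated(out), , drop = FALSE]
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Write a nucleosome dyad track to BED
#' @param track Dyad-track tibble (`chrom`, `pos`).
#' @param path Output BED file.
#' @export
write_nucleosome_track <- function(track, path) {
  utils::write.table(
    data.frame(track$chrom, track$pos, track$pos + 1L),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
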