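#' Signed distances from fragment ends to the nearest nucleosome dyad
#'
#' Fragments whose `[start, end)` interval contains at least one dyad qualify
#' and contribute two signed distances, one per end: end coordinate minus the
#' dyad nearest to that end (each end may use a different dyad). Fragments not
#' overlapping any dyad are excluded and counted in the `n_excluded`
#' attribute.
#'
#' @param fragments Fragment tibble.
#' @param track Dyad-track tibble (`chrom`, `pos`), sorted.
#' @param label Optional gene-set label stored in the result.
#' @return Tibble with `end_type` (`"start"`/`"end"`), `distance` (bp, signed)
#'   and `label`; attribute `n_excluded`.
#' @export
end_dyad_distances <- function(fragments, track, label = NA_character_) {
  if (nrow(track) == 0L) stop("empty nucleosome track")
  out <- vector("list", 0L)
  n_excluded <- 0L
  for (chr in unique(fragments$chrom)) {
    frag <- fragments[fragments$chrom == chr, , drop = FALSE]
    pos <- track$pos[track$chrom == chr]
    if (length(pos) == 0L) {
      n_excluded <- n_excluded + nrow(frag)
      next
    }
    pos <- sort(pos)
    # a dyad lies in [start, end) iff the count of dyads < end exceeds those < start
    n_before_start <- findInterval(frag$start - 1L, pos)
    n_before_end <- findInterval(frag$end - 1L, pos)
    qualifies <- n_before_end > n_before_start
    n_excluded <- n_excluded + sum(!qualifies)
    if (!any(qualifies)) next
    frag <- frag[qualifies, , drop = FALSE]
    nearest <- function(x) {
      i <- findInterval(x, pos)
      lo <- pmax(i, 1L)
      hi <- pmin(i + 1L, length(pos))
      ifelse(i == 0L, pos[hi],
             ifelse(i == length(pos), pos[lo],
                    ifelse(x - pos[lo] <= pos[hi] - x, pos[lo], pos[hi])))
    }
    out[[length(out) + 1L]] <- tibble(
      end_type = rep(c("start", "end"), each = nrow(frag)),
      distance = c(frag$start - nearest(frag$start),
                   frag$end - nearest(frag$end)),
      label = label
    )
  }
  res <- if (length(out) == 0L) {
    tibble(end_type = character(), distance = integer(), label = character())
  } else {
    dplyr::bind_rows(out)
  }
  attr(res, "n_excluded") <- n_excluded
  res
}

#' Core/linker end fraction
#'
#' Classifies fragment-end-to-dyad distances by absolute value: core
#' |d| <= 75 bp (the nucleosome-protected core), linker 75 < |d| <= 95 bp
#' (inter-nucleosomal DNA), beyond |d| > 95 bp (counted but excluded from the
#' ratio). The core/linker end fraction is core count / linker count;
#' undefined (flagged) when no ends fall in the linker.
#'
#' @param distances Tibble from [end_dyad_distances()] (or any tibble with a
#'   `distance` column), non-empty.
#' @param core_bp Core half-width (default 75).
#' @param linker_bp Outer linker bound (default 95).
#' @return List with `core`, `linker`, `beyond`, `fraction`, `undefined`.
#' @export
core_linker_fraction <- function(distances, core_bp = 75, linker_bp = 95) {
  if (nrow(distances) == 0L) stop("empty distance set")
  d <- abs(distances$distance)
  core <- sum(d <= core_bp)
  linker <- sum(d > core_bp & d <= linker_bp)
  beyond <- sum(d > linker_bp)
  list(
    core = core, linker = linker, beyond = beyond,
    fraction = if (linker > 0L) core / linker else NA_real_,
    undefined = linker == 0L
  )
}

#' Fragment-end frequency profile around the dyad
#'
#' Normalised frequency of fragment ends per signed offset (or absolute
#' offset when `folded = TRUE`) within `[-half_window, +half_window]` bp of
#' the nearest dyad. Frequencies sum to 1 over the window; mass outside it is
#' reported via the `excluded_mass` attribute.
#'
#' @param distances Tibble from [end_dyad_distances()], non-empty.
#' @param half_window Window half-width in bp (default 95).
#' @param bin Offset bin width in bp (default 1).
#' @param folded Fold signed offsets to |d| (default `FALSE`).
#' @return Tibble with `offset`, `n`, `freq`; attribute `excluded_mass`.
#' @export
end_distance_profile <- function(distances, half_window = 95, bin = 1,
                                 folded = FALSE) {
  if (nrow(distances) == 0L) stop("empty distance set")
  d <- distances$distance
  if (folded) d <- abs(d)
  inw <- abs(distances$distance) <= half_window
  excluded <- mean(!inw)
  d <- d[inw]
  lo <- if (folded) 0 else -half_window
  centers <- seq(lo, half_window, by = bin)
  idx <- findInterval(d, centers - bin / 2, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  idx[idx > length(centers)] <- length(centers)
  n <- tabulate(idx, nbins = length(centers))
  out <- tibble(offset = centers, n = n, freq = n / sum(n))
  attr(out, "excluded_mass") <- excluded
  out
}
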