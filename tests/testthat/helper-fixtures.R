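# Shared fixtures and independent oracles, built in code at test time.

.fixture_env <- new.env(parent = emptyenv())

# small cohort reused across module tests (memoised)
small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    cfg <- simulation_config(seed = 101L, n_cancer = 5L, n_healthy = 2L,
                             fragments_per_sample = 20000L)
    .fixture_env$cohort <- simulate_cohort(cfg)
  }
  .fixture_env$cohort
}

# 1 kb random reference for motif-annotation tests
tiny_reference <- function(seed = 7L, len = 1000L) {
  set.seed(seed)
  ref <- Biostrings::DNAStringSet(paste(
    sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""))
  names(ref) <- "chr1"
  ref
}

# brute-force Benjamini-Hochberg step-up (independent of p.adjust)
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# exact upper-tail hypergeometric by factorial enumeration
hyper_brute <- function(k, size_a, size_b, universe) {
  jmax <- min(size_a, size_b)
  if (k > jmax) return(0)
  total <- choose(universe, size_b)
  sum(vapply(k:jmax, function(j) {
    choose(size_a, j) * choose(universe - size_a, size_b - j)
  }, numeric(1))) / total
}

# classic Friedman chi-square statistic from average ranks (no tie
# correction; oracle for continuous data)
friedman_brute <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  ranks <- t(apply(m, 1L, rank))
  colsum <- colSums(ranks)
  12 / (n * k * (k + 1)) * sum(colsum^2) - 3 * n * (k + 1)
}

# brute-force nearest-dyad end distances (all-pairs minimum)
end_dyad_brute <- function(fragments, pos) {
  rows <- list()
  for (i in seq_len(nrow(fragments))) {
    s <- fragments$start[i]
    e <- fragments$end[i]
    if (!any(pos >= s & pos <= e - 1L)) next
    rows[[length(rows) + 1L]] <- c(
      s - pos[which.min(abs(s - pos))],
      e - pos[which.min(abs(e - pos))])
  }
  do.call(rbind, rows)
}
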