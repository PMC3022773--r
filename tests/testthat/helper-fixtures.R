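# Fixture builders and independent oracles used across the suite.

# Small hand-built annotation: two genes on a 10 kb chromosome.
#   tx_a chrT:1000-4000 exons [1000,1500) [2000,2600) [3500,4000)
#   tx_b chrT:6000-8000 exons [6000,6400) [7500,8000)
toy_annotation <- function(chrom_sizes = c(chrT = 10000L)) {
  df <- data.frame(
    tx_id = c("tx_a", "tx_b"),
    chrom = "chrT",
    strand = c("+", "-"),
    start = c(1000L, 6000L),
    end = c(4000L, 8000L),
    stringsAsFactors = FALSE
  )
  df$exon_starts <- list(c(1000L, 2000L, 3500L), c(6000L, 7500L))
  df$exon_ends <- list(c(1500L, 2600L, 4000L), c(6400L, 8000L))
  transcript_annotation(df, chrom_sizes = chrom_sizes)
}

# An annotation with no transcripts at all.
empty_annotation <- function(chrom_sizes) {
  df <- data.frame(tx_id = character(0), chrom = character(0),
                   strand = character(0), start = integer(0), end = integer(0),
                   stringsAsFactors = FALSE)
  df$exon_starts <- list()
  df$exon_ends <- list()
  transcript_annotation(df, chrom_sizes = chrom_sizes)
}

# Minimal placement table from parallel vectors.
toy_alignments <- function(chrom, start, end, read_id = NULL) {
  data.frame(
    read_id = read_id %||% sprintf("r%03d", seq_along(start)),
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# --- independent oracles ----------------------------------------------------

# Exhaustive global alignment score by plain recursion (no memoization):
# every alignment path is enumerated. Tractable for lengths <= ~6.
bf_global_score <- function(tc, rc, i = length(tc), j = length(rc)) {
  if (i == 0L && j == 0L) return(0)
  best <- -Inf
  if (i > 0L && j > 0L) {
    s <- if (tc[i] == rc[j]) 5 else -4
    best <- max(best, bf_global_score(tc, rc, i - 1L, j - 1L) + s)
  }
  if (i > 0L) best <- max(best, bf_global_score(tc, rc, i - 1L, j) - 4)
  if (j > 0L) best <- max(best, bf_global_score(tc, rc, i, j - 1L) - 4)
  best
}

# Fitting score: best global score of the tag against any reference substring.
bf_fitting_score <- function(tag, ref) {
  tc <- strsplit(tag, "")[[1]]
  rc <- strsplit(ref, "")[[1]]
  m <- length(rc)
  best <- bf_global_score(tc, character(0))  # empty substring
  for (j0 in seq_len(m)) {
    for (j1 in j0:m) {
      best <- max(best, bf_global_score(tc, rc[j0:j1]))
    }
  }
  best
}

# Per-base coverage counting by explicit looping over reads and bases.
bf_coverage <- function(alignments, chrom_len) {
  cov <- numeric(chrom_len)
  for (i in seq_len(nrow(alignments))) {
    idx <- (alignments$start[i] + 1L):alignments$end[i]
    cov[idx] <- cov[idx] + 1
  }
  cov
}

# Base-pair 2x2 contingency by explicit per-base membership over a small
# single-chromosome universe [0, len).
bf_contingency <- function(set_a, set_b, len) {
  member <- function(set) {
    v <- logical(len)
    for (i in seq_len(nrow(set))) {
      v[(set$start[i] + 1L):set$end[i]] <- TRUE
    }
    v
  }
  a <- member(set_a)
  b <- member(set_b)
  matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)), 2L, 2L)
}

# Descending competition ranks by counting strictly larger values.
bf_rank <- function(x) vapply(x, function(v) sum(x > v) + 1L, integer(1))

# Spearman correlation by hand: mid-ranks, then the Pearson formula.
bf_spearman <- function(x, y) {
  midrank <- function(v) {
    vapply(v, function(a) sum(v < a) + (sum(v == a) + 1) / 2, numeric(1))
  }
  rx <- midrank(x)
  ry <- midrank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Chi-square statistic from the textbook formula.
bf_chisq <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}
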