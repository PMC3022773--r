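# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Convert internal 0-based half-open intervals to a GRanges (1-based closed).
gr0 <- function(chrom, start, end, seqlengths = NULL, ...) {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    ...
  )
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

# Back-conversion: GRanges to a 0-based half-open data.frame.
df0 <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

# Nearest-rank percentile of a weighted sample: value at rank
# ceiling(p/100 * N) of the expanded, sorted population.
nearest_rank_percentile <- function(values, weights, p) {
  stopifnot(length(values) == length(weights), p > 0, p < 100)
  if (length(values) == 0L) return(NA_real_)
  o <- order(values)
  values <- values[o]
  weights <- as.numeric(weights[o])
  n <- sum(weights)
  rank <- ceiling(p / 100 * n)
  idx <- which(cumsum(weights) >= rank)[1L]
  values[idx]
}

# Full-precision numeric formatting that survives a write/read round trip.
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  # prefer the shortest representation that still round-trips
  for (digits in c(16L, 15L)) {
    cand <- sprintf(paste0("%.", digits, "g"), x)
    ok <- as.numeric(cand) == x
    out[ok] <- cand[ok]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
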