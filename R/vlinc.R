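#' Parameters of the vlinc domain caller
#'
#' The caller thresholds per-chromosome intergenic read density at the
#' `threshold_percentile` of positive density values, merges
#' above-threshold runs separated by at most `max_gap` bases, and reports
#' merged runs spanning at least `min_run` bases. Defaults are the
#' published settings: 80th percentile, MaxGap 5000, MinRun 50000.
#'
#' @param threshold_percentile Percentile (0-100, exclusive) of positive
#'   per-base density values, taken per chromosome by nearest rank.
#' @param max_gap Maximum gap (bp) merged into a run.
#' @param min_run Minimum reported domain span (bp).
#' @return An object of class `"caller_params"`.
#' @export
caller_params <- function(threshold_percentile = 80, max_gap = 5000L,
                          min_run = 50000L) {
  if (threshold_percentile <= 0 || threshold_percentile >= 100) {
    stop("threshold_percentile must lie strictly between 0 and 100", call. = FALSE)
  }
  if (max_gap < 0) stop("max_gap must be nonnegative", call. = FALSE)
  if (min_run <= 0) stop("min_run must be positive", call. = FALSE)
  structure(list(threshold_percentile = threshold_percentile,
                 max_gap = as.integer(max_gap), min_run = as.integer(min_run)),
            class = "caller_params")
}

#' Pool intergenic read density across samples
#'
#' Keeps only intergenic-classified reads from every sample, pools them,
#' and normalizes the pooled coverage by the pooled informative total
#' (reads per 10 M informative of the pooled set).
#'
#' @param samples List of samples; each a list with `alignments` (a
#'   classified informative read table, see [classify_reads()]) and
#'   `informative_count`.
#' @param annotation A [transcript_annotation()] (supplies contig sizes).
#' @return A numeric [S4Vectors::RleList] density track.
#' @export
pool_intergenic_density <- function(samples, annotation) {
  if (length(samples) == 0L) stop("at least one sample required", call. = FALSE)
  pooled <- do.call(rbind, lapply(samples, function(s) {
    a <- s$alignments
    a <- a[a$category == "intergenic", c("chrom", "start", "end"), drop = FALSE]
    a
  }))
  if (nrow(pooled) == 0L) stop("no intergenic reads to pool", call. = FALSE)
  total <- sum(vapply(samples, function(s) s$informative_count, numeric(1)))
  density_track(pooled, total, annotation_chrom_sizes(annotation))
}

#' Call vlinc domains from an intergenic density track
#'
#' Per chromosome, the threshold is the nearest-rank
#' `threshold_percentile` of the positive (nonzero) per-base density
#' values; bases at or above it form runs; runs separated by at most
#' `max_gap` bases are merged (the gap is included in the span); merged
#' runs are clipped against transcript spans so reported intervals stay
#' intergenic, and those spanning at least `min_run` bases are reported.
#' Domain ids are assigned in genome order as `vlinc_1`, `vlinc_2`, ...
#'
#' @param density Numeric RleList from [pool_intergenic_density()] or
#'   [density_track()].
#' @param params A [caller_params()].
#' @param annotation A [transcript_annotation()] used for clipping.
#' @return Data frame of domains: `vlinc_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @export
call_domains <- function(density, params = caller_params(), annotation) {
  spans <- GenomicRanges::reduce(annotation_spans(annotation), ignore.strand = TRUE)
  out <- lapply(names(density), function(chrom) {
    rle <- density[[chrom]]
    vals <- S4Vectors::runValue(rle)
    lens <- S4Vectors::runLength(rle)
    pos <- vals > 0
    if (!any(pos)) return(NULL)
    thr <- nearest_rank_percentile(vals[pos], lens[pos], params$threshold_percentile)
    above <- methods::as(IRanges::slice(rle, lower = thr, includeLower = TRUE),
                         "IRanges")
    merged <- IRanges::reduce(above, min.gapwidth = params$max_gap + 1L)
    if (length(merged) == 0L) return(NULL)
    gr <- GenomicRanges::GRanges(chrom, merged)
    clipped <- GenomicRanges::setdiff(gr, spans, ignore.strand = TRUE)
    clipped <- clipped[GenomicRanges::width(clipped) >= params$min_run]
    if (length(clipped) == 0L) return(NULL)
    df0(clipped)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(vlinc_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0), stringsAsFactors = FALSE))
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  row.names(out) <- NULL
  cbind(vlinc_id = sprintf("vlinc_%d", seq_len(nrow(out))), out,
        stringsAsFactors = FALSE)
}

#' Compare called domains with planted ground truth
#'
#' Matches each planted domain to the called domain with maximal overlap
#' and reports the Jaccard index (intersection over union) per matched
#' pair, plus both unmatched lists.
#'
#' @param called,planted Domain data frames (`chrom`, `start`, `end`; id
#'   columns optional).
#' @return List with `pairs` (planted id/index, called id/index, overlap
#'   bp, jaccard), `unmatched_planted`, `unmatched_called`, and
#'   `mean_jaccard` over planted domains (unmatched count as 0).
#' @export
recover_planted <- function(called, planted) {
  cal <- gr0(called$chrom, called$start, called$end)
  pla <- gr0(planted$chrom, planted$start, planted$end)
  hits <- GenomicRanges::findOverlaps(pla, cal, ignore.strand = TRUE)
  if (length(hits) > 0L) {
    ov <- GenomicRanges::width(IRanges::pintersect(
      pla[S4Vectors::queryHits(hits)], cal[S4Vectors::subjectHits(hits)]))
    un <- GenomicRanges::width(pla[S4Vectors::queryHits(hits)]) +
      GenomicRanges::width(cal[S4Vectors::subjectHits(hits)]) - ov
    df <- data.frame(planted = S4Vectors::queryHits(hits),
                     called = S4Vectors::subjectHits(hits),
                     overlap_bp = ov, jaccard = ov / un)
    # keep, per planted domain, the called domain with maximal overlap
    df <- df[order(df$planted, -df$overlap_bp), , drop = FALSE]
    df <- df[!duplicated(df$planted), , drop = FALSE]
    row.names(df) <- NULL
  } else {
    df <- data.frame(planted = integer(0), called = integer(0),
                     overlap_bp = integer(0), jaccard = numeric(0))
  }
  jac <- rep(0, length(pla))
  jac[df$planted] <- df$jaccard
  list(pairs = df,
       unmatched_planted = setdiff(seq_along(pla), df$planted),
       unmatched_called = setdiff(seq_along(cal), df$called),
       mean_jaccard = if (length(pla) > 0L) mean(jac) else NA_real_)
}
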