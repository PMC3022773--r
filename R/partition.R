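#' Classify placed reads as exonic, intronic or intergenic
#'
#' A read is exonic if its aligned genomic footprint overlaps at least one
#' exonic base of any transcript on either strand; otherwise intronic if
#' it overlaps any transcript span; otherwise intergenic. The precedence
#' exon > intron > intergenic resolves boundary-spanning reads
#' conservatively: ambiguous exonic overlap deflates, never inflates, the
#' un-annotated fraction.
#'
#' @param alignments Placement table (`chrom`, `start`, `end`), one row per
#'   informative read.
#' @param annotation A [transcript_annotation()].
#' @return The table with a `category` factor column
#'   (`exonic`/`intronic`/`intergenic`) added.
#' @export
classify_reads <- function(alignments, annotation) {
  cs <- annotation_chrom_sizes(annotation)
  bad <- setdiff(unique(alignments$chrom), names(cs))
  if (length(bad) > 0L) {
    stop("reads on unknown chromosome: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  category <- rep("intergenic", nrow(alignments))
  if (nrow(alignments) > 0L) {
    reads_gr <- gr0(alignments$chrom, alignments$start, alignments$end)
    in_span <- GenomicRanges::countOverlaps(reads_gr, annotation_spans(annotation),
                                            ignore.strand = TRUE) > 0L
    in_exon <- GenomicRanges::countOverlaps(reads_gr, annotation_exons(annotation),
                                            ignore.strand = TRUE) > 0L
    category[in_span] <- "intronic"
    category[in_exon] <- "exonic"
  }
  alignments$category <- factor(category,
                                levels = c("exonic", "intronic", "intergenic"))
  alignments
}

#' Summarize the exonic/intronic/intergenic partition of a sample
#'
#' @param alignments Classified read table (see [classify_reads()]).
#' @param sample_id Optional sample label.
#' @return Data frame with one row per category: `count` and `fraction`
#'   over the informative total, plus the total as attribute
#'   `informative_count`.
#' @export
partition_summary <- function(alignments, sample_id = NA_character_) {
  if (nrow(alignments) == 0L) {
    stop("cannot summarize a sample with zero informative reads", call. = FALSE)
  }
  counts <- table(alignments$category)
  out <- data.frame(
    sample_id = sample_id,
    category = names(counts),
    count = as.integer(counts),
    fraction = as.numeric(counts) / nrow(alignments),
    stringsAsFactors = FALSE
  )
  attr(out, "informative_count") <- nrow(alignments)
  out
}

#' Percentage helper for relative-mass bookkeeping
#'
#' Relative mass of a read (or base-pair) subset as a percentage of a
#' total, e.g. reads in vlinc regions accounted for by EST exons over all
#' vlinc reads.
#'
#' @param count Subset size.
#' @param total Denominator (e.g. informative reads).
#' @return `100 * count / total`.
#' @export
relative_mass_pct <- function(count, total) {
  if (any(total <= 0)) stop("total must be positive", call. = FALSE)
  100 * count / total
}

#' Per-base read density normalized to reads per 10 million
#'
#' Coverage depth at every genomic base, scaled by `1e7 / informative_count`
#' so values are comparable across samples of different depth ("reads per
#' genomic base in 10 million non-ribosomal, non-mitochondrial reads").
#'
#' @param alignments Placement table (`chrom`, `start`, `end`).
#' @param informative_count Informative reads in the sample (> 0).
#' @param chrom_sizes Named contig lengths; the track covers every contig
#'   at full length (zero where no read aligns).
#' @return A numeric [S4Vectors::RleList], one run-length vector per contig.
#' @export
density_track <- function(alignments, informative_count, chrom_sizes) {
  if (informative_count <= 0) stop("informative_count must be positive", call. = FALSE)
  gr <- gr0(alignments$chrom, alignments$start, alignments$end,
            seqlengths = chrom_sizes)
  cov <- GenomicRanges::coverage(gr)
  cov * (1e7 / informative_count)
}

#' Per-feature expression normalized to reads per 10 million
#'
#' Counts informative reads overlapping each feature interval (a
#' transcript's full exon+intron span, or a vlinc domain) and reports the
#' normalized count and the relative mass.
#'
#' @param features Data frame (`feature_id`, `chrom`, `start`, `end`,
#'   0-based half-open) or a GRanges with a `feature_id` column.
#' @param alignments Placement table of informative reads.
#' @param informative_count Informative reads in the sample.
#' @return Data frame: `feature_id`, `raw_count`, `normalized_count`
#'   (reads per 10 M informative) and `relative_mass_pct`.
#' @export
feature_expression <- function(features, alignments, informative_count) {
  if (informative_count <= 0) stop("informative_count must be positive", call. = FALSE)
  if (inherits(features, "GRanges")) {
    ids <- features$feature_id
    f_gr <- features
  } else {
    ids <- features$feature_id
    f_gr <- gr0(features$chrom, features$start, features$end)
  }
  if (anyDuplicated(ids)) stop("duplicate feature ids", call. = FALSE)
  reads_gr <- gr0(alignments$chrom, alignments$start, alignments$end)
  raw <- GenomicRanges::countOverlaps(f_gr, reads_gr, ignore.strand = TRUE)
  data.frame(
    feature_id = ids,
    raw_count = as.integer(raw),
    normalized_count = raw * 1e7 / informative_count,
    relative_mass_pct = relative_mass_pct(raw, informative_count),
    stringsAsFactors = FALSE
  )
}

#' Screen spliced transcripts for intron read density at exonic levels
#'
#' Considers spliced transcripts whose summed exon+intron read count,
#' normalized to reads per 10 M informative, reaches
#' `min_reads_per_10M`; flags those with at least one intron whose mean
#' per-base read density equals or exceeds the mean density over the
#' transcript's exons. Transcripts without introns are skipped.
#'
#' @param annotation A [transcript_annotation()].
#' @param alignments Placement table of informative reads.
#' @param informative_count Informative reads in the sample.
#' @param min_reads_per_10M Expression floor for consideration (default 50).
#' @return Data frame per considered transcript: `tx_id`,
#'   `normalized_count`, `exon_density`, `max_intron_density`, `flagged`.
#' @export
intron_exon_density_screen <- function(annotation, alignments, informative_count,
                                       min_reads_per_10M = 50) {
  spliced <- annotation[vapply(annotation$exon_starts, length, 1L) >= 2L, ,
                        drop = FALSE]
  if (nrow(spliced) == 0L) {
    return(data.frame(tx_id = character(0), normalized_count = numeric(0),
                      exon_density = numeric(0), max_intron_density = numeric(0),
                      flagged = logical(0), stringsAsFactors = FALSE))
  }
  spans <- data.frame(feature_id = spliced$tx_id, chrom = spliced$chrom,
                      start = spliced$start, end = spliced$end,
                      stringsAsFactors = FALSE)
  expr <- feature_expression(spans, alignments, informative_count)
  consider <- spliced[expr$normalized_count >= min_reads_per_10M, , drop = FALSE]
  expr <- expr[expr$normalized_count >= min_reads_per_10M, , drop = FALSE]

  cov <- density_track(alignments, informative_count,
                       annotation_chrom_sizes(annotation))
  mean_density <- function(chrom, starts, ends) {
    v <- IRanges::Views(cov[[chrom]], IRanges::IRanges(starts + 1L, ends))
    sum(sum(v)) / sum(ends - starts)
  }
  res <- lapply(seq_len(nrow(consider)), function(i) {
    es <- consider$exon_starts[[i]]
    ee <- consider$exon_ends[[i]]
    ch <- consider$chrom[i]
    exon_d <- mean_density(ch, es, ee)
    intron_s <- ee[-length(ee)]
    intron_e <- es[-1]
    intron_d <- vapply(seq_along(intron_s), function(j) {
      mean_density(ch, intron_s[j], intron_e[j])
    }, numeric(1))
    c(exon_density = exon_d, max_intron_density = max(intron_d))
  })
  res <- do.call(rbind, res)
  data.frame(
    tx_id = consider$tx_id,
    normalized_count = expr$normalized_count,
    exon_density = res[, "exon_density"],
    max_intron_density = res[, "max_intron_density"],
    flagged = res[, "max_intron_density"] >= res[, "exon_density"],
    stringsAsFactors = FALSE
  )
}
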