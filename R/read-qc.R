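#' Trim leading T homopolymers from read sequences
#'
#' Single-molecule sequencing of polyA-tailed cDNA leaves a leading run of
#' T bases on many reads; the longest leading T run is removed before any
#' other processing. An all-T read trims to the empty string.
#'
#' @param sequence Character vector of reads over `{A,C,G,T,N}`.
#' @return Trimmed sequences.
#' @export
trim_leading_t <- function(sequence) {
  sub("^T+", "", sequence)
}

#' Filter reads by minimum trimmed length
#'
#' @param reads Data frame with a `sequence` column (already trimmed), or a
#'   character vector of sequences.
#' @param min_len Minimum retained length (default 25 bases).
#' @return The retained subset, same shape as the input.
#' @export
filter_min_length <- function(reads, min_len = 25L) {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  keep <- nchar(seqs) >= min_len
  if (is.data.frame(reads)) reads[keep, , drop = FALSE] else reads[keep]
}

#' Score a gapped alignment
#'
#' The raw score is `5 * matches - 4 * errors`, where errors count every
#' non-match display column: substitutions and gaps on either sequence.
#' The normalized score divides by the ungapped tag length, so a perfect
#' alignment scores exactly 5. The canonical worked case — 31 matches, 2
#' errors, tag length 32 — scores 147 raw and 4.59375 normalized.
#'
#' @param tag,ref Gapped display strings of equal length (gap = `-`);
#'   no column may be a gap in both.
#' @return Data frame with `tag_length`, `n_matches`, `n_errors`,
#'   `raw_score`, `normalized_score`, one row per alignment.
#' @export
score_alignment <- function(tag, ref) {
  if (length(tag) != length(ref)) stop("tag and ref lengths differ", call. = FALSE)
  dl <- nchar(tag)
  if (any(dl != nchar(ref))) {
    stop("gapped tag and ref must have equal display length", call. = FALSE)
  }
  tag_length <- nchar(gsub("-", "", tag, fixed = TRUE))
  if (any(tag_length == 0L)) {
    stop("alignment with empty (all-gap) tag cannot be scored", call. = FALSE)
  }
  n_matches <- integer(length(tag))
  nz <- which(dl > 0L)
  if (length(nz) > 0L) {
    tc <- strsplit(tag[nz], "", fixed = TRUE)
    rc <- strsplit(ref[nz], "", fixed = TRUE)
    # a column matches iff characters are equal; all-gap columns are disallowed
    n_matches[nz] <- mapply(function(a, b) sum(a == b & a != "-"), tc, rc)
  }
  n_errors <- dl - n_matches
  raw <- 5L * n_matches - 4L * n_errors
  data.frame(tag_length = tag_length, n_matches = n_matches, n_errors = n_errors,
             raw_score = raw, normalized_score = raw / tag_length)
}

#' Score an alignment table
#'
#' Adds the scoring columns of [score_alignment()] to an alignment record
#' table (`read_id`, `chrom`, `start`, `tag`, `ref`).
#'
#' @param alignments Alignment record data frame.
#' @return The table with `tag_length`, `n_matches`, `n_errors`,
#'   `raw_score`, `normalized_score` and `end` (0-based half-open) added.
#' @export
score_alignments <- function(alignments) {
  sc <- score_alignment(alignments$tag, alignments$ref)
  alignments[names(sc)] <- sc
  alignments$end <- alignments$start +
    nchar(gsub("-", "", alignments$ref, fixed = TRUE))
  alignments
}

#' Filter scored reads by normalized score
#'
#' @param alignments Scored alignment table (see [score_alignments()]).
#' @param threshold Minimum normalized score retained: 4.5 for the human
#'   genome, 4.3 for the fly genome.
#' @return The retained subset.
#' @export
filter_by_normalized_score <- function(alignments, threshold = 4.5) {
  alignments[alignments$normalized_score >= threshold, , drop = FALSE]
}

#' Keep reads with a unique best placement
#'
#' A read is retained only if exactly one of its candidate placements
#' attains its maximum raw score; ties drop the read entirely. The
#' retained row carries that best placement and the total number of
#' best-scoring placements seen (`n_best_placements`, always 1 for
#' survivors by construction; the pre-filter multiplicity is recorded).
#'
#' @param alignments Scored alignment table, possibly several rows per
#'   `read_id`.
#' @return One row per surviving read.
#' @export
unique_best_filter <- function(alignments) {
  if (nrow(alignments) == 0L) {
    alignments$n_best_placements <- integer(0)
    return(alignments)
  }
  best <- stats::ave(alignments$raw_score, alignments$read_id, FUN = max)
  at_best <- alignments$raw_score == best
  n_best <- stats::ave(as.integer(at_best), alignments$read_id, FUN = sum)
  keep <- at_best & n_best == 1L
  out <- alignments[keep, , drop = FALSE]
  out$n_best_placements <- n_best[keep]
  row.names(out) <- NULL
  out
}

#' Exclude ribosomal and mitochondrial reads
#'
#' Removes reads placed on excluded contigs (the ribosomal repeat decoy and
#' the mitochondrial genome) or overlapping masked rRNA repeat intervals by
#' at least one base. The survivors are the "informative reads", the
#' denominator of all subsequent normalizations.
#'
#' @param alignments Placement table (one row per read).
#' @param excluded_contigs Contig names removed wholesale
#'   (default `c("rDNA", "chrM")`).
#' @param rrna_intervals Optional [GenomicRanges::GRanges] of masked rRNA
#'   repeats; any overlap triggers exclusion.
#' @param known_chroms Optional character vector of valid contig names;
#'   an interval on an unknown contig is an error.
#' @return The informative read table, with attribute
#'   `informative_count` set to its row count.
#' @export
exclude_rrna_mt <- function(alignments, excluded_contigs = c("rDNA", "chrM"),
                            rrna_intervals = NULL, known_chroms = NULL) {
  keep <- !(alignments$chrom %in% excluded_contigs)
  if (!is.null(rrna_intervals) && length(rrna_intervals) > 0L) {
    if (!is.null(known_chroms)) {
      bad <- setdiff(as.character(GenomicRanges::seqnames(rrna_intervals)), known_chroms)
      if (length(bad) > 0L) {
        stop("unknown contig in rRNA interval list: ", paste(bad, collapse = ", "),
             call. = FALSE)
      }
    }
    reads_gr <- gr0(alignments$chrom, alignments$start, alignments$end)
    hit <- GenomicRanges::countOverlaps(reads_gr, rrna_intervals,
                                        ignore.strand = TRUE) > 0L
    keep <- keep & !hit
  }
  out <- alignments[keep, , drop = FALSE]
  row.names(out) <- NULL
  attr(out, "informative_count") <- nrow(out)
  out
}

#' Run the full read QC and scoring pipeline
#'
#' Fixed stage order: trim leading T, minimum-length filter, score, apply
#' the normalized-score threshold, unique-best-placement filter, then
#' ribosomal/mitochondrial exclusion. Each stage only removes or annotates
#' reads. Returns the informative read table plus a per-stage count log.
#'
#' @param reads Raw read table (`read_id`, `sequence`).
#' @param alignments Candidate placements for the trimmed reads.
#' @param min_len Minimum trimmed length (default 25).
#' @param score_threshold Normalized-score cutoff (default 4.5, human).
#' @param excluded_contigs,rrna_intervals,known_chroms
#'   Passed to [exclude_rrna_mt()].
#' @return List with `informative` (scored, filtered placements) and
#'   `stage_counts` (named integer vector of reads surviving each stage).
#' @export
qc_pipeline <- function(reads, alignments, min_len = 25L, score_threshold = 4.5,
                        excluded_contigs = c("rDNA", "chrM"),
                        rrna_intervals = NULL, known_chroms = NULL) {
  counts <- c(input = nrow(reads))
  reads$sequence <- trim_leading_t(reads$sequence)
  reads <- filter_min_length(reads, min_len)
  counts["min_length"] <- nrow(reads)

  alignments <- alignments[alignments$read_id %in% reads$read_id, , drop = FALSE]
  alignments <- score_alignments(alignments)
  alignments <- filter_by_normalized_score(alignments, score_threshold)
  counts["score_threshold"] <- length(unique(alignments$read_id))

  alignments <- unique_best_filter(alignments)
  counts["unique_best"] <- nrow(alignments)

  informative <- exclude_rrna_mt(alignments, excluded_contigs, rrna_intervals,
                                 known_chroms)
  counts["informative"] <- nrow(informative)
  list(informative = informative, stage_counts = counts)
}
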