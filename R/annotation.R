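#' Construct a transcript annotation table
#'
#' A `transcript_annotation` is a data.frame with one row per transcript
#' (`tx_id`, `chrom`, `strand`, `start`, `end`) and list columns
#' `exon_starts`/`exon_ends` holding the ordered exon blocks. All
#' coordinates are 0-based half-open; conversion to 1-based browser
#' coordinates happens only in the I/O layer.
#'
#' @param df Data frame with the columns above.
#' @param chrom_sizes Named integer vector of contig lengths.
#' @param deserts Optional data.frame of annotation-free intervals reserved
#'   for vlinc planting (used by the synthetic generator).
#' @return The validated `transcript_annotation`.
#' @export
transcript_annotation <- function(df, chrom_sizes, deserts = NULL) {
  req <- c("tx_id", "chrom", "strand", "start", "end", "exon_starts", "exon_ends")
  if (!all(req %in% names(df))) {
    stop("annotation must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$tx_id)) stop("duplicate transcript ids", call. = FALSE)
  for (i in seq_len(nrow(df))) {
    es <- df$exon_starts[[i]]
    ee <- df$exon_ends[[i]]
    if (length(es) != length(ee) || any(ee <= es)) {
      stop("malformed exon blocks in ", df$tx_id[i], call. = FALSE)
    }
    if (is.unsorted(es, strictly = TRUE) || any(es[-1] < ee[-length(ee)])) {
      stop("exon blocks must be sorted and disjoint in ", df$tx_id[i], call. = FALSE)
    }
    if (es[1] < df$start[i] || ee[length(ee)] > df$end[i]) {
      stop("exon blocks outside transcript span in ", df$tx_id[i], call. = FALSE)
    }
    if (df$start[i] < 0 || df$end[i] > chrom_sizes[[df$chrom[i]]]) {
      stop("transcript ", df$tx_id[i], " outside chromosome bounds", call. = FALSE)
    }
  }
  attr(df, "chrom_sizes") <- chrom_sizes
  attr(df, "deserts") <- deserts
  class(df) <- c("transcript_annotation", "data.frame")
  df
}

#' @rdname transcript_annotation
#' @param annotation A `transcript_annotation`.
#' @export
annotation_chrom_sizes <- function(annotation) attr(annotation, "chrom_sizes")

#' Exon, intron and span intervals of an annotation
#'
#' @param annotation A `transcript_annotation`.
#' @return A [GenomicRanges::GRanges] (unstranded) with a `tx_id` metadata
#'   column; coordinates are converted from the internal 0-based half-open
#'   convention.
#' @export
annotation_exons <- function(annotation) {
  n_ex <- vapply(annotation$exon_starts, length, 1L)
  gr0(rep(annotation$chrom, n_ex),
      unlist(annotation$exon_starts, use.names = FALSE) %||% integer(0),
      unlist(annotation$exon_ends, use.names = FALSE) %||% integer(0),
      tx_id = rep(annotation$tx_id, n_ex))
}

#' @rdname annotation_exons
#' @export
annotation_introns <- function(annotation) {
  parts <- lapply(seq_len(nrow(annotation)), function(i) {
    es <- annotation$exon_starts[[i]]
    ee <- annotation$exon_ends[[i]]
    if (length(es) < 2L) {
      return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                        tx_id = character(0), stringsAsFactors = FALSE))
    }
    data.frame(chrom = annotation$chrom[i],
               start = ee[-length(ee)], end = es[-1],
               tx_id = annotation$tx_id[i], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, parts)
  if (is.null(df) || nrow(df) == 0L) {
    gr <- GenomicRanges::GRanges()
    gr$tx_id <- character(0)
    return(gr)
  }
  gr0(df$chrom, df$start, df$end, tx_id = df$tx_id)
}

#' @rdname annotation_exons
#' @export
annotation_spans <- function(annotation) {
  gr0(annotation$chrom, annotation$start, annotation$end,
      tx_id = annotation$tx_id)
}
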