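# Readers and writers for the on-disk formats. All intervals are 0-based
# half-open internally; BED-family formats share that convention, so only
# browser-style 1-based output (not used here) would need conversion.
# Numeric columns are written with enough digits to round-trip exactly.

#' Read and write FASTA sequence sets
#'
#' @param seqs Named character vector of sequences.
#' @param path File path.
#' @return `read_fasta()` returns a named character vector.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- names(x)
  out
}

# internal: TSV with header, exact numeric formatting
write_tsv_exact <- function(df, path, col.names = TRUE) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- fmt_num(out[[nm]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col.names)
  invisible(path)
}

read_tsv_checked <- function(path, col_names, numeric_cols = character(0),
                             integer_cols = character(0), header = TRUE) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = header, quote = "",
                      comment.char = "", colClasses = "character",
                      stringsAsFactors = FALSE),
    error = function(e) stop("malformed file ", path, ": ", conditionMessage(e),
                             call. = FALSE)
  )
  if (!header) names(df) <- col_names[seq_len(ncol(df))]
  missing <- setdiff(col_names, names(df))
  if (length(missing) > 0L) {
    stop("file ", path, " lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (nm in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    if (anyNA(v) && !anyNA(df[[nm]])) {
      bad <- which(is.na(v))[1]
      stop("file ", path, " line ", bad + as.integer(header),
           ": non-numeric value in column ", nm, call. = FALSE)
    }
    df[[nm]] <- v
  }
  for (nm in intersect(integer_cols, names(df))) {
    df[[nm]] <- as.integer(df[[nm]])
  }
  df
}

#' Read and write BED interval files
#'
#' Plain BED (chrom, start, end, optional name): 0-based half-open, no
#' header, tab-separated.
#'
#' @param intervals Data frame with `chrom`, `start`, `end` and optionally
#'   a name column (any of `name`, `vlinc_id`, `feature_id`).
#' @param path File path.
#' @return `read_bed()` returns a data.frame `chrom`, `start`, `end`
#'   (+ `name` when present).
#' @export
write_bed <- function(intervals, path) {
  name_col <- intersect(c("name", "vlinc_id", "feature_id"), names(intervals))[1]
  df <- intervals[, c("chrom", "start", "end")]
  if (!is.na(name_col)) df$name <- intervals[[name_col]]
  write_tsv_exact(df, path, col.names = FALSE)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "start", "end", "name"), header = FALSE,
                         integer_cols = c("start", "end"))
  df[, intersect(c("chrom", "start", "end", "name"), names(df)), drop = FALSE]
}

#' Read and write transcript models as BED12
#'
#' @param annotation A [transcript_annotation()].
#' @param path File path.
#' @param chrom_sizes Contig lengths for the reconstructed annotation.
#' @return `read_bed12()` returns a [transcript_annotation()].
#' @export
write_bed12 <- function(annotation, path) {
  n_ex <- vapply(annotation$exon_starts, length, 1L)
  sizes <- mapply(function(s, e) paste0(paste(e - s, collapse = ","), ","),
                  annotation$exon_starts, annotation$exon_ends)
  rel <- mapply(function(s, g) paste0(paste(s - g, collapse = ","), ","),
                annotation$exon_starts, annotation$start)
  df <- data.frame(chrom = annotation$chrom, start = annotation$start,
                   end = annotation$end, name = annotation$tx_id, score = 0L,
                   strand = annotation$strand, thickStart = annotation$start,
                   thickEnd = annotation$end, itemRgb = 0L, blockCount = n_ex,
                   blockSizes = unlist(sizes), blockStarts = unlist(rel),
                   stringsAsFactors = FALSE)
  write_tsv_exact(df, path, col.names = FALSE)
}

parse_int_list <- function(x) {
  lapply(strsplit(x, ",", fixed = TRUE), as.integer)
}

#' @rdname write_bed12
#' @export
read_bed12 <- function(path, chrom_sizes) {
  cols <- c("chrom", "start", "end", "name", "score", "strand", "thickStart",
            "thickEnd", "itemRgb", "blockCount", "blockSizes", "blockStarts")
  df <- read_tsv_checked(path, cols, header = FALSE,
                         integer_cols = c("start", "end", "blockCount"))
  sizes <- parse_int_list(df$blockSizes)
  rel <- parse_int_list(df$blockStarts)
  out <- data.frame(tx_id = df$name, chrom = df$chrom, strand = df$strand,
                    start = df$start, end = df$end, stringsAsFactors = FALSE)
  out$exon_starts <- mapply(function(r, g) g + r, rel, df$start, SIMPLIFY = FALSE)
  out$exon_ends <- mapply(function(es, sz) es + sz, out$exon_starts, sizes,
                          SIMPLIFY = FALSE)
  transcript_annotation(out, chrom_sizes = chrom_sizes)
}

#' Read and write transcript models as genePred-like TSV
#'
#' Columns: `tx_id`, `chrom`, `strand`, `start`, `end`, `exon_count`,
#' `exon_starts`, `exon_ends` (comma-separated absolute coordinates),
#' with a header row; coordinates 0-based half-open as in genePred.
#'
#' @param annotation A [transcript_annotation()].
#' @param path File path.
#' @param chrom_sizes Contig lengths for the reconstructed annotation.
#' @return `read_genepred()` returns a [transcript_annotation()].
#' @export
write_genepred <- function(annotation, path) {
  df <- data.frame(
    tx_id = annotation$tx_id, chrom = annotation$chrom,
    strand = annotation$strand, start = annotation$start, end = annotation$end,
    exon_count = vapply(annotation$exon_starts, length, 1L),
    exon_starts = vapply(annotation$exon_starts,
                         function(x) paste0(paste(x, collapse = ","), ","), ""),
    exon_ends = vapply(annotation$exon_ends,
                       function(x) paste0(paste(x, collapse = ","), ","), ""),
    stringsAsFactors = FALSE
  )
  write_tsv_exact(df, path)
}

#' @rdname write_genepred
#' @export
read_genepred <- function(path, chrom_sizes) {
  cols <- c("tx_id", "chrom", "strand", "start", "end", "exon_count",
            "exon_starts", "exon_ends")
  df <- read_tsv_checked(path, cols, integer_cols = c("start", "end"))
  out <- df[, c("tx_id", "chrom", "strand", "start", "end")]
  out$exon_starts <- parse_int_list(df$exon_starts)
  out$exon_ends <- parse_int_list(df$exon_ends)
  transcript_annotation(out, chrom_sizes = chrom_sizes)
}

#' Read and write density tracks as bedGraph
#'
#' Zero-density runs are omitted on write (standard bedGraph practice);
#' the reader reconstructs them from `chrom_sizes`, so a write/read round
#' trip preserves every value exactly.
#'
#' @param track Numeric RleList from [density_track()].
#' @param path File path.
#' @param chrom_sizes Named contig lengths used to restore zero runs.
#' @return `read_bedgraph()` returns a numeric RleList.
#' @export
write_bedgraph <- function(track, path) {
  parts <- lapply(names(track), function(chrom) {
    rle <- track[[chrom]]
    ir <- IRanges::IRanges(start = cumsum(c(1L, S4Vectors::runLength(rle)))[
      seq_along(S4Vectors::runLength(rle))],
      width = S4Vectors::runLength(rle))
    v <- S4Vectors::runValue(rle)
    keep <- v != 0
    data.frame(chrom = rep(chrom, sum(keep)), start = IRanges::start(ir)[keep] - 1L,
               end = IRanges::end(ir)[keep], value = v[keep],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, parts)
  write_tsv_exact(df, path, col.names = FALSE)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path, chrom_sizes) {
  df <- read_tsv_checked(path, c("chrom", "start", "end", "value"), header = FALSE,
                         integer_cols = c("start", "end"),
                         numeric_cols = "value")
  tracks <- lapply(names(chrom_sizes), function(chrom) {
    sub <- df[df$chrom == chrom, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    size <- chrom_sizes[[chrom]]
    lens <- integer(0)
    vals <- numeric(0)
    prev_end <- 0L
    for (i in seq_len(nrow(sub))) {
      if (sub$start[i] > prev_end) {
        lens <- c(lens, sub$start[i] - prev_end); vals <- c(vals, 0)
      }
      lens <- c(lens, sub$end[i] - sub$start[i]); vals <- c(vals, sub$value[i])
      prev_end <- sub$end[i]
    }
    if (prev_end < size) { lens <- c(lens, size - prev_end); vals <- c(vals, 0) }
    S4Vectors::Rle(values = vals, lengths = lens)
  })
  names(tracks) <- names(chrom_sizes)
  methods::as(tracks, "RleList")
}

#' Read and write alignment record tables
#'
#' The native interchange format: a TSV with header carrying at least
#' `read_id`, `chrom`, `start`, `tag`, `ref` (gapped display strings, so
#' the scoring formula is auditable from the file). Any additional scoring
#' columns present are preserved.
#'
#' @param alignments Alignment table.
#' @param path File path.
#' @return `read_alignments()` returns the table.
#' @export
write_alignments <- function(alignments, path) {
  write_tsv_exact(alignments, path)
}

#' @rdname write_alignments
#' @export
read_alignments <- function(path) {
  df <- read_tsv_checked(path, c("read_id", "chrom", "start", "tag", "ref"),
                         integer_cols = c("start", "end", "tag_length",
                                          "n_matches", "n_errors", "raw_score",
                                          "n_best_placements"),
                         numeric_cols = "normalized_score")
  df
}

#' Import a minimal SAM subset as alignment records
#'
#' Read-only support for mapped, single-end SAM records: each mapped line
#' is converted to an alignment record by expanding its CIGAR (M/=/X, I,
#' D, S and H operations) against the supplied genome, reconstructing the
#' gapped tag/reference display strings used by the scorer.
#'
#' @param path SAM file path.
#' @param genome Named character vector of contig sequences.
#' @return Alignment table (`read_id`, `chrom`, `start`, `tag`, `ref`).
#' @export
read_sam <- function(path, genome) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  out <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) stop("malformed SAM line ", k, call. = FALSE)
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0L) next  # unmapped
    chrom <- f[3]
    pos0 <- as.integer(f[4]) - 1L
    cigar <- f[6]
    seq <- f[10]
    ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
    qi <- 0L
    ri <- pos0
    tg <- character(0)
    rg <- character(0)
    for (op in ops) {
      n <- as.integer(sub("[A-Z=]$", "", op))
      code <- sub("^[0-9]+", "", op)
      if (code %in% c("M", "=", "X")) {
        tg <- c(tg, substring(seq, qi + 1L, qi + n))
        rg <- c(rg, substring(genome[[chrom]], ri + 1L, ri + n))
        qi <- qi + n; ri <- ri + n
      } else if (code == "I") {
        tg <- c(tg, substring(seq, qi + 1L, qi + n))
        rg <- c(rg, strrep("-", n))
        qi <- qi + n
      } else if (code %in% c("D", "N")) {
        tg <- c(tg, strrep("-", n))
        rg <- c(rg, substring(genome[[chrom]], ri + 1L, ri + n))
        ri <- ri + n
      } else if (code == "S") {
        qi <- qi + n  # soft clip: not part of the alignment
      } # H, P consume nothing here
    }
    out[[k]] <- data.frame(read_id = f[1], chrom = chrom, start = pos0,
                           tag = paste(tg, collapse = ""),
                           ref = paste(rg, collapse = ""),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(read_id = character(0), chrom = character(0),
                      start = integer(0), tag = character(0), ref = character(0),
                      stringsAsFactors = FALSE)
  }
  row.names(out) <- NULL
  out
}

#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Values that look
#' numeric are converted; comma-separated values become vectors.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_config_file <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], regexec("^([^=]+)=(.*)$", lines[i]))[[1]]
    if (length(m) != 3L) stop("malformed config line ", i, ": ", lines[i],
                              call. = FALSE)
    key <- trimws(m[2])
    val <- trimws(strsplit(m[3], ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!anyNA(num)) num else val
  }
  out
}
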