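#' Rank features by expression within each sample
#'
#' Descending competition ranks per sample: ties share the best rank and
#' the next rank skips (counts `[10, 5, 5, 1]` rank `[1, 2, 2, 4]`).
#' Features absent from a sample count as zero expression. Ranking a vlinc
#' within the combined vlinc + gene universe is the same call on the
#' row-bound expression matrix.
#'
#' @param expression Numeric matrix, features x samples (rownames =
#'   feature ids). `NA` entries are treated as 0.
#' @return Integer matrix of the same shape holding per-sample ranks.
#' @export
rank_features <- function(expression) {
  expression[is.na(expression)] <- 0
  apply(expression, 2L, function(x) rank(-x, ties.method = "min"))
}

#' Summarize ranks of selected features across a sample group
#'
#' @param ranks Rank matrix from [rank_features()].
#' @param feature_ids Features (rownames) to summarize.
#' @param samples Columns forming the group.
#' @return Data frame: `feature_id`, `average_rank`, `minimum_rank` over
#'   the group.
#' @export
group_rank_summary <- function(ranks, feature_ids, samples) {
  sub <- ranks[feature_ids, samples, drop = FALSE]
  data.frame(feature_id = feature_ids,
             average_rank = rowMeans(sub),
             minimum_rank = apply(sub, 1L, min),
             stringsAsFactors = FALSE)
}

#' Tumour/normal fold ratio of maximal normalized counts
#'
#' For each feature, the ratio of the maximal normalized count over the
#' tumour samples to the maximal normalized count over the normal samples,
#' with a pseudocount added to both maxima to guard zero denominators.
#' The summary reports the median ratio, counts of features enriched
#' two-fold and ten-fold in either direction, and a one-sample t-test of
#' the log2 ratios against zero.
#'
#' @param expression Numeric matrix, features x samples.
#' @param design Data frame with columns `sample` and `group`
#'   (`"tumour"`/`"normal"`); every expression column must be labelled.
#' @param pseudocount Added to both maxima (default 1 normalized read).
#' @return List with `ratios` (named per-feature vector), `median_ratio`,
#'   `n_tumour_2x`, `n_tumour_10x`, `n_normal_2x`, `n_normal_10x`, and
#'   `t_test` (the `htest` on log2 ratios).
#' @export
max_count_fold_ratio <- function(expression, design, pseudocount = 1) {
  tum <- design$sample[design$group == "tumour"]
  nor <- design$sample[design$group == "normal"]
  if (length(tum) == 0L || length(nor) == 0L) {
    stop("both tumour and normal groups must be nonempty", call. = FALSE)
  }
  max_t <- apply(expression[, tum, drop = FALSE], 1L, max)
  max_n <- apply(expression[, nor, drop = FALSE], 1L, max)
  ratios <- (max_t + pseudocount) / (max_n + pseudocount)
  lr <- log2(ratios)
  tt <- if (length(ratios) > 1L && stats::sd(lr) > 0) {
    stats::t.test(lr, mu = 0)
  } else NULL
  list(ratios = ratios,
       median_ratio = stats::median(ratios),
       n_tumour_2x = sum(ratios >= 2),
       n_tumour_10x = sum(ratios >= 10),
       n_normal_2x = sum(ratios <= 1 / 2),
       n_normal_10x = sum(ratios <= 1 / 10),
       t_test = tt)
}

#' Pairwise Spearman correlations with a quartile expression filter
#'
#' When the filter is on, features are sorted by total expression summed
#' across samples and only the top two quartiles (Q1-Q2, the top 50%) are
#' retained before correlating — avoiding correlation inflation from
#' features expressed in no sample. A constant expression vector has no
#' defined rank correlation; such pairs are reported as `NA`.
#'
#' @param expression Numeric matrix, features x samples.
#' @param quartile_filter Apply the Q1-Q2 filter (default `TRUE`).
#' @return Symmetric correlation matrix (samples x samples) with unit
#'   diagonal where defined; the retained feature ids are attached as
#'   attribute `features_used`.
#' @export
spearman_matrix <- function(expression, quartile_filter = TRUE) {
  if (ncol(expression) < 2L) stop("at least two samples required", call. = FALSE)
  if (quartile_filter) {
    total <- rowSums(expression)
    keep <- order(total, decreasing = TRUE)[seq_len(ceiling(nrow(expression) / 2))]
    expression <- expression[sort(keep), , drop = FALSE]
  }
  mat <- suppressWarnings(stats::cor(expression, method = "spearman"))
  # constant vectors yield NA (undefined), but a sample against itself is 1
  diag(mat)[!is.na(diag(mat))] <- 1
  attr(mat, "features_used") <- rownames(expression)
  mat
}

#' Classify sample pairs for group-averaged correlations
#'
#' @param design Data frame with columns `sample`, `group`
#'   (`"tumour"`/`"normal"`), and optional `patient` and `type` (tumour
#'   subtype, e.g. to separate a cell line from a tumour family).
#' @return Data frame of unordered sample pairs with a `class` column:
#'   `same_patient`, `different_patient` (same tumour type),
#'   `tumour_vs_other_tumour`, `tumour_vs_normal`, `normal_vs_normal`.
#' @export
classify_sample_pairs <- function(design) {
  n <- nrow(design)
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  a <- design[idx[, 1L], ]
  b <- design[idx[, 2L], ]
  cls <- character(nrow(idx))
  both_t <- a$group == "tumour" & b$group == "tumour"
  cls[!both_t & (a$group == "tumour" | b$group == "tumour")] <- "tumour_vs_normal"
  cls[a$group == "normal" & b$group == "normal"] <- "normal_vs_normal"
  if (!is.null(design$type)) {
    same_type <- both_t & a$type == b$type
  } else {
    same_type <- both_t
  }
  cls[both_t & !same_type] <- "tumour_vs_other_tumour"
  if (!is.null(design$patient)) {
    same_pat <- !is.na(a$patient) & !is.na(b$patient) & a$patient == b$patient
  } else {
    same_pat <- rep(FALSE, nrow(idx))
  }
  cls[same_type & same_pat] <- "same_patient"
  cls[same_type & !same_pat] <- "different_patient"
  data.frame(sample_a = a$sample, sample_b = b$sample, class = cls,
             stringsAsFactors = FALSE)
}

#' Average correlations over sample-pair classes
#'
#' @param mat Correlation matrix (samples x samples, dimnames = samples).
#' @param pairs Pair classification from [classify_sample_pairs()].
#' @return Named numeric vector of mean correlations per pair class
#'   (`NA` pairs dropped from the mean).
#' @export
average_correlations <- function(mat, pairs) {
  vals <- mat[cbind(pairs$sample_a, pairs$sample_b)]
  tapply(vals, pairs$class, function(v) mean(v, na.rm = TRUE))
}

#' Overlap between two interval sets with chi-square significance
#'
#' Counts intervals of each set overlapping the other by at least
#' `min_overlap_bp` in a single pairwise intersection, measures total
#' overlapping base pairs, and tests the base-pair 2x2 contingency
#' (in/out of A x in/out of B over the universe) by chi-square without
#' continuity correction.
#'
#' @param set_a,set_b Interval data frames (`chrom`, `start`, `end`) or
#'   GRanges.
#' @param universe Interval set over which base-pair membership is counted
#'   (e.g. intergenic space).
#' @param min_overlap_bp Minimum single-pair intersection width for an
#'   interval to count as overlapping (default 1).
#' @return List: `n_a_overlapping`, `n_b_overlapping`, `overlap_bp`,
#'   `contingency` (2x2 bp matrix), `chisq_statistic`, `p_value`.
#' @export
interval_overlap <- function(set_a, set_b, universe, min_overlap_bp = 1L) {
  if (min_overlap_bp < 0) stop("min_overlap_bp must be nonnegative", call. = FALSE)
  as_gr <- function(x) {
    if (inherits(x, "GRanges")) x else gr0(x$chrom, x$start, x$end)
  }
  a <- as_gr(set_a)
  b <- as_gr(set_b)
  uni <- GenomicRanges::reduce(as_gr(universe), ignore.strand = TRUE)

  hits <- GenomicRanges::findOverlaps(a, b, ignore.strand = TRUE,
                                      minoverlap = max(1L, min_overlap_bp))
  n_a <- length(unique(S4Vectors::queryHits(hits)))
  n_b <- length(unique(S4Vectors::subjectHits(hits)))

  a_u <- GenomicRanges::intersect(GenomicRanges::reduce(a, ignore.strand = TRUE),
                                  uni, ignore.strand = TRUE)
  b_u <- GenomicRanges::intersect(GenomicRanges::reduce(b, ignore.strand = TRUE),
                                  uni, ignore.strand = TRUE)
  ab <- GenomicRanges::intersect(a_u, b_u, ignore.strand = TRUE)
  bp_ab <- sum(GenomicRanges::width(ab))
  bp_a <- sum(GenomicRanges::width(a_u))
  bp_b <- sum(GenomicRanges::width(b_u))
  bp_u <- sum(GenomicRanges::width(uni))
  tab <- matrix(c(bp_ab, bp_a - bp_ab, bp_b - bp_ab,
                  bp_u - bp_a - bp_b + bp_ab), 2L, 2L,
                dimnames = list(in_a = c("yes", "no"), in_b = c("yes", "no")))
  test <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(n_a_overlapping = n_a, n_b_overlapping = n_b, overlap_bp = bp_ab,
       contingency = tab, chisq_statistic = unname(test$statistic),
       p_value = test$p.value)
}

#' Compare interval length distributions of two sets
#'
#' @param set_a,set_b Interval data frames (`chrom`, `start`, `end`) or
#'   GRanges; both nonempty.
#' @return List with `median_a`, `median_b` (bp) and `t_test`, the Welch
#'   two-sample t-test on raw lengths.
#' @export
median_length_compare <- function(set_a, set_b) {
  len <- function(x) {
    if (inherits(x, "GRanges")) GenomicRanges::width(x) else x$end - x$start
  }
  la <- len(set_a)
  lb <- len(set_b)
  if (length(la) == 0L || length(lb) == 0L) {
    stop("both interval sets must be nonempty", call. = FALSE)
  }
  list(median_a = stats::median(la), median_b = stats::median(lb),
       t_test = stats::t.test(la, lb))
}
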