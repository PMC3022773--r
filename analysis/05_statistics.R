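#!/usr/bin/env Rscript
# Downstream statistics over the called vlincs and annotated transcripts:
# per-sample normalized expression, abundance ranking of the top vlincs
# within the combined vlinc + gene universe, tumour/normal fold ratios of
# maximal counts, Spearman correlation matrices with the Q1-Q2 expression
# filter, interval overlap against an independent domain catalogue, and a
# median-length comparison.

suppressMessages(library(vlincr))

data_dir <- "results/analysis/data"
part_dir <- "results/analysis/partition"
vlinc_dir <- "results/analysis/vlinc"
out <- "results/analysis/stats"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

design <- utils::read.table(file.path(data_dir, "design.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
cs <- utils::read.table(file.path(data_dir, "chrom.sizes"), sep = "\t")
chrom_sizes <- stats::setNames(cs$V2, cs$V1)
annotation <- read_genepred(file.path(data_dir, "annotation.genePred"),
                            chrom_sizes)
called <- read_bed(file.path(vlinc_dir, "vlinc_called.bed"))

features <- rbind(
  data.frame(feature_id = annotation$tx_id, chrom = annotation$chrom,
             start = annotation$start, end = annotation$end,
             stringsAsFactors = FALSE),
  data.frame(feature_id = called$name, chrom = called$chrom,
             start = called$start, end = called$end, stringsAsFactors = FALSE))
is_vlinc <- startsWith(features$feature_id, "vlinc")

expr <- sapply(design$sample, function(id) {
  a <- read_alignments(file.path(part_dir, paste0(id, ".classified.tsv")))
  feature_expression(features, a, nrow(a))$normalized_count
})
rownames(expr) <- features$feature_id
utils::write.table(data.frame(feature_id = rownames(expr), expr),
                   file.path(out, "expression.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

## Ranking of the leukaemia line's top vlincs, within the combined universe
ranks <- rank_features(expr)
top <- order(expr[is_vlinc, "k562"], decreasing = TRUE)[1:3]
top_ids <- rownames(expr)[is_vlinc][top]
eft <- design$sample[design$group == "tumour" & design$sample != "k562"]
normal <- design$sample[design$group == "normal"]
rank_tab <- data.frame(
  vlinc = top_ids,
  k562_rank = ranks[top_ids, "k562"],
  avg_rank_eft = group_rank_summary(ranks, top_ids, eft)$average_rank,
  min_rank_eft = group_rank_summary(ranks, top_ids, eft)$minimum_rank,
  avg_rank_normal = group_rank_summary(ranks, top_ids, normal)$average_rank,
  min_rank_normal = group_rank_summary(ranks, top_ids, normal)$minimum_rank)
utils::write.table(rank_tab, file.path(out, "top_vlinc_ranks.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
print(rank_tab, row.names = FALSE)

## Tumour/normal fold ratios of maximal normalized counts over the vlincs
fr <- max_count_fold_ratio(expr[is_vlinc, , drop = FALSE], design)
utils::write.table(data.frame(vlinc = names(fr$ratios), ratio = fr$ratios),
                   file.path(out, "fold_ratios.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("median tumour/normal fold ratio over %d vlincs: %.2f (t-test on log2 ratios p = %.2g)\n",
            length(fr$ratios), fr$median_ratio,
            if (is.null(fr$t_test)) NA else fr$t_test$p.value))
cat(sprintf("%d vlincs at >= 2x and %d at >= 10x in tumours; %d / %d the other way\n",
            fr$n_tumour_2x, fr$n_tumour_10x, fr$n_normal_2x, fr$n_normal_10x))

## Spearman correlations with the Q1-Q2 expression filter
pairs <- classify_sample_pairs(design)
for (set in c("vlinc", "gene")) {
  sub <- if (set == "vlinc") expr[is_vlinc, , drop = FALSE] else
    expr[!is_vlinc, , drop = FALSE]
  m <- spearman_matrix(sub, quartile_filter = TRUE)
  utils::write.table(data.frame(sample = rownames(m), m),
                     file.path(out, paste0("spearman_", set, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  avg <- average_correlations(m, pairs)
  cat(set, "correlation averages:\n")
  print(round(avg, 2))
}

## Overlap with an independent catalogue of chromatin-defined domains.
## No external catalogue exists for a synthetic genome, so a synthetic one
## is built: jittered fragments of half the planted domains plus unrelated
## intergenic intervals (emulating partially overlapping discoveries from a
## different assay).
planted <- read_bed(file.path(data_dir, "domains_planted.bed"))
set.seed(404)
frag <- planted[seq(1, nrow(planted), by = 2), ]
frag$start <- frag$start + sample(5000:20000, nrow(frag))
frag$end <- pmin(frag$end + sample(-30000:30000, nrow(frag)), chrom_sizes[frag$chrom])
decoys <- data.frame(chrom = "chr2",
                     start = as.integer(seq(2.45e6, 3.2e6, length.out = 4)),
                     end = as.integer(seq(2.45e6, 3.2e6, length.out = 4)) + 25000L)
catalogue <- rbind(frag[, c("chrom", "start", "end")], decoys)
write_bed(catalogue, file.path(out, "synthetic_chromatin_domains.bed"))

spans <- annotation_spans(annotation)
main <- setdiff(names(chrom_sizes), c("rDNA", "chrM"))
universe <- GenomicRanges::setdiff(
  GenomicRanges::GRanges(main, IRanges::IRanges(1, chrom_sizes[main])),
  GenomicRanges::reduce(spans), ignore.strand = TRUE)

ov <- interval_overlap(called[, c("chrom", "start", "end")], catalogue,
                       universe, min_overlap_bp = 10000L)
cat(sprintf("%d/%d called vlincs overlap %d/%d catalogue domains by >= 10 kb (chi-square %.1f, p = %.2g)\n",
            ov$n_a_overlapping, nrow(called), ov$n_b_overlapping,
            nrow(catalogue), ov$chisq_statistic, ov$p_value))

ml <- median_length_compare(called[, c("chrom", "start", "end")], catalogue)
cat(sprintf("median span: called vlincs %.0f kb vs catalogue %.0f kb (t-test p = %.2g)\n",
            ml$median_a / 1000, ml$median_b / 1000, ml$t_test$p.value))
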