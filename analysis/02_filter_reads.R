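#!/usr/bin/env Rscript
# Read QC: trim leading-T artifacts, drop reads under 25 nt, score every
# candidate placement with the (5*matches - 4*errors)/tag_length scheme,
# keep reads at normalized score >= 4.5 with a unique best placement, and
# exclude ribosomal/mitochondrial alignments. Reports the per-stage yield.

suppressMessages(library(vlincr))

data_dir <- "results/analysis/data"
out <- "results/analysis/qc"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

design <- utils::read.table(file.path(data_dir, "design.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
cs <- utils::read.table(file.path(data_dir, "chrom.sizes"), sep = "\t")
chrom_sizes <- stats::setNames(cs$V2, cs$V1)

log <- NULL
for (id in design$sample) {
  seqs <- read_fasta(file.path(data_dir, paste0(id, ".reads.fa")))
  reads <- data.frame(read_id = names(seqs), sequence = unname(seqs),
                      stringsAsFactors = FALSE)
  aln <- read_alignments(file.path(data_dir, paste0(id, ".alignments.tsv")))
  qc <- qc_pipeline(reads, aln, min_len = 25L, score_threshold = 4.5,
                    known_chroms = names(chrom_sizes))
  write_alignments(qc$informative, file.path(out, paste0(id, ".informative.tsv")))
  log <- rbind(log, data.frame(sample = id, t(qc$stage_counts)))
}
utils::write.table(log, file.path(out, "stage_counts.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

print(log, row.names = FALSE)
cat(sprintf("informative yield: %.1f%%-%.1f%% of input reads\n",
            100 * min(log$informative / log$input),
            100 * max(log$informative / log$input)))
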