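test_that("synthetic_config validates its invariants", {
  expect_s3_class(synthetic_config(), "synthetic_config")
  bad_mix <- c(ribosomal = 0.5, mitochondrial = 0.1, exonic = 0.3,
               intronic = 0.2, intergenic = 0.1)
  expect_error(synthetic_config(mixture = bad_mix), "sum to 1")
  expect_error(synthetic_config(vlinc_length_range = c(40000L, 60000L)),
               "50,000")
  expect_error(synthetic_config(chrom_sizes = c(chr1 = -5L)), "positive")
})

test_that("generate_annotation places genes within bounds and is deterministic", {
  cfg <- synthetic_config(seed = 3, chrom_sizes = c(chr1 = 1e6),
                          n_genes = 2L, exons_per_gene = c(3L, 3L),
                          mixture = c(ribosomal = 0, mitochondrial = 0,
                                      exonic = 0.4, intronic = 0.35,
                                      intergenic = 0.25))
  anno <- generate_annotation(cfg)
  expect_equal(nrow(anno), 2L)
  expect_equal(sum(vapply(anno$exon_starts, length, 1L)), 6L)
  expect_true(all(anno$start >= 0 & anno$end <= 1e6))
  for (i in 1:2) {
    es <- anno$exon_starts[[i]]
    ee <- anno$exon_ends[[i]]
    expect_false(is.unsorted(es, strictly = TRUE))
    expect_true(all(es[-1] >= ee[-length(ee)]))       # disjoint blocks
    expect_true(es[1] >= anno$start[i] && ee[3] <= anno$end[i])
  }
  # the reserved gene desert stays annotation-free
  deserts <- attr(anno, "deserts")
  expect_true(all(anno$end <= deserts$start[match(anno$chrom, deserts$chrom)]))
  expect_identical(anno, generate_annotation(cfg))

  empty <- generate_annotation(synthetic_config(n_genes = 0L))
  expect_equal(nrow(empty), 0L)
})

test_that("annotation generation fails when genes cannot fit", {
  cfg <- synthetic_config(chrom_sizes = c(chr1 = 50000L), n_genes = 50L)
  expect_error(generate_annotation(cfg), "cannot fit")
})

test_that("generated reads follow the category mixture and the seed contract", {
  mix <- c(ribosomal = 0, mitochondrial = 0, exonic = 0.4, intronic = 0.35,
           intergenic = 0.25)
  cfg <- synthetic_config(seed = 11, chrom_sizes = c(chr1 = 2e6, chr2 = 1e6),
                          n_genes = 20L, n_reads = 10000L, mixture = mix,
                          vlinc_n = 0L)
  anno <- generate_annotation(cfg)
  genome <- generate_genome(cfg)
  out <- generate_reads(anno, cfg, genome)
  frac <- prop.table(table(factor(out$truth$category, names(mix))))
  for (cat in c("exonic", "intronic", "intergenic")) {
    se <- sqrt(mix[[cat]] * (1 - mix[[cat]]) / cfg$n_reads)
    expect_lt(abs(frac[[cat]] - mix[[cat]]), 3 * se)
  }
  expect_identical(out, generate_reads(anno, cfg, genome))

  # ground-truth intervals lie within chromosome bounds
  sizes <- cfg$chrom_sizes[out$truth$chrom]
  expect_true(all(out$truth$start >= 0 & out$truth$end <= sizes))
})

test_that("error-free reads are exact substrings of their source contig", {
  cfg <- synthetic_config(seed = 5, n_reads = 500L, error_rate = 0,
                          leading_t_rate = 0, multimap_rate = 0)
  genome <- generate_genome(cfg)
  anno <- generate_annotation(cfg)
  out <- generate_reads(anno, cfg, genome)
  extracted <- unname(substring(genome[out$truth$chrom], out$truth$start + 1L,
                                out$truth$end))
  # trimming eats genuine leading Ts, so compare against the trimmed window
  expect_identical(trim_leading_t(out$reads$sequence),
                   trim_leading_t(extracted))
  expect_identical(gsub("-", "", out$alignments$tag, fixed = TRUE),
                   trim_leading_t(out$reads$sequence))
})

test_that("deletions dominate the error profile as configured", {
  cfg <- synthetic_config(seed = 9, n_reads = 4000L, error_rate = 0.05,
                          leading_t_rate = 0, multimap_rate = 0)
  out <- generate_reads(generate_annotation(cfg), cfg)
  tag_gaps <- sum(lengths(gregexpr("-", out$alignments$tag, fixed = TRUE)) *
                    grepl("-", out$alignments$tag, fixed = TRUE))
  ref_gaps <- sum(lengths(gregexpr("-", out$alignments$ref, fixed = TRUE)) *
                    grepl("-", out$alignments$ref, fixed = TRUE))
  sc <- score_alignment(out$alignments$tag, out$alignments$ref)
  substitutions <- sum(sc$n_errors) - tag_gaps - ref_gaps
  expect_gt(tag_gaps, substitutions)   # deletion-dominant
  expect_gt(substitutions, ref_gaps)   # insertions rarest
})

test_that("leading-T artifacts appear at the configured rate", {
  cfg <- synthetic_config(seed = 13, n_reads = 5000L, leading_t_rate = 0.2,
                          error_rate = 0)
  out <- generate_reads(generate_annotation(cfg), cfg)
  # artifact or genuine leading T: at least the artifact rate, well below 1
  has_t <- startsWith(out$reads$sequence, "T")
  expect_gt(mean(has_t), 0.2)
  expect_lt(mean(has_t), 0.6)
})

test_that("planted vlinc domains are disjoint, long, and outside genes", {
  cfg <- synthetic_config(seed = 2, chrom_sizes = c(chr1 = 5e6), n_genes = 0L,
                          desert_fraction = 0.98, n_reads = 2000L,
                          mixture = c(ribosomal = 0, mitochondrial = 0,
                                      exonic = 0, intronic = 0, intergenic = 1))
  anno <- generate_annotation(cfg)
  vl <- plant_vlincs(anno, cfg, background_intergenic_count = 2000L,
                     lengths = c(60000L, 100000L, 300000L))
  expect_equal(nrow(vl$domains), 3L)
  expect_setequal(vl$domains$end - vl$domains$start, c(60000L, 100000L, 300000L))
  d <- vl$domains[order(vl$domains$start), ]
  expect_true(all(d$start[-1] >= d$end[-nrow(d)]))  # pairwise disjoint
  # the scale of the most abundant published domain is representable
  one <- plant_vlincs(anno, cfg, 2000L, lengths = 324190L)
  expect_equal(one$domains$end - one$domains$start, 324190L)
  # multiplier = 1 plants no extra signal (negative control for the caller)
  cfg1 <- synthetic_config(seed = 2, chrom_sizes = c(chr1 = 5e6), n_genes = 0L,
                           desert_fraction = 0.98, vlinc_multiplier = 1,
                           mixture = c(ribosomal = 0, mitochondrial = 0,
                                       exonic = 0, intronic = 0, intergenic = 1))
  none <- plant_vlincs(anno, cfg1, 2000L, lengths = 60000L)
  expect_equal(nrow(none$reads), 0L)

  # pre-chosen domains are honoured as given, and their reads stay inside
  given <- data.frame(vlinc_id = "vlinc_x", chrom = "chr1",
                      start = 100000L, end = 200000L, stringsAsFactors = FALSE)
  vx <- plant_vlincs(anno, cfg, 2000L, domains = given)
  expect_identical(vx$domains, given)
  expect_true(all(vx$truth$start >= 100000L & vx$truth$end <= 200000L))
  expect_error(plant_vlincs(anno, cfg, 2000L,
                            domains = transform(given, end = 140000L)),
               "50,000")
})

test_that("planting fails without enough annotation-free space", {
  cfg <- synthetic_config(seed = 2, chrom_sizes = c(chr1 = 3e5), n_genes = 0L)
  anno <- generate_annotation(cfg)
  expect_error(plant_vlincs(anno, cfg, 100L, lengths = c(200000L, 200000L)),
               "insufficient intergenic space")
})

test_that("planted domains raise within-domain density by the multiplier", {
  cfg <- synthetic_config(seed = 21, n_reads = 20000L)
  s <- simulate_sample(cfg)
  dom <- s$domains
  expect_true(nrow(dom) >= 1L)
  planted_reads <- sum(s$truth$planted)
  bg <- s$truth[!s$truth$planted & s$truth$category == "intergenic", ]
  # planted read count matches (multiplier - 1) x background rate x domain bp
  spans <- annotation_spans(s$annotation)
  main <- setdiff(names(cfg$chrom_sizes), c("rDNA", "chrM"))
  intergenic_bp <- sum(cfg$chrom_sizes[main]) -
    sum(GenomicRanges::width(GenomicRanges::reduce(spans)))
  expected <- (cfg$vlinc_multiplier - 1) * nrow(bg) / intergenic_bp *
    sum(dom$end - dom$start)
  expect_lt(abs(planted_reads - expected) / expected, 0.05)
})
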