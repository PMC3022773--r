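rle_track <- function(values, lengths, chrom = "chrT") {
  out <- list(S4Vectors::Rle(values = values, lengths = lengths))
  names(out) <- chrom
  methods::as(out, "RleList")
}

test_that("caller parameters are validated", {
  p <- caller_params()
  expect_equal(p$threshold_percentile, 80)
  expect_equal(p$max_gap, 5000L)
  expect_equal(p$min_run, 50000L)
  expect_error(caller_params(threshold_percentile = 0), "between 0 and 100")
  expect_error(caller_params(max_gap = -1), "nonnegative")
  expect_error(caller_params(min_run = 0), "positive")
})

test_that("intergenic pooling sums reads across samples before normalizing", {
  anno <- toy_annotation(chrom_sizes = c(chrT = 10000L))
  aln <- classify_reads(toy_alignments("chrT", c(4500, 4600, 1100),
                                       c(4530, 4630, 1130)), anno)
  s1 <- list(alignments = aln, informative_count = 3L)
  pooled1 <- pool_intergenic_density(list(s1), anno)
  pooled2 <- pool_intergenic_density(list(s1, s1), anno)

  # identical samples: raw depth doubles, and so does the denominator
  raw1 <- as.numeric(pooled1[["chrT"]]) * 3 / 1e7
  raw2 <- as.numeric(pooled2[["chrT"]]) * 6 / 1e7
  expect_equal(raw2, 2 * raw1)

  # genic reads contribute nothing
  expect_equal(sum(raw1), 2 * 30)

  # brute-force per-base pooled sum on the toy genome
  intergenic <- aln[aln$category == "intergenic", ]
  expect_equal(as.numeric(pooled2[["chrT"]]),
               (bf_coverage(intergenic, 10000L) * 2) * 1e7 / 6)

  expect_error(pool_intergenic_density(list(), anno), "at least one sample")
  genic_only <- list(alignments = aln[aln$category != "intergenic", ],
                     informative_count = 1L)
  expect_error(pool_intergenic_density(list(genic_only), anno),
               "no intergenic reads")
})

test_that("domain calling applies threshold, gap merging and minimum run", {
  anno <- empty_annotation(c(chrT = 200000L))
  p <- caller_params()

  # single 60 kb above-threshold block
  d1 <- call_domains(rle_track(c(0, 5, 0), c(10000, 60000, 130000)), p, anno)
  expect_equal(nrow(d1), 1L)
  expect_equal(c(d1$start, d1$end), c(10000L, 70000L))
  expect_equal(d1$vlinc_id, "vlinc_1")

  # two 30 kb blocks separated by 4 kb merge into one 64 kb domain
  d2 <- call_domains(rle_track(c(0, 5, 0, 5, 0),
                               c(10000, 30000, 4000, 30000, 126000)), p, anno)
  expect_equal(nrow(d2), 1L)
  expect_equal(d2$end - d2$start, 64000L)

  # the same two blocks separated by 6 kb stay apart and fail MinRun
  d3 <- call_domains(rle_track(c(0, 5, 0, 5, 0),
                               c(10000, 30000, 6000, 30000, 124000)), p, anno)
  expect_equal(nrow(d3), 0L)

  # a lone 40 kb block is below MinRun
  d4 <- call_domains(rle_track(c(0, 5, 0), c(10000, 40000, 150000)), p, anno)
  expect_equal(nrow(d4), 0L)

  # a chromosome with no positive density yields no domains, not an error
  d5 <- call_domains(rle_track(0, 200000), p, anno)
  expect_equal(nrow(d5), 0L)
})

test_that("the per-chromosome threshold is the nearest-rank percentile of positive values", {
  anno <- empty_annotation(c(chrT = 300000L))
  # positive bases: 70 kb at 1 and 10 kb at 9 -> the 80th percentile (rank
  # 64,000 of 80,000) is 1, so both blocks pass and merge through the 3 kb gap
  track <- rle_track(c(0, 1, 0, 9, 0), c(1000, 70000, 3000, 10000, 216000))
  d <- call_domains(track, caller_params(), anno)
  expect_equal(nrow(d), 1L)
  expect_equal(d$end - d$start, 83000L)
  # at the 95th percentile (rank 76,000) the threshold is 9: only the
  # 10 kb block survives thresholding and MinRun then rejects it
  d95 <- call_domains(track, caller_params(threshold_percentile = 95), anno)
  expect_equal(nrow(d95), 0L)
})

test_that("called domains are clipped against transcript spans", {
  cs <- c(chrT = 300000L)
  df <- data.frame(tx_id = "tx_g", chrom = "chrT", strand = "+",
                   start = 70000L, end = 74000L, stringsAsFactors = FALSE)
  df$exon_starts <- list(c(70000L, 73000L))
  df$exon_ends <- list(c(70500L, 74000L))
  anno <- transcript_annotation(df, chrom_sizes = cs)
  # 130 kb above-threshold run crossing the gene: clipped into 60 kb + 66 kb
  d <- call_domains(rle_track(c(0, 5, 0), c(10000, 130000, 160000)),
                    caller_params(), anno)
  expect_equal(nrow(d), 2L)
  expect_equal(d$end[1], 70000L)
  expect_equal(d$start[2], 74000L)
  dom_gr <- GenomicRanges::GRanges("chrT", IRanges::IRanges(d$start + 1L, d$end))
  expect_true(all(GenomicRanges::countOverlaps(dom_gr,
                                               annotation_spans(anno)) == 0L))
})

test_that("domain invariants hold under fuzzing and parameters act monotonically", {
  anno <- empty_annotation(c(chrT = 1000000L))
  withr::with_seed(55, {
    for (trial in 1:20) {
      n_runs <- sample(20:50, 1)
      lens <- sample(500:15000, n_runs, replace = TRUE)
      lens <- c(lens, 1000000L - sum(lens))
      vals <- c(round(stats::runif(n_runs, 0, 4), 2), 0)
      track <- rle_track(vals, lens)
      p <- caller_params()
      d <- call_domains(track, p, anno)
      if (nrow(d) > 0L) {
        expect_true(all(d$end - d$start >= p$min_run))
        d <- d[order(d$start), ]
        expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
      }
      # deterministic given density and params
      expect_identical(d, call_domains(track, p, anno))
      # raising min_run never adds domains
      d_hi <- call_domains(track, caller_params(min_run = 80000L), anno)
      expect_lte(nrow(d_hi), nrow(d))
      # raising max_gap never splits a domain: every domain called at the
      # smaller gap lies within a single domain called at the larger gap
      d_gap <- call_domains(track, caller_params(max_gap = 20000L), anno)
      if (nrow(d) > 0L) {
        for (i in seq_len(nrow(d))) {
          expect_true(any(d_gap$start <= d$start[i] & d_gap$end >= d$end[i]))
        }
      }
    }
  })
})

test_that("recover_planted reports Jaccard overlap of called vs planted", {
  dom <- data.frame(chrom = "chrT", start = c(10000L, 200000L),
                    end = c(80000L, 260000L), stringsAsFactors = FALSE)
  self <- recover_planted(dom, dom)
  expect_equal(self$pairs$jaccard, c(1, 1))
  expect_equal(self$mean_jaccard, 1)
  expect_length(self$unmatched_planted, 0L)

  shifted <- transform(dom, start = start + 500000L, end = end + 500000L)
  disj <- recover_planted(shifted, dom)
  expect_equal(nrow(disj$pairs), 0L)
  expect_equal(disj$mean_jaccard, 0)
  expect_length(disj$unmatched_planted, 2L)

  half <- data.frame(chrom = "chrT", start = 10000L, end = 45000L,
                     stringsAsFactors = FALSE)
  partial <- recover_planted(half, dom[1, ])
  expect_equal(partial$pairs$jaccard, 35000 / 70000)
})
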