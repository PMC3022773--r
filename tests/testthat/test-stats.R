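test_that("feature ranking uses descending competition ranks", {
  expr <- matrix(c(10, 5, 5, 1), ncol = 1,
                 dimnames = list(paste0("f", 1:4), "s1"))
  expect_equal(unname(rank_features(expr)[, 1]), c(1L, 2L, 2L, 4L))

  single <- matrix(3, 1, 2, dimnames = list("f1", c("s1", "s2")))
  expect_true(all(rank_features(single) == 1L))

  # missing (NA) expression counts as zero
  na_expr <- matrix(c(4, NA, 2), ncol = 1,
                    dimnames = list(paste0("f", 1:3), "s1"))
  expect_equal(unname(rank_features(na_expr)[, 1]), c(1L, 3L, 2L))

  withr::with_seed(77, {
    for (trial in 1:10) {
      x <- sample(0:20, 30, replace = TRUE)
      m <- matrix(x, ncol = 1, dimnames = list(paste0("f", 1:30), "s"))
      expect_equal(unname(rank_features(m)[, 1]), bf_rank(x))
    }
  })
})

test_that("group rank summaries average and minimize across samples", {
  expr <- matrix(c(10, 1, 2, 8, 1, 9), nrow = 2,
                 dimnames = list(c("v1", "g1"), c("s1", "s2", "s3")))
  rk <- rank_features(expr)
  gs <- group_rank_summary(rk, "v1", c("s1", "s2", "s3"))
  expect_equal(gs$average_rank, mean(c(1, 2, 2)))
  expect_equal(gs$minimum_rank, 1)
})

test_that("tumour/normal fold ratios follow maxima with a pseudocount guard", {
  expr <- matrix(c(5, 10, 3, 2, 1), nrow = 1,
                 dimnames = list("v1", paste0("s", 1:5)))
  design <- data.frame(sample = paste0("s", 1:5),
                       group = c("tumour", "tumour", "tumour", "normal", "normal"),
                       stringsAsFactors = FALSE)
  fr <- max_count_fold_ratio(expr, design, pseudocount = 0)
  expect_equal(unname(fr$ratios), 10 / 2)

  flat <- matrix(rep(4, 10), nrow = 2,
                 dimnames = list(c("a", "b"), paste0("s", 1:5)))
  fr2 <- max_count_fold_ratio(flat, design)
  expect_equal(unname(fr2$ratios), c(1, 1))
  expect_equal(fr2$median_ratio, 1)
  expect_null(fr2$t_test)  # constant log-ratios: no variance to test

  # pseudocount keeps features absent in normals finite
  zero_n <- matrix(c(9, 9, 9, 0, 0), nrow = 1,
                   dimnames = list("v", paste0("s", 1:5)))
  expect_equal(unname(max_count_fold_ratio(zero_n, design)$ratios), 10)

  expect_error(max_count_fold_ratio(expr, transform(design, group = "tumour")),
               "nonempty")
})

test_that("fold ratios are invariant to global count rescaling", {
  withr::with_seed(88, {
    expr <- matrix(stats::rpois(60, 20), nrow = 10,
                   dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
    design <- data.frame(sample = paste0("s", 1:6),
                         group = rep(c("tumour", "normal"), each = 3),
                         stringsAsFactors = FALSE)
    a <- max_count_fold_ratio(expr, design, pseudocount = 0)
    b <- max_count_fold_ratio(expr * 7.5, design, pseudocount = 0)
    expect_equal(a$ratios, b$ratios)
    expect_equal(a$median_ratio, b$median_ratio)
  })
})

test_that("planted tumour enrichment is recovered in the median ratio", {
  withr::with_seed(99, {
    n_feat <- 200L
    base <- stats::rgamma(n_feat, shape = 2, rate = 0.02)
    enriched <- rep(c(TRUE, FALSE), each = n_feat / 2)
    expr <- sapply(1:6, function(s) stats::rpois(n_feat, base))
    expr[enriched, 1:4] <- sapply(1:4, function(s) {
      stats::rpois(sum(enriched), base[enriched] * 4)
    })
    dimnames(expr) <- list(paste0("f", 1:n_feat), paste0("s", 1:6))
    design <- data.frame(sample = paste0("s", 1:6),
                         group = c(rep("tumour", 4), rep("normal", 2)),
                         stringsAsFactors = FALSE)
    fr <- max_count_fold_ratio(expr, design)
    med_enriched <- stats::median(fr$ratios[enriched])
    expect_gt(med_enriched, 3)
    expect_lt(med_enriched, 6)
    expect_lt(fr$t_test$p.value, 1e-6)
  })
})

test_that("Spearman matrices are symmetric with unit diagonal and honour ties", {
  expr <- matrix(c(1, 2, 3, 4, 5,
                   1, 2, 3, 4, 5,
                   5, 4, 3, 2, 1), ncol = 3,
                 dimnames = list(paste0("f", 1:5), c("s1", "s1b", "s2")))
  m <- spearman_matrix(expr, quartile_filter = FALSE)
  expect_equal(m["s1", "s1b"], 1)
  expect_equal(m["s1", "s2"], -1)
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 1))

  withr::with_seed(111, {
    x <- sample(0:8, 5, replace = TRUE)
    y <- sample(0:8, 5, replace = TRUE)
    toy <- cbind(s1 = x, s2 = y)
    rownames(toy) <- paste0("f", 1:5)
    m2 <- spearman_matrix(toy, quartile_filter = FALSE)
    expect_equal(m2["s1", "s2"], bf_spearman(x, y))
  })

  # constant expression: undefined correlation reported as missing
  const <- cbind(s1 = c(1, 1, 1), s2 = c(1, 2, 3))
  rownames(const) <- paste0("f", 1:3)
  expect_true(is.na(spearman_matrix(const, quartile_filter = FALSE)["s1", "s2"]))
})

test_that("the quartile filter keeps the top half by summed expression", {
  expr <- matrix(c(100, 10, 1, 0,
                   90, 12, 2, 0), ncol = 2,
                 dimnames = list(paste0("f", 1:4), c("s1", "s2")))
  m <- spearman_matrix(expr, quartile_filter = TRUE)
  expect_equal(attr(m, "features_used"), c("f1", "f2"))
})

test_that("sample pairs classify into the correlation-average classes", {
  design <- data.frame(
    sample = c("eft1p", "eft1m", "eft2p", "k562", "liver", "brain"),
    group = c("tumour", "tumour", "tumour", "tumour", "normal", "normal"),
    patient = c("p1", "p1", "p2", NA, NA, NA),
    type = c("EFT", "EFT", "EFT", "leukaemia", NA, NA),
    stringsAsFactors = FALSE
  )
  pairs <- classify_sample_pairs(design)
  get <- function(a, b) {
    pairs$class[(pairs$sample_a == a & pairs$sample_b == b) |
                  (pairs$sample_a == b & pairs$sample_b == a)]
  }
  expect_equal(get("eft1p", "eft1m"), "same_patient")
  expect_equal(get("eft1p", "eft2p"), "different_patient")
  expect_equal(get("eft1p", "k562"), "tumour_vs_other_tumour")
  expect_equal(get("eft1p", "liver"), "tumour_vs_normal")
  expect_equal(get("liver", "brain"), "normal_vs_normal")

  mat <- matrix(0.5, 6, 6, dimnames = list(design$sample, design$sample))
  mat["eft1p", "eft1m"] <- mat["eft1m", "eft1p"] <- 0.9
  avg <- average_correlations(mat, pairs)
  expect_equal(unname(avg["same_patient"]), 0.9)
  expect_equal(unname(avg["tumour_vs_normal"]), 0.5)
})

test_that("interval overlap counts, base pairs and chi-square match brute force", {
  uni <- data.frame(chrom = "chrT", start = 0L, end = 1000L)
  a <- data.frame(chrom = "chrT", start = c(0L, 500L), end = c(200L, 700L))
  b <- data.frame(chrom = "chrT", start = c(100L, 800L), end = c(300L, 900L))

  ov <- interval_overlap(a, b, uni)
  expect_equal(ov$n_a_overlapping, 1L)
  expect_equal(ov$n_b_overlapping, 1L)
  expect_equal(ov$overlap_bp, 100L)
  bf <- bf_contingency(a, b, 1000L)
  expect_equal(unname(ov$contingency), bf)
  expect_equal(ov$chisq_statistic, bf_chisq(bf), tolerance = 1e-12)

  # identical sets: every interval overlaps, bp overlap is the full set
  self <- interval_overlap(a, a, uni)
  expect_equal(self$n_a_overlapping, 2L)
  expect_equal(self$overlap_bp, 400L)

  # disjoint sets: no overlap
  disj <- interval_overlap(a, data.frame(chrom = "chrT", start = 900L, end = 950L),
                           uni)
  expect_equal(disj$n_a_overlapping, 0L)
  expect_equal(disj$overlap_bp, 0L)

  # bp overlap is symmetric
  ba <- interval_overlap(b, a, uni)
  expect_equal(ba$overlap_bp, ov$overlap_bp)

  # the minimum-overlap rule gates interval counting
  strict <- interval_overlap(a, b, uni, min_overlap_bp = 150L)
  expect_equal(strict$n_a_overlapping, 0L)

  expect_error(interval_overlap(a, b, uni, min_overlap_bp = -1), "nonnegative")
})

test_that("median length comparison matches a sort-based oracle", {
  a <- data.frame(chrom = "chrT", start = c(0L, 100L, 300L),
                  end = c(10L, 120L, 330L))
  same <- median_length_compare(a, a)
  expect_equal(same$median_a, same$median_b)
  expect_gt(same$t_test$p.value, 0.99)

  long <- data.frame(chrom = "chrT", start = 0L, end = 50000L * (1:5))
  long$start <- c(0L, 0L, 0L, 0L, 0L)
  short <- data.frame(chrom = "chrT", start = 0L, end = 10000L * (1:5))
  cmp <- median_length_compare(long, short)
  expect_gt(cmp$median_a, cmp$median_b)

  withr::with_seed(123, {
    for (trial in 1:5) {
      la <- sample(1000:90000, 11)
      lb <- sample(1000:90000, 7)
      res <- median_length_compare(
        data.frame(chrom = "c", start = 0L, end = la),
        data.frame(chrom = "c", start = 0L, end = lb))
      expect_equal(res$median_a, sort(la)[6])      # middle of 11
      expect_equal(res$median_b, sort(lb)[4])     # middle of 7
    }
  })
  expect_error(median_length_compare(a[0, ], a), "nonempty")
})
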