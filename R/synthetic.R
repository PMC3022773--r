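#' Configuration for the synthetic SMS experiment generator
#'
#' Bundles and validates every knob of the synthetic-data module: genome
#' layout, gene structure, read-length and error models, the category
#' mixture, and the planted vlinc domains. Defaults emulate the read
#' properties of HeliScope-style single-molecule sequencing: short reads
#' (25-55 nt trimmed length, mean ~34), deletion-dominant errors, a
#' leading-T tailing artifact, and a read mixture dominated by ribosomal
#' RNA before exclusion.
#'
#' @param seed Integer seed; every generator call is deterministic given it.
#' @param chrom_sizes Named integer vector of contig lengths (bp). Decoy
#'   contigs named `"rDNA"` and `"chrM"` play the role of the ribosomal
#'   repeat unit and the mitochondrial genome for the exclusion filter.
#' @param n_genes Number of transcripts to place on the non-decoy contigs.
#' @param exons_per_gene Integer range `c(min, max)` of exons per transcript.
#' @param exon_length,intron_length Ranges (bp) for exon and intron sizes.
#' @param read_length_range Trimmed read length range; reads are drawn as
#'   `min + Binomial(30, 0.3)` truncated to the range (mean ~34 nt).
#' @param n_reads Number of reads per sample.
#' @param mixture Named fractions over
#'   `c("ribosomal","mitochondrial","exonic","intronic","intergenic")`
#'   summing to 1.
#' @param error_rate Per-base error probability.
#' @param deletion_fraction,insertion_fraction Fraction of errors that are
#'   deletions / insertions; the remainder are substitutions. Deletions
#'   dominate by default, as in single-molecule sequencing.
#' @param leading_t_rate Probability a read carries a leading-T artifact.
#' @param leading_t_mean Mean artifact length (geometric).
#' @param multimap_rate Probability a read is given a second, equally
#'   scoring decoy placement (exercises the unique-best filter).
#' @param desert_fraction Fraction of each non-decoy chromosome (its right
#'   end) kept free of genes: the gene desert where vlincs are planted.
#' @param vlinc_n Number of vlinc domains to plant.
#' @param vlinc_length_range Domain length range (bp); minimum 50,000.
#' @param vlinc_multiplier Within-domain read density as a multiple of the
#'   background intergenic density.
#' @return An object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(seed = 1L,
                             chrom_sizes = c(chr1 = 5e6, chr2 = 4e6, chr3 = 3e6,
                                             rDNA = 43000, chrM = 16571),
                             n_genes = 60L,
                             exons_per_gene = c(3L, 8L),
                             exon_length = c(150L, 1000L),
                             intron_length = c(500L, 20000L),
                             read_length_range = c(25L, 55L),
                             n_reads = 20000L,
                             mixture = c(ribosomal = 0.30, mitochondrial = 0.05,
                                         exonic = 0.31, intronic = 0.22,
                                         intergenic = 0.12),
                             error_rate = 0.03,
                             deletion_fraction = 0.6,
                             insertion_fraction = 0.1,
                             leading_t_rate = 0.10,
                             leading_t_mean = 3,
                             multimap_rate = 0.02,
                             desert_fraction = 0.4,
                             vlinc_n = 3L,
                             vlinc_length_range = c(60000L, 300000L),
                             vlinc_multiplier = 25) {
  chrom_sizes <- round(chrom_sizes)
  mode(chrom_sizes) <- "integer"
  cfg <- list(
    seed = as.integer(seed), chrom_sizes = chrom_sizes,
    n_genes = as.integer(n_genes), exons_per_gene = as.integer(exons_per_gene),
    exon_length = as.integer(exon_length), intron_length = as.integer(intron_length),
    read_length_range = as.integer(read_length_range), n_reads = as.integer(n_reads),
    mixture = mixture, error_rate = error_rate,
    deletion_fraction = deletion_fraction, insertion_fraction = insertion_fraction,
    leading_t_rate = leading_t_rate, leading_t_mean = leading_t_mean,
    multimap_rate = multimap_rate, desert_fraction = desert_fraction,
    vlinc_n = as.integer(vlinc_n),
    vlinc_length_range = as.integer(vlinc_length_range),
    vlinc_multiplier = vlinc_multiplier
  )
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  cats <- c("ribosomal", "mitochondrial", "exonic", "intronic", "intergenic")
  if (is.null(names(cfg$chrom_sizes)) || any(names(cfg$chrom_sizes) == "")) {
    stop("chrom_sizes must be a named vector", call. = FALSE)
  }
  if (any(cfg$chrom_sizes <= 0L)) stop("all chromosome lengths must be positive", call. = FALSE)
  if (!setequal(names(cfg$mixture), cats)) {
    stop("mixture must be named over: ", paste(cats, collapse = ", "), call. = FALSE)
  }
  if (any(cfg$mixture < 0)) stop("mixture fractions must be nonnegative", call. = FALSE)
  if (abs(sum(cfg$mixture) - 1) > 1e-9) {
    stop("mixture fractions must sum to 1 (got ", sum(cfg$mixture), ")", call. = FALSE)
  }
  if (cfg$vlinc_n > 0L && cfg$vlinc_length_range[1] < 50000L) {
    stop("vlinc lengths must be at least 50,000 bp", call. = FALSE)
  }
  if (cfg$error_rate < 0 || cfg$error_rate >= 1) stop("error_rate must lie in [0, 1)", call. = FALSE)
  if (cfg$deletion_fraction + cfg$insertion_fraction > 1) {
    stop("deletion_fraction + insertion_fraction must not exceed 1", call. = FALSE)
  }
  if (cfg$desert_fraction < 0 || cfg$desert_fraction >= 1) {
    stop("desert_fraction must lie in [0, 1)", call. = FALSE)
  }
  invisible(cfg)
}

decoy_chroms <- function(cfg) intersect(c("rDNA", "chrM"), names(cfg$chrom_sizes))
main_chroms <- function(cfg) setdiff(names(cfg$chrom_sizes), decoy_chroms(cfg))

# sample n integers uniformly from [lo, hi]; safe when lo == hi
sample_range <- function(lo, hi, n) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

sample_read_lengths <- function(cfg, n) {
  lo <- cfg$read_length_range[1]
  hi <- cfg$read_length_range[2]
  pmin(lo + stats::rbinom(n, 30L, 0.3), hi)
}

#' Generate a random genome matching a synthetic configuration
#'
#' @param config A [synthetic_config()].
#' @return Named character vector of uppercase DNA sequences, one per contig.
#' @export
generate_genome <- function(config) {
  with_seed(config$seed + 101L, {
    vapply(names(config$chrom_sizes), function(chrom) {
      n <- config$chrom_sizes[[chrom]]
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    }, character(1))
  })
}

#' Generate a transcript annotation with a reserved gene desert
#'
#' Places `n_genes` non-overlapping transcripts on the non-decoy contigs.
#' The right-most `desert_fraction` of every non-decoy chromosome is kept
#' annotation-free so that vlinc domains can be planted wholly outside
#' gene spans. All coordinates are 0-based half-open.
#'
#' @param config A [synthetic_config()].
#' @return A `transcript_annotation` data.frame (one row per transcript:
#'   `tx_id`, `chrom`, `strand`, `start`, `end` plus list columns
#'   `exon_starts`/`exon_ends`) carrying `chrom_sizes` and gene-desert
#'   intervals as attributes.
#' @export
generate_annotation <- function(config) {
  chroms <- main_chroms(config)
  deserts <- data.frame(
    chrom = chroms,
    start = as.integer(floor(config$chrom_sizes[chroms] * (1 - config$desert_fraction))),
    end = as.integer(config$chrom_sizes[chroms]),
    stringsAsFactors = FALSE, row.names = NULL
  )

  anno <- with_seed(config$seed + 202L, {
    # free space available for genes, per chromosome
    free <- lapply(chroms, function(ch) {
      cbind(start = 0L, end = deserts$start[deserts$chrom == ch])
    })
    names(free) <- chroms

    rows <- vector("list", config$n_genes)
    if (config$n_genes > 0L) {
      for (i in seq_len(config$n_genes)) {
        n_ex <- sample_range(config$exons_per_gene[1], config$exons_per_gene[2], 1L)
        ex_len <- sample_range(config$exon_length[1], config$exon_length[2], n_ex)
        in_len <- if (n_ex > 1L) {
          sample_range(config$intron_length[1], config$intron_length[2], n_ex - 1L)
        } else integer(0)
        glen <- sum(ex_len) + sum(in_len)

        # find a free interval that fits, leaving a 1 kb buffer between genes
        fits <- lapply(chroms, function(ch) {
          f <- free[[ch]]
          which(f[, "end"] - f[, "start"] >= glen + 2000L)
        })
        avail <- chroms[vapply(fits, length, 1L) > 0L]
        if (length(avail) == 0L) {
          stop("requested genes cannot fit in the non-desert genome", call. = FALSE)
        }
        ch <- if (length(avail) == 1L) avail else sample(avail, 1L)
        slot <- fits[[match(ch, chroms)]]
        j <- if (length(slot) == 1L) slot else sample(slot, 1L)
        f <- free[[ch]]
        gstart <- f[j, "start"] + 1000L +
          sample.int(f[j, "end"] - f[j, "start"] - glen - 2000L + 1L, 1L) - 1L
        gend <- gstart + glen
        # split the free interval
        free[[ch]] <- rbind(
          f[-j, , drop = FALSE],
          cbind(start = f[j, "start"], end = gstart),
          cbind(start = gend, end = f[j, "end"])
        )

        offs <- cumsum(c(0L, as.integer(rbind(ex_len, c(in_len, 0L))[, seq_len(n_ex)])))
        ex_start <- gstart + offs[seq_len(n_ex) * 2L - 1L]
        rows[[i]] <- list(
          chrom = ch, strand = sample(c("+", "-"), 1L),
          start = gstart, end = gend,
          exon_starts = as.integer(ex_start),
          exon_ends = as.integer(ex_start + ex_len)
        )
      }
    }
    rows
  })

  df <- data.frame(
    tx_id = sprintf("tx_%03d", seq_along(anno)),
    chrom = vapply(anno, `[[`, "", "chrom"),
    strand = vapply(anno, `[[`, "", "strand"),
    start = vapply(anno, `[[`, 0L, "start"),
    end = vapply(anno, `[[`, 0L, "end"),
    stringsAsFactors = FALSE
  )
  if (nrow(df) == 0L) {
    df <- data.frame(tx_id = character(0), chrom = character(0), strand = character(0),
                     start = integer(0), end = integer(0), stringsAsFactors = FALSE)
    df$exon_starts <- list()
    df$exon_ends <- list()
  } else {
    df$exon_starts <- lapply(anno, `[[`, "exon_starts")
    df$exon_ends <- lapply(anno, `[[`, "exon_ends")
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    row.names(df) <- NULL
    df$tx_id <- sprintf("tx_%03d", seq_len(nrow(df)))
  }
  transcript_annotation(df, chrom_sizes = config$chrom_sizes, deserts = deserts)
}

# --- read construction ------------------------------------------------------

# Apply the SMS error model to reference windows, returning gapped
# tag/reference display strings of equal length (no all-gap columns).
mutate_windows <- function(windows, error_rate, del_frac, ins_frac) {
  n <- length(windows)
  tag <- windows
  ref <- windows
  if (n == 0L || error_rate == 0) {
    return(list(tag = tag, ref = ref))
  }
  lens <- nchar(windows)
  n_err <- stats::rbinom(n, lens, error_rate)
  idx <- which(n_err > 0L)
  if (length(idx) == 0L) return(list(tag = tag, ref = ref))

  bases <- c("A", "C", "G", "T")
  chars <- strsplit(windows[idx], "", fixed = TRUE)
  for (k in seq_along(idx)) {
    rc <- chars[[k]]
    L <- length(rc)
    ne <- min(n_err[idx[k]], L - 1L)  # keep at least one tag base
    pos <- sort(sample.int(L, ne))
    type <- sample(c("del", "ins", "sub"), ne, replace = TRUE,
                   prob = c(del_frac, ins_frac, 1 - del_frac - ins_frac))
    tg <- as.list(rc)
    rf <- as.list(rc)
    for (e in seq_len(ne)) {
      p <- pos[e]
      if (type[e] == "del") {
        tg[[p]] <- "-"
      } else if (type[e] == "sub") {
        tg[[p]] <- sample(setdiff(bases, rc[p]), 1L)
      } else { # insertion: extra tag base aligned to a reference gap before p
        tg[[p]] <- c(sample(bases, 1L), rc[p])
        rf[[p]] <- c("-", rc[p])
      }
    }
    tag[idx[k]] <- paste(unlist(tg), collapse = "")
    ref[idx[k]] <- paste(unlist(rf), collapse = "")
  }
  list(tag = tag, ref = ref)
}

# Re-anchor a gapped alignment after leading-T trimming of the tag:
# drop leading display columns while the tag character is a T (genuine
# leading T, trimmed with the artifact) or a gap; reference bases dropped
# this way shift the genomic start.
trim_alignment_leading_t <- function(tag_g, ref_g, start) {
  need <- grepl("^[T-]", tag_g)
  if (!any(need)) return(list(tag = tag_g, ref = ref_g, start = start))
  w <- which(need)
  tg_chars <- strsplit(tag_g[w], "", fixed = TRUE)
  rf_chars <- strsplit(ref_g[w], "", fixed = TRUE)
  for (k in seq_along(w)) {
    tg <- tg_chars[[k]]
    rf <- rf_chars[[k]]
    i <- 1L
    shift <- 0L
    while (i <= length(tg) && (tg[i] == "T" || tg[i] == "-")) {
      if (rf[i] != "-") shift <- shift + 1L
      i <- i + 1L
    }
    if (i > 1L) {
      tag_g[w[k]] <- paste(tg[i:length(tg)], collapse = "")
      ref_g[w[k]] <- paste(rf[i:length(rf)], collapse = "")
      if (i > length(tg)) { tag_g[w[k]] <- ""; ref_g[w[k]] <- "" }
      start[w[k]] <- start[w[k]] + shift
    }
  }
  list(tag = tag_g, ref = ref_g, start = start)
}

# Sample read start positions uniformly within a set of intervals
# (data.frame chrom/start/end), one per requested read length.
sample_positions <- function(intervals, read_lens) {
  n <- length(read_lens)
  out_chrom <- character(n)
  out_start <- integer(n)
  if (n == 0L) return(data.frame(chrom = out_chrom, start = out_start))
  widths <- intervals$end - intervals$start
  ok <- widths >= max(read_lens)
  if (!any(ok)) stop("no interval large enough for the requested reads", call. = FALSE)
  intervals <- intervals[ok, , drop = FALSE]
  widths <- widths[ok]
  pick <- sample.int(nrow(intervals), n, replace = TRUE, prob = widths)
  span <- intervals$end[pick] - intervals$start[pick] - read_lens + 1L
  off <- floor(stats::runif(n) * span)
  data.frame(chrom = intervals$chrom[pick],
             start = as.integer(intervals$start[pick] + off),
             stringsAsFactors = FALSE)
}

# Intervals (0-based) from which each read category is drawn.
category_intervals <- function(annotation, config) {
  cs <- attr(annotation, "chrom_sizes")
  spans <- annotation_spans(annotation)
  exons <- annotation_exons(annotation)
  introns <- annotation_introns(annotation)
  main <- main_chroms(config)
  genome_gr <- gr0(main, rep(0L, length(main)), cs[main])
  intergenic <- GenomicRanges::setdiff(genome_gr, GenomicRanges::reduce(spans),
                                       ignore.strand = TRUE)
  out <- list(
    exonic = df0(exons),
    intronic = df0(introns),
    intergenic = df0(intergenic)
  )
  if ("rDNA" %in% names(cs)) {
    out$ribosomal <- data.frame(chrom = "rDNA", start = 0L, end = cs[["rDNA"]],
                                stringsAsFactors = FALSE)
  }
  if ("chrM" %in% names(cs)) {
    out$mitochondrial <- data.frame(chrom = "chrM", start = 0L, end = cs[["chrM"]],
                                    stringsAsFactors = FALSE)
  }
  out
}

# Build reads (raw sequences + true-placement alignment records + truth
# labels) at given category labels and positions.
build_reads <- function(ids, category, pos, lens, genome, config, planted = FALSE) {
  windows <- substring(genome[pos$chrom], pos$start + 1L, pos$start + lens)
  mut <- mutate_windows(windows, config$error_rate,
                        config$deletion_fraction, config$insertion_fraction)
  tag_ungapped <- gsub("-", "", mut$tag, fixed = TRUE)

  # leading-T tailing artifact on the raw sequence
  n <- length(ids)
  art <- stats::runif(n) < config$leading_t_rate
  k <- integer(n)
  if (any(art)) k[art] <- stats::rgeom(sum(art), 1 / config$leading_t_mean) + 1L
  raw <- paste0(strrep("T", k), tag_ungapped)

  # the recorded alignment corresponds to the trimmed tag
  tr <- trim_alignment_leading_t(mut$tag, mut$ref, pos$start)

  alignments <- data.frame(
    read_id = ids, chrom = pos$chrom, start = tr$start,
    tag = tr$tag, ref = tr$ref, stringsAsFactors = FALSE
  )
  truth <- data.frame(
    read_id = ids, category = category, chrom = pos$chrom,
    start = tr$start,
    end = tr$start + nchar(gsub("-", "", tr$ref, fixed = TRUE)),
    planted = rep(planted, length.out = length(ids)), stringsAsFactors = FALSE
  )
  reads <- data.frame(read_id = ids, sequence = raw, stringsAsFactors = FALSE)
  list(reads = reads, alignments = alignments, truth = truth)
}

#' Generate SMS-like reads with ground-truth labels
#'
#' Draws reads from the configured category mixture (ribosomal /
#' mitochondrial / exonic / intronic / intergenic), placing each read
#' wholly inside an interval of its category, then applies the
#' deletion-dominant error model and the leading-T artifact. A configured
#' fraction of reads receives a second, equally scoring decoy placement.
#'
#' @param annotation A `transcript_annotation` from [generate_annotation()].
#' @param config A [synthetic_config()].
#' @param genome Optional genome from [generate_genome()]; generated from
#'   `config` when omitted.
#' @return A list with `reads` (read_id, raw sequence), `alignments`
#'   (read_id, chrom, start, gapped tag/ref; one row per placement) and
#'   `truth` (read_id, true category and origin interval).
#' @export
generate_reads <- function(annotation, config, genome = NULL) {
  validate_synthetic_config(config)
  if (is.null(genome)) genome <- generate_genome(config)
  ivs <- category_intervals(annotation, config)
  with_seed(config$seed + 303L, {
    cats <- names(config$mixture)
    category <- sample(cats, config$n_reads, replace = TRUE, prob = config$mixture)
    lens <- sample_read_lengths(config, config$n_reads)
    ids <- sprintf("read_%07d", seq_len(config$n_reads))

    pos <- data.frame(chrom = character(config$n_reads),
                      start = integer(config$n_reads), stringsAsFactors = FALSE)
    for (cat in unique(category)) {
      sel <- category == cat
      if (is.null(ivs[[cat]])) {
        stop("mixture assigns mass to '", cat,
             "' but the genome has no matching region", call. = FALSE)
      }
      pos[sel, ] <- sample_positions(ivs[[cat]], lens[sel])
    }
    out <- build_reads(ids, category, pos, lens, genome, config)

    # decoy multi-mapping placements: an exact repeat elsewhere in the genome
    mm <- which(stats::runif(config$n_reads) < config$multimap_rate)
    if (length(mm) > 0L) {
      main <- main_chroms(config)
      sizes <- config$chrom_sizes[main]
      ch <- sample(main, length(mm), replace = TRUE, prob = sizes)
      maxlen <- nchar(gsub("-", "", out$alignments$ref[mm], fixed = TRUE))
      st <- as.integer(floor(stats::runif(length(mm)) * (sizes[ch] - maxlen)))
      decoys <- out$alignments[mm, , drop = FALSE]
      decoys$chrom <- ch
      decoys$start <- st
      out$alignments <- rbind(out$alignments, decoys)
      row.names(out$alignments) <- NULL
    }
    out
  })
}

#' Plant vlinc domains and their elevated intergenic read density
#'
#' Chooses pairwise-disjoint gene-desert intervals of at least 50 kb and
#' generates the extra intergenic reads needed to raise within-domain read
#' density to `vlinc_multiplier` times the background intergenic density.
#'
#' @param annotation A `transcript_annotation` with gene-desert attributes.
#' @param config A [synthetic_config()] with `vlinc_n > 0`.
#' @param background_intergenic_count Number of background intergenic reads
#'   already generated (sets the baseline density).
#' @param genome Optional genome; generated from `config` when omitted.
#' @param lengths Optional vector of exact domain lengths (bp), overriding
#'   the configured length range; must all be at least 50,000.
#' @param domains Optional data.frame (`vlinc_id`, `chrom`, `start`, `end`)
#'   of pre-chosen domains to populate instead of placing new ones —
#'   lets several samples of one experiment share identical domains while
#'   differing in multiplier.
#' @return A list with `domains` (data.frame `vlinc_id`, `chrom`, `start`,
#'   `end`) and the extra `reads`/`alignments`/`truth` tables
#'   (truth$planted is `TRUE`).
#' @export
plant_vlincs <- function(annotation, config, background_intergenic_count,
                         genome = NULL, lengths = NULL, domains = NULL) {
  validate_synthetic_config(config)
  if (!is.null(lengths) && any(lengths < 50000L)) {
    stop("vlinc lengths must be at least 50,000 bp", call. = FALSE)
  }
  if (!is.null(domains) && any(domains$end - domains$start < 50000L)) {
    stop("vlinc lengths must be at least 50,000 bp", call. = FALSE)
  }
  if (is.null(genome)) genome <- generate_genome(config)
  deserts <- attr(annotation, "deserts")
  with_seed(config$seed + 404L, {
    if (is.null(domains)) {
      lens <- if (!is.null(lengths)) as.integer(lengths) else {
        sample_range(config$vlinc_length_range[1], config$vlinc_length_range[2],
                     config$vlinc_n)
      }
      # place sequentially into desert free space, 20 kb buffer between domains
      free <- deserts
      dom <- vector("list", length(lens))
      for (i in seq_along(lens)) {
        fit <- which(free$end - free$start >= lens[i] + 40000L)
        if (length(fit) == 0L) {
          stop("insufficient intergenic space to plant the requested vlinc domains",
               call. = FALSE)
        }
        j <- if (length(fit) == 1L) fit else sample(fit, 1L)
        span <- free$end[j] - free$start[j] - lens[i] - 40000L
        st <- free$start[j] + 20000L + if (span > 0L) sample.int(span + 1L, 1L) - 1L else 0L
        dom[[i]] <- data.frame(chrom = free$chrom[j], start = st, end = st + lens[i],
                               stringsAsFactors = FALSE)
        free <- rbind(free[-j, , drop = FALSE],
                      data.frame(chrom = free$chrom[j], start = free$start[j], end = st,
                                 stringsAsFactors = FALSE),
                      data.frame(chrom = free$chrom[j], start = st + lens[i],
                                 end = free$end[j], stringsAsFactors = FALSE))
      }
      domains <- do.call(rbind, dom)
      domains <- domains[order(domains$chrom, domains$start), , drop = FALSE]
      row.names(domains) <- NULL
      domains <- cbind(vlinc_id = sprintf("vlinc_%d", seq_len(nrow(domains))), domains,
                       stringsAsFactors = FALSE)
    }

    # background intergenic per-base density sets the baseline
    ivs <- category_intervals(annotation, config)
    intergenic_bp <- sum(ivs$intergenic$end - ivs$intergenic$start)
    lambda <- background_intergenic_count / intergenic_bp
    extra_per_domain <- round((config$vlinc_multiplier - 1) * lambda *
                                (domains$end - domains$start))

    n_extra <- sum(extra_per_domain)
    if (n_extra > 0L) {
      rl <- sample_read_lengths(config, n_extra)
      dom_idx <- rep(seq_len(nrow(domains)), extra_per_domain)
      span <- domains$end[dom_idx] - domains$start[dom_idx] - rl
      st <- as.integer(domains$start[dom_idx] + floor(stats::runif(n_extra) * span))
      ids <- sprintf("vread_%07d", seq_len(n_extra))
      out <- build_reads(ids, rep("intergenic", n_extra),
                         data.frame(chrom = domains$chrom[dom_idx], start = st,
                                    stringsAsFactors = FALSE),
                         rl, genome, config, planted = TRUE)
    } else {
      out <- build_reads(character(0), character(0),
                         data.frame(chrom = character(0), start = integer(0)),
                         integer(0), genome, config)
    }
    c(list(domains = domains), out)
  })
}

#' Simulate one complete SMS sample
#'
#' Composes [generate_genome()], [generate_annotation()],
#' [generate_reads()] and [plant_vlincs()] into a single deterministic
#' sample with ground truth.
#'
#' @param config A [synthetic_config()].
#' @param annotation,genome Optionally reuse a shared annotation/genome
#'   (several samples of one experiment share both).
#' @return A list: `config`, `genome`, `annotation`, `domains`, `reads`,
#'   `alignments`, `truth`.
#' @export
simulate_sample <- function(config, annotation = NULL, genome = NULL) {
  if (is.null(genome)) genome <- generate_genome(config)
  if (is.null(annotation)) annotation <- generate_annotation(config)
  base <- generate_reads(annotation, config, genome)
  if (config$vlinc_n > 0L) {
    n_bg <- sum(base$truth$category == "intergenic")
    vl <- plant_vlincs(annotation, config, n_bg, genome)
    base$reads <- rbind(base$reads, vl$reads)
    base$alignments <- rbind(base$alignments, vl$alignments)
    base$truth <- rbind(base$truth, vl$truth)
    domains <- vl$domains
  } else {
    domains <- data.frame(vlinc_id = character(0), chrom = character(0),
                          start = integer(0), end = integer(0),
                          stringsAsFactors = FALSE)
  }
  list(config = config, genome = genome, annotation = annotation,
       domains = domains, reads = base$reads, alignments = base$alignments,
       truth = base$truth)
}
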