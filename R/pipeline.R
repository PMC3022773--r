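#' Run the end-to-end dark-matter quantification pipeline
#'
#' Wires the stages together for one or more samples: read QC and scoring,
#' exonic/intronic/intergenic partition, per-sample density tracks and
#' feature expression, pooled intergenic density and vlinc calling, and
#' (with two or more samples) expression ranking, a Spearman correlation
#' matrix and, when the design labels both groups, tumour/normal fold
#' ratios. All artifacts plus a JSON run manifest land in `out_dir`.
#'
#' @param config Named list (or path to a key-value file parsed by
#'   [read_config_file()]) with entries:
#'   \describe{
#'     \item{annotation}{path to a genePred-like TSV (see
#'       [write_genepred()]).}
#'     \item{chrom_sizes}{named contig lengths, or path to a two-column
#'       TSV `chrom<TAB>size`.}
#'     \item{samples}{character vector of sample ids.}
#'     \item{alignments.<id>}{alignment TSV per sample.}
#'     \item{reads.<id>}{optional raw-read FASTA per sample (enables the
#'       trim + minimum-length stage).}
#'     \item{group.<id>}{optional `tumour`/`normal` label per sample.}
#'     \item{min_len, score_threshold, threshold_percentile, max_gap,
#'       min_run, pseudocount}{stage parameters (defaults 25, 4.5, 80,
#'       5000, 50000, 1).}
#'     \item{out_dir}{output directory.}
#'   }
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_config_file(config)
  }
  for (req in c("annotation", "samples", "out_dir")) {
    if (is.null(config[[req]])) stop("config lacks required entry: ", req,
                                     call. = FALSE)
  }
  # every referenced input must exist before any computation starts
  paths <- c(annotation = config$annotation)
  for (id in config$samples) {
    aln <- config[[paste0("alignments.", id)]]
    if (is.null(aln)) stop("config lacks alignments for sample ", id, call. = FALSE)
    paths[paste0("alignments.", id)] <- aln
    rd <- config[[paste0("reads.", id)]]
    if (!is.null(rd)) paths[paste0("reads.", id)] <- rd
  }
  if (is.character(config$chrom_sizes) && length(config$chrom_sizes) == 1L &&
      file.exists(config$chrom_sizes)) {
    paths["chrom_sizes"] <- config$chrom_sizes
  }
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop("missing input file(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }

  if (!is.null(names(config$chrom_sizes)) && is.numeric(config$chrom_sizes)) {
    chrom_sizes <- config$chrom_sizes
  } else {
    cs <- read_tsv_checked(paths[["chrom_sizes"]], c("chrom", "size"),
                           header = FALSE, integer_cols = "size")
    chrom_sizes <- stats::setNames(cs$size, cs$chrom)
  }
  min_len <- config$min_len %||% 25L
  score_threshold <- config$score_threshold %||% 4.5
  params <- caller_params(config$threshold_percentile %||% 80,
                          config$max_gap %||% 5000L,
                          config$min_run %||% 50000L)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  annotation <- run_stage("load_annotation",
                          read_genepred(config$annotation, chrom_sizes))

  samples <- list()
  stage_counts <- list()
  summaries <- list()
  for (id in config$samples) {
    aln <- run_stage("load_alignments", read_alignments(paths[[paste0("alignments.", id)]]))
    reads <- if (paste0("reads.", id) %in% names(paths)) {
      seqs <- run_stage("load_reads", read_fasta(paths[[paste0("reads.", id)]]))
      data.frame(read_id = names(seqs), sequence = unname(seqs),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(read_id = unique(aln$read_id),
                 sequence = gsub("-", "", aln$tag[match(unique(aln$read_id), aln$read_id)],
                                 fixed = TRUE),
                 stringsAsFactors = FALSE)
    }
    qc <- run_stage("read_qc", qc_pipeline(
      reads, aln, min_len = min_len, score_threshold = score_threshold,
      known_chroms = names(chrom_sizes)))
    informative <- run_stage("classify", classify_reads(qc$informative, annotation))
    n_inf <- nrow(informative)
    summ <- run_stage("partition", partition_summary(informative, id))
    dens <- run_stage("density", density_track(informative, n_inf, chrom_sizes))
    write_alignments(informative, out(paste0(id, ".informative.tsv")))
    write_tsv_exact(summ, out(paste0(id, ".partition.tsv")))
    write_bedgraph(dens, out(paste0(id, ".density.bedGraph")))
    samples[[id]] <- list(alignments = informative, informative_count = n_inf)
    stage_counts[[id]] <- as.list(qc$stage_counts)
    summaries[[id]] <- summ
  }

  pooled <- run_stage("pool_density", pool_intergenic_density(samples, annotation))
  write_bedgraph(pooled, out("pooled_intergenic.bedGraph"))
  domains <- run_stage("call_vlinc", call_domains(pooled, params, annotation))
  write_bed(domains, out("vlinc_domains.bed"))

  # per-sample expression over transcripts + called vlincs
  features <- rbind(
    data.frame(feature_id = annotation$tx_id, chrom = annotation$chrom,
               start = annotation$start, end = annotation$end,
               stringsAsFactors = FALSE),
    data.frame(feature_id = domains$vlinc_id, chrom = domains$chrom,
               start = domains$start, end = domains$end, stringsAsFactors = FALSE)
  )
  expr <- matrix(0, nrow(features), length(samples),
                 dimnames = list(features$feature_id, names(samples)))
  for (id in names(samples)) {
    fe <- run_stage("expression", feature_expression(
      features, samples[[id]]$alignments, samples[[id]]$informative_count))
    expr[, id] <- fe$normalized_count
    write_tsv_exact(fe, out(paste0(id, ".expression.tsv")))
  }

  if (length(samples) >= 2L) {
    ranks <- rank_features(expr)
    write_tsv_exact(data.frame(feature_id = rownames(ranks), ranks,
                               stringsAsFactors = FALSE),
                    out("feature_ranks.tsv"))
    mat <- run_stage("correlation", spearman_matrix(expr))
    write_tsv_exact(data.frame(sample = rownames(mat), mat,
                               stringsAsFactors = FALSE),
                    out("spearman_matrix.tsv"))
    groups <- vapply(config$samples, function(id) {
      config[[paste0("group.", id)]] %||% NA_character_
    }, character(1))
    if (all(c("tumour", "normal") %in% groups)) {
      design <- data.frame(sample = config$samples, group = groups,
                           stringsAsFactors = FALSE)
      fr <- run_stage("fold_ratio", max_count_fold_ratio(
        expr, design, config$pseudocount %||% 1))
      write_tsv_exact(data.frame(feature_id = names(fr$ratios),
                                 ratio = unname(fr$ratios),
                                 stringsAsFactors = FALSE),
                      out("fold_ratios.tsv"))
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("vlincr")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    parameters = list(min_len = min_len, score_threshold = score_threshold,
                      threshold_percentile = params$threshold_percentile,
                      max_gap = params$max_gap, min_run = params$min_run),
    inputs = as.list(paths),
    seed = config$seed %||% NA,
    stages = c("read_qc", "classify", "partition", "density", "call_vlinc",
               "expression"),
    stage_counts = stage_counts,
    n_domains = nrow(domains)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
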