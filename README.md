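# vlincr

Most of the stable non-ribosomal, non-mitochondrial RNA in a human cell
maps outside annotated protein-coding exons. `vlincr` quantifies that
un-annotated ("dark matter") fraction from short, error-prone
single-molecule sequencing reads and locates the very long intergenic
non-coding (**vlinc**) domains — intergenic regions ≥ 50 kb with elevated
pooled read density — that account for much of it. It is written for
transcriptome analysts who want the complete pipeline as tested,
composable R functions, exercisable end to end on synthetic data with
known ground truth.

The package implements:

* **Read QC and scoring** — leading-T trimming, a 25 nt minimum length,
  alignment scoring `S = (5·matches − 4·errors) / L_tag` (errors =
  substitutions + gaps on either sequence; `L_tag` the ungapped trimmed
  read length), a normalized-score threshold (4.5 human / 4.3 fly), a
  unique-best-placement filter, and ribosomal/mitochondrial exclusion.
  Survivors are the *informative reads*, the denominator of every
  normalization. A dynamic-programming aligner under the same scoring
  serves at window scale.
* **Annotation partition** — exonic / intronic / intergenic
  classification (precedence exon > intron > intergenic, strand
  combined), relative-mass summaries, per-base density tracks in reads
  per 10 million informative, per-feature normalized expression, and an
  intron-vs-exon density screen.
* **vlinc calling** — per chromosome on pooled intergenic density:
  threshold at the 80th percentile (nearest rank) of positive per-base
  values, merge runs separated by ≤ 5 kb (MaxGap), clip against gene
  spans, report runs ≥ 50 kb (MinRun).
* **Comparative statistics** — competition ranking of vlincs among
  annotated genes, tumour/normal fold ratios of maximal counts with a
  log2 one-sample t-test, Spearman correlation matrices with a top-half
  (Q1–Q2) expression filter and group-averaged pair classes, base-pair
  interval-overlap enrichment with a chi-square contingency test, and
  median interval-length comparison.
* **Mass bookkeeping** — read mass (`35 nt × 340 g/mol / N_A ≈ 2×10⁻²⁰ g`),
  reads needed to sequence a cell's 20 pg of RNA (~10⁹, above the 10⁸
  mark), and the small share of informative RNA a polyA selection keeps
  (6.25–25%).
* **Synthetic data** — a seeded generator for genomes, annotations,
  deletion-dominant SMS-like reads with leading-T artifacts and decoy
  multi-mappings, and planted ≥ 50 kb domains at a configurable density
  multiplier, with full ground-truth labels.

## Worked example

```r
library(vlincr)

# the canonical scoring example: 31 matches, 2 errors, 32 nt tag
score_alignment("CCTCCGTGTTGTTCCAGCC-CAGTGCTCGCAGG",
                "C-TCCGTGTTGTTCCAGCCACAGTGCTCGCAGG")
#>   tag_length n_matches n_errors raw_score normalized_score
#> 1         32        31        2       147          4.59375

# simulate a sample with three planted vlinc domains, run the QC pipeline
cfg <- synthetic_config(seed = 7, n_reads = 8000)
s   <- simulate_sample(cfg)
qc  <- qc_pipeline(s$reads, s$alignments, known_chroms = names(cfg$chrom_sizes))
qc$stage_counts
#>           input      min_length score_threshold     unique_best     informative
#>            9168            9163            8442            8291            5775

inf <- classify_reads(qc$informative, s$annotation)
partition_summary(inf, "demo")
#>   sample_id   category count fraction
#> 1      demo     exonic  2329 0.403290
#> 2      demo   intronic  1517 0.262684
#> 3      demo intergenic  1929 0.334026

# call domains from intergenic density and compare with the planted truth
pooled <- pool_intergenic_density(
  list(list(alignments = inf, informative_count = nrow(inf))), s$annotation)
called <- call_domains(pooled, caller_params(), s$annotation)
called
#>   vlinc_id chrom   start     end
#> 1  vlinc_1  chr1 3733004 3890919
#> 2  vlinc_2  chr2 2764088 2946946
#> 3  vlinc_3  chr3 1888719 2038276
recover_planted(called, s$domains)$mean_jaccard
#> [1] 0.962
```

The stage counts read: 9,168 raw reads (8,000 background plus planted
domain reads), 5 lost to the 25 nt minimum after leading-T trimming,
721 to the normalized-score threshold of 4.5, 151 to multi-mapping ties,
and 2,516 ribosomal/mitochondrial reads excluded — leaving 5,775
informative reads. Of those, ~60% are non-exonic. The three called
domains recover the planted ones with a mean Jaccard of 0.96.

## The analysis workflow

Numbered drivers under `analysis/` rebuild the study's full analysis on
a nine-sample synthetic panel (six Ewing-family tumour samples from four
patients, a leukaemia cell line, two normal tissues, thirty shared
planted domains) and write their tables under `results/analysis/`:

| script | what it does |
|---|---|
| `01_simulate.R` | genome, annotation, domains, per-sample reads + ground truth |
| `02_filter_reads.R` | QC pipeline per sample, per-stage yield table |
| `03_partition.R` | exonic/intronic/intergenic fractions, density tracks, intron screen |
| `04_call_vlincs.R` | pooled tumour intergenic density → called domains vs planted |
| `05_statistics.R` | expression, rankings, fold ratios, correlations, overlaps |
| `06_mass_bookkeeping.R` | cellular RNA mass estimates |

Run them in order with `Rscript analysis/01_simulate.R` etc. after
installing the package.

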