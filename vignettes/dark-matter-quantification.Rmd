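---
title: "Quantifying dark matter RNA: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dark matter RNA: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vlincr)
```

## The problem

A large share of the stable, non-ribosomal, non-mitochondrial RNA in a
human cell maps outside annotated protein-coding exons. Measuring how
large that share is — by *relative mass*, i.e. the fraction of sequencing
reads, not the fraction of genomic bases — requires counting reads from
total RNA without amplification or polyA selection, classifying each read
against a transcript annotation, and normalizing everything to a common
denominator of *informative reads*: uniquely, confidently placed reads
that are neither ribosomal nor mitochondrial. `vlincr` implements that
quantification pipeline for short (25–55 nt), error-prone single-molecule
sequencing reads, together with a caller for very long intergenic
non-coding (vlinc) domains — intergenic regions of at least 50 kb with
elevated pooled read density — and the downstream comparative statistics:
abundance ranking, tumour/normal fold ratios, rank-correlation matrices,
interval-overlap enrichment and cellular RNA mass bookkeeping.

## Read filtering and the alignment score

Single-molecule reads of polyA-tailed cDNA begin with a poly-T artifact
and suffer deletion-dominant errors. The pipeline order is fixed:

1. trim the leading T homopolymer (`trim_leading_t()`);
2. drop reads shorter than 25 nt after trimming (`filter_min_length()`);
3. score each candidate placement as
   `raw = 5 * matches − 4 * errors`, where *errors* counts substitutions
   **and** gapped positions on either sequence, and
   `normalized = raw / tag_length` with `tag_length` the ungapped trimmed
   read length (`score_alignment()`);
4. keep placements with normalized score ≥ 4.5 (human; 4.3 for the
   fly genome) — `filter_by_normalized_score()`;
5. keep reads whose best raw score is attained by exactly one placement;
   ties discard the read (`unique_best_filter()`);
6. remove reads on the ribosomal-repeat and mitochondrial contigs, or
   overlapping a masked rRNA repeat by ≥ 1 bp (`exclude_rrna_mt()`).

The survivors are the informative reads; their count is the denominator
for every normalized quantity downstream. A perfect alignment scores
exactly 5 per base, so `normalized_score ≤ 5` always, with equality only
for error-free placements. The canonical worked case — 31 matches,
2 errors, tag length 32 — gives `(31·5 − 2·4) = 147` and
`147/32 = 4.59375`, which passes the human threshold.

`align_read()` is a dynamic-programming aligner under the same scoring
(+5 match, −4 substitution, −4 per gapped position), used at desk scale:
fitting a tag against a reference window (free reference ends) or global
end-to-end alignment. It is validated in two independent ways: against
plain recursive enumeration of all alignments for tiny pairs, and against
`Biostrings::pairwiseAlignment()` with the equivalent substitution matrix
and gap penalties for 1,000 random pairs.

## Classification and density

`classify_reads()` assigns each informative read by its aligned genomic
footprint with precedence **exon > intron > intergenic**, strand-agnostic
(reverse transcription produces spurious second strands, so both strands
are combined). A read touching even one exonic base counts as exonic;
this deflates, never inflates, the non-exonic ("dark matter") estimate.
The per-base density track is coverage depth scaled by
`1e7 / informative_count` — "reads per genomic base in 10 million
informative reads" — and feature-level expression is the count of reads
overlapping the feature interval, normalized the same way
(`density_track()`, `feature_expression()`). We interpret the density
statistic as coverage depth; a reads-starting-per-base variant would be
an alternative reading of the same description, and the brute-force
oracles in the test suite pin down which one is implemented.

## The vlinc domain caller

`call_domains()` works per chromosome on the pooled intergenic density
(`pool_intergenic_density()` pools intergenic reads across samples and
normalizes by the pooled informative total):

* **Threshold** — the 80th percentile (nearest rank) of the *positive*
  per-base density values. Restricting the percentile population to
  nonzero bases is a deliberate choice: over a mostly-zero genome the
  80th percentile of all bases would be 0 and every covered base would
  pass. The original thresholding was done interactively in a genome
  browser whose exact semantics (binning, percentile population) are not
  recoverable; our semantics are documented defaults, not a claim about
  the original run.
* **MaxGap = 5000** — above-threshold runs separated by ≤ 5 kb merge,
  gap included.
* **MinRun = 50000** — merged runs are clipped against transcript spans
  (so a merged gap crossing a gene edge cannot leak genic bases into a
  domain) and then reported if they still span ≥ 50 kb. Clipping before
  the length filter keeps the ≥ 50 kb invariant true of every reported
  domain.

Percentile by nearest rank is deterministic and interpolation-free; ids
are assigned in genome order as `vlinc_1, vlinc_2, …`. Two monotonicity
properties are enforced by tests: raising `min_run` never adds domains,
and raising `max_gap` never splits one.

The caller's operating regime matters: with mean background read spacing
well above `max_gap` and within-domain spacing well below it, planted
domains are recovered nearly exactly, while a uniform sparse background
produces no ≥ 50 kb runs. The acceptance checks run exactly that design:
a ~12 Mb three-chromosome genome, 8,000 reads (background intergenic
spacing ~8 kb), domains of 60–300 kb at 25x background density — mean
Jaccard between called and planted domains ≥ 0.95, and a matched
negative control without planted signal calling essentially nothing.
When the background spacing approaches `max_gap`, background runs start
to merge and precision degrades — the same trade-off the published
parameters face at genome scale.

## Comparative statistics

* `rank_features()` ranks features per sample by normalized count with
  descending competition ranks: ties share the best rank and the next
  rank skips (`[10, 5, 5, 1] → [1, 2, 2, 4]`), reproducible and
  order-independent. Ranking a vlinc among annotated genes is the same
  call on the row-bound expression matrix.
* `max_count_fold_ratio()` computes, per feature, (max normalized count
  over tumour samples + pseudocount) / (max over normals + pseudocount).
  The pseudocount (default 1 normalized read) keeps features absent in
  normals finite. Significance is a one-sample t-test of the log2 ratios
  against 0: ratios are strictly positive and right-skewed, so the test
  is taken on the log scale. The summary also counts features ≥ 2x and
  ≥ 10x in either direction.
* `spearman_matrix()` optionally applies the Q1–Q2 filter first: features
  are sorted by expression summed across samples and only the top 50%
  are correlated, avoiding correlation inflation from features expressed
  nowhere. Constant vectors have no defined rank correlation and are
  reported `NA`, never coerced to 0. `classify_sample_pairs()` +
  `average_correlations()` average the matrix over same-patient,
  different-patient, tumour-vs-normal and tumour-vs-other-tumour pairs.
* `interval_overlap()` counts intervals of either set overlapping the
  other by at least `min_overlap_bp` in a single pairwise intersection,
  and tests the base-pair 2x2 contingency (in/out of A x in/out of B
  over a stated universe, e.g. intergenic space) by chi-square without
  continuity correction — at base-pair resolution the nominal counts are
  enormous and the correction is immaterial.
* `median_length_compare()` reports per-set median interval lengths and
  a Welch t-test on the raw lengths.

## Mass bookkeeping

`read_mass(35)` = 35 x 340 g/mol / N~A~ ≈ 2 x 10^-20^ g: 340 g/mol is
the mean residue mass of an internal ribonucleotide monophosphate, chosen
because it reproduces the standard printed figure at one significant
digit. `reads_needed()` divides the *total* (undepleted) 20 pg of
cellular RNA by the mass of an average read — about 10^9^ reads — rather
than only the ~6% informative sub-mass (~6 x 10^7^): ribosomal RNA
cannot be physically pre-selected away read-by-read, so sequencing
through the whole pool is what a single-cell-equivalent experiment
costs, and only this reading exceeds the conventional 10^8^ bound. Both
readings are implemented in the returned list (`total_reads`,
`informative_reads`). `polya_informative_fraction()` evaluates
`yield x (1 − contamination) / informative_fraction` at the extreme
pairings of the stated ranges (1–2% yield, 50% residual ribosomal/mt
contamination, 4–8% informative fraction), giving 6.25%–25%.

## The synthetic-data generator

Every stage is testable without downloads because the generator produces
a genome, an annotation, reads and ground truth from one seed:

* **Genome** — random uniform DNA over named contigs (default
  chr1–chr3, 12 Mb total) plus two decoys: `rDNA` (43 kb, standing in
  for the ribosomal repeat unit — no real rDNA sequence is bundled) and
  `chrM` (16,571 bp). Decoys exercise the exclusion filter by name.
* **Annotation** — non-overlapping multi-exon transcripts placed outside
  a reserved gene desert (the right 40% of each chromosome), so vlinc
  domains can be planted wholly outside gene spans.
* **Reads** — drawn from a category mixture over
  ribosomal/mitochondrial/exonic/intronic/intergenic (default
  0.30/0.05/0.31/0.22/0.12, so that informative reads split roughly
  48/34/18 across exonic/intronic/intergenic, in the range reported for
  RiboMinus total RNA). Trimmed lengths are `25 + Binomial(30, 0.3)`,
  range 25–55 with mean ~34 nt — a right-skewed distribution is needed
  because a uniform 25–55 law would have mean 40, not the observed
  ~33–36. Errors occur per base at rate 0.03 with 60% deletions, 10%
  insertions, 30% substitutions (deletion-dominant, as in
  single-molecule sequencing; the true instrument error rate is not
  published, so the rate is configurable, not calibrated). 10% of reads
  carry a leading-T artifact of geometric length (mean 3); the recorded
  true alignment always corresponds to the *trimmed* tag, including
  genuine leading-T bases removed with the artifact. 2% of reads get an
  equally scoring decoy placement to exercise the unique-best filter
  (simulated at the alignment-record level, as if the genome carried an
  exact repeat).
* **Domains** — `plant_vlincs()` places pairwise-disjoint ≥ 50 kb
  intervals in the desert with 20 kb buffers and adds intergenic reads
  inside them until the within-domain density is `vlinc_multiplier`
  times the background intergenic density (default 25x — consistent
  with the most abundant of these domains ranking among the top-100
  annotated genes). A multiplier of 1 plants intervals with no signal:
  the caller's negative control.

Reads are placed wholly inside an interval of their true category, so
interior classification must agree exactly with ground truth — the tests
assert exact agreement, not merely high accuracy. Coordinates are
0-based half-open everywhere internally and in the BED-family files;
1-based browser coordinates would be converted only at I/O.

What the generator does **not** emulate: sequence-composition bias,
repeat structure and mappability (the genome is uniform random),
transcript-level expression heterogeneity beyond the planted domains,
splice-junction reads, strand asymmetries, and instrument-specific error
hotspots. Passing tests therefore demonstrate the correctness of the
algorithms under the stated read model, not the field behaviour of an
aligner on a real genome — genome-scale alignment and the original
deposited reads are explicitly out of scope.

## Numerical and I/O choices

* Percentiles: nearest rank on the weighted (run-length) population of
  positive values; no interpolation.
* All emitters write numerics with enough significant digits to
  round-trip bit-exactly (`%.15g`–`%.17g`, shortest that survives);
  bedGraph omits zero runs and the reader reconstructs them from contig
  sizes, so write-then-read is the identity on every track.
* Degenerate inputs fail loudly and early: empty informative sets,
  mixtures not summing to 1, zero-length tags, unknown contigs in
  exclusion lists, genes or domains that cannot fit. A chromosome with
  no positive density yields no domains, not an error.
* Ties: unique-best filtering drops tied reads (conservative reading of
  "unique best"); ranking uses competition ("min") ranks.
* `run_pipeline()` writes a JSON manifest (package and R versions,
  parameters, seed, inputs, per-stage read counts) sufficient to
  reproduce a run; reruns with the same config and seed are
  byte-identical.

## Problem sizes used in the checks

The test-suite and acceptance runs use deliberately desk-sized
conditions, chosen once as the package's study design: a 12 Mb
three-chromosome genome with 60 genes; 8,000 reads for domain recovery
(three planted domains, 25x background); 100,000 reads for mixture
recovery (fractions within three binomial standard errors of the
configured mixture); 1,000 random pairs of length ≤ 8 for the aligner
oracle; 1 kb universes for per-base overlap enumeration. The bundled
analysis scripts scale up to a 24 Mb genome, nine samples and thirty
planted domains. Dataset-scale published quantities (hundreds of
domains, genome-wide fractions from millions of deposited reads) are
not reproducible at this scale and are covered by these property-based
checks instead.

## Limitations

The aligner is a window-scale tool, not a genome indexer; the caller's
precision depends on pooled background sparsity relative to `max_gap`;
strand-specific classification and antisense calling are intentionally
absent (strands are combined); and transcript structure within called
domains is not inferred — the domains are spans, nothing more.
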