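---
title: "Methods: sex-chromosome scanning and SNP marker filtering from blood RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-chromosome scanning and SNP marker filtering from blood RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zwscan)
```

## Scope and model

`zwscan` analyses bulk blood RNA-seq from a two-species, two-sex bird
cohort downstream of assembly and alignment. Its inputs are the artifacts
an aligner/caller pipeline produces — a transcript FASTA, a gene × sample
read-count matrix, a VCF with per-sample total depth (DP) and alt-allele
depth (AD), a sample sheet, and a gene-to-chromosome synteny map. The
package never realigns reads; alignment and variant calling are consumed,
not reimplemented.

Three biological regularities drive the analysis:

* **No dosage compensation (ZW system).** Males are ZZ, females ZW. A
  Z-linked gene outside the pseudoautosomal region (PAR) has two male
  copies and one female copy and is expressed at ~2× in males
  (log2 M:F ≈ 1); PAR genes are diploid in both sexes (log2 M:F ≈ 0).
* **Female hemizygosity outside the PAR.** A female carries a single Z
  allele there, so she can never be heterozygous: heterozygous-SNP density
  outside the PAR is male-biased.
* **Hemoglobin dominance of blood libraries.** A few globin transcripts
  absorb a large, roughly constant fraction of every library and are
  flagged by expression share, not homology.

## Stages

### Hemoglobin accounting and depletion

A transcript is flagged when its pooled (all-sample) read share is at
least the flagging threshold (inclusive ≥). `flag_high_share_transcripts()`
defaults to 0.20 per transcript; the pipeline configuration flags at 0.05
per transcript because hemoglobin consists of two subunit transcripts that
jointly hold ~20% of a blood library — roughly 10% each — while a typical
transcript in a 6,000-gene universe holds ~0.02%, so 0.05 separates the
two populations by more than two orders of magnitude. Depletion removes
flagged rows and reports the removed total; read pairs are conserved at
every stage. Subsampling to a fixed budget is a multivariate
hypergeometric draw across (transcript, sample) cells (sequentially
composed `rhyper` draws), so each cell's expectation is
`target × cell / total` and the output total is exact. Percentages are
rounded to the nearest integer, ties away from zero, which is how
read-accounting tables are conventionally printed (17.6% prints as 18%).

### ORF discovery and SNP effects

All three frames on both strands are scanned. An ORF runs from a start
codon — or the contig edge, making it 5′-partial — to a stop codon — or
the edge, 3′-partial. Codons containing N never match start/stop and
translate to X. Amino-acid length excludes the stop codon. One deliberate
reduction: an edge-to-edge candidate with *neither* start nor stop carries
no frame signal, so only the longest such frame per strand is reported
(otherwise every frameless sequence would yield six redundant "ORFs").

The coding filter keeps the single longest ORF per transcript when its
length is **strictly** greater than 100 aa (a 100-aa ORF is rejected);
ties break complete-over-partial, then plus strand, then leftmost. A
substitution outside the retained ORF is noncoding; inside, the affected
codon is read in the ORF's frame and strand and both alleles are
translated with the standard genetic code, stop counting as an amino-acid
state (stop-gain is therefore nonsynonymous). Codons containing N are
indeterminate: reported in the noncoding bucket and excluded from
amino-acid-change counts — the conservative choice.

### SNP marker rules

All frequencies are per-individual alt-read fractions (`AD/DP`), undefined
at zero depth. The filters, with their exact boundaries:

| rule | default | boundary |
|---|---|---|
| coverage: every bird's depth | ≥ 50 reads | inclusive |
| contig variant density (within-species markers only) | < 1/200 bp | strict |
| within-species: some bird low, some bird high | < 5% and > 35% | both strict |
| species-diagnostic: every bird of one species high, every bird of the other low | > 80% and < 5% | both strict |

The coverage cohort is all 16 birds; the density cap counts variants
before coverage filtering (the cap models paralog-collapse artifacts,
which do not disappear when an individual site fails coverage). Diagnostic
calls require coverage but not the density cap. The per-bird reading of
the diagnostic rule is the default; a pooled-read mode
(`species_diagnostic(..., mode = "pooled")`) is provided because pooled
frequency is the other defensible reading. A site is never simultaneously
diagnostic and a within-species marker. `classify_sites()` evaluates all
rules vectorized; the exported single-site functions are the testable
contracts the vectorized path is checked against.

### Differential expression

Counts are quantile-normalized: every column receives the row-wise mean of
the sorted columns; tied entries within a column receive the mean of the
reference values their ranks span, so results cannot depend on the input
order of ties. The test is a per-gene negative-binomial likelihood-ratio
test of one mean versus two means with the gene's dispersion held fixed —
with fixed dispersion the NB mean MLE is the sample mean, so the fit is
closed-form — referred to χ²₁ and Benjamini–Hochberg adjusted. Dispersion
is method-of-moments, `α̂ = max(0, (s² − m)/m²)` from within-group
residuals, shrunk toward the median dispersion with weight
`n₀/(n₀ + df)`, `n₀ = 10` by default: enough to stabilize 16-sample
estimates without erasing genuine per-gene differences. The NB
log-likelihood uses the gamma-function continuous extension because
quantile-normalized counts are not integers. Fold changes use pseudocount
0.5.

Species calls require adjusted p < 0.05 **and** |log2FC| ≥ 1 (inclusive —
"at least two-fold"). Sex calls use significance alone, because a two-fold
male bias is exactly the signature of non-PAR Z linkage being tested for;
the two-fold subset is annotated in parallel. The significance criterion
is BH-adjusted p at a configurable level — the ranking statistic of any
particular DE package release is deliberately not reproduced. The sex test
pools species; species-blocked testing is a possible refinement the
package does not implement because the pooled design matches how the
sex-bias heat-map analysis is normally run.

### Sex-chromosome scan

Genes are ordered by synteny position on the Z (stable order for ties;
unmapped genes are excluded and counted). Per gene the scan computes
`log2((mean male + 0.5)/(mean female + 0.5))` on normalized counts and
per-sex heterozygous-SNP density — heterozygous means alt frequency in
[0.2, 0.8] (inclusive band) with depth ≥ 50; density is heterozygous
sample-site events per kb of transcript per individual. The band stands in
for genotype calls, which DP/AD-level input does not carry; 0.2/0.8 is
symmetric and far from both the hemizygous poles (0, 1) and binomial noise
at depth 50.

Both series are smoothed with a ten-gene moving average, centred with
offsets −5…+4 (an even window needs an asymmetry convention; this one is
stated so results are reproducible) and truncated at the ends. A gene is
non-PAR-flagged when smoothed log2 M:F > 0.5 — the midpoint of the two
expected modes at 0 and 1 — and the smoothed male/female density ratio
exceeds 1.5 (female density + ε, ε = 1e−9, guards division by zero). Runs
of ≥ 5 flagged genes become non-PAR-like regions; shorter runs are treated
as smoothing noise. Regions partition the ordered genes.

The PAR boundary is estimated by an exhaustive least-squares
single-changepoint fit on the log2 M:F series (one mean left of k, one
right; ties resolve to the smallest k). A single changepoint is the right
model for one PAR/non-PAR transition; the region caller, not the
changepoint fit, handles the possibility of interleaved strata.

## The synthetic generator

`sim_config()` defaults encode the study design the pipeline targets: two
species of 8 birds each at equal sex ratio; 300 Z-syntenic genes with the
first two-thirds (200) pseudoautosomal; male/female mean ratio 2.0 outside
the PAR; hemoglobin at 20% of every library (two subunits, 45/55 split);
NB counts at mean depth 500 reads per gene per sample with per-gene
dispersion α ~ Gamma(shape 2, mean 0.1); 10% of genes carrying a species
log2 fold change ~ N(0, 1); diagnostic SNPs at 0.5/kb and within-species
SNPs at 0.5 and 1.0/kb for the two species — unequal diversity, as between
a severely bottlenecked and a merely small population. Transcript lengths
are log-normal with ~2 kb median. Site depth equals the gene's count
(uniform coverage along the transcript — the simplest model under which
the 50-read filter is meaningfully exercised); alt depth is
Binomial(depth, dosage) with dosage 0, ½, or 1, and hemizygous females
drawing a single allele (never ½). Positions are 0-based half-open
internally and 1-based only in the VCF/BED dialects on disk; identical
configurations produce byte-identical bundles.

The autosomal background defaults to 5,700 genes so the 300 Z genes are
~5% of the transcriptome, matching the proportion seen when ~300 of ~8,000
orthologue-mapped transcripts hit the Z. This matters: quantile
normalization forces equal column distributions, so the male-specific
non-PAR excess is redistributed across all genes. With Z genes at 5% of
the universe the induced bias on log2 M:F is ≈ −0.02; in a Z-heavy toy
universe (say 30% Z) it reaches −0.12 and visibly drags the PAR mode off
zero. That shrinkage is a property of quantile normalization itself, not
of the scan.

What the generator does **not** emulate: read-level artifacts (no FASTQ,
no sequencing error model, no mapping bias), indels, alternative-splicing
isoforms (one transcript per gene), gene-length-dependent expression
biases, correlated expression between neighbouring genes, and
linkage-disequilibrium structure among SNPs. Passing recovery tests
therefore show the inference machinery is correct under the stated noise
model — not that real blood RNA-seq meets that model.

## Numerical and testing choices

* Dispersion floor 1e−8 (α below it is treated as Poisson); mean floor
  1e−8 in the NB log-likelihood; LRT statistics clipped at 0.
* The permutation oracle for the NB test uses 3-vs-3 toys with all 20
  label splits. A single gene's conditional permutation distribution has
  only 10 distinct atoms (mirror splits coincide), so per-gene p-value
  agreement below 0.1 is impossible by construction; the oracle therefore
  pools permuted statistics across the toy's null genes — the standard
  permutation null for DE statistics — and holds the mean absolute p-value
  difference to 0.05.
* Diagnostic-SNP recall is measured among planted sites that pass the
  coverage filter: a site with no usable data in some bird is outside the
  classifier's contract, exactly as real marker discovery is conditioned
  on covered sites.
* Problem sizes: unit tests run scaled-down universes (tens to hundreds of
  genes); the acceptance checks run the full 6,000-gene design with 20
  seeds for the dosage modes, 50 for boundary recovery, and 20
  (at mean depth 100, 600-gene universe) for diagnostic precision/recall.
  These sizes give Monte-Carlo error comfortably below the tolerances
  being asserted.
* Boundary-recovery error is essentially zero for mean depth ≥ 50 with 8
  birds per sex — the log2 step of 1.0 dwarfs count noise — so the
  decreases-with-depth property is only visible from the starved-coverage
  regime (depth ~1) upward, and is tested there.

## Limitations

* Hemoglobin flagging is purely expression-share-based; a transcript
  family that splits its output across many moderately expressed members
  would evade it (a user-supplied id list can be passed to `deplete()`).
* The sex test pools species; a strong species × sex interaction would
  dilute power.
* The scan assumes the synteny proxy is correct per gene; mis-mapped genes
  add noise the moving average only partly absorbs.
* The changepoint fit assumes one boundary; genuinely mosaic Z strata
  would be reported by the region caller but summarized by a single k.
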