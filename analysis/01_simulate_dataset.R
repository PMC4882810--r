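#!/usr/bin/env Rscript

# Stage 1: generate the synthetic ZW blood-transcriptome dataset.
#
# Two species, eight birds each at equal sex ratio; 300 Z-syntenic genes of
# which the first two-thirds are pseudoautosomal; two hemoglobin subunit
# transcripts absorbing ~20% of every library; negative-binomial counts at
# a mean depth of 500 reads per gene per sample; species-diagnostic and
# within-species SNPs with binomial allele depths and female hemizygosity
# outside the PAR. The bundle (FASTA + TSV counts + VCF + BED map + sample
# sheet + JSON truth) lands in results/data/.

suppressPackageStartupMessages(library(zwscan))

cfg <- sim_config(seed = 1L)
ds <- simulate_dataset(cfg)
write_dataset("results/data", ds$map, ds$counts, ds$variants, ds$sheet,
              ds$truth, ds$seqs)

cat("Simulated", nrow(ds$map), "genes x", nrow(ds$sheet), "samples;",
    nrow(ds$variants$sites), "variant sites\n")
cat("True PAR boundary at Z gene index", ds$truth$par_boundary_index, "of",
    cfg$n_z_genes, "\n")
cat("Hemoglobin transcripts:", paste(ds$truth$hemoglobin_ids, collapse = ", "),
    sprintf("(%.1f%% of counts)",
            100 * sum(ds$counts[ds$truth$hemoglobin_ids, ]) / sum(ds$counts)),
    "\n")
cat("Bundle written to results/data/\n")
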