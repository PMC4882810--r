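#!/usr/bin/env Rscript

# Stage 4: differential expression between species and between sexes.
#
# Counts are quantile-normalized, then tested per gene with a negative-
# binomial likelihood-ratio test (moment dispersion, shrunk to the common
# value). Species calls additionally require an (inclusive) two-fold
# change; sex calls use significance alone -- a two-fold male bias is the
# expected signature of non-PAR Z linkage, not a nuisance -- with the
# two-fold subset reported in parallel.

suppressPackageStartupMessages(library(zwscan))

ds <- read_dataset("results/data")
norm <- quantile_normalize(ds$counts)

sp <- sort(unique(ds$sheet$species))
res_sp <- de_test(norm, ds$sheet$sample[ds$sheet$species == sp[1]],
                  ds$sheet$sample[ds$sheet$species == sp[2]], level = 0.05)
res_sp$call <- classify_species_de(res_sp, min_fold = 2)
cat(sprintf("Species DE (adj. p < 0.05, >= 2-fold): %d genes (%d up in %s, %d up in %s)\n",
            sum(res_sp$call != "ns"), sum(res_sp$call == "up_in_A"), sp[1],
            sum(res_sp$call == "up_in_B"), sp[2]))
up <- abs(res_sp$log2_fold_change[res_sp$call != "ns"])
if (length(up)) {
  cat(sprintf("Mean |fold change| among called genes: %.1f (range %.1f-%.1f)\n",
              mean(2^up), min(2^up), max(2^up)))
}

res_sex <- de_test(norm, ds$sheet$sample[ds$sheet$sex == "M"],
                   ds$sheet$sample[ds$sheet$sex == "F"], level = 0.05)
sex_call <- classify_sex_de(res_sex)
cat(sprintf("Sex DE (no fold floor): %d genes (%d male-biased, %d female-biased; %d at >= 2-fold)\n",
            sum(sex_call$call != "ns"),
            sum(sex_call$call == "male_biased"),
            sum(sex_call$call == "female_biased"),
            sum(sex_call$call != "ns" & sex_call$twofold)))

dir.create("results", showWarnings = FALSE)
utils::write.table(res_sp, "results/de_species.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(cbind(res_sex, call = sex_call$call,
                         twofold = sex_call$twofold),
                   "results/de_sex.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
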