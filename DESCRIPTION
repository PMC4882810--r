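Package: zwscan
Title: Blood-Transcriptome Sex-Chromosome Scan and SNP Marker Pipeline for ZW Birds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Reimplements a blood-transcriptome analysis pipeline for birds
    (ZW sex determination) downstream of assembly and alignment: hemoglobin
    read accounting and depletion, open-reading-frame discovery with
    synonymous/nonsynonymous SNP effect annotation, multi-rule SNP marker
    classification (within-species and species-diagnostic), negative-binomial
    differential expression between species and sexes on quantile-normalized
    counts, and a Z-chromosome scan that infers pseudoautosomal (PAR) versus
    non-PAR regions from male-to-female expression ratios and sex-specific
    SNP density along a synteny-ordered gene map. A synthetic ZW-genome data
    generator (negative-binomial counts, binomial allele depths, female
    hemizygosity outside the PAR) makes every stage testable without
    downloads and provides ground truth for parameter-recovery checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
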